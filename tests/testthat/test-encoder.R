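test_that("encoder builds the stated shapes and is deterministic under seed", {
  cfg <- encoder_config(500L)
  model <- build_encoder(cfg, seed = 7L)
  X <- matrix(rnorm(10 * 500), 10, 500)
  out <- contraclust:::encoder_forward(model, X)$out
  expect_equal(dim(out), c(10L, 60L))

  # single affine map 2 -> 3
  small <- build_encoder(encoder_config(2L, layer_sizes = 3L,
                                        norm_after_hidden = FALSE),
                         seed = 1L)
  y <- contraclust:::encoder_forward(small, matrix(rnorm(8), 4, 2))$out
  expect_equal(dim(y), c(4L, 3L))

  # same seed, same initial function
  m1 <- build_encoder(cfg, seed = 42L)
  m2 <- build_encoder(cfg, seed = 42L)
  expect_identical(contraclust:::encoder_forward(m1, X)$out,
                   contraclust:::encoder_forward(m2, X)$out)
  expect_error(encoder_config(500L, layer_sizes = c(200L, 1L)), ">= 2")
})

test_that("parameter counting reproduces the architecture footprint", {
  expect_identical(count_parameters(encoder_config(500L)), 111180L)
  # decomposition: affine layers plus 2 x width per normalized hidden layer
  expect_identical(100200L + 400L + 8040L + 80L + 2460L, 111180L)
  expect_identical(
    count_parameters(encoder_config(500L, norm_after_hidden = FALSE)),
    110700L
  )
  expect_identical(
    count_parameters(encoder_config(2L, layer_sizes = 3L,
                                    norm_after_hidden = FALSE)),
    9L
  )
})

test_that("NT-Xent matches the brute-force oracle on random instances", {
  set.seed(99)
  for (rep in 1:50) {
    N <- sample(1:8, 1)
    e <- sample(2:6, 1)
    tau <- sample(c(0.1, 0.5, 1.0), 1)
    z <- matrix(rnorm(2 * N * e), 2 * N, e)
    expect_equal(nt_xent_loss(z, tau), oracle_nt_xent(z, tau),
                 tolerance = 1e-6)
  }
})

test_that("NT-Xent analytic cases hold exactly", {
  set.seed(5)
  # one pair, no negatives: numerator equals denominator
  expect_equal(nt_xent_loss(matrix(rnorm(6), 2, 3), 0.37), 0)
  # four identical rows: all similarities equal, loss = ln 3 for any tau
  for (tau in c(0.1, 0.5, 2)) {
    expect_equal(nt_xent_loss(matrix(1, 4, 5), tau), log(3))
  }
  # orthogonal pairs worked example
  z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(nt_xent_loss(z, 0.5), log(1 + 2 * exp(-2)))
  expect_error(nt_xent_loss(rbind(c(0, 0), c(1, 1)), 0.5), "zero norm")
  expect_error(nt_xent_loss(matrix(rnorm(9), 3, 3), 0.5), "2N rows")
})

test_that("NT-Xent is invariant to rotations and per-row positive rescaling", {
  set.seed(17)
  z <- matrix(rnorm(8 * 4), 8, 4)
  base <- nt_xent_loss(z, 0.5)
  rot <- qr.Q(qr(matrix(rnorm(16), 4, 4)))  # random orthogonal matrix
  expect_equal(nt_xent_loss(z %*% rot, 0.5), base, tolerance = 1e-10)
  z2 <- z
  z2[3, ] <- 7.3 * z2[3, ]
  expect_equal(nt_xent_loss(z2, 0.5), base, tolerance = 1e-10)
})

test_that("the analytic NT-Xent gradient matches finite differences", {
  set.seed(23)
  z <- matrix(rnorm(6 * 4), 6, 4)
  got <- contraclust:::nt_xent(z, 0.5)$grad
  eps <- 1e-6
  num <- matrix(0, nrow(z), ncol(z))
  for (i in seq_len(nrow(z))) {
    for (j in seq_len(ncol(z))) {
      zp <- z; zp[i, j] <- zp[i, j] + eps
      zm <- z; zm[i, j] <- zm[i, j] - eps
      num[i, j] <- (nt_xent_loss(zp, 0.5) - nt_xent_loss(zm, 0.5)) / (2 * eps)
    }
  }
  expect_equal(got, num, tolerance = 1e-6)
})

test_that("training reduces the contrastive loss and is reproducible", {
  sim <- tiny_sim(n_groups = 4L, cells = 25L, genes = 400L, seed = 3L)
  pm <- preprocess(sim$cm, preprocess_config(n_top_genes = 100L))
  ecfg <- encoder_config(100L, layer_sizes = c(64L, 32L))
  deltas <- numeric(3)
  for (s in 1:3) {
    tcfg <- train_config(epochs = 10L, batch_size = 50L, seed = s)
    fit <- train_encoder(pm, ecfg, tcfg)
    expect_length(fit$loss_history, 10L)
    deltas[s] <- utils::tail(fit$loss_history, 1) - fit$loss_history[1]
  }
  expect_lt(mean(deltas), 0)

  tcfg <- train_config(epochs = 4L, batch_size = 50L, seed = 11L)
  f1 <- train_encoder(pm, ecfg, tcfg)
  f2 <- train_encoder(pm, ecfg, tcfg)
  expect_identical(f1$embedding$z, f2$embedding$z)
  expect_identical(f1$loss_history, f2$loss_history)
})

test_that("the default architecture emits 60-dimensional embeddings", {
  sim <- tiny_sim(n_groups = 2L, cells = 30L, genes = 700L, seed = 5L)
  pm <- preprocess(sim$cm, preprocess_config(n_top_genes = 500L))
  fit <- train_encoder(pm, tcfg = train_config(epochs = 2L,
                                               batch_size = 30L, seed = 1L))
  expect_equal(dim(fit$embedding$z), c(60L, 60L))
  expect_equal(ncol(fit$embedding$z), 60L)
})
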