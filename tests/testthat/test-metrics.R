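test_that("ARI: identities, the -0.5 worked example, and oracle agreement", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ari(c("a", "a", "b", "b"), c("q", "q", "p", "p")), 1)
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  set.seed(41)
  for (rep in 1:10) {
    truth <- sample(1:4, 30, replace = TRUE)
    pred <- sample(1:3, 30, replace = TRUE)
    expect_equal(ari(truth, pred), oracle_ari(truth, pred),
                 tolerance = 1e-12)
    expect_equal(ari(truth, pred), mclust::adjustedRandIndex(truth, pred),
                 tolerance = 1e-12)
    expect_equal(ari(truth, pred), ari(pred, truth))  # symmetry
  }
  expect_error(ari(1:3, 1:4), "length")
})

test_that("NMI: identities, degenerate single cluster, and oracle agreement", {
  expect_equal(nmi(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(nmi(c(1, 2, 1, 2), rep(1, 4)), 0)
  set.seed(43)
  for (rep in 1:5) {
    truth <- sample(1:5, 200, replace = TRUE)
    pred <- sample(1:4, 200, replace = TRUE)
    expect_equal(nmi(truth, pred), oracle_nmi(truth, pred),
                 tolerance = 1e-10)
    expect_equal(nmi(truth, pred), nmi(pred, truth))
  }
})

test_that("silhouette: separable example, sign flip, and oracle agreement", {
  X <- matrix(c(0, 0, 10, 10), 4, 1)
  expect_equal(silhouette_score(X, c(0, 0, 1, 1)), 1)
  # swapping the labels between the two tight blobs makes it negative
  Xb <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  expect_lt(silhouette_score(Xb, c(1, 0, 0, 1)), 0)
  set.seed(47)
  X20 <- matrix(rnorm(20 * 3), 20, 3)
  lab <- sample(1:3, 20, replace = TRUE)
  expect_equal(silhouette_score(X20, lab), oracle_silhouette(X20, lab),
               tolerance = 1e-10)
  expect_error(silhouette_score(X20, rep(1, 20)), "2 <= K")
})

test_that("Calinski-Harabasz: worked example, scale invariance, oracle", {
  X <- matrix(c(0, 1, 10, 11), 4, 1)
  expect_equal(calinski_harabasz(X, c(0, 0, 1, 1)), 200)
  set.seed(53)
  X20 <- matrix(rnorm(20 * 4), 20, 4)
  lab <- sample(1:3, 20, replace = TRUE)
  val <- calinski_harabasz(X20, lab)
  expect_equal(val, oracle_calinski(X20, lab), tolerance = 1e-8)
  expect_equal(calinski_harabasz(3.7 * X20, lab), val, tolerance = 1e-8)
  # zero within-dispersion is flagged, not returned as Inf
  expect_error(calinski_harabasz(matrix(c(0, 0, 1, 1), 4, 1),
                                 c(0, 0, 1, 1)), "unbounded")
})

test_that("cluster-count error is the relative difference", {
  expect_equal(k_error(8, 4), 1)
  expect_equal(k_error(4, 4), 0)
  expect_equal(k_error(13, 11), 2 / 11)
  expect_lt(abs(k_error(13, 11) - 0.1818), 1e-3)
  expect_error(k_error(3, 0), ">= 1")
})

test_that("coefficient of variation is the sample sd over the mean", {
  expect_equal(coefficient_of_variation(c(1, 1, 1)), 0)
  expect_equal(coefficient_of_variation(c(2, 4)), stats::sd(c(2, 4)) / 3)
  set.seed(59)
  v <- rexp(10) + 1
  expect_equal(coefficient_of_variation(5 * v),
               coefficient_of_variation(v))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(3), "at least 2")
})

test_that("score_partition assembles internal and external scores", {
  blobs <- make_blobs(seed = 61L)
  part <- kmeans_cluster(blobs$emb,
                         cluster_params("kmeans", n_clusters = 2L,
                                        seed = 1L))
  sc <- score_partition(part, blobs$emb, truth = blobs$truth)
  expect_equal(sc$ari, 1)
  expect_equal(sc$nmi, 1)
  expect_equal(sc$k_error, 0)
  expect_gt(sc$silhouette, 0.8)
  expect_gt(sc$calinski, 100)
  sc2 <- score_partition(part, blobs$emb)
  expect_true(is.na(sc2$ari) && is.na(sc2$nmi))
  expect_equal(sc2$silhouette, sc$silhouette)
})
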