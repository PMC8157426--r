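# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive double loops and textbook
# formulas, sharing no code with the implementations they check.

# NT-Xent by explicit enumeration of every ordered similarity term.
oracle_nt_xent <- function(z, tau) {
  m <- nrow(z)
  cos_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  total <- 0
  for (i in seq_len(m)) {
    j <- if (i %% 2 == 1) i + 1L else i - 1L
    num <- exp(cos_sim(z[i, ], z[j, ]) / tau)
    den <- 0
    for (k in seq_len(m)) {
      if (k != i) den <- den + exp(cos_sim(z[i, ], z[k, ]) / tau)
    }
    total <- total - log(num / den)
  }
  total / m
}

# Adjusted Rand index from explicit pair counting.
oracle_ari <- function(truth, pred) {
  n <- length(truth)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_t <- truth[i] == truth[j]
      same_p <- pred[i] == pred[j]
      if (same_t && same_p) n11 <- n11 + 1
      else if (same_t && !same_p) n10 <- n10 + 1
      else if (!same_t && same_p) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  total <- n11 + n10 + n01 + n00
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) return(1)
  (n11 - expected) / (max_index - expected)
}

# NMI from explicit entropy sums over the label classes.
oracle_nmi <- function(truth, pred) {
  n <- length(truth)
  tu <- unique(truth)
  pu <- unique(pred)
  h <- function(groups, universe) {
    tot <- 0
    for (g in universe) {
      p <- sum(groups == g) / n
      if (p > 0) tot <- tot - p * log(p)
    }
    tot
  }
  ht <- h(truth, tu)
  hp <- h(pred, pu)
  if (ht == 0 || hp == 0) return(0)
  mi <- 0
  for (a in tu) {
    for (b in pu) {
      pab <- sum(truth == a & pred == b) / n
      if (pab > 0) {
        mi <- mi + pab * log(pab / ((sum(truth == a) / n) *
                                      (sum(pred == b) / n)))
      }
    }
  }
  mi / ((ht + hp) / 2)
}

# Mean silhouette by double loop over points.
oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      other <- which(labels == g)
      b <- min(b, mean(vapply(other, function(j) d(i, j), numeric(1))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Calinski-Harabasz by direct dispersion sums.
oracle_calinski <- function(X, labels) {
  n <- nrow(X)
  ks <- unique(labels)
  K <- length(ks)
  grand <- colMeans(X)
  B <- 0
  W <- 0
  for (g in ks) {
    Xg <- X[labels == g, , drop = FALSE]
    cg <- colMeans(Xg)
    B <- B + nrow(Xg) * sum((cg - grand)^2)
    for (i in seq_len(nrow(Xg))) W <- W + sum((Xg[i, ] - cg)^2)
  }
  (B / (K - 1)) / (W / (n - K))
}

# Two well-separated Gaussian blobs; small enough that every clusterer's
# neighborhood spans a whole blob.
make_blobs <- function(n_per = 20L, dim = 4L, sep = 8, sd = 0.5,
                       seed = 1L) {
  set.seed(seed)
  z <- rbind(
    matrix(stats::rnorm(n_per * dim, sd = sd), n_per),
    matrix(stats::rnorm(n_per * dim, sd = sd) + sep, n_per)
  )
  list(emb = embedding(z), truth = rep(1:2, each = n_per))
}

# Small informative simulation for fast pipeline tests.
tiny_sim <- function(n_groups = 2L, cells = 30L, genes = 300L,
                     seed = 1L, mid = -10) {
  simulate_counts(sim_config(
    n_genes = genes, group_sizes = rep(cells, n_groups),
    de_prob = 0.1, fac_scale = 0.8, dropout_mid = mid, seed = seed
  ))
}

# Small pipeline configuration matched to tiny_sim.
tiny_cfg <- function(k = 2L, epochs = 8L, mask = 0.9, method = "kmeans",
                     n_runs = 2L, genes = 100L, layers = c(64L, 32L),
                     output_dir = NULL) {
  pipeline_config(
    preprocess = preprocess_config(n_top_genes = genes),
    augment = augment_config(mask_ratio = mask),
    layer_sizes = layers,
    train = train_config(epochs = epochs, batch_size = 32L),
    cluster = if (method %in% c("leiden", "meanshift")) {
      cluster_params(method, n_neighbors = 10L)
    } else {
      cluster_params(method, n_clusters = k)
    },
    n_runs = n_runs,
    output_dir = output_dir
  )
}
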