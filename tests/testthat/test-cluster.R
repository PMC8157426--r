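test_that("kmeans separates blobs, handles k=1, and is deterministic", {
  blobs <- make_blobs(seed = 2L)
  p <- kmeans_cluster(blobs$emb, cluster_params("kmeans", n_clusters = 2L,
                                                seed = 3L))
  expect_equal(ari(blobs$truth, p$labels), 1)
  expect_equal(p$K, 2L)

  p1 <- kmeans_cluster(blobs$emb, cluster_params("kmeans", n_clusters = 1L,
                                                 seed = 3L))
  expect_equal(p1$K, 1L)
  expect_true(all(p1$labels == 0L))

  pa <- kmeans_cluster(blobs$emb, cluster_params("kmeans", n_clusters = 3L,
                                                 seed = 9L))
  pb <- kmeans_cluster(blobs$emb, cluster_params("kmeans", n_clusters = 3L,
                                                 seed = 9L))
  expect_identical(pa$labels, pb$labels)
  expect_error(
    kmeans_cluster(blobs$emb, cluster_params("kmeans", n_clusters = 100L)),
    "exceeds"
  )
})

test_that("leiden recovers separable blobs and responds to resolution", {
  blobs <- make_blobs(n_per = 20L, seed = 5L)
  p <- leiden_cluster(blobs$emb, cluster_params("leiden", seed = 1L))
  expect_equal(p$K, 2L)
  expect_equal(ari(blobs$truth, p$labels), 1)

  # K is non-decreasing in the resolution on a fixed embedding
  set.seed(7)
  z <- embedding(matrix(rnorm(200 * 8), 200, 8))
  ks <- vapply(c(0.5, 1, 2, 4), function(r) {
    leiden_cluster(z, cluster_params("leiden", resolution = r,
                                     seed = 2L))$K
  }, integer(1))
  expect_true(all(diff(ks) >= 0))

  pa <- leiden_cluster(blobs$emb, cluster_params("leiden", seed = 8L))
  pb <- leiden_cluster(blobs$emb, cluster_params("leiden", seed = 8L))
  expect_identical(pa$labels, pb$labels)
  expect_error(
    leiden_cluster(blobs$emb, cluster_params("leiden", n_neighbors = 100L)),
    "more cells"
  )
})

test_that("leiden splits two disconnected kNN components exactly", {
  # blobs so far apart that the kNN graph has two components
  blobs <- make_blobs(n_per = 18L, sep = 100, seed = 11L)
  g <- contraclust:::knn_graph(blobs$emb$z, 10L)
  expect_equal(igraph::count_components(g), 2L)
  p <- leiden_cluster(blobs$emb,
                      cluster_params("leiden", n_neighbors = 10L,
                                     resolution = 1, seed = 1L))
  expect_equal(p$K, 2L)
  expect_equal(ari(blobs$truth, p$labels), 1)
})

test_that("every pluggable method returns a valid partition on easy data", {
  blobs <- make_blobs(seed = 13L)
  n <- length(blobs$truth)
  for (m in c("kmeans", "leiden", "birch", "gmm", "meanshift", "spectral",
              "ward")) {
    k <- if (m %in% c("leiden", "meanshift")) NULL else 2L
    params <- if (is.null(k)) {
      cluster_params(m, n_neighbors = 10L, seed = 4L)
    } else {
      cluster_params(m, n_clusters = k, seed = 4L)
    }
    p <- cluster_embedding(blobs$emb, params)
    expect_s3_class(p, "partition")
    expect_length(p$labels, n)
    # labels are a surjection onto 0..K-1
    expect_setequal(unique(p$labels), seq_len(p$K) - 1L)
    expect_equal(ari(blobs$truth, p$labels), 1,
                 tolerance = 1e-12, label = m)
  }
  expect_error(cluster_params("gmm"), "requires n_clusters")
})

test_that("partition labels are size-ordered consecutive integers", {
  p <- partition(c("x", "y", "y", "y", "z", "z"))
  expect_identical(p$labels, c(2L, 0L, 0L, 0L, 1L, 1L))
  expect_equal(p$K, 3L)
  expect_error(partition(character(0)), "empty")
})

test_that("the naive PCA+KMeans baseline solves separable data with K = k", {
  sim <- tiny_sim(n_groups = 2L, cells = 30L, genes = 300L, seed = 17L)
  p <- naive_baseline(sim$cm, k = 2L, seed = 1L,
                      pcfg = preprocess_config(n_top_genes = 100L))
  expect_equal(p$K, 2L)
  expect_equal(ari(sim$cm$labels, p$labels), 1)
  expect_identical(p$method, "naive_pca_kmeans")
})
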