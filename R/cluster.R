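#' Clustering parameters
#'
#' One bag of parameters shared by all pluggable clustering algorithms
#' applied to the learned embedding.
#'
#' @param method One of `"kmeans"`, `"leiden"`, `"birch"`, `"gmm"`,
#'   `"meanshift"`, `"spectral"`, `"ward"`.
#' @param n_clusters Number of clusters k; required for kmeans, birch, gmm,
#'   spectral and ward; ignored by leiden and meanshift, which infer it.
#' @param max_iter Maximum Lloyd iterations for kmeans (default 300).
#' @param n_init Number of kmeans restarts; the best inertia wins (default
#'   10).
#' @param n_neighbors Neighborhood size of the kNN graph for Leiden (default
#'   15).
#' @param resolution Leiden modularity resolution (default 1).
#' @param seed Integer seed (default 0).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(method = c("kmeans", "leiden", "birch", "gmm",
                                      "meanshift", "spectral", "ward"),
                           n_clusters = NULL, max_iter = 300L, n_init = 10L,
                           n_neighbors = 15L, resolution = 1.0, seed = 0L) {
  method <- match.arg(method)
  needs_k <- method %in% c("kmeans", "birch", "gmm", "spectral", "ward")
  if (needs_k) {
    if (is.null(n_clusters)) {
      stop("method '", method, "' requires n_clusters", call. = FALSE)
    }
    n_clusters <- as.integer(n_clusters)
    if (n_clusters < 1L) stop("n_clusters must be >= 1", call. = FALSE)
  }
  if (n_neighbors < 2L) stop("n_neighbors must be >= 2", call. = FALSE)
  structure(
    list(method = method, n_clusters = n_clusters,
         max_iter = as.integer(max_iter), n_init = as.integer(n_init),
         n_neighbors = as.integer(n_neighbors), resolution = resolution,
         seed = as.integer(seed)),
    class = "cluster_params"
  )
}

#' Cluster assignment container
#'
#' Labels are re-indexed to consecutive integers starting at 0, ordered by
#' decreasing cluster size (largest cluster = 0), for stable reporting.
#'
#' @param labels Vector of cluster assignments (any coding).
#' @param cell_ids Character vector of cell identifiers.
#' @param method Name of the producing algorithm.
#' @param params Parameter snapshot (list).
#' @return A `partition` with fields `labels` (0-based integers), `K`,
#'   `cell_ids`, `method`, `params`.
#' @export
partition <- function(labels, cell_ids = NULL, method = "unknown",
                      params = list()) {
  raw <- as.character(labels)
  n <- length(raw)
  if (n == 0L) stop("partition cannot be empty", call. = FALSE)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  sizes <- sort(table(raw), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  lab <- unname(remap[raw])
  structure(
    list(labels = as.integer(lab), K = length(sizes),
         cell_ids = as.character(cell_ids), method = method,
         params = params),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition> ", length(x$labels), " cells in ", x$K, " clusters (",
      x$method, ")\n", sep = "")
  invisible(x)
}

#' Tidy a partition into a tibble
#'
#' @param x A [partition()].
#' @param ... Unused.
#' @return A tibble with columns `cell_id`, `cluster`.
#' @export
tidy.partition <- function(x, ...) {
  tibble::tibble(cell_id = x$cell_ids, cluster = x$labels)
}

#' One-row summary of a partition
#'
#' @param x A [partition()].
#' @param ... Unused.
#' @return A tibble with `K`, `n_cells`, `largest`, `smallest` cluster sizes.
#' @export
glance.partition <- function(x, ...) {
  sizes <- table(x$labels)
  tibble::tibble(K = x$K, n_cells = length(x$labels),
                 largest = max(sizes), smallest = min(sizes),
                 method = x$method)
}

# k-means++ seeding: spread the initial centers with probability
# proportional to squared distance from the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(X, 2L, centers[1L, ], "-")^2)
  for (j in 2L:k) {
    if (sum(d2) == 0) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ], "-")^2))
  }
  centers
}

#' KMeans clustering of an embedding
#'
#' Lloyd's algorithm with k-means++ seeding and `n_init` restarts; the run
#' with the lowest within-cluster sum of squares (inertia) is kept.
#' Deterministic under `params$seed`.
#'
#' @param emb An [embedding()] or numeric matrix.
#' @param params A [cluster_params()] with `n_clusters` set.
#' @return A [partition()].
#' @export
kmeans_cluster <- function(emb, params = cluster_params("kmeans",
                                                        n_clusters = 2L)) {
  X <- if (inherits(emb, "embedding")) emb$z else as.matrix(emb)
  ids <- if (inherits(emb, "embedding")) emb$cell_ids else rownames(X)
  k <- params$n_clusters
  if (k > nrow(X)) stop("n_clusters (", k, ") exceeds the number of cells (",
                        nrow(X), ")", call. = FALSE)
  set.seed(params$seed)
  if (k == 1L) {
    return(partition(rep(0L, nrow(X)), cell_ids = ids, method = "kmeans",
                     params = params))
  }
  best <- NULL
  for (run in seq_len(params$n_init)) {
    centers <- kmeanspp_centers(X, k)
    km <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = params$max_iter,
                    algorithm = "Lloyd")
    )
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  partition(best$cluster, cell_ids = ids, method = "kmeans", params = params)
}

# Symmetrized (union) k-nearest-neighbour graph on Euclidean distances,
# built on the embedding directly (no PCA step).
knn_graph <- function(X, n_neighbors) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2L:(n_neighbors + 1L)]  # skip self
    edges[[i]] <- cbind(i, nb)
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Leiden community detection on the embedding's kNN graph
#'
#' Builds the symmetrized Euclidean k-nearest-neighbour graph on the
#' embedding, then optimizes modularity with the Leiden algorithm at the
#' given resolution. The number of clusters is inferred.
#'
#' @param emb An [embedding()] or numeric matrix.
#' @param params A [cluster_params()]; uses `n_neighbors`, `resolution`,
#'   `seed`.
#' @return A [partition()].
#' @export
leiden_cluster <- function(emb, params = cluster_params("leiden")) {
  X <- if (inherits(emb, "embedding")) emb$z else as.matrix(emb)
  ids <- if (inherits(emb, "embedding")) emb$cell_ids else rownames(X)
  if (nrow(X) <= params$n_neighbors) {
    stop("need more cells (", nrow(X), ") than n_neighbors (",
         params$n_neighbors, ")", call. = FALSE)
  }
  g <- knn_graph(X, params$n_neighbors)
  set.seed(params$seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = params$resolution,
                                 n_iterations = 5L)
  partition(igraph::membership(comm), cell_ids = ids, method = "leiden",
            params = params)
}

# Gaussian-kernel mean-shift mode seeking. Self-contained implementation:
# every point ascends to its density mode; modes closer than a merge radius
# collapse into one cluster. The bandwidth defaults to a quantile of the
# pairwise distances.
meanshift_cluster_impl <- function(X, bandwidth = NULL, max_iter = 100L,
                                   tol = 1e-4) {
  n <- nrow(X)
  if (is.null(bandwidth)) {
    D <- stats::dist(X)
    bandwidth <- stats::quantile(D, 0.3)
    if (bandwidth == 0) bandwidth <- mean(D) + 1e-12
  }
  modes <- X
  for (iter in seq_len(max_iter)) {
    D2 <- outer(rowSums(modes^2), rowSums(X^2), "+") -
      2 * tcrossprod(modes, X)
    W <- exp(-D2 / (2 * bandwidth^2))
    new_modes <- (W %*% X) / rowSums(W)
    shift <- sqrt(rowSums((new_modes - modes)^2))
    modes <- new_modes
    if (max(shift) < tol * bandwidth) break
  }
  # merge modes within half a bandwidth
  labels <- integer(n)
  centers <- NULL
  for (i in seq_len(n)) {
    if (is.null(centers)) {
      centers <- modes[i, , drop = FALSE]
      labels[i] <- 1L
      next
    }
    d <- sqrt(rowSums(sweep(centers, 2L, modes[i, ], "-")^2))
    j <- which.min(d)
    if (d[j] < bandwidth / 2) {
      labels[i] <- j
    } else {
      centers <- rbind(centers, modes[i, ])
      labels[i] <- nrow(centers)
    }
  }
  labels
}

# Two-stage clustering in the spirit of BIRCH: a sequential leader pass
# groups points into fine subclusters within a distance threshold, then the
# subcluster centroids are merged by Ward linkage down to k clusters.
birch_cluster_impl <- function(X, k, threshold = NULL) {
  n <- nrow(X)
  if (is.null(threshold)) {
    samp <- X[sample.int(n, min(n, 200L)), , drop = FALSE]
    threshold <- stats::quantile(stats::dist(samp), 0.1)
    if (threshold == 0) threshold <- 1e-8
  }
  centers <- X[1L, , drop = FALSE]
  counts <- 1L
  assign <- integer(n)
  assign[1L] <- 1L
  for (i in 2L:n) {
    d <- sqrt(rowSums(sweep(centers, 2L, X[i, ], "-")^2))
    j <- which.min(d)
    if (d[j] <= threshold) {
      # update the running centroid of the subcluster
      centers[j, ] <- (centers[j, ] * counts[j] + X[i, ]) / (counts[j] + 1L)
      counts[j] <- counts[j] + 1L
      assign[i] <- j
    } else {
      centers <- rbind(centers, X[i, ])
      counts <- c(counts, 1L)
      assign[i] <- nrow(centers)
    }
  }
  n_sub <- nrow(centers)
  if (n_sub <= k) return(assign)
  hc <- stats::hclust(stats::dist(centers), method = "ward.D2")
  sub_lab <- stats::cutree(hc, k = k)
  sub_lab[assign]
}

#' Cluster an embedding with any supported algorithm
#'
#' Dispatches on `params$method` over the same embedding and returns a
#' uniform [partition()]. KMeans, Leiden, GMM (via \pkg{mclust}), spectral
#' clustering (via \pkg{kernlab}) and Ward hierarchical clustering wrap
#' established implementations; mean-shift and the BIRCH-style two-stage
#' reducer are small self-contained implementations.
#'
#' @param emb An [embedding()] or numeric matrix.
#' @param params A [cluster_params()].
#' @return A [partition()].
#' @examples
#' z <- embedding(rbind(matrix(rnorm(40), 20), matrix(rnorm(40) + 8, 20)))
#' cluster_embedding(z, cluster_params("ward", n_clusters = 2))
#' @export
cluster_embedding <- function(emb, params) {
  stopifnot(inherits(params, "cluster_params"))
  X <- if (inherits(emb, "embedding")) emb$z else as.matrix(emb)
  ids <- if (inherits(emb, "embedding")) emb$cell_ids else rownames(X)
  k <- params$n_clusters
  set.seed(params$seed)
  labels <- switch(params$method,
    kmeans = return(kmeans_cluster(emb, params)),
    leiden = return(leiden_cluster(emb, params)),
    gmm = {
      fit <- mclust::Mclust(X, G = k, verbose = FALSE)
      if (is.null(fit)) stop("GMM fit failed", call. = FALSE)
      fit$classification
    },
    ward = {
      stats::cutree(stats::hclust(stats::dist(X), method = "ward.D2"), k = k)
    },
    spectral = {
      sc <- kernlab::specc(X, centers = k)
      as.integer(sc)
    },
    meanshift = meanshift_cluster_impl(X),
    birch = birch_cluster_impl(X, k)
  )
  partition(labels, cell_ids = ids, method = params$method, params = params)
}

#' Naive PCA + KMeans baseline
#'
#' The reference naive method: cluster with KMeans the first two principal
#' components of the preprocessed expression matrix. Serves as the floor any
#' representation-learning method should beat.
#'
#' @param cm A [count_matrix()].
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param pcfg A [preprocess_config()] applied before PCA.
#' @return A [partition()].
#' @export
naive_baseline <- function(cm, k, seed = 0L, pcfg = preprocess_config()) {
  pm <- preprocess(cm, pcfg)
  pcs <- stats::prcomp(pm$values, center = TRUE, scale. = FALSE,
                       rank. = 2L)$x
  p <- cluster_params("kmeans", n_clusters = k, seed = seed)
  out <- kmeans_cluster(embedding(pcs, cell_ids = pm$cell_ids), p)
  out$method <- "naive_pca_kmeans"
  out
}
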