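#' Adjusted Rand index
#'
#' Chance-adjusted agreement between two labelings, computed from the
#' contingency table: proportional to the number of sample pairs grouped the
#' same way in both, adjusted so that random labelings score ~0. Symmetric
#' and invariant to label renaming; identical labelings score 1.
#'
#' @param truth,pred Label vectors of equal length (>= 2); any coding.
#' @return A real in `[-1, 1]`.
#' @examples
#' ari(c(0, 0, 1, 1), c(0, 1, 0, 1))  # -0.5
#' @export
ari <- function(truth, pred) {
  check_labels(truth, pred)
  tab <- table(truth, pred)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both labelings trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' Mutual information between the two labelings normalized by the arithmetic
#' mean of their entropies. Ignores label permutations. Degenerate cases
#' where either labeling carries no information (a single cluster) return 0.
#'
#' @param truth,pred Label vectors of equal length.
#' @return A real in `[0, 1]`.
#' @export
nmi <- function(truth, pred) {
  check_labels(truth, pred)
  tab <- table(truth, pred)
  n <- sum(tab)
  p <- tab / n
  pr <- rowSums(p)
  pc <- colSums(p)
  h_true <- -sum(ifelse(pr > 0, pr * log(pr), 0))
  h_pred <- -sum(ifelse(pc > 0, pc * log(pc), 0))
  if (h_true == 0 || h_pred == 0) return(0)
  outer_p <- outer(pr, pc)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer_p[nz]))
  mi / ((h_true + h_pred) / 2)
}

#' Mean silhouette score
#'
#' For each point, `a` is its mean distance to its own cluster and `b` the
#' smallest mean distance to another cluster; the silhouette is
#' `(b - a) / max(a, b)`, averaged over points (Euclidean distances).
#' Singleton clusters contribute 0. Measures compactness/separation without
#' ground truth; ranges over `[-1, 1]`.
#'
#' @param emb An [embedding()] or numeric matrix.
#' @param pred Cluster labels, one per row; needs `2 <= K <= n-1`.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(emb, pred) {
  X <- if (inherits(emb, "embedding")) emb$z else as.matrix(emb)
  pred <- as.integer(factor(pred))
  n <- nrow(X)
  K <- length(unique(pred))
  if (K < 2L || K > n - 1L) {
    stop("silhouette needs 2 <= K <= n-1 clusters, got K=", K, call. = FALSE)
  }
  sil <- cluster::silhouette(pred, dist(X))
  mean(sil[, "sil_width"])
}

#' Calinski-Harabasz score
#'
#' Ratio of between-cluster to within-cluster dispersion,
#' `[B/(K-1)] / [W/(n-K)]`, where B and W are the sums of squared distances
#' of cluster centroids to the global centroid (size-weighted) and of points
#' to their cluster centroid. Higher means denser, better-separated
#' clusters; invariant to coordinate scaling.
#'
#' @param emb An [embedding()] or numeric matrix.
#' @param pred Cluster labels; needs `2 <= K <= n-1`.
#' @return A non-negative real; an error is raised when the within-cluster
#'   dispersion is exactly 0 (score unbounded).
#' @export
calinski_harabasz <- function(emb, pred) {
  X <- if (inherits(emb, "embedding")) emb$z else as.matrix(emb)
  pred <- as.integer(factor(pred))
  n <- nrow(X)
  K <- length(unique(pred))
  if (K < 2L || K > n - 1L) {
    stop("calinski_harabasz needs 2 <= K <= n-1 clusters, got K=", K,
         call. = FALSE)
  }
  grand <- colMeans(X)
  B <- 0
  W <- 0
  for (g in unique(pred)) {
    Xg <- X[pred == g, , drop = FALSE]
    cg <- colMeans(Xg)
    B <- B + nrow(Xg) * sum((cg - grand)^2)
    W <- W + sum(sweep(Xg, 2L, cg, "-")^2)
  }
  if (W == 0) {
    stop("within-cluster dispersion is 0; Calinski-Harabasz is unbounded",
         call. = FALSE)
  }
  (B / (K - 1)) / (W / (n - K))
}

#' Relative error of the predicted cluster count
#'
#' `(pred_K - true_K) / true_K`: positive when the method over-estimates the
#' number of clusters, negative when it under-estimates.
#'
#' @param pred_K Predicted number of clusters.
#' @param true_K True number of clusters (>= 1).
#' @return A real.
#' @export
k_error <- function(pred_K, true_K) {
  if (true_K < 1) stop("true_K must be >= 1", call. = FALSE)
  (pred_K - true_K) / true_K
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean; the scale-free spread used
#' to compare run-to-run stability across scores living on different scales.
#'
#' @param values Numeric vector of length >= 2 with nonzero mean.
#' @return A real.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean",
                   call. = FALSE)
  stats::sd(values) / m
}

#' Score a partition against an embedding and optional ground truth
#'
#' @param part A [partition()].
#' @param emb An [embedding()] (for the internal scores).
#' @param truth Optional ground-truth labels; when given, ARI, NMI and the
#'   cluster-count error are included.
#' @return A one-row tibble with columns `ari`, `nmi`, `k_error` (NA without
#'   truth), `silhouette`, `calinski`, `K`.
#' @export
score_partition <- function(part, emb, truth = NULL) {
  stopifnot(inherits(part, "partition"))
  sil <- tryCatch(silhouette_score(emb, part$labels),
                  error = function(e) NA_real_)
  cal <- tryCatch(calinski_harabasz(emb, part$labels),
                  error = function(e) NA_real_)
  if (is.null(truth)) {
    tibble::tibble(ari = NA_real_, nmi = NA_real_, k_error = NA_real_,
                   silhouette = sil, calinski = cal, K = part$K)
  } else {
    tibble::tibble(
      ari = ari(truth, part$labels),
      nmi = nmi(truth, part$labels),
      k_error = k_error(part$K, length(unique(truth))),
      silhouette = sil, calinski = cal, K = part$K
    )
  }
}

check_labels <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("label vectors differ in length (", length(truth), " vs ",
         length(pred), ")", call. = FALSE)
  }
  if (length(truth) < 2L) stop("need at least 2 observations", call. = FALSE)
  invisible(TRUE)
}
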