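#' Simulation configuration
#'
#' Parameters of the splatter-style generative model for grouped scRNA-seq
#' counts: gamma-distributed gene base means, per-group multiplicative
#' differential-expression factors, lognormal library sizes, Poisson
#' sampling, and an expression-dependent logistic dropout layer. The
#' defaults reproduce the balanced study design: 2500 genes, groups of 250
#' cells, `de_prob` 0.1, `fac_scale` 0.2, dropout shape -1 with midpoints in
#' `{-1, 0, 1, 1.5}` spanning realized dropout rates of roughly 5-38%.
#'
#' @param n_genes Number of genes (default 2500).
#' @param group_sizes Integer vector of cells per group (default 4 groups of
#'   250).
#' @param de_prob Probability that a gene is differentially expressed in a
#'   group (default 0.1).
#' @param fac_scale Lognormal sdlog of the DE factors (default 0.2).
#' @param dropout_mid Logistic dropout midpoint on the log-mean scale
#'   (default -1; larger means more dropout).
#' @param dropout_shape Logistic dropout slope (default -1).
#' @param mean_shape,mean_rate Gamma shape/rate of gene base means (defaults
#'   0.6 / 0.3).
#' @param lib_loc,lib_scale Lognormal meanlog/sdlog of cell library sizes
#'   (defaults 11 / 0.2).
#' @param seed Integer seed (default 0).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2500L, group_sizes = rep(250L, 4L),
                       de_prob = 0.1, fac_scale = 0.2,
                       dropout_mid = -1, dropout_shape = -1,
                       mean_shape = 0.6, mean_rate = 0.3,
                       lib_loc = 11, lib_scale = 0.2, seed = 0L) {
  group_sizes <- as.integer(group_sizes)
  if (any(group_sizes < 1L)) stop("all group sizes must be >= 1",
                                  call. = FALSE)
  if (de_prob < 0 || de_prob > 1) stop("de_prob must be in [0, 1]",
                                       call. = FALSE)
  if (mean_shape <= 0 || mean_rate <= 0 || fac_scale < 0 || lib_scale < 0) {
    stop("distribution parameters must be positive", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
         de_prob = de_prob, fac_scale = fac_scale,
         dropout_mid = dropout_mid, dropout_shape = dropout_shape,
         mean_shape = mean_shape, mean_rate = mean_rate,
         lib_loc = lib_loc, lib_scale = lib_scale, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a grouped scRNA-seq count matrix
#'
#' Generative steps, all seeded: (1) gene base means
#' `lambda_g ~ Gamma(mean_shape, rate = mean_rate)`; (2) per group, each
#' gene is differentially expressed with probability `de_prob`, receiving a
#' multiplicative factor `LogNormal(0, fac_scale)`; (3) each cell draws a
#' library size `LogNormal(lib_loc, lib_scale)` and its gene means are the
#' group's expression profile normalized to proportions times that library
#' size; (4) counts are Poisson draws around those means; (5) each entry is
#' zeroed with probability
#' `1 / (1 + exp(-shape * (ln(mu) - mid)))` (logistic dropout on the
#' expression mean). Zeros arising from Poisson sampling are *not* counted
#' in the realized dropout rate, which only tracks observed counts zeroed by
#' the dropout step.
#'
#' @param cfg A [sim_config()].
#' @return A `simulated_dataset`: list with `cm` (a [count_matrix()] whose
#'   labels are the true groups), `true_dropout_rate`, and `config`.
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200,
#'   group_sizes = rep(25, 2), seed = 1))
#' sim$true_dropout_rate
#' @export
simulate_counts <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  d <- cfg$n_genes
  groups <- rep(seq_along(cfg$group_sizes), cfg$group_sizes)
  n <- length(groups)
  lambda <- stats::rgamma(d, shape = cfg$mean_shape, rate = cfg$mean_rate)
  n_groups <- length(cfg$group_sizes)
  de_fac <- matrix(1, n_groups, d)
  for (g in seq_len(n_groups)) {
    is_de <- stats::runif(d) < cfg$de_prob
    de_fac[g, is_de] <- stats::rlnorm(sum(is_de), meanlog = 0,
                                      sdlog = cfg$fac_scale)
  }
  group_mean <- sweep(de_fac, 2L, lambda, "*")       # groups x genes
  group_prop <- group_mean / rowSums(group_mean)     # expression proportions
  lib <- stats::rlnorm(n, meanlog = cfg$lib_loc, sdlog = cfg$lib_scale)
  mu <- group_prop[groups, , drop = FALSE] * lib     # cells x genes
  counts <- matrix(stats::rpois(n * d, lambda = mu), n, d)
  # logistic dropout on the underlying mean
  pi_drop <- 1 / (1 + exp(-cfg$dropout_shape * (log(mu) - cfg$dropout_mid)))
  dropped <- matrix(stats::runif(n * d) < pi_drop, n, d)
  expressed <- counts > 0
  realized <- if (any(expressed)) {
    sum(dropped & expressed) / sum(expressed)
  } else {
    0
  }
  counts[dropped] <- 0L
  cm <- count_matrix(counts,
                     cell_ids = paste0("cell_", seq_len(n)),
                     gene_ids = paste0("gene_", seq_len(d)),
                     labels = paste0("group_", groups))
  structure(list(cm = cm, true_dropout_rate = realized, config = cfg),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("<simulated_dataset> ", nrow(x$cm$counts), " cells x ",
      ncol(x$cm$counts), " genes, ", length(x$config$group_sizes),
      " groups; realized dropout ",
      sprintf("%.1f%%", 100 * x$true_dropout_rate), "\n", sep = "")
  invisible(x)
}

#' Balanced simulation suite
#'
#' Twelve balanced datasets: group counts in `{4, 8, 16}` crossed with
#' dropout midpoints in `{-1, 0, 1, 1.5}`, 250 cells per group, 2500 genes,
#' `fac_scale` 0.2 — realized dropout spans roughly 5-38%.
#'
#' @param seed Integer base seed; each dataset uses a distinct offset.
#' @param n_genes Number of genes (default 2500).
#' @param cells_per_group Cells per group (default 250).
#' @return A list of `simulated_dataset` objects with a `design` tibble
#'   attribute.
#' @export
make_balanced_suite <- function(seed = 0L, n_genes = 2500L,
                                cells_per_group = 250L) {
  design <- expand.grid(groups = c(4L, 8L, 16L),
                        mid = c(-1, 0, 1, 1.5))
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    cfg <- sim_config(
      n_genes = n_genes,
      group_sizes = rep(cells_per_group, design$groups[i]),
      dropout_mid = design$mid[i],
      seed = seed + i
    )
    out[[i]] <- simulate_counts(cfg)
  }
  attr(out, "design") <- tibble::as_tibble(design)
  out
}

# Geometric-decay group sizes: `total` cells in `n_groups` groups whose
# smallest/largest ratio is `min_ratio`, with a floor on the smallest group.
imbalanced_sizes <- function(total, n_groups, min_ratio, floor_cells = 10L) {
  q <- min_ratio^(1 / (n_groups - 1))
  prop <- q^(seq_len(n_groups) - 1L)
  sizes <- pmax(floor_cells, round(total * prop / sum(prop)))
  sizes[1L] <- sizes[1L] + (total - sum(sizes))  # absorb rounding drift
  # rounding can nudge the realized ratio above the band; shave the smallest
  # group (down to the floor) into the largest until it fits
  while (sizes[n_groups] > floor_cells &&
         sizes[n_groups] / sizes[1L] > min_ratio) {
    sizes[n_groups] <- sizes[n_groups] - 1L
    sizes[1L] <- sizes[1L] + 1L
  }
  as.integer(sizes)
}

#' Imbalanced simulation suite
#'
#' Twelve datasets of 3000 cells with `{4, 8, 16}` groups whose sizes decay
#' geometrically — the smallest/largest ratio spans 0.6 (4 groups) down to
#' 0.01 (16 groups), floored at 10 cells — crossed with dropout midpoints
#' `{-1, 0, 1, 1.5}`.
#'
#' @param seed Integer base seed.
#' @param n_genes Number of genes (default 2500).
#' @param total_cells Cells per dataset (default 3000).
#' @return A list of `simulated_dataset` objects with a `design` tibble
#'   attribute.
#' @export
make_imbalanced_suite <- function(seed = 0L, n_genes = 2500L,
                                  total_cells = 3000L) {
  ratio_for <- c(`4` = 0.6, `8` = 0.08, `16` = 0.01)
  design <- expand.grid(groups = c(4L, 8L, 16L),
                        mid = c(-1, 0, 1, 1.5))
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    g <- design$groups[i]
    cfg <- sim_config(
      n_genes = n_genes,
      group_sizes = imbalanced_sizes(total_cells, g,
                                     ratio_for[[as.character(g)]]),
      dropout_mid = design$mid[i],
      seed = seed + 100L + i
    )
    out[[i]] <- simulate_counts(cfg)
  }
  attr(out, "design") <- tibble::as_tibble(design)
  out
}

#' Stratified downsampling of cells
#'
#' Randomly retains the given fraction of cells within each ground-truth
#' label, so all groups keep a proportional representation (within one cell
#' of the exact fraction per label).
#'
#' @param cm A [count_matrix()] with labels.
#' @param fraction Fraction of cells to keep, in `(0, 1]`.
#' @param seed Integer seed.
#' @return A [count_matrix()] restricted to the sampled cells.
#' @export
stratified_downsample <- function(cm, fraction, seed = 0L) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$labels)) {
    stop("stratified downsampling needs ground-truth labels", call. = FALSE)
  }
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  if (fraction == 1) return(cm)
  set.seed(seed)
  keep <- integer(0L)
  for (lab in unique(cm$labels)) {
    idx <- which(cm$labels == lab)
    n_keep <- round(length(idx) * fraction)
    if (n_keep < 1L) {
      stop("fraction ", fraction, " empties label '", lab, "'",
           call. = FALSE)
    }
    keep <- c(keep, sample(idx, n_keep))
  }
  subset(cm, cells = sort(keep))
}
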