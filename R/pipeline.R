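#' Pipeline configuration
#'
#' Bundles the configuration of every stage: preprocessing, augmentation,
#' encoder architecture, training, clustering, and the experiment protocol
#' (number of repeated runs, output directory).
#'
#' @param preprocess A [preprocess_config()].
#' @param augment An [augment_config()].
#' @param layer_sizes Encoder layer widths (default `c(200, 40, 60)`); the
#'   input width is taken from the preprocessed data at run time.
#' @param norm_after_hidden Feature normalization after hidden layers
#'   (default TRUE).
#' @param train A [train_config()].
#' @param cluster A [cluster_params()].
#' @param n_runs Number of repeated runs for experiments (default 3; seeds
#'   are derived as `base_seed + run - 1`).
#' @param output_dir Optional directory where runs write their artifacts
#'   (embedding, partition, scores, config snapshot, log).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            augment = augment_config(),
                            layer_sizes = c(200L, 40L, 60L),
                            norm_after_hidden = TRUE,
                            train = train_config(),
                            cluster = cluster_params("kmeans",
                                                     n_clusters = 2L),
                            n_runs = 3L,
                            output_dir = NULL) {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(augment, "augment_config"),
            inherits(train, "train_config"),
            inherits(cluster, "cluster_params"))
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("n_runs must be >= 1", call. = FALSE)
  structure(
    list(preprocess = preprocess, augment = augment,
         layer_sizes = as.integer(layer_sizes),
         norm_after_hidden = isTRUE(norm_after_hidden),
         train = train, cluster = cluster, n_runs = n_runs,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Run the full two-phase pipeline on a count matrix
#'
#' Preprocess, train the contrastive encoder, cluster the embedding. When
#' ground-truth labels are present the external scores (ARI, NMI,
#' cluster-count error) are computed alongside the internal ones
#' (silhouette, Calinski-Harabasz). Fully deterministic under `seed`.
#'
#' @param cm A [count_matrix()].
#' @param cfg A [pipeline_config()].
#' @param seed Optional integer overriding both the training and clustering
#'   seeds.
#' @return A `contraclust_fit`: list with `embedding`, `partition`, `scores`
#'   (one-row tibble), `loss_history`, `preprocessed`, `config`, `timings`.
#' @examples
#' \donttest{
#' sim <- simulate_counts(sim_config(n_genes = 300,
#'   group_sizes = rep(30, 2), seed = 1))
#' cfg <- pipeline_config(
#'   preprocess = preprocess_config(n_top_genes = 100),
#'   layer_sizes = c(32, 16),
#'   train = train_config(epochs = 5, batch_size = 30),
#'   cluster = cluster_params("kmeans", n_clusters = 2))
#' fit <- run_pipeline(sim$cm, cfg, seed = 1)
#' fit$scores
#' }
#' @export
run_pipeline <- function(cm, cfg = pipeline_config(), seed = NULL) {
  stopifnot(inherits(cm, "count_matrix"), inherits(cfg, "pipeline_config"))
  tcfg <- cfg$train
  clp <- cfg$cluster
  if (!is.null(seed)) {
    tcfg$seed <- as.integer(seed)
    clp$seed <- as.integer(seed)
  }
  timings <- c(preprocess = NA_real_, train = NA_real_, cluster = NA_real_)
  t0 <- proc.time()[["elapsed"]]
  pm <- preprocess(cm, cfg$preprocess)
  timings["preprocess"] <- proc.time()[["elapsed"]] - t0
  ecfg <- encoder_config(input_dim = ncol(pm$values),
                         layer_sizes = cfg$layer_sizes,
                         norm_after_hidden = cfg$norm_after_hidden)
  t0 <- proc.time()[["elapsed"]]
  fit <- train_encoder(pm, ecfg, tcfg, cfg$augment)
  timings["train"] <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  part <- cluster_embedding(fit$embedding, clp)
  timings["cluster"] <- proc.time()[["elapsed"]] - t0
  scores <- score_partition(part, fit$embedding, truth = cm$labels)
  out <- structure(
    list(embedding = fit$embedding, partition = part, scores = scores,
         loss_history = fit$loss_history, encoder = fit,
         config = cfg, seed = tcfg$seed, timings = timings),
    class = "contraclust_fit"
  )
  if (!is.null(cfg$output_dir)) write_run_artifacts(out, cfg$output_dir)
  out
}

#' @export
print.contraclust_fit <- function(x, ...) {
  cat("<contraclust_fit> ", length(x$partition$labels), " cells -> ",
      x$partition$K, " clusters (", x$partition$method, ")\n", sep = "")
  print(x$scores)
  invisible(x)
}

#' Tidy a pipeline fit into per-cell assignments
#'
#' @param x A `contraclust_fit`.
#' @param ... Unused.
#' @return A tibble with `cell_id`, `cluster`.
#' @export
tidy.contraclust_fit <- function(x, ...) tidy(x$partition)

#' One-row summary of a pipeline fit
#'
#' @param x A `contraclust_fit`.
#' @param ... Unused.
#' @return The scores tibble augmented with the final training loss and
#'   seed.
#' @export
glance.contraclust_fit <- function(x, ...) {
  dplyr::bind_cols(
    x$scores,
    tibble::tibble(final_loss = utils::tail(x$loss_history, 1L),
                   seed = x$seed)
  )
}

write_run_artifacts <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_embedding(fit$embedding, file.path(dir, "embedding.csv"))
  write_partition(fit$partition, file.path(dir, "partition.csv"))
  utils::write.csv(fit$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  snapshot_config(fit$config, file.path(dir, "config.yaml"))
  writeLines(
    c(paste0("seed: ", fit$seed),
      paste0("timings: ",
             paste(names(fit$timings),
                   signif(fit$timings, 4), sep = "=", collapse = " "))),
    file.path(dir, "run.log")
  )
  invisible(dir)
}

snapshot_config <- function(cfg, path) {
  flat <- unclass(cfg)
  flat <- lapply(flat, function(x) if (is.list(x)) unclass(x) else x)
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(flat, path)
  } else {
    dput(flat, file = path)
  }
  invisible(path)
}

# Run the pipeline cfg$n_runs times with seeds base_seed + 0..(n_runs-1);
# returns one score row per run.
run_replicates <- function(cm, cfg, base_seed, setting = NA_character_) {
  rows <- vector("list", cfg$n_runs)
  for (run in seq_len(cfg$n_runs)) {
    s <- base_seed + run - 1L
    fit <- run_pipeline(cm, cfg, seed = s)
    rows[[run]] <- dplyr::bind_cols(
      tibble::tibble(setting = setting, run = run, seed = s),
      fit$scores
    )
  }
  dplyr::bind_rows(rows)
}

experiment_result <- function(results, summary, chosen = NULL,
                              protocol = "experiment") {
  structure(list(results = results, summary = summary, chosen = chosen,
                 protocol = protocol),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result: ", x$protocol, "> ", nrow(x$results),
      " runs across ", nrow(x$summary), " settings\n", sep = "")
  print(x$summary)
  if (!is.null(x$chosen)) cat("chosen setting: ", x$chosen, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.experiment_result <- function(x, ...) x$results

#' @export
glance.experiment_result <- function(x, ...) x$summary

summarize_settings <- function(results) {
  results |>
    dplyr::group_by(.data$setting) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("ari", "nmi", "silhouette", "calinski")),
                    list(mean = ~mean(.x, na.rm = TRUE)),
                    .names = "{.col}_{.fn}"),
      K_mean = mean(.data$K),
      n_runs = dplyr::n(),
      .groups = "drop"
    )
}

#' Gene-count sweep
#'
#' Runs the pipeline at several HVG counts (`n_runs` seeded runs each) and
#' selects the input size maximizing the mean internal silhouette score.
#' Ground-truth labels are never consulted for the choice; sizes exceeding
#' the number of surviving genes are skipped with a warning.
#'
#' @param cm A [count_matrix()].
#' @param sizes Gene counts to try; the string `"all"` means every gene
#'   surviving the expression filter. Default
#'   `c(500, 1000, 1500, 3000, 5000, "all")`.
#' @param cfg A [pipeline_config()].
#' @param base_seed Base seed for the replicate runs.
#' @return An `experiment_result` whose `chosen` element is the selected
#'   size.
#' @export
sweep_gene_count <- function(cm, sizes = c(500, 1000, 1500, 3000, 5000,
                                           "all"),
                             cfg = pipeline_config(), base_seed = 0L) {
  n_avail <- ncol(filter_genes(cm, cfg$preprocess$min_cells_expressed)$counts)
  all_rows <- list()
  for (sz in sizes) {
    if (!identical(sz, "all")) {
      szn <- as.integer(sz)
      if (szn > n_avail) {
        warning("size ", szn, " exceeds the ", n_avail,
                " available genes; skipped", call. = FALSE)
        next
      }
    }
    cfg_i <- cfg
    cfg_i$preprocess$n_top_genes <- if (identical(sz, "all")) "all"
                                    else as.integer(sz)
    label <- if (identical(sz, "all")) "all" else as.character(sz)
    all_rows[[label]] <- run_replicates(cm, cfg_i, base_seed,
                                        setting = label)
  }
  results <- dplyr::bind_rows(all_rows)
  summary <- summarize_settings(results)
  chosen <- summary$setting[which.max(summary$silhouette_mean)]
  experiment_result(results, summary, chosen = chosen,
                    protocol = "gene_count_sweep")
}

#' Mask-ratio sweep
#'
#' Runs the pipeline across input-dropout (gene-masking) ratios and
#' tabulates the mean internal and external scores per ratio.
#'
#' @param cm A [count_matrix()].
#' @param ratios Masking ratios in `[0, 1)` (default `seq(0.2, 0.9, 0.1)`).
#' @param cfg A [pipeline_config()].
#' @param base_seed Base seed for the replicate runs.
#' @return An `experiment_result`.
#' @export
sweep_mask_ratio <- function(cm, ratios = seq(0.2, 0.9, by = 0.1),
                             cfg = pipeline_config(), base_seed = 0L) {
  if (any(ratios < 0 | ratios >= 1)) {
    stop("ratios must lie in [0, 1)", call. = FALSE)
  }
  all_rows <- list()
  for (r in ratios) {
    cfg_i <- cfg
    cfg_i$augment$mask_ratio <- r
    label <- format(r)
    all_rows[[label]] <- run_replicates(cm, cfg_i, base_seed,
                                        setting = label)
  }
  results <- dplyr::bind_rows(all_rows)
  experiment_result(results, summarize_settings(results),
                    protocol = "mask_ratio_sweep")
}

#' Architecture grid search
#'
#' Runs the pipeline for each candidate encoder architecture and records the
#' trainable-parameter count alongside the scores. Invalid architectures are
#' skipped with a warning.
#'
#' @param cm A [count_matrix()].
#' @param grid List of layer-size vectors, e.g. `list(c(200, 40, 60), c(60,
#'   20), 2)`.
#' @param cfg A [pipeline_config()].
#' @param base_seed Base seed for the replicate runs.
#' @return An `experiment_result`; `results` carries an `n_parameters`
#'   column.
#' @export
sweep_architecture <- function(cm, grid, cfg = pipeline_config(),
                               base_seed = 0L) {
  stopifnot(length(grid) >= 1L)
  # input width is fixed by preprocessing, needed for parameter counts
  pm_width <- if (identical(cfg$preprocess$n_top_genes, "all")) {
    ncol(filter_genes(cm, cfg$preprocess$min_cells_expressed)$counts)
  } else {
    cfg$preprocess$n_top_genes
  }
  all_rows <- list()
  for (arch in grid) {
    label <- paste0("[", paste(arch, collapse = ","), "]")
    ecfg <- tryCatch(
      encoder_config(input_dim = pm_width, layer_sizes = arch,
                     norm_after_hidden = cfg$norm_after_hidden),
      error = function(e) {
        warning("architecture ", label, " skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(ecfg)) next
    cfg_i <- cfg
    cfg_i$layer_sizes <- as.integer(arch)
    rows <- run_replicates(cm, cfg_i, base_seed, setting = label)
    rows$n_parameters <- count_parameters(ecfg)
    all_rows[[label]] <- rows
  }
  results <- dplyr::bind_rows(all_rows)
  experiment_result(results, summarize_settings(results),
                    protocol = "architecture_search")
}

#' Multi-seed stability and downsampling report
#'
#' Two arms: (1) `n_runs` seeded runs on the full data, summarized by the
#' coefficient of variation of each score; (2) stratified downsampling to
#' the given cell fractions, `n_runs` runs each.
#'
#' @param cm A [count_matrix()] with labels (needed for the stratified
#'   arm).
#' @param cfg A [pipeline_config()] with `n_runs >= 2`.
#' @param fractions Cell fractions for the downsampling arm (default
#'   `c(0.25, 0.5, 0.75, 1)`).
#' @param base_seed Base seed.
#' @return An `experiment_result`; `summary` gains `*_cv` columns and
#'   `results` carries a `fraction` column.
#' @export
stability_report <- function(cm, cfg = pipeline_config(),
                             fractions = c(0.25, 0.5, 0.75, 1),
                             base_seed = 0L) {
  if (cfg$n_runs < 2L) stop("stability needs n_runs >= 2", call. = FALSE)
  all_rows <- list()
  for (f in fractions) {
    cm_f <- if (f == 1) cm else stratified_downsample(cm, f,
                                                      seed = base_seed + 1000L * f)
    rows <- run_replicates(cm_f, cfg, base_seed,
                           setting = format(f))
    rows$fraction <- f
    all_rows[[format(f)]] <- rows
  }
  results <- dplyr::bind_rows(all_rows)
  summary <- summarize_settings(results)
  cv_of <- function(x) if (all(is.na(x)) || mean(x, na.rm = TRUE) == 0)
    NA_real_ else coefficient_of_variation(x[!is.na(x)])
  cvs <- results |>
    dplyr::group_by(.data$setting) |>
    dplyr::summarise(ari_cv = cv_of(.data$ari), nmi_cv = cv_of(.data$nmi),
                     silhouette_cv = cv_of(.data$silhouette),
                     calinski_cv = cv_of(.data$calinski), .groups = "drop")
  summary <- dplyr::left_join(summary, cvs, by = "setting")
  experiment_result(results, summary, protocol = "stability")
}
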