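#' Plot a cell embedding in its first two principal components
#'
#' @param object An [embedding()].
#' @param colour_by Optional vector (cluster labels or ground truth), one
#'   per cell.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.embedding <- function(object, colour_by = NULL, ...) {
  pcs <- stats::prcomp(object$z, rank. = 2L)$x
  df <- tibble::tibble(PC1 = pcs[, 1L], PC2 = pcs[, 2L])
  if (!is.null(colour_by)) {
    df$group <- factor(colour_by)
    ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                     colour = .data$group)) +
      ggplot2::geom_point(size = 0.8, alpha = 0.8) +
      ggplot2::labs(colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
      ggplot2::geom_point(size = 0.8, alpha = 0.8) +
      ggplot2::theme_minimal()
  }
}

#' Plot a pipeline fit: embedding coloured by predicted cluster
#'
#' @param object A `contraclust_fit` from [run_pipeline()].
#' @param ... Passed to [autoplot.embedding()].
#' @return A ggplot object.
#' @export
autoplot.contraclust_fit <- function(object, ...) {
  autoplot.embedding(object$embedding,
                     colour_by = paste0("c", object$partition$labels), ...) +
    ggplot2::ggtitle(paste0(object$partition$method, ", K = ",
                            object$partition$K))
}

#' Plot the training loss history
#'
#' @param fit An `encoder_fit` or `contraclust_fit`.
#' @return A ggplot object of mean contrastive loss per epoch.
#' @export
plot_loss <- function(fit) {
  lh <- fit$loss_history
  df <- tibble::tibble(epoch = seq_along(lh), loss = lh)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(y = "mean NT-Xent loss") +
    ggplot2::theme_minimal()
}

#' Plot an experiment result: mean score per setting
#'
#' @param object An `experiment_result`.
#' @param score Which score to plot (default `"ari"`; internal-only runs can
#'   use `"silhouette"`).
#' @param ... Unused.
#' @return A ggplot object with per-run points and per-setting means.
#' @export
autoplot.experiment_result <- function(object, score = "ari", ...) {
  score_col <- match.arg(score, c("ari", "nmi", "silhouette", "calinski"))
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(.data$setting, .data[[score_col]])) +
    ggplot2::geom_point(alpha = 0.6,
                        position = ggplot2::position_jitter(width = 0.08,
                                                            height = 0)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "firebrick") +
    ggplot2::labs(x = object$protocol, y = score_col) +
    ggplot2::theme_minimal()
}
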