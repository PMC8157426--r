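#' Augmentation configuration
#'
#' Controls the strong augmentation applied to each view of a mini-batch:
#' random gene masking through input-level dropout, optionally followed by
#' additive Gaussian noise.
#'
#' @param mask_ratio Probability of zeroing each entry, in `[0, 1)`. Default
#'   0.9: performance of the contrastive representation peaks at very strong
#'   masking.
#' @param noise_std Standard deviation of additive Gaussian noise (default 0:
#'   noise does not improve the representation and is off by default).
#' @param rescale_survivors Multiply surviving entries by `1/(1-mask_ratio)`
#'   (standard train-time dropout semantics, making the augmentation unbiased
#'   in expectation). Default TRUE; exposed for ablation.
#' @return An `augment_config` list.
#' @export
augment_config <- function(mask_ratio = 0.9, noise_std = 0,
                           rescale_survivors = TRUE) {
  if (mask_ratio < 0 || mask_ratio >= 1) {
    stop("mask_ratio must be in [0, 1)", call. = FALSE)
  }
  if (noise_std < 0) stop("noise_std must be >= 0", call. = FALSE)
  structure(
    list(mask_ratio = mask_ratio, noise_std = noise_std,
         rescale_survivors = isTRUE(rescale_survivors)),
    class = "augment_config"
  )
}

#' Mask random genes via input-level dropout
#'
#' Each entry is independently zeroed with probability `mask_ratio`; with
#' `rescale_survivors` the surviving entries are scaled by
#' `1/(1-mask_ratio)` so the expected output equals the input. Randomness is
#' drawn from R's global RNG, so each call produces a fresh mask.
#'
#' @param batch Numeric matrix (cells x genes).
#' @param cfg An [augment_config()].
#' @return A matrix of the same shape.
#' @export
mask_genes <- function(batch, cfg = augment_config()) {
  stopifnot(inherits(cfg, "augment_config"))
  p <- cfg$mask_ratio
  if (p == 0) return(batch)
  keep <- matrix(stats::runif(length(batch)) >= p, nrow(batch), ncol(batch))
  out <- batch * keep
  if (cfg$rescale_survivors) out <- out / (1 - p)
  out
}

#' Add i.i.d. Gaussian noise
#'
#' @param batch Numeric matrix.
#' @param noise_std Noise standard deviation (>= 0).
#' @return `batch + N(0, noise_std^2)` noise.
#' @export
add_noise <- function(batch, noise_std) {
  if (noise_std < 0) stop("noise_std must be >= 0", call. = FALSE)
  if (noise_std == 0) return(batch)
  batch + matrix(stats::rnorm(length(batch), sd = noise_std),
                 nrow(batch), ncol(batch))
}

#' Create the two augmented views of a mini-batch
#'
#' Two fully independent applications of [mask_genes()] (and [add_noise()]
#' when `noise_std > 0`); the views share no randomness.
#'
#' @param batch Numeric matrix with at least 2 rows.
#' @param cfg An [augment_config()].
#' @return A list with elements `view1` and `view2`.
#' @export
make_views <- function(batch, cfg = augment_config()) {
  if (nrow(batch) < 2L) stop("a batch needs at least 2 cells", call. = FALSE)
  one_view <- function() {
    v <- mask_genes(batch, cfg)
    if (cfg$noise_std > 0) v <- add_noise(v, cfg$noise_std)
    v
  }
  list(view1 = one_view(), view2 = one_view())
}
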