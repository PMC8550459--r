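#' Attention intensity configuration
#'
#' The intensity parameter `alpha` sets how strongly the training loss favours
#' the target class: a target image contributes with weight `alpha`, a
#' non-target image with weight `(1 - alpha) / (N - 1)`. `alpha = 1/N` weights
#' every class equally (no selective attention, the control model);
#' `alpha = 0.5` balances the target class against all non-target classes
#' combined; `alpha = 1` ignores non-target classes entirely. Values below
#' `1/N` (anti-attention to the target) are rejected.
#'
#' @param alpha Attention intensity in `[1/n_classes, 1]`.
#' @param n_classes Total number of classes N in the classification task.
#' @param target Non-empty integer set of target class ids in `1..N`.
#' @return An object of class `intensity_config`.
#' @examples
#' intensity_config(0.5, n_classes = 10, target = 3)
#' @export
intensity_config <- function(alpha, n_classes, target) {
  n_classes <- as.integer(n_classes)
  target <- as.integer(target)
  if (n_classes < 2L) stop("`n_classes` must be at least 2.")
  if (length(target) == 0L) stop("`target` must be a non-empty set of class ids.")
  if (any(target < 1L | target > n_classes)) {
    stop(sprintf("`target` must lie in 1..%d.", n_classes))
  }
  if (alpha < 1 / n_classes - 1e-12 || alpha > 1 + 1e-12) {
    stop(sprintf(
      "`alpha` = %g is outside [1/N, 1] = [%g, 1]: intensities below uniform weighting are not considered.",
      alpha, 1 / n_classes
    ))
  }
  structure(
    list(alpha = as.numeric(alpha), n_classes = n_classes,
         target = sort(unique(target))),
    class = "intensity_config"
  )
}

#' @export
print.intensity_config <- function(x, ...) {
  cat(sprintf("<intensity_config> alpha = %g, N = %d, target = {%s}\n",
              x$alpha, x$n_classes, paste(x$target, collapse = ",")))
  invisible(x)
}

#' The canonical attention intensity grid
#'
#' Five intensities expressed through the class count N: `1/N` (no selective
#' attention), `2/N` (weak), `0.5` (balanced), `(N-1)/N` (strong) and `1`
#' (complete target focus).
#'
#' @param n_classes Total number of classes N.
#' @return Numeric vector of length 5.
#' @examples
#' alpha_grid(10)
#' @export
alpha_grid <- function(n_classes) {
  N <- as.integer(n_classes)
  c(1 / N, 2 / N, 0.5, (N - 1) / N, 1)
}

#' Cross-entropy of the true-class probability
#'
#' `-log(p)` with the natural logarithm, for the probability the model assigns
#' to an image's true class. Probabilities at or below zero are clamped to
#' `floor` (with a warning) so training losses stay finite.
#'
#' @param prob_true_class Numeric vector of true-class probabilities in
#'   `(0, 1]`.
#' @param floor Clamping floor for non-positive probabilities.
#' @return Numeric vector of non-negative losses.
#' @examples
#' cross_entropy(c(1, 0.5, 0.25))
#' @export
cross_entropy <- function(prob_true_class, floor = 1e-12) {
  if (any(prob_true_class > 1 + 1e-9)) {
    stop("probabilities greater than 1 are invalid")
  }
  if (any(prob_true_class <= 0)) {
    warning(sprintf("%d non-positive probabilities clamped to %g before log",
                    sum(prob_true_class <= 0), floor))
    prob_true_class <- pmax(prob_true_class, floor)
  }
  -log(pmin(prob_true_class, 1))
}

#' Per-image loss weight under an intensity configuration
#'
#' Target-class images weigh `alpha`; non-target images weigh
#' `(1 - alpha) / (N - 1)`. At `alpha = 1/N` the two coincide and every image
#' carries the same weight.
#'
#' @param label Integer vector of class ids.
#' @param config An [intensity_config()].
#' @return Numeric vector of non-negative weights, one per label.
#' @examples
#' cfg <- intensity_config(0.5, 1000, target = 1)
#' per_image_weight(c(1, 2), cfg)
#' @export
per_image_weight <- function(label, config) {
  stopifnot(inherits(config, "intensity_config"))
  ifelse(label %in% config$target,
         config$alpha,
         (1 - config$alpha) / (config$n_classes - 1))
}

#' Weighted batch loss
#'
#' Sum over images of `per-image weight x subsample correction x
#' cross-entropy`. The batch reduction is a sum (not a mean), so `alpha`
#' keeps its interpretation as an absolute class weight.
#'
#' @param probs_true True-class probability per image.
#' @param labels Class id per image.
#' @param config An [intensity_config()].
#' @param sample_correction Up-weighting factor per image (`>= 1`),
#'   compensating for non-target subsampling; 1 for target images.
#' @return Single non-negative number.
#' @export
weighted_batch_loss <- function(probs_true, labels, config,
                                sample_correction = rep(1, length(labels))) {
  if (length(probs_true) != length(labels) ||
      length(labels) != length(sample_correction)) {
    stop(sprintf(
      "length mismatch: probs_true %d, labels %d, sample_correction %d",
      length(probs_true), length(labels), length(sample_correction)
    ))
  }
  sum(per_image_weight(labels, config) * sample_correction *
        cross_entropy(probs_true))
}

#' Correction factor for non-target subsampling
#'
#' When an epoch uses only `n_sampled` of a non-target class's
#' `n_class_images` training images, each sampled image is up-weighted by the
#' inverse sampling fraction so the class's expected contribution to the loss
#' is unchanged.
#'
#' @param n_class_images Number of training images the class has.
#' @param n_sampled Number of images drawn this epoch.
#' @return `n_class_images / n_sampled`, always `>= 1`.
#' @examples
#' subsample_correction(20, 2)
#' @export
subsample_correction <- function(n_class_images, n_sampled) {
  if (any(n_sampled < 1)) stop("`n_sampled` must be at least 1")
  if (any(n_sampled > n_class_images)) {
    stop("`n_sampled` cannot exceed `n_class_images`")
  }
  n_class_images / n_sampled
}
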