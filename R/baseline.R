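#' Retrain the final fully connected layer (non-attentional baseline)
#'
#' The transfer-learning comparator: the attention layer is absent (identity)
#' and only the final fully connected layer's parameters are trained, with
#' exactly the same weighted loss, per-epoch non-target subsampling, seeds
#' and early stopping as [train_attention()]. Under the same seed both
#' methods consume identical epoch samples and loss weights, so differences
#' in the resulting detection metrics are attributable to where the trainable
#' parameters sit.
#'
#' @param backbone A trained `conv_backbone` (all layers below the final one
#'   stay frozen).
#' @param split A [split_dataset()].
#' @param intensity An [intensity_config()].
#' @param train_cfg A [train_config()].
#' @param warm_start Start from the backbone's trained final-layer parameters
#'   (default) or from a fresh random initialisation.
#' @return A `retrain_fit`: list with `model` (a `conv_backbone` whose final
#'   layer is replaced, everything else untouched), `fc` (the new `Wfc`,
#'   `bfc`), `log`, `stopped_reason`, `epochs_run`, `epoch_ids`.
#' @export
retrain_final_layer <- function(backbone, split, intensity,
                                train_cfg = train_config(),
                                warm_start = TRUE) {
  stopifnot(inherits(backbone, "conv_backbone"),
            inherits(split, "split_dataset"),
            inherits(intensity, "intensity_config"))
  fit <- .run_weighted_training(backbone, split, intensity, train_cfg,
                                mode = "final", warm_start = warm_start)
  model <- backbone
  model$params$Wfc <- fit$fc$Wfc
  model$params$bfc <- fit$fc$bfc
  model$id <- paste0(backbone$id, "-retrained")
  fit$param <- NULL
  fit$model <- model
  fit$intensity <- intensity
  class(fit) <- "retrain_fit"
  fit
}

#' @export
print.retrain_fit <- function(x, ...) {
  cat(sprintf("<retrain_fit> alpha = %g, target = {%s}: %d epochs (%s)\n",
              x$intensity$alpha, paste(x$intensity$target, collapse = ","),
              x$epochs_run, x$stopped_reason))
  invisible(x)
}

#' Compare attention and retrain-final sweeps
#'
#' Pairs the two sweeps cell-by-cell (same target class, same intensity, same
#' test-set kind) and reports per-class differences in d' and criterion
#' (attention minus baseline) together with a paired t test across classes at
#' each intensity. A single shared class leaves the t statistic undefined
#' (flagged `NA`), not an error.
#'
#' @param attention_sweep,baseline_sweep `sweep_result` objects over the same
#'   target classes and intensities.
#' @param testset Which test-set kind to compare (`"standard"` or
#'   `"blended"`).
#' @return A list of class `model_comparison`: `differences` (tibble with
#'   `target`, `alpha`, `delta_dprime`, `delta_criterion`) and `tests`
#'   (tibble per alpha with paired t statistics for both measures).
#' @export
compare_models <- function(attention_sweep, baseline_sweep,
                           testset = "standard") {
  ma <- dplyr::filter(attention_sweep$metrics, .data$testset == !!testset)
  mb <- dplyr::filter(baseline_sweep$metrics, .data$testset == !!testset)
  if (!setequal(unique(ma$target), unique(mb$target))) {
    stop("the two sweeps cover different target-class lists")
  }
  if (!setequal(unique(ma$alpha), unique(mb$alpha))) {
    stop("the two sweeps cover different intensity grids")
  }
  j <- dplyr::inner_join(
    dplyr::select(ma, "target", "alpha",
                  dprime_attention = "dprime", criterion_attention = "criterion"),
    dplyr::select(mb, "target", "alpha",
                  dprime_baseline = "dprime", criterion_baseline = "criterion"),
    by = c("target", "alpha")
  )
  diffs <- dplyr::mutate(
    j,
    delta_dprime = .data$dprime_attention - .data$dprime_baseline,
    delta_criterion = .data$criterion_attention - .data$criterion_baseline
  )
  paired <- function(x) {
    if (length(x) < 2L || stats::sd(x) < .Machine$double.eps) {
      c(t = NA_real_, df = length(x) - 1L, p = NA_real_)
    } else {
      tt <- stats::t.test(x)
      c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
    }
  }
  tests <- dplyr::group_modify(
    dplyr::group_by(diffs, .data$alpha),
    function(d, key) {
      td <- paired(d$delta_dprime)
      tc <- paired(d$delta_criterion)
      tibble::tibble(
        n_classes = nrow(d),
        mean_delta_dprime = mean(d$delta_dprime),
        t_dprime = td["t"], df = td["df"], p_dprime = td["p"],
        mean_delta_criterion = mean(d$delta_criterion),
        t_criterion = tc["t"], p_criterion = tc["p"]
      )
    }
  )
  structure(
    list(differences = dplyr::select(
      diffs, "target", "alpha", "delta_dprime", "delta_criterion"
    ), tests = dplyr::ungroup(tests), testset = testset),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s test set\n", x$testset))
  print(x$tests)
  invisible(x)
}
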