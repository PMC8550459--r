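#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a sweep result into one row per evaluated cell
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return The metrics tibble: `target`, `alpha`, `method`, `testset`,
#'   counts, corrected rates, `dprime`, `criterion`, training epochs.
#' @method tidy sweep_result
#' @export
tidy.sweep_result <- function(x, ...) x$metrics

#' One-row summary of a sweep
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return Tibble with the sweep dimensions and (when defined) the
#'   standard-set ANOVA F across intensities and the paired t between the two
#'   best intensities.
#' @method glance sweep_result
#' @export
glance.sweep_result <- function(x, ...) {
  s <- x$stats
  tibble::tibble(
    method = x$method,
    n_targets = length(x$targets),
    n_alphas = length(x$alphas),
    anova_F = if (is.null(s)) NA_real_ else s$anova_F,
    anova_df1 = if (is.null(s)) NA_integer_ else s$anova_df[1L],
    anova_df2 = if (is.null(s)) NA_integer_ else s$anova_df[2L],
    paired_t = if (is.null(s)) NA_real_ else s$paired_t,
    paired_df = if (is.null(s)) NA_integer_ else s$paired_df,
    alpha_best = if (is.null(s)) NA_character_ else s$alpha_best
  )
}

#' @rdname train_attention
#' @param x An `attention_fit`.
#' @param ... Unused.
#' @method tidy attention_fit
#' @export
tidy.attention_fit <- function(x, ...) x$log

#' @rdname train_attention
#' @method glance attention_fit
#' @export
glance.attention_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$intensity$alpha,
    target = paste(x$intensity$target, collapse = ","),
    epochs = x$epochs_run,
    stopped_reason = x$stopped_reason,
    final_train_loss = utils::tail(x$log$train_loss, 1L),
    final_val_loss = utils::tail(stats::na.omit(x$log$val_loss), 1L),
    n_zeroed = count_zeroed(x$weights),
    weight_variance = weight_variance(x$weights)
  )
}

#' @rdname retrain_final_layer
#' @param x A `retrain_fit`.
#' @param ... Unused.
#' @method tidy retrain_fit
#' @export
tidy.retrain_fit <- function(x, ...) x$log

#' @rdname compare_models
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) x$differences

#' @rdname compare_models
#' @method glance model_comparison
#' @export
glance.model_comparison <- function(x, ...) x$tests

#' Plot the cost/benefit pattern of a sweep
#'
#' Mean metric across target classes as a function of attention intensity,
#' one panel per measure, separately for the standard and blended test sets.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics,
    cols = c("hit_rate", "fa_rate", "dprime", "criterion"),
    names_to = "measure", values_to = "value"
  )
  long$measure <- factor(long$measure,
                         levels = c("hit_rate", "fa_rate", "dprime", "criterion"))
  s <- dplyr::summarise(
    dplyr::group_by(long, .data$testset, .data$alpha, .data$measure),
    value = mean(.data$value), .groups = "drop"
  )
  ggplot2::ggplot(s, ggplot2::aes(x = .data$alpha, y = .data$value,
                                  colour = .data$testset)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "attention intensity (alpha)", y = NULL,
                  colour = "test set",
                  title = "Costs and benefits of goal-directed attention") +
    ggplot2::theme_minimal()
}

#' Plot training curves of an attention fit
#'
#' @param object An `attention_fit` or `retrain_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot attention_fit
#' @export
autoplot.attention_fit <- function(object, ...) {
  log <- object$log
  ggplot2::ggplot(log, ggplot2::aes(x = .data$epoch)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$train_loss,
                                    colour = "training")) +
    ggplot2::geom_point(
      data = log[!is.na(log$val_loss), ],
      ggplot2::aes(y = .data$val_loss, colour = "validation")
    ) +
    ggplot2::labs(x = "epoch", y = "weighted cross-entropy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot retrain_fit
#' @export
autoplot.retrain_fit <- autoplot.attention_fit

#' Plot attention-weight distributions across intensities
#'
#' Violin-style view of the trained attention weights pooled over target
#' classes, one distribution per intensity.
#'
#' @param sweep A `sweep_result` from the attention method.
#' @return A ggplot object.
#' @export
plot_weight_distributions <- function(sweep) {
  if (is.null(sweep$weights)) {
    stop("the sweep has no attention weights (retrain method?)")
  }
  rows <- purrr::map_dfr(sweep$weights, function(w) {
    tibble::tibble(alpha = w$alpha, weight = w$values)
  })
  ggplot2::ggplot(rows, ggplot2::aes(x = factor(.data$alpha),
                                     y = .data$weight)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::labs(x = "attention intensity (alpha)",
                  y = "attention weight") +
    ggplot2::theme_minimal()
}
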