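#' Construct filter-wise attention weights
#'
#' The attention layer is a single non-negative gain per convolutional filter
#' at the insertion point, shared across all spatial positions. Freshly
#' constructed weights are all exactly 1.0 (identity modulation); training
#' moves them in `[0, +Inf)`.
#'
#' @param n_filters Number of filters at the insertion point.
#' @param alpha Attention intensity the weights are (to be) trained at.
#' @param target Integer set of target class ids.
#' @param backbone_id Identifier of the frozen backbone.
#' @param values Optional initial values (default all ones).
#' @return An object of class `attention_weights`.
#' @examples
#' w <- attention_weights(8, alpha = 0.5, target = 1)
#' w$values
#' @export
attention_weights <- function(n_filters, alpha = NA_real_,
                              target = integer(), backbone_id = NA_character_,
                              values = NULL) {
  if (is.null(values)) values <- rep(1, n_filters)
  if (length(values) != n_filters) {
    stop(sprintf("values length %d does not match n_filters %d",
                 length(values), n_filters))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("attention weights must be finite and non-negative")
  }
  structure(
    list(values = as.numeric(values), alpha = alpha,
         target = as.integer(target), backbone_id = backbone_id),
    class = "attention_weights"
  )
}

#' @export
print.attention_weights <- function(x, ...) {
  cat(sprintf(
    "<attention_weights> %d filters, alpha = %s, target = {%s}; %d zeroed, var %.4g\n",
    length(x$values),
    ifelse(is.na(x$alpha), "?", format(x$alpha)),
    paste(x$target, collapse = ","),
    sum(x$values <= 1e-6),
    stats::var(x$values) * (length(x$values) - 1) / length(x$values)
  ))
  invisible(x)
}

.gain_values <- function(w, n_required = NULL) {
  v <- if (inherits(w, "attention_weights")) w$values else as.numeric(w)
  if (!is.null(n_required) && length(v) != n_required) {
    stop(sprintf(
      "attention weight length %d does not match filter count %d at the insertion point",
      length(v), n_required
    ))
  }
  v
}

#' Modulate an activation tensor with attention weights
#'
#' Hadamard (element-wise) product between activations and the filter-wise
#' attention weights, the same gain applied at every spatial position of a
#' filter's map.
#'
#' @param activations Array `(h, w, filters[, batch])`.
#' @param weights An [attention_weights()] object or numeric vector with one
#'   non-negative entry per filter.
#' @return Array of the same shape as `activations`.
#' @export
apply_attention <- function(activations, weights) {
  d <- dim(activations)
  if (length(d) == 3L) dim(activations) <- d <- c(d, 1L)
  v <- .gain_values(weights, d[3L])
  if (any(v < 0)) stop("attention weights must be non-negative")
  activations * rep(rep(v, each = d[1L] * d[2L]), times = d[4L])
}

#' Project attention weights onto the non-negative orthant
#'
#' Clamps every entry at zero (`max(entry, 0)`); idempotent. Applied after
#' every optimiser step during training so that a turned-off filter has a
#' weight of exactly 0.
#'
#' @param weights An [attention_weights()] object or numeric vector. Unlike
#'   the constructor, negative entries are accepted here (they are what the
#'   projection removes).
#' @return Object of the same type with all entries `>= 0`.
#' @export
project_nonnegative <- function(weights) {
  if (inherits(weights, "attention_weights")) {
    weights$values <- pmax(weights$values, 0)
    weights
  } else {
    pmax(as.numeric(weights), 0)
  }
}

#' A frozen backbone with an attention layer inserted
#'
#' Couples a frozen convolutional classifier with a set of filter-wise
#' attention weights applied at the backbone's insertion point. The backbone's
#' parameters are never changed by attention training; only `attention`
#' varies.
#'
#' @param backbone A `conv_backbone`.
#' @param attention An [attention_weights()] object; defaults to all ones
#'   (identity modulation).
#' @return An object of class `modulated_classifier`.
#' @examples
#' bb <- build_fixture_backbone(n_classes = 5, image_size = 32, seed = 1)
#' mc <- modulated_classifier(bb)
#' @export
modulated_classifier <- function(backbone,
                                 attention = attention_weights(
                                   insertion_filters(backbone),
                                   backbone_id = backbone$id
                                 )) {
  stopifnot(inherits(backbone, "conv_backbone"))
  .gain_values(attention, insertion_filters(backbone))
  structure(list(backbone = backbone, attention = attention),
            class = "modulated_classifier")
}

#' @export
print.modulated_classifier <- function(x, ...) {
  cat("<modulated_classifier>\n  ")
  print(x$backbone)
  cat("  ")
  print(x$attention)
  invisible(x)
}

#' @describeIn modulated_classifier Class probabilities under attention
#'   modulation: one row per image, rows sum to 1. With all-ones attention
#'   this equals the unmodulated backbone's output.
#' @param object A `modulated_classifier`.
#' @param newdata Images (`image_set`, `labeled_image`, or array).
#' @param ... Unused.
#' @export
predict.modulated_classifier <- function(object, newdata, ...) {
  p <- t(.net_forward(object$backbone, newdata, gain = object$attention)$probs)
  colnames(p) <- as.character(seq_len(object$backbone$n_classes))
  p
}
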