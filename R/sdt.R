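#' Max (top-k) decision rule
#'
#' Returns the k most probable classes; ties are broken toward the lowest
#' class index so the rule is deterministic.
#'
#' @param probs Probability vector (length N, summing to 1), or an `n x N`
#'   matrix of probabilities (one row per image).
#' @param k Number of classes to return.
#' @return Integer vector of k class ids for a vector input; an `n x k`
#'   integer matrix for a matrix input.
#' @examples
#' decide(c(0.1, 0.7, 0.2))
#' decide(c(0.4, 0.4, 0.2))        # tie -> lowest index
#' @export
decide <- function(probs, k = 1L) {
  if (is.matrix(probs)) {
    out <- t(apply(probs, 1L, .decide_one, k = k))
    if (k == 1L) dim(out) <- c(nrow(probs), 1L)
    return(out)
  }
  .decide_one(probs, k)
}

.decide_one <- function(p, k) {
  if (k > length(p)) {
    stop(sprintf("k = %d exceeds the number of classes (%d)", k, length(p)))
  }
  if (abs(sum(p) - 1) > 1e-4) {
    stop("`probs` must sum to 1")
  }
  order(-p, seq_along(p))[seq_len(k)]
}

#' Confusion counts for target detection
#'
#' @param hits,misses,false_alarms,correct_rejections Non-negative integers.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(hits, misses, false_alarms, correct_rejections) {
  v <- c(hits, misses, false_alarms, correct_rejections)
  if (any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers")
  }
  structure(
    list(hits = as.integer(hits), misses = as.integer(misses),
         false_alarms = as.integer(false_alarms),
         correct_rejections = as.integer(correct_rejections)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> hits %d, misses %d, FAs %d, CRs %d\n",
              x$hits, x$misses, x$false_alarms, x$correct_rejections))
  invisible(x)
}

# TRUE per trial when the model's response includes the target.
.pred_in_target <- function(predictions, target) {
  if (is.matrix(predictions)) {
    apply(predictions, 1L, function(r) any(r %in% target))
  } else {
    predictions %in% target
  }
}

#' Score standard (single-label) test trials
#'
#' A trial is target-present when its true label is in the target set. A hit
#' is a target response (the model's choice is in the target set) on a
#' target-present trial; a false alarm is a target response on a
#' target-absent trial.
#'
#' @param predictions Predicted class id per image (vector), or an `n x k`
#'   matrix of top-k choices (a target response is "target in the top k").
#' @param labels True class id per image.
#' @param target Integer set of target class ids.
#' @return A [confusion_counts()] object.
#' @export
score_standard <- function(predictions, labels, target) {
  n_pred <- if (is.matrix(predictions)) nrow(predictions) else length(predictions)
  if (n_pred != length(labels)) {
    stop(sprintf("length mismatch: %d predictions vs %d labels",
                 n_pred, length(labels)))
  }
  present <- labels %in% target
  said_target <- .pred_in_target(predictions, target)
  confusion_counts(
    hits = sum(present & said_target),
    misses = sum(present & !said_target),
    false_alarms = sum(!present & said_target),
    correct_rejections = sum(!present & !said_target)
  )
}

#' Score blended (two-label) test trials
#'
#' Each blended image carries two distinct ground-truth labels. A trial is
#' target-present when either label is in the target set; a hit is a target
#' response on such a trial and a false alarm is a target response when
#' neither label is a target.
#'
#' @param predictions Predicted class id per image (vector or top-k matrix).
#' @param label_pairs Two-column matrix (or data frame) of ground-truth label
#'   pairs, one row per blended image.
#' @param target Integer set of target class ids.
#' @return A [confusion_counts()] object.
#' @export
score_blended <- function(predictions, label_pairs, target) {
  label_pairs <- as.matrix(label_pairs)
  if (ncol(label_pairs) != 2L) stop("`label_pairs` must have two columns")
  if (any(label_pairs[, 1L] == label_pairs[, 2L])) {
    stop("blended images must carry two distinct ground-truth labels")
  }
  n_pred <- if (is.matrix(predictions)) nrow(predictions) else length(predictions)
  if (n_pred != nrow(label_pairs)) {
    stop(sprintf("length mismatch: %d predictions vs %d label pairs",
                 n_pred, nrow(label_pairs)))
  }
  present <- (label_pairs[, 1L] %in% target) | (label_pairs[, 2L] %in% target)
  said_target <- .pred_in_target(predictions, target)
  confusion_counts(
    hits = sum(present & said_target),
    misses = sum(present & !said_target),
    false_alarms = sum(!present & said_target),
    correct_rejections = sum(!present & !said_target)
  )
}

#' Hit and false-alarm rates with extreme-rate correction
#'
#' `H = hits / (hits + misses)` and `F = FAs / (FAs + CRs)`. Rates of exactly
#' 0 or 1 are replaced by `1/(2n)` and `1 - 1/(2n)` (n = trials of that
#' type), the standard correction that keeps the normal-model statistics
#' finite.
#'
#' @param counts A [confusion_counts()] object.
#' @return Named numeric vector `c(H = ..., F = ...)`.
#' @examples
#' rates(confusion_counts(10, 0, 0, 10))
#' @export
rates <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n_present <- counts$hits + counts$misses
  n_absent <- counts$false_alarms + counts$correct_rejections
  if (n_present < 1L || n_absent < 1L) {
    stop("need at least one target-present and one target-absent trial")
  }
  fix <- function(r, n) {
    if (r <= 0) 1 / (2 * n) else if (r >= 1) 1 - 1 / (2 * n) else r
  }
  c(H = fix(counts$hits / n_present, n_present),
    F = fix(counts$false_alarms / n_absent, n_absent))
}

#' Sensitivity d' from hit and false-alarm rates
#'
#' `d' = z(H) - z(F)` with z the standard-normal quantile function. Rates must
#' lie strictly inside (0, 1); apply [rates()] first for finite counts.
#'
#' @param H Hit rate in (0, 1).
#' @param F False-alarm rate in (0, 1).
#' @return Numeric d'.
#' @examples
#' dprime(0.84, 0.16)
#' @export
dprime <- function(H, F) {
  .check_rate(H, "H"); .check_rate(F, "F")
  stats::qnorm(H) - stats::qnorm(F)
}

#' Criterion location c
#'
#' `c = -(z(H) + z(F)) / 2`: negative values indicate a liberal bias toward
#' responding "target".
#'
#' @inheritParams dprime
#' @return Numeric criterion location.
#' @examples
#' criterion_location(0.9, 0.5)
#' @export
criterion_location <- function(H, F) {
  .check_rate(H, "H"); .check_rate(F, "F")
  -(stats::qnorm(H) + stats::qnorm(F)) / 2
}

.check_rate <- function(x, nm) {
  if (any(x <= 0 | x >= 1)) {
    stop(sprintf("`%s` must lie strictly inside (0, 1); correct extreme rates first", nm))
  }
}

#' Full signal-detection summary for one set of counts
#'
#' @param counts A [confusion_counts()] object.
#' @return One-row tibble with the counts, corrected rates, `dprime` and
#'   `criterion`.
#' @export
sdt_metrics <- function(counts) {
  r <- rates(counts)
  tibble::tibble(
    hits = counts$hits, misses = counts$misses,
    false_alarms = counts$false_alarms,
    correct_rejections = counts$correct_rejections,
    hit_rate = unname(r["H"]), fa_rate = unname(r["F"]),
    dprime = dprime(r["H"], r["F"]),
    criterion = criterion_location(r["H"], r["F"])
  )
}

#' Intensity-sweep statistics over a d' matrix
#'
#' One-way ANOVA of d' across intensity levels, treating each (target class,
#' intensity) cell as one observation grouped by intensity (df = (A - 1,
#' A*C - A) for C classes and A levels), plus a paired t test across classes
#' between the highest-mean and second-highest-mean intensity columns
#' (df = C - 1). Degenerate inputs (no variance) are flagged rather than
#' raised.
#'
#' @param dprime_matrix Numeric matrix, target classes x intensity levels;
#'   column names are taken as the intensity labels.
#' @return A list of class `sweep_stats`: `anova_F`, `anova_df`, `anova_p`,
#'   `paired_t`, `paired_df`, `paired_p`, `alpha_best`, `alpha_second`, and a
#'   character vector `flags` naming any degenerate statistic.
#' @export
sweep_statistics <- function(dprime_matrix) {
  m <- as.matrix(dprime_matrix)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 target classes and 2 intensity levels")
  }
  if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
  A <- ncol(m); C <- nrow(m)
  flags <- character(0)
  long <- data.frame(
    d = as.vector(m),
    level = factor(rep(colnames(m), each = C), levels = colnames(m))
  )
  anova_df <- c(A - 1L, A * C - A)
  if (stats::var(long$d) < .Machine$double.eps) {
    anova_F <- NA_real_; anova_p <- NA_real_
    flags <- c(flags, "anova_no_variance")
  } else {
    ft <- stats::anova(stats::lm(d ~ level, data = long))
    anova_F <- ft[["F value"]][1L]
    anova_p <- ft[["Pr(>F)"]][1L]
    anova_df <- c(ft$Df[1L], ft$Df[2L])
  }
  mu <- colMeans(m)
  ord <- order(-mu, seq_len(A))
  best <- ord[1L]; second <- ord[2L]
  diffs <- m[, best] - m[, second]
  if (stats::sd(diffs) < .Machine$double.eps) {
    paired_t <- NA_real_; paired_p <- NA_real_
    flags <- c(flags, "paired_t_no_variance")
  } else {
    tt <- stats::t.test(m[, best], m[, second], paired = TRUE)
    paired_t <- unname(tt$statistic)
    paired_p <- tt$p.value
  }
  structure(
    list(
      anova_F = anova_F, anova_df = anova_df, anova_p = anova_p,
      paired_t = paired_t, paired_df = C - 1L, paired_p = paired_p,
      alpha_best = colnames(m)[best], alpha_second = colnames(m)[second],
      flags = flags
    ),
    class = "sweep_stats"
  )
}

#' @export
print.sweep_stats <- function(x, ...) {
  cat(sprintf(
    "<sweep_stats> F(%d,%d) = %s, p = %s; paired t(%d) = %s (best %s vs %s)%s\n",
    x$anova_df[1L], x$anova_df[2L],
    ifelse(is.na(x$anova_F), "undef", sprintf("%.2f", x$anova_F)),
    ifelse(is.na(x$anova_p), "undef", format.pval(x$anova_p, digits = 3)),
    x$paired_df,
    ifelse(is.na(x$paired_t), "undef", sprintf("%.2f", x$paired_t)),
    x$alpha_best, x$alpha_second,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""
  ))
  invisible(x)
}
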