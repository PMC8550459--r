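#' Training configuration for attention (and final-layer) training
#'
#' Defaults follow the training regime used throughout: Adam with learning
#' rate 0.0003 and batch size 16; at most 5000 epochs; each epoch uses all
#' target-class training images plus a fresh random 10% of each non-target
#' class (up-weighted in the loss to correct the imbalance); validation loss
#' is checked every 2 epochs and training stops once the relative improvement
#' is below 0.1% at two consecutive checks.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param nontarget_fraction Fraction of each non-target class sampled per
#'   epoch, in `(0, 1]`.
#' @param check_interval Epochs between validation-loss checks.
#' @param rel_improve_threshold Relative improvement below which a check
#'   counts toward stopping, in `(0, 1)`.
#' @param consecutive_checks_to_stop Consecutive sub-threshold checks needed.
#' @param train_fraction Per-class fraction of the pool used for training
#'   (remainder is validation) when splitting.
#' @param seed Integer seed driving all sampling in the run.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 3e-4, batch_size = 16L,
                         max_epochs = 5000L, nontarget_fraction = 0.1,
                         check_interval = 2L, rel_improve_threshold = 0.001,
                         consecutive_checks_to_stop = 2L,
                         train_fraction = 0.9, seed = 1L) {
  stopifnot(
    learning_rate > 0, batch_size >= 1, max_epochs >= 1,
    nontarget_fraction > 0, nontarget_fraction <= 1,
    check_interval >= 1,
    rel_improve_threshold > 0, rel_improve_threshold < 1,
    consecutive_checks_to_stop >= 1,
    train_fraction > 0
  )
  structure(
    list(
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs),
      nontarget_fraction = nontarget_fraction,
      check_interval = as.integer(check_interval),
      rel_improve_threshold = rel_improve_threshold,
      consecutive_checks_to_stop = as.integer(consecutive_checks_to_stop),
      train_fraction = train_fraction, seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Split an image pool into train / validation / test sets
#'
#' Per-class random split: `round(train_fraction * n)` of each class's images
#' train, the remainder validate. An optional test fraction is held out first
#' (the evaluation experiments draw their stimuli from it). Deterministic
#' given the seed; splits are disjoint by image id and every class appears in
#' every non-empty split.
#'
#' @param pool An `image_set`.
#' @param train_fraction Fraction of the (post-test) pool trained on; must
#'   leave at least one validation image per class.
#' @param seed Integer seed.
#' @param test_fraction Fraction of each class held out as test images.
#' @return A `split_dataset`: list with `image_set`s `train`, `validation`,
#'   `test`.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_classes = 3, images_per_class = 10))
#' sp <- split_dataset(ds, train_fraction = 0.9, seed = 1)
#' length(sp$train); length(sp$validation)
#' @export
split_dataset <- function(pool, train_fraction = 0.9, seed = 1L,
                          test_fraction = 0) {
  stopifnot(inherits(pool, "image_set"))
  if (train_fraction >= 1) {
    stop("`train_fraction` must be < 1: the validation split would be empty.")
  }
  classes <- sort(unique(pool$info$class))
  counts <- table(pool$info$class)
  small <- names(counts)[counts < 3L]
  if (length(small) > 0L) {
    stop(sprintf("every class needs at least 3 images; class(es) %s have fewer",
                 paste(small, collapse = ", ")))
  }
  idx_train <- integer(0); idx_val <- integer(0); idx_test <- integer(0)
  .with_seed(seed, {
    for (k in classes) {
      idx <- which(pool$info$class == k)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_test <- round(test_fraction * n)
      n_train <- round(train_fraction * (n - n_test))
      n_val <- n - n_test - n_train
      if (n_val < 1L) {
        stop(sprintf("class %s would have an empty validation split", k))
      }
      idx_test <- c(idx_test, idx[seq_len(n_test)])
      idx_train <- c(idx_train, idx[n_test + seq_len(n_train)])
      idx_val <- c(idx_val, idx[n_test + n_train + seq_len(n_val)])
    }
  })
  structure(
    list(
      train = .img_subset(pool, sort(idx_train)),
      validation = .img_subset(pool, sort(idx_val)),
      test = .img_subset(pool, sort(idx_test))
    ),
    class = "split_dataset"
  )
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("<split_dataset> train %d / validation %d / test %d images\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Draw one epoch's training sample
#'
#' Every training image of each target class is included with correction 1.
#' For each non-target class with `n` training images, `max(1, round(fraction
#' * n))` images are drawn without replacement, each carrying the inverse
#' sampling fraction as its loss correction. A fresh sample is drawn on every
#' call (the trainer derives a per-epoch seed).
#'
#' @param split A [split_dataset()].
#' @param config An [intensity_config()] naming the target classes.
#' @param fraction Non-target sampling fraction in `(0, 1]`.
#' @param seed Integer seed for this draw.
#' @return Tibble with columns `index` (position in the train set), `id`,
#'   `class`, `correction`.
#' @export
make_epoch_sample <- function(split, config, fraction = 0.1, seed = 1L) {
  info <- split$train$info
  cl <- split(seq_len(nrow(info)), info$class)
  es <- .epoch_sample_idx(cl, config$target, fraction, seed)
  tibble::tibble(
    index = es$index,
    id = info$id[es$index],
    class = info$class[es$index],
    correction = es$correction
  )
}

# Lean integer core of make_epoch_sample, used inside the training loop.
# `class_idx` is a list of train-set row indices named by class id.
.epoch_sample_idx <- function(class_idx, target, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  .with_seed(seed, {
    idx_out <- vector("list", length(class_idx))
    corr_out <- vector("list", length(class_idx))
    for (i in seq_along(class_idx)) {
      idx <- class_idx[[i]]
      if (as.integer(names(class_idx)[i]) %in% target) {
        idx_out[[i]] <- idx
        corr_out[[i]] <- rep(1, length(idx))
      } else {
        s <- max(1L, round(fraction * length(idx)))
        idx_out[[i]] <- idx[sample.int(length(idx), s)]
        corr_out[[i]] <- rep(length(idx) / s, s)
      }
    }
    list(index = unlist(idx_out, use.names = FALSE),
         correction = unlist(corr_out, use.names = FALSE))
  })
}

#' Early-stopping decision from validation-loss checks
#'
#' Stops once the most recent `consecutive` relative improvements
#' `(L_prev - L_curr) / L_prev` are each below `threshold` (a worsening loss
#' counts as a sub-threshold improvement). With fewer than `consecutive + 1`
#' checks there is not enough history to stop.
#'
#' @param validation_losses Validation losses at successive checks, in time
#'   order.
#' @param threshold Relative-improvement threshold.
#' @param consecutive Number of consecutive sub-threshold checks required.
#' @return Logical.
#' @examples
#' should_stop(c(1.0, 0.9995, 0.99945))        # TRUE
#' should_stop(c(1.0, 0.9, 0.8995))            # FALSE
#' @export
should_stop <- function(validation_losses, threshold = 0.001,
                        consecutive = 2L) {
  n <- length(validation_losses)
  if (n < consecutive + 1L) return(FALSE)
  prev <- validation_losses[(n - consecutive):(n - 1L)]
  curr <- validation_losses[(n - consecutive + 1L):n]
  all((prev - curr) / prev < threshold)
}

# ---- fast tail (post-insertion) machinery -----------------------------------
# During attention training the backbone below the insertion point never
# changes, so insertion activations are computed once per dataset. Because
# the attention gain scales whole channels, the convolution patch matrix of
# the modulated activations equals the cached patch matrix with its columns
# scaled, which removes the per-step im2col cost.

.tail_cache <- function(bb, acts) {
  ins <- .insertion_index(bb)
  d <- dim(acts)
  list(
    ins = ins,
    acts = if (ins == 3L) acts else NULL,
    M = if (ins < 3L) .im2col(acts, 3L) else NULL,
    rows_per_image = d[1L] * d[2L],
    hw = d[1:2],
    n = d[4L]
  )
}

.tail_run <- function(bb, tc, sel, g, keep = FALSE) {
  ins <- tc$ins
  B <- length(sel)
  H <- tc$hw[1L]; W <- tc$hw[2L]
  cache <- list(B = B)
  if (ins == 3L) {
    a0 <- tc$acts[, , , sel, drop = FALSE]
    am <- a0 * rep(rep(g, each = H * W), times = B)
    feat <- matrix(am, ncol = B)
    if (keep) cache$a0 <- a0
  } else {
    l1 <- ins + 1L
    rpi <- tc$rows_per_image
    rows <- rep((sel - 1L) * rpi, each = rpi) + seq_len(rpi)
    Mb <- tc$M[rows, , drop = FALSE]
    Wl <- bb$params[[paste0("W", l1)]]
    Fl <- dim(Wl)[4L]
    # channel gains scale the patch-matrix columns; fold them into the (much
    # smaller) kernel matrix instead: Mb diag(gcol) W == Mb (gcol * W)
    Wg <- matrix(Wl, ncol = Fl) * rep(g, each = 9L)
    y <- Mb %*% Wg
    y <- y + matrix(bb$params[[paste0("b", l1)]], nrow(y), Fl, byrow = TRUE)
    pre <- aperm(array(y, c(H, W, B, Fl)), c(1L, 2L, 4L, 3L))
    pl <- .pool_fwd(.relu(pre), masks = keep)
    h <- pl$y
    if (keep) {
      cache$Mb <- Mb
      cache$pre1 <- pre
      cache$pool1 <- pl[c("masks", "in_dim")]
    }
    if (l1 < 3L) {
      for (l in (l1 + 1L):3L) {
        cv <- .conv_fwd(h, bb$params[[paste0("W", l)]],
                        bb$params[[paste0("b", l)]])
        pl <- .pool_fwd(.relu(cv$y), masks = keep)
        if (keep) {
          cache[[paste0("cols", l)]] <- cv$cols
          cache[[paste0("pre", l)]] <- cv$y
          cache[[paste0("pool", l)]] <- pl[c("masks", "in_dim")]
        }
        h <- pl$y
      }
    }
    feat <- matrix(h, ncol = B)
  }
  logits <- crossprod(bb$params$Wfc, feat) + bb$params$bfc
  if (keep) cache$feat <- feat
  list(probs = .softmax(logits), cache = cache)
}

# Gradient of the loss w.r.t. the attention gain, given dlogits (N x B).
.tail_grad_gain <- function(bb, tc, cache, dlogits, g) {
  ins <- tc$ins
  B <- cache$B
  dfeat <- bb$params$Wfc %*% dlogits
  if (ins == 3L) {
    da <- array(dfeat, c(tc$hw, length(g), B))
    return(apply(da * cache$a0, 3L, sum))
  }
  if (ins == 1L) {
    pl3 <- cache$pool3
    dh <- array(dfeat, c(pl3$in_dim[1L] %/% 2L, pl3$in_dim[2L] %/% 2L,
                         pl3$in_dim[3L], B))
    da <- .pool_bwd(pl3, dh)
    dpre <- da * (cache$pre3 > 0)
    dh <- .conv_bwd(cache$cols3, bb$params$W3, dpre)$dx
  } else {
    pl1 <- cache$pool1
    dh <- array(dfeat, c(pl1$in_dim[1L] %/% 2L, pl1$in_dim[2L] %/% 2L,
                         pl1$in_dim[3L], B))
  }
  pl1 <- cache$pool1
  da <- .pool_bwd(pl1, dh)
  dpre <- da * (cache$pre1 > 0)
  l1 <- ins + 1L
  Wl <- bb$params[[paste0("W", l1)]]
  Fl <- dim(Wl)[4L]
  dym <- matrix(aperm(dpre, c(1L, 2L, 4L, 3L)), ncol = Fl)
  dcols <- tcrossprod(dym, matrix(Wl, ncol = Fl))
  colSums(matrix(colSums(dcols * cache$Mb), 9L, length(g)))
}

# Weighted validation loss of the gain on a cached dataset.
.tail_val_loss <- function(bb, tc, g, labels, weights) {
  probs <- .tail_run(bb, tc, seq_len(tc$n), g)$probs
  pt <- probs[cbind(labels, seq_along(labels))]
  sum(weights * -log(pmax(pt, 1e-12)))
}

#' Train the attention weights for one (target class, intensity) pair
#'
#' Gradient training of the filter-wise attention gain with the weighted
#' cross-entropy loss, keeping every backbone parameter fixed. Each epoch
#' uses all target-class training images plus a fresh subsample of each
#' non-target class (see [make_epoch_sample()]); after every Adam step the
#' weights are projected back onto `[0, +Inf)`, so switched-off filters are
#' exactly zero. Validation loss (weighted cross-entropy over the full
#' validation set, no subsampling) is checked every `check_interval` epochs
#' and drives early stopping via [should_stop()]. The run is fully
#' reproducible from `train_cfg$seed`.
#'
#' @param model A [modulated_classifier()] whose attention is all ones.
#' @param split A [split_dataset()].
#' @param intensity An [intensity_config()].
#' @param train_cfg A [train_config()].
#' @return An `attention_fit`: list with `weights` (an
#'   [attention_weights()]), `log` (tibble `epoch`, `train_loss`, `val_loss`
#'   with `NA` off checks), `stopped_reason` (`"early_stop"` or
#'   `"max_epochs"`), `epochs_run`, and the sampled id sequence per epoch in
#'   `epoch_ids`.
#' @export
train_attention <- function(model, split, intensity,
                            train_cfg = train_config()) {
  stopifnot(inherits(model, "modulated_classifier"),
            inherits(split, "split_dataset"),
            inherits(intensity, "intensity_config"))
  bb <- model$backbone
  g <- .gain_values(model$attention, insertion_filters(bb))
  if (any(abs(g - 1) > 1e-9)) {
    stop("attention must be initialised to all ones before training")
  }
  fit <- .run_weighted_training(bb, split, intensity, train_cfg,
                                mode = "attention")
  fit$weights <- attention_weights(
    length(fit$param), alpha = intensity$alpha, target = intensity$target,
    backbone_id = bb$id, values = fit$param
  )
  fit$param <- NULL
  fit$intensity <- intensity
  class(fit) <- "attention_fit"
  fit
}

#' @export
print.attention_fit <- function(x, ...) {
  cat(sprintf("<attention_fit> alpha = %g, target = {%s}: %d epochs (%s)\n",
              x$intensity$alpha, paste(x$intensity$target, collapse = ","),
              x$epochs_run, x$stopped_reason))
  invisible(x)
}

# Shared training loop for attention gains ("attention") and the final
# fully connected layer ("final"); both consume identical epoch samples and
# loss weights under the same seed.
.run_weighted_training <- function(bb, split, intensity, cfg, mode,
                                   warm_start = TRUE) {
  tr <- split$train; va <- split$validation
  acts_tr <- insertion_activations(bb, tr)
  acts_va <- insertion_activations(bb, va)
  n_tr <- length(tr)
  if (mode == "final") {
    # cache penultimate features once: only the fc layer changes
    ones <- rep(1, insertion_filters(bb))
    tc0 <- .tail_cache(bb, acts_tr)
    feat_tr <- .tail_feats(bb, tc0, ones)
    feat_va <- .tail_feats(bb, .tail_cache(bb, acts_va), ones)
    params <- if (warm_start) {
      list(Wfc = bb$params$Wfc, bfc = bb$params$bfc)
    } else {
      .with_seed(cfg$seed, list(
        Wfc = matrix(stats::rnorm(length(bb$params$Wfc), 0,
                                  sqrt(1 / nrow(bb$params$Wfc))),
                     nrow(bb$params$Wfc), ncol(bb$params$Wfc)),
        bfc = numeric(length(bb$params$bfc))
      ))
    }
  } else {
    tc_tr <- .tail_cache(bb, acts_tr)
    tc_va <- .tail_cache(bb, acts_va)
    params <- list(g = rep(1, insertion_filters(bb)))
  }
  labels_tr <- tr$info$class
  labels_va <- va$info$class
  ids_tr <- tr$info$id
  class_idx <- split(seq_len(n_tr), labels_tr)
  w_img <- per_image_weight(labels_tr, intensity)
  w_va <- per_image_weight(labels_va, intensity)
  st <- .adam_init(params)
  N <- bb$n_classes
  train_loss <- rep(NA_real_, cfg$max_epochs)
  val_loss <- rep(NA_real_, cfg$max_epochs)
  val_checks <- numeric(0)
  epoch_ids <- list()
  stopped <- "max_epochs"
  epochs_run <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    es <- .epoch_sample_idx(class_idx, intensity$target,
                            cfg$nontarget_fraction,
                            .epoch_seed(cfg$seed, epoch))
    n_ep <- length(es$index)
    ord <- .with_seed(.epoch_seed(cfg$seed, epoch) + 1L, sample.int(n_ep))
    sel_ep <- es$index[ord]
    cls_ep <- labels_tr[sel_ep]
    epoch_ids[[epoch]] <- ids_tr[sel_ep]
    wts <- w_img[sel_ep] * es$correction[ord]
    ep_loss <- 0
    for (start in seq(1L, n_ep, by = cfg$batch_size)) {
      b <- start:min(start + cfg$batch_size - 1L, n_ep)
      sel <- sel_ep[b]
      B <- length(b)
      if (mode == "final") {
        feat <- feat_tr[, sel, drop = FALSE]
        logits <- crossprod(params$Wfc, feat) + params$bfc
        probs <- .softmax(logits)
      } else {
        fw <- .tail_run(bb, tc_tr, sel, params$g, keep = TRUE)
        probs <- fw$probs
      }
      pt <- probs[cbind(cls_ep[b], seq_len(B))]
      ep_loss <- ep_loss + sum(wts[b] * -log(pmax(pt, 1e-12)))
      y <- matrix(0, N, B)
      y[cbind(cls_ep[b], seq_len(B))] <- 1
      dlogits <- (probs - y) * rep(wts[b], each = N)
      grads <- if (mode == "final") {
        list(Wfc = feat %*% t(dlogits), bfc = rowSums(dlogits))
      } else {
        list(g = .tail_grad_gain(bb, tc_tr, fw$cache, dlogits, params$g))
      }
      upd <- .adam_step(params, grads, st, cfg$learning_rate)
      params <- upd$params
      st <- upd$state
      if (mode == "attention") params$g <- pmax(params$g, 0)
    }
    if (!is.finite(ep_loss)) {
      stop(sprintf("non-finite training loss at epoch %d", epoch))
    }
    train_loss[epoch] <- ep_loss
    epochs_run <- epoch
    if (epoch %% cfg$check_interval == 0L) {
      vl <- if (mode == "final") {
        probs <- .softmax(crossprod(params$Wfc, feat_va) + params$bfc)
        pt <- probs[cbind(labels_va, seq_along(labels_va))]
        sum(w_va * -log(pmax(pt, 1e-12)))
      } else {
        .tail_val_loss(bb, tc_va, params$g, labels_va, w_va)
      }
      val_loss[epoch] <- vl
      val_checks <- c(val_checks, vl)
      if (should_stop(val_checks, cfg$rel_improve_threshold,
                      cfg$consecutive_checks_to_stop)) {
        stopped <- "early_stop"
        break
      }
    }
  }
  list(
    param = if (mode == "final") params else params$g,
    fc = if (mode == "final") params else NULL,
    log = tibble::tibble(
      epoch = seq_len(epochs_run),
      train_loss = train_loss[seq_len(epochs_run)],
      val_loss = val_loss[seq_len(epochs_run)]
    ),
    stopped_reason = stopped,
    epochs_run = epochs_run,
    epoch_ids = epoch_ids,
    config = cfg
  )
}

# Penultimate (pre-fc) features for all cached images under a fixed gain.
.tail_feats <- function(bb, tc, g) {
  ins <- tc$ins
  n <- tc$n
  if (ins == 3L) {
    am <- tc$acts * rep(rep(g, each = prod(tc$hw)), times = n)
    return(matrix(am, ncol = n))
  }
  # run the tail once over everything, reusing .tail_run's plumbing
  fwcache <- .tail_run(bb, tc, seq_len(n), g, keep = TRUE)
  fwcache$cache$feat
}
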