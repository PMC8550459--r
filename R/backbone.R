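#' Build the fixture convolutional backbone
#'
#' A miniature feed-forward convolutional classifier: three conv blocks
#' (3x3 same conv, ReLU, 2x2 max pool) followed by one fully connected
#' softmax layer. The named insertion point for the attention layer defaults
#' to the output of the penultimate convolutional block (`"block2"`), whose
#' filter count fixes the length of the attention weight vector.
#'
#' @param n_classes Number of output classes N.
#' @param image_size Input side length in pixels (multiple of 8).
#' @param filters Integer vector of length 3: filters per conv block.
#' @param seed Seed for the deterministic parameter initialisation.
#' @return An object of class `conv_backbone`.
#' @examples
#' bb <- build_fixture_backbone(n_classes = 10, image_size = 32, seed = 1)
#' insertion_filters(bb)
#' @export
build_fixture_backbone <- function(n_classes, image_size = 32L,
                                   filters = c(16L, 32L, 32L), seed = 1L) {
  stopifnot(length(filters) == 3L, image_size %% 8L == 0L)
  in_ch <- c(3L, filters[1L], filters[2L])
  final_hw <- image_size %/% 8L
  p_flat <- final_hw * final_hw * filters[3L]
  params <- .with_seed(seed, {
    p <- list()
    for (l in 1:3) {
      fan_in <- 9L * in_ch[l]
      p[[paste0("W", l)]] <- array(
        stats::rnorm(9L * in_ch[l] * filters[l], 0, sqrt(2 / fan_in)),
        c(3L, 3L, in_ch[l], filters[l])
      )
      p[[paste0("b", l)]] <- numeric(filters[l])
    }
    # small final-layer init so an untrained net outputs near-uniform
    # probabilities (each within a factor ~2 of 1/N)
    p$Wfc <- matrix(stats::rnorm(p_flat * n_classes, 0, 0.01),
                    p_flat, n_classes)
    p$bfc <- numeric(n_classes)
    p
  })
  structure(
    list(
      params = params,
      n_classes = as.integer(n_classes),
      image_size = as.integer(image_size),
      filters = as.integer(filters),
      insertion = "block2",
      id = sprintf("fixture-cnn-%d-%d-%d", n_classes, image_size, seed),
      trained = FALSE
    ),
    class = "conv_backbone"
  )
}

#' @export
print.conv_backbone <- function(x, ...) {
  cat(sprintf(
    "<conv_backbone> %s: %d classes, %dpx input, blocks [%s], insertion after %s (%d filters)%s\n",
    x$id, x$n_classes, x$image_size,
    paste(x$filters, collapse = ", "), x$insertion,
    insertion_filters(x), if (x$trained) ", trained" else ", untrained"
  ))
  invisible(x)
}

#' Filter count at the attention insertion point
#'
#' @param backbone A `conv_backbone`.
#' @return Integer number of filters whose activations the attention layer
#'   modulates; equals the required attention-weight length.
#' @export
insertion_filters <- function(backbone) {
  backbone$filters[.insertion_index(backbone)]
}

.insertion_index <- function(backbone) {
  i <- match(backbone$insertion, c("block1", "block2", "block3"))
  if (is.na(i)) stop("unknown insertion point: ", backbone$insertion)
  i
}

# Coerce image input (image_set, labeled_image, or array) to (H, W, C, B).
.as_image_batch <- function(x) {
  if (inherits(x, "image_set")) return(x$images)
  if (inherits(x, "labeled_image")) x <- x$pixels
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) stop("expected an image array (H, W, C[, B])")
  x
}

# Full forward pass. `gain` (numeric vector or attention_weights) multiplies
# every channel of the insertion block's output; NULL means no modulation.
# Returns list(probs = N x B, cache) where cache holds everything the
# backward pass needs.
.net_forward <- function(bb, x, gain = NULL, keep = FALSE) {
  x <- .as_image_batch(x)
  if (dim(x)[1L] != bb$image_size || dim(x)[3L] != 3L) {
    stop(sprintf("input shape (%s) does not match backbone input contract (%dx%dx3)",
                 paste(dim(x)[1:3], collapse = "x"), bb$image_size, bb$image_size))
  }
  ins <- .insertion_index(bb)
  if (!is.null(gain)) gain <- .gain_values(gain, bb$filters[ins])
  B <- dim(x)[4L]
  cache <- list(ins = ins, B = B)
  h <- x
  for (l in 1:3) {
    cv <- .conv_fwd(h, bb$params[[paste0("W", l)]], bb$params[[paste0("b", l)]])
    a <- .relu(cv$y)
    pl <- .pool_fwd(a, masks = keep)
    h <- pl$y
    if (l == ins && !is.null(gain)) {
      d <- dim(h)
      h <- h * rep(rep(gain, each = d[1L] * d[2L]), times = d[4L])
    }
    if (keep) {
      cache[[paste0("cols", l)]] <- cv$cols
      cache[[paste0("pre", l)]] <- cv$y
      cache[[paste0("pool", l)]] <- pl[c("masks", "in_dim")]
      cache[[paste0("out", l)]] <- h
    }
  }
  feat <- matrix(h, ncol = B)
  logits <- crossprod(bb$params$Wfc, feat) + bb$params$bfc
  probs <- .softmax(logits)
  if (keep) {
    cache$feat <- feat
    cache$gain <- gain
  }
  list(probs = probs, cache = cache)
}

# Backward from dlogits (N x B) through the whole net.
# wrt = "backbone": gradients for all parameters (no gain in the graph).
# wrt = "final": gradient for the fully connected layer only.
.net_backward <- function(bb, cache, dlogits, wrt = c("backbone", "final")) {
  wrt <- match.arg(wrt)
  grads <- list(
    Wfc = cache$feat %*% t(dlogits),
    bfc = rowSums(dlogits)
  )
  if (wrt == "final") return(grads)
  dfeat <- bb$params$Wfc %*% dlogits
  dh <- array(dfeat, dim = c(cache$pool3$in_dim[1:2] / 2L,
                             bb$filters[3L], cache$B))
  for (l in 3:1) {
    pl <- cache[[paste0("pool", l)]]
    da <- .pool_bwd(pl, dh)
    dpre <- da * (cache[[paste0("pre", l)]] > 0)
    cb <- .conv_bwd(cache[[paste0("cols", l)]], bb$params[[paste0("W", l)]],
                    dpre, need_dx = l > 1L)
    grads[[paste0("W", l)]] <- cb$dW
    grads[[paste0("b", l)]] <- cb$db
    if (l > 1L) dh <- cb$dx
  }
  grads
}

#' Class probabilities from a backbone
#'
#' @param object A `conv_backbone`.
#' @param newdata An `image_set`, `labeled_image`, or pixel array
#'   `(H, W, C[, B])`.
#' @param ... Unused.
#' @return Matrix of class probabilities, one row per image, columns named by
#'   class index; each row sums to 1.
#' @export
predict.conv_backbone <- function(object, newdata, ...) {
  p <- t(.net_forward(object, newdata)$probs)
  colnames(p) <- as.character(seq_len(object$n_classes))
  p
}

#' Activations at the attention insertion point
#'
#' Runs the backbone up to (and including) its insertion block and returns the
#' activation tensor the attention layer multiplies.
#'
#' @param backbone A `conv_backbone`.
#' @param x Images (`image_set` or array).
#' @return Array `(h, w, filters, batch)`.
#' @export
insertion_activations <- function(backbone, x) {
  x <- .as_image_batch(x)
  ins <- .insertion_index(backbone)
  h <- x
  for (l in seq_len(ins)) {
    cv <- .conv_fwd(h, backbone$params[[paste0("W", l)]],
                    backbone$params[[paste0("b", l)]])
    h <- .pool_fwd(.relu(cv$y), masks = FALSE)$y
  }
  h
}

#' Snapshot of all backbone parameters
#'
#' Used to assert that attention training leaves the backbone untouched.
#'
#' @param backbone A `conv_backbone`.
#' @return Named list of numeric arrays (a deep copy).
#' @export
backbone_params <- function(backbone) backbone$params

#' Train the fixture backbone
#'
#' Ordinary N-way training of all backbone parameters (unweighted mean
#' cross-entropy, Adam), used once to produce the frozen classifier that
#' attention training then modulates.
#'
#' @param backbone A `conv_backbone`.
#' @param train An `image_set` of training images.
#' @param validation An `image_set` used to report accuracy.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param seed Seed controlling shuffling.
#' @param verbose Print per-epoch validation accuracy.
#' @return The trained `conv_backbone`, with a `history` tibble attached
#'   (`epoch`, `train_loss`, `val_accuracy`).
#' @export
train_backbone <- function(backbone, train, validation,
                           epochs = 30L, lr = 1e-3, batch_size = 32L,
                           seed = 1L, verbose = FALSE) {
  n <- length(train)
  labels <- train$info$class
  params <- backbone$params
  st <- .adam_init(params)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- .with_seed(.epoch_seed(seed, ep), sample.int(n))
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      sel <- ord[start:min(start + batch_size - 1L, n)]
      bb <- backbone; bb$params <- params
      fw <- .net_forward(bb, train$images[, , , sel, drop = FALSE], keep = TRUE)
      B <- length(sel)
      y <- matrix(0, backbone$n_classes, B)
      y[cbind(labels[sel], seq_len(B))] <- 1
      p_true <- fw$probs[cbind(labels[sel], seq_len(B))]
      ep_loss <- ep_loss + sum(-log(pmax(p_true, 1e-12)))
      dlogits <- (fw$probs - y) / B
      grads <- .net_backward(bb, fw$cache, dlogits, wrt = "backbone")
      upd <- .adam_step(params, grads, st, lr)
      params <- upd$params
      st <- upd$state
    }
    bb <- backbone; bb$params <- params
    acc <- mean(apply(predict(bb, validation), 1L, which.max) ==
                  validation$info$class)
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / n,
                                 val_accuracy = acc)
    if (verbose) {
      message(sprintf("epoch %d: train loss %.4f, val acc %.3f",
                      ep, ep_loss / n, acc))
    }
  }
  backbone$params <- params
  backbone$trained <- TRUE
  backbone$history <- dplyr::bind_rows(hist)
  backbone
}
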