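# Internal numerical kernels for the miniature convolutional networks.
#
# Layout conventions (column-major R arrays):
#   image / activation batch: (height, width, channels, batch)
#   conv kernels:             (k, k, in_channels, out_channels)
#   class probabilities:      (n_classes, batch) matrix
#
# Convolutions are stride-1, zero-padded "same"; pooling is 2x2 max, stride 2.
# All forward/backward passes are plain vectorised R: the networks used here
# are small enough that BLAS-backed matrix products dominate the cost.

# Unfold a batch into convolution patches. Rows are (h, w, b) with h fastest,
# so the rows of the result are contiguous per image; columns are (di, dj, c)
# with di fastest, matching matrix(W, k*k*C, F) for kernels W of dim (k,k,C,F).
.im2col <- function(x, k) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; B <- d[4L]
  pad <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2L * pad, W + 2L * pad, C, B))
  xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  out <- matrix(0, H * W * B, k * k * C)
  q <- 0L
  for (cc in seq_len(C)) {
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        q <- q + 1L
        out[, q] <- xp[di:(di + H - 1L), dj:(dj + W - 1L), cc, ]
      }
    }
  }
  out
}

# Forward convolution; returns the output activations plus the patch matrix
# (reused by the backward pass).
.conv_fwd <- function(x, W, b) {
  d <- dim(x)
  H <- d[1L]; Wd <- d[2L]; B <- d[4L]
  Fo <- dim(W)[4L]
  cols <- .im2col(x, dim(W)[1L])
  y <- cols %*% matrix(W, ncol = Fo)
  y <- y + matrix(b, nrow(y), Fo, byrow = TRUE)
  list(y = aperm(array(y, c(H, Wd, B, Fo)), c(1L, 2L, 4L, 3L)), cols = cols)
}

# Gradients of a conv layer. `dy` has the layer's output shape (H, W, F, B).
.conv_bwd <- function(cols, W, dy, need_dx = TRUE) {
  k <- dim(W)[1L]; C <- dim(W)[3L]; Fo <- dim(W)[4L]
  d <- dim(dy)
  H <- d[1L]; Wd <- d[2L]; B <- d[4L]
  dym <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), H * Wd * B, Fo)
  out <- list(
    dW = array(crossprod(cols, dym), dim(W)),
    db = colSums(dym)
  )
  if (need_dx) {
    # gradient w.r.t. the input of a same-padded correlation is a same-padded
    # correlation of dy with the spatially flipped, channel-transposed kernels
    Wf <- aperm(W[k:1, k:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
    dxm <- .im2col(dy, k) %*% matrix(Wf, ncol = C)
    out$dx <- aperm(array(dxm, c(H, Wd, B, C)), c(1L, 2L, 4L, 3L))
  }
  out
}

# 2x2 max pooling with first-wins tie-breaking (deterministic backward).
# Argmax masks are only materialised when a backward pass will need them.
.pool_fwd <- function(x, masks = TRUE) {
  d <- dim(x)
  i1 <- seq(1L, d[1L], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2L], 2L); j2 <- j1 + 1L
  p11 <- x[i1, j1, , , drop = FALSE]
  p21 <- x[i2, j1, , , drop = FALSE]
  p12 <- x[i1, j2, , , drop = FALSE]
  p22 <- x[i2, j2, , , drop = FALSE]
  y <- pmax(p11, p21, p12, p22)
  if (!masks) return(list(y = y, in_dim = d))
  m11 <- p11 == y
  m21 <- (p21 == y) & !m11
  m12 <- (p12 == y) & !m11 & !m21
  m22 <- !m11 & !m21 & !m12
  list(y = y, masks = list(m11, m21, m12, m22), in_dim = d)
}

.pool_bwd <- function(cache, dy) {
  d <- cache$in_dim
  i1 <- seq(1L, d[1L], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2L], 2L); j2 <- j1 + 1L
  dx <- array(0, d)
  dx[i1, j1, , ] <- dy * cache$masks[[1L]]
  dx[i2, j1, , ] <- dy * cache$masks[[2L]]
  dx[i1, j2, , ] <- dy * cache$masks[[3L]]
  dx[i2, j2, , ] <- dy * cache$masks[[4L]]
  dx
}

.relu <- function(x) pmax(x, 0)

# Column-wise softmax of a logits matrix (n_classes x batch).
.softmax <- function(z) {
  z <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# Adam over a flat named list of numeric arrays.
.adam_init <- function(params) {
  zeros_like <- function(p) { p[] <- 0; p }
  list(
    m = lapply(params, zeros_like),
    v = lapply(params, zeros_like),
    t = 0L
  )
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-epoch RNG stream: resampling changes every epoch yet the
# whole run is reproducible from one seed. Kept inside 32-bit integer range.
.epoch_seed <- function(seed, epoch) {
  as.integer((as.numeric(seed) * 2654435.0 + 7919.0 * epoch) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
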