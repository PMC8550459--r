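#' Specification of the synthetic image world
#'
#' Describes a deterministic, parametric K-class image-classification task
#' that stands in for a large photographic dataset at desk scale. Each class
#' is a family of coloured, oriented textures with soft blobs: the class
#' determines a base hue, a grating orientation and frequency, and a blob
#' count, while each image jitters those parameters and adds pixel noise.
#' Colour and texture are carried by separable convolutional channels, which
#' is precisely the structure a filter-wise attention mechanism can exploit.
#'
#' `similarity` interpolates every class's generative parameters toward the
#' grand mean: at 0 the classes are maximally separated, at 1 all classes
#' share identical parameters and only noise distinguishes images, driving
#' any classifier toward chance.
#'
#' @param n_classes Number of classes K.
#' @param images_per_class Images generated per class.
#' @param image_size Side length in pixels (square images, 3 channels).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param similarity Overlap of class parameter ranges, in `[0, 1]`.
#' @param seed Integer seed; the dataset is a pure function of the spec.
#' @return An object of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(n_classes = 4, images_per_class = 6)
#' ds <- generate_dataset(spec)
#' dim(ds$images)
#' @export
synthetic_spec <- function(n_classes = 10L, images_per_class = 60L,
                           image_size = 32L, noise_sd = 0.05,
                           similarity = 0.45, seed = 42L) {
  if (n_classes < 1L) stop("`n_classes` must be a positive integer.")
  if (images_per_class < 1L) stop("`images_per_class` must be positive.")
  if (image_size < 8L || image_size %% 4L != 0L) {
    stop("`image_size` must be a multiple of 4 and at least 8.")
  }
  if (similarity < 0 || similarity > 1) stop("`similarity` must be in [0, 1].")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative.")
  structure(
    list(
      n_classes = as.integer(n_classes),
      images_per_class = as.integer(images_per_class),
      image_size = as.integer(image_size),
      channels = 3L,
      noise_sd = noise_sd,
      similarity = similarity,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# Vectorised numeric HSV -> RGB (h, s, v in [0, 1]); returns an n x 3 matrix.
.hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# Per-class generative parameter distributions. `similarity` contracts the
# class centres toward the grand mean and simultaneously widens the per-image
# jitter around each centre, so class parameter ranges overlap increasingly:
# at 0 classes are well separated, at 1 every class draws from the same
# distribution and only noise distinguishes images. The overlap is what gives
# the task an irreducible (Bayes) error, mirroring a classifier that is
# converged yet imperfect.
.class_params <- function(spec) {
  K <- spec$n_classes
  s <- spec$similarity
  k <- seq_len(K)
  contract <- function(x) (1 - s) * x + s * mean(x)
  hue_c <- contract((k - 0.5) / K)
  theta_c <- contract(pi * (k - 1) / K)
  freq_c <- contract(3 + ((k - 1) %% 4))
  blobs <- round(contract(1 + ((k - 1) %% 3)))
  jit_scale <- 0.05 + 0.75 * s
  list(
    hue = hue_c, theta = theta_c, freq = freq_c, blobs = blobs,
    hue_jit = jit_scale / K,
    theta_jit = jit_scale * pi / K,
    freq_jit = jit_scale
  )
}

# One image: bright blobs in the class hue at random positions, over a dim
# grayscale grating at the class orientation/frequency. Class identity lives
# in localised structure (coloured blobs, oriented texture), so averaging two
# images — the blended-stimulus construction — leaves both classes' features
# visible at half contrast instead of destroying them, as with photographs.
.render_image <- function(size, pars, k, noise_sd) {
  hue <- pars$hue[k] + stats::runif(1, -pars$hue_jit, pars$hue_jit)
  theta <- pars$theta[k] + stats::runif(1, -pars$theta_jit, pars$theta_jit)
  freq <- pars$freq[k] + stats::runif(1, -pars$freq_jit, pars$freq_jit)
  u <- matrix(seq(0, 1, length.out = size), size, size)
  v <- t(u)
  phase <- stats::runif(1, 0, 2 * pi)
  grating <- 0.5 + 0.5 * sin(2 * pi * freq * (u * cos(theta) + v * sin(theta)) + phase)
  base <- 0.15 + 0.25 * grating
  blob <- matrix(0, size, size)
  for (i in seq_len(max(1L, pars$blobs[k]))) {
    cx <- stats::runif(1, 0.2, 0.8)
    cy <- stats::runif(1, 0.2, 0.8)
    sd <- stats::runif(1, 0.09, 0.16)
    blob <- pmax(blob, exp(-((u - cx)^2 + (v - cy)^2) / (2 * sd^2)))
  }
  col <- .hsv_to_rgb(rep(hue %% 1, size * size),
                     0.85 + stats::runif(1, -0.05, 0.05), 0.95)
  img <- array(0, c(size, size, 3L))
  for (ch in 1:3) {
    img[, , ch] <- base * (1 - blob) + blob * array(col[, ch], c(size, size))
  }
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate the synthetic labelled image set
#'
#' Renders `n_classes * images_per_class` images deterministically from the
#' spec's seed. Pixels are floats in `[0, 1]`.
#'
#' @param spec A [synthetic_spec()].
#' @return An `image_set`: a list with `images`, an array of dimension
#'   `(size, size, 3, n)`, and `info`, a tibble with columns `id`, `class`
#'   (integer in `1..K`) and `class_name`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_classes < 1L) stop("degenerate spec: no classes")
  pars <- .class_params(spec)
  n <- spec$n_classes * spec$images_per_class
  images <- array(0, c(spec$image_size, spec$image_size, 3L, n))
  id <- character(n)
  cls <- integer(n)
  .with_seed(spec$seed, {
    idx <- 0L
    for (k in seq_len(spec$n_classes)) {
      for (i in seq_len(spec$images_per_class)) {
        idx <- idx + 1L
        images[, , , idx] <- .render_image(spec$image_size, pars, k,
                                           spec$noise_sd)
        id[idx] <- sprintf("c%02d_i%03d", k, i)
        cls[idx] <- k
      }
    }
  })
  new_image_set(
    images,
    tibble::tibble(id = id, class = cls,
                   class_name = sprintf("class%02d", cls))
  )
}

#' @rdname generate_dataset
#' @param images Array `(H, W, C, n)` of pixels in `[0, 1]`.
#' @param info Tibble with one row per image (`id`, `class`, `class_name`).
#' @export
new_image_set <- function(images, info) {
  stopifnot(length(dim(images)) == 4L, nrow(info) == dim(images)[4L])
  structure(list(images = images, info = info), class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_set> %d images, %dx%dx%d, %d classes\n",
              d[4L], d[1L], d[2L], d[3L],
              length(unique(x$info$class))))
  invisible(x)
}

#' @export
length.image_set <- function(x) dim(x$images)[4L]

# Subset an image_set by image index.
.img_subset <- function(set, idx) {
  new_image_set(set$images[, , , idx, drop = FALSE], set$info[idx, ])
}

#' A single labelled image
#'
#' Light container for one image with its class label and stable id.
#'
#' @param pixels Array `(H, W, C)` of values in `[0, 1]`.
#' @param label Integer class id.
#' @param id Stable string identity.
#' @export
labeled_image <- function(pixels, label, id = "img") {
  stopifnot(length(dim(pixels)) == 3L)
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 1)) {
    stop("pixels must be finite and in [0, 1]")
  }
  structure(list(pixels = pixels, label = as.integer(label), id = id),
            class = "labeled_image")
}
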