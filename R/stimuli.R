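#' Alpha-blend two labelled images
#'
#' Pixelwise mix of two images from different classes: each component's pixel
#' values are scaled (by `mix` and `1 - mix`, 50/50 by default) and summed,
#' in floating point, clipped to `[0, 1]`. The result carries both
#' ground-truth labels.
#'
#' @param image_a,image_b [labeled_image()] objects with identical spatial
#'   dimensions and distinct labels.
#' @param mix Weight of `image_a` in the blend.
#' @return A `blended_image`: list with `pixels`, `label_a`, `label_b`,
#'   `source_ids`.
#' @export
blend <- function(image_a, image_b, mix = 0.5) {
  stopifnot(inherits(image_a, "labeled_image"),
            inherits(image_b, "labeled_image"))
  if (!identical(dim(image_a$pixels), dim(image_b$pixels))) {
    stop(sprintf("image dimensions differ: (%s) vs (%s)",
                 paste(dim(image_a$pixels), collapse = "x"),
                 paste(dim(image_b$pixels), collapse = "x")))
  }
  if (image_a$label == image_b$label) {
    stop("blended images must combine two distinct classes")
  }
  if (mix < 0 || mix > 1) stop("`mix` must be in [0, 1]")
  px <- pmin(pmax(mix * image_a$pixels + (1 - mix) * image_b$pixels, 0), 1)
  structure(
    list(pixels = px, label_a = image_a$label, label_b = image_b$label,
         source_ids = c(image_a$id, image_b$id)),
    class = "blended_image"
  )
}

#' Assemble a balanced standard test set
#'
#' All test images of the target class(es) plus an equal-count random sample
#' of non-target test images, drawn uniformly across all non-target images
#' without replacement. The balance (equal target-present and target-absent
#' trial counts) is what licenses the signal-detection analysis.
#'
#' @param split A [split_dataset()] with a non-empty test split.
#' @param target Integer set of target class ids.
#' @param seed Integer seed; the same seed reproduces the same selection.
#' @return An `image_set` containing the balanced test set.
#' @export
assemble_standard_testset <- function(split, target, seed = 1L) {
  info <- split$test$info
  if (nrow(info) == 0L) stop("the test split is empty")
  idx_t <- which(info$class %in% target)
  idx_n <- which(!(info$class %in% target))
  if (length(idx_t) == 0L) stop("no target-class test images")
  if (length(idx_n) < length(idx_t)) {
    stop(sprintf("not enough non-target test images (%d) to balance %d target images",
                 length(idx_n), length(idx_t)))
  }
  take_n <- .with_seed(seed, idx_n[sample.int(length(idx_n), length(idx_t))])
  .img_subset(split$test, sort(c(idx_t, take_n)))
}

#' Assemble a balanced blended test set
#'
#' Builds `n_per_side` target-present blends (one component drawn from the
#' target class's test images, the other from a uniformly chosen different
#' class) and `n_per_side` target-absent blends (components from two distinct
#' non-target classes), all 50/50 mixes. Target components are used at most
#' once each.
#'
#' @param split A [split_dataset()] with a non-empty test split.
#' @param target Integer set of target class ids.
#' @param n_per_side Number of blends on each side of the balance.
#' @param seed Integer seed.
#' @return A `blended_set`: list with `images`, an array `(H, W, C, 2 *
#'   n_per_side)`, and `info`, a tibble with `label_a`, `label_b`, `id_a`,
#'   `id_b`, `target_present`.
#' @export
assemble_blended_testset <- function(split, target, n_per_side = 10L,
                                     seed = 1L) {
  info <- split$test$info
  if (nrow(info) == 0L) stop("the test split is empty")
  classes <- sort(unique(info$class))
  nontarget_classes <- setdiff(classes, target)
  idx_t <- which(info$class %in% target)
  if (length(idx_t) < n_per_side) {
    stop(sprintf("need %d target test images for %d target-present blends, have %d",
                 n_per_side, n_per_side, length(idx_t)))
  }
  if (length(nontarget_classes) < 2L) {
    stop("need at least two non-target classes to form target-absent blends")
  }
  imgs <- split$test$images
  d <- dim(imgs)
  out <- array(0, c(d[1:3], 2L * n_per_side))
  rows <- vector("list", 2L * n_per_side)
  .with_seed(seed, {
    comp_t <- idx_t[sample.int(length(idx_t), n_per_side)]
    for (i in seq_len(n_per_side)) {
      a <- comp_t[i]
      other_class <- sample(setdiff(classes, info$class[a]), 1L)
      b <- sample(which(info$class == other_class), 1L)
      bl <- blend(
        labeled_image(imgs[, , , a], info$class[a], info$id[a]),
        labeled_image(imgs[, , , b], info$class[b], info$id[b])
      )
      out[, , , i] <- bl$pixels
      rows[[i]] <- tibble::tibble(
        label_a = bl$label_a, label_b = bl$label_b,
        id_a = bl$source_ids[1L], id_b = bl$source_ids[2L],
        target_present = TRUE
      )
    }
    for (i in seq_len(n_per_side)) {
      cls <- sample(nontarget_classes, 2L)
      a <- sample(which(info$class == cls[1L]), 1L)
      b <- sample(which(info$class == cls[2L]), 1L)
      bl <- blend(
        labeled_image(imgs[, , , a], info$class[a], info$id[a]),
        labeled_image(imgs[, , , b], info$class[b], info$id[b])
      )
      out[, , , n_per_side + i] <- bl$pixels
      rows[[n_per_side + i]] <- tibble::tibble(
        label_a = bl$label_a, label_b = bl$label_b,
        id_a = bl$source_ids[1L], id_b = bl$source_ids[2L],
        target_present = FALSE
      )
    }
  })
  structure(list(images = out, info = dplyr::bind_rows(rows)),
            class = "blended_set")
}

#' @export
print.blended_set <- function(x, ...) {
  cat(sprintf("<blended_set> %d blends (%d target-present)\n",
              nrow(x$info), sum(x$info$target_present)))
  invisible(x)
}

#' Load a class-labelled image directory as a challenge set
#'
#' Reads a directory laid out as `class_name/*.png` (or `.jpg`/`.jpeg`),
#' mapping directory names to class ids through `class_map`. Pixels are
#' scaled to `[0, 1]`; grayscale images are replicated to 3 channels and
#' alpha channels dropped. Unmapped class directories and unreadable files
#' are skipped with a warning. Intended for user-supplied challenge sets
#' (e.g. a natural adversarial collection) evaluated with the same balanced
#' scoring as the standard test sets.
#'
#' @param directory Path to the image root.
#' @param class_map Named integer vector mapping directory name to class id.
#' @param size Optional target side length; images are resampled to
#'   `size x size` by nearest-neighbour indexing when given.
#' @return An `image_set`.
#' @export
load_challenge_set <- function(directory, class_map, size = NULL) {
  if (!dir.exists(directory)) stop("directory does not exist: ", directory)
  class_dirs <- list.dirs(directory, recursive = FALSE)
  if (length(class_dirs) == 0L) stop("empty directory: ", directory)
  pix <- list(); ids <- character(0); cls <- integer(0)
  for (cd in class_dirs) {
    nm <- basename(cd)
    if (!nm %in% names(class_map)) {
      warning("skipping unmapped class directory: ", nm)
      next
    }
    files <- list.files(cd, full.names = TRUE)
    for (f in files) {
      ext <- tolower(tools::file_ext(f))
      img <- switch(ext,
        png = tryCatch(png::readPNG(f), error = function(e) NULL),
        jpg = ,
        jpeg = tryCatch(jpeg::readJPEG(f), error = function(e) NULL),
        NULL
      )
      if (is.null(img)) {
        warning("skipping unreadable or non-image file: ", basename(f))
        next
      }
      if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
      if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
      if (!is.null(size)) {
        ri <- round(seq(1L, dim(img)[1L], length.out = size))
        ci <- round(seq(1L, dim(img)[2L], length.out = size))
        img <- img[ri, ci, , drop = FALSE]
      }
      pix[[length(pix) + 1L]] <- img
      ids <- c(ids, paste0(nm, "/", basename(f)))
      cls <- c(cls, as.integer(class_map[[nm]]))
    }
  }
  if (length(pix) == 0L) stop("no readable images found in ", directory)
  dims <- vapply(pix, function(p) dim(p)[1:2], integer(2))
  if (any(dims != dims[, 1L])) {
    stop("images have inconsistent dimensions; pass `size` to resample")
  }
  images <- array(0, c(dim(pix[[1L]]), length(pix)))
  for (i in seq_along(pix)) images[, , , i] <- pix[[i]]
  new_image_set(images, tibble::tibble(
    id = ids, class = cls,
    class_name = names(class_map)[match(cls, class_map)]
  ))
}
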