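#' Save and load attention weights as JSON
#'
#' The artifact records the weight vector together with the intensity, target
#' set and backbone identifier it was trained with.
#'
#' @param weights An [attention_weights()] object.
#' @param path Destination file.
#' @return `path`, invisibly (`write_attention_weights`); an
#'   [attention_weights()] object (`read_attention_weights`).
#' @export
write_attention_weights <- function(weights, path) {
  stopifnot(inherits(weights, "attention_weights"))
  jsonlite::write_json(
    list(values = weights$values, alpha = weights$alpha,
         target = weights$target, backbone_id = weights$backbone_id),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_attention_weights
#' @export
read_attention_weights <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  attention_weights(
    length(x$values), alpha = x$alpha %||% NA_real_,
    target = x$target %||% integer(),
    backbone_id = x$backbone_id %||% NA_character_,
    values = x$values
  )
}

#' Save and load a backbone checkpoint as JSON
#'
#' Plain-text checkpoint: every parameter array is stored flattened with its
#' dimensions, alongside a sidecar block recording the insertion-point name
#' and filter count.
#'
#' @param backbone A `conv_backbone`.
#' @param path Destination file.
#' @return `path`, invisibly (`write_backbone`); a `conv_backbone`
#'   (`read_backbone`).
#' @export
write_backbone <- function(backbone, path) {
  stopifnot(inherits(backbone, "conv_backbone"))
  params <- lapply(backbone$params, function(p) {
    list(dim = dim(p) %||% length(p), values = as.vector(p))
  })
  jsonlite::write_json(
    list(
      params = params,
      n_classes = backbone$n_classes,
      image_size = backbone$image_size,
      filters = backbone$filters,
      insertion = backbone$insertion,
      insertion_filters = insertion_filters(backbone),
      id = backbone$id,
      trained = backbone$trained
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_backbone
#' @export
read_backbone <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(x$params, function(p) {
    if (length(p$dim) > 1L) array(p$values, unlist(p$dim)) else p$values
  })
  structure(
    list(
      params = params,
      n_classes = as.integer(x$n_classes),
      image_size = as.integer(x$image_size),
      filters = as.integer(x$filters),
      insertion = x$insertion,
      id = x$id,
      trained = isTRUE(x$trained)
    ),
    class = "conv_backbone"
  )
}
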