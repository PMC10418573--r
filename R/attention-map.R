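#' Attention maps
#'
#' An `attention_map` is a dense nonnegative 2D scalar field over the pixels
#' of a stimulus image. The same container is used for gaze heat maps
#' (duration-weighted fixation density), classifier saliency maps
#' (occlusion-sensitivity importance), and difference maps (residual
#' attention after common-pattern subtraction). Values are stored as a
#' numeric matrix with rows = image rows (y, top to bottom) and
#' columns = image columns (x, left to right), origin at the top-left.
#'
#' @param values numeric matrix of attention values. Must be finite
#'   everywhere and nonnegative unless `kind = "difference"`.
#' @param kind one of `"gaze"`, `"saliency"`, `"difference"`.
#' @return an `attention_map` object (a classed numeric matrix).
#' @examples
#' m <- attention_map(matrix(runif(25), 5, 5))
#' map_kind(m)
#' @export
attention_map <- function(values, kind = c("gaze", "saliency", "difference")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) {
    stop("attention map values must be finite everywhere", call. = FALSE)
  }
  if (kind != "difference" && any(values < 0)) {
    stop("attention map of kind '", kind, "' must be nonnegative", call. = FALSE)
  }
  structure(values, kind = kind, class = c("attention_map", "matrix", "array"))
}

#' @rdname attention_map
#' @param x object to test or query.
#' @export
is_attention_map <- function(x) inherits(x, "attention_map")

#' @rdname attention_map
#' @export
map_kind <- function(x) {
  stopifnot(is_attention_map(x))
  attr(x, "kind")
}

# Re-wrap a plain matrix computed from a map, preserving/overriding kind.
as_map <- function(values, kind) {
  attention_map(unclass(values), kind = kind)
}

#' @export
print.attention_map <- function(x, ...) {
  cat(sprintf("<attention_map [%s]> %d x %d px, sum = %.4g, max = %.4g\n",
              map_kind(x), nrow(x), ncol(x), sum(x), max(x)))
  invisible(x)
}

# Dimension check used throughout; names the offending object when given.
check_same_dim <- function(a, b, what = "maps") {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b)) {
    stop(sprintf("dimension mismatch between %s: %dx%d vs %dx%d",
                 what, nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Locate the peak of an attention map
#'
#' Coordinates follow the raster convention used throughout the package:
#' 0-based, origin at the top-left, x = column, y = row.
#'
#' @param map an [attention_map()].
#' @return named numeric vector `c(x, y)` of the 0-based pixel coordinates of
#'   the maximum cell (ties broken by first occurrence in column-major order).
#' @export
map_argmax <- function(map) {
  stopifnot(is_attention_map(map))
  idx <- which.max(map)
  c(x = (idx - 1) %/% nrow(map), y = (idx - 1) %% nrow(map))
}
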