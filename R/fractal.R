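#' Box-counting fractal dimension of a binary raster
#'
#' Covers the pattern with square boxes on a dyadic ladder of sizes (2 px
#' up to a quarter of the bounding box) and fits the slope of
#' `log N(s) ~ log(1/s)` by ordinary least squares, `N(s)` being the
#' number of boxes containing at least one foreground pixel.  At least
#' five ladder points are required, i.e. the pattern must span at least
#' 128 px in one direction.
#'
#' @param x either a logical/0-1 matrix, or an n x 2 matrix of foreground
#'   pixel coordinates.
#' @return list-free numeric: the fitted dimension.
#' @examples
#' m <- matrix(FALSE, 300, 300); m[, 150] <- TRUE
#' fractalDimensionBoxcount(m)  # close to 1
#' @export
fractalDimensionBoxcount <- function(x) {
  if (is.matrix(x) && (is.logical(x) ||
      (is.numeric(x) && ncol(x) != 2L))) {
    coords <- which(x != 0, arr.ind = TRUE)
  } else {
    coords <- as.matrix(x)
  }
  if (!nrow(coords)) stop("empty pattern: nothing to cover")
  cx <- coords[, 1] - min(coords[, 1])
  cy <- coords[, 2] - min(coords[, 2])
  extent <- max(max(cx), max(cy)) + 1
  sizes <- 2^seq_len(30)
  sizes <- sizes[sizes <= extent / 4]
  if (length(sizes) < 5L)
    stop("pattern too small for a box-size ladder of >= 5 points ",
         "(needs an extent of at least 128 px)")
  counts <- vapply(sizes, function(s) {
    length(unique(cx %/% s + (cy %/% s) * 2^26))
  }, 0L)
  fit <- lm(log(counts) ~ log(1 / sizes))
  unname(coef(fit)[2])
}
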