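#' Intensity image
#'
#' Wraps a 2D grayscale slice as a matrix of finite intensities together with
#' its physical pixel size. Intensities are optionally min-max normalized to
#' \[0, 1\]; the persistence threshold selection assumes this normalization.
#'
#' @param values Numeric matrix (rows x cols) of finite intensities.
#' @param pixel_size Physical edge length of one pixel in micrometres.
#' @param normalize If `TRUE` (default), min-max normalize the values to
#'   \[0, 1\]. A constant image normalizes to all zeros. If `FALSE`, values
#'   must already lie in \[0, 1\].
#' @return An object of class `intensity_image` with fields `values`,
#'   `pixel_size`.
#' @export
intensity_image <- function(values, pixel_size = 0.16, normalize = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("image must be at least 2x2")
  if (!all(is.finite(values)))
    stop("image intensities must all be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a positive scalar")
  if (normalize) {
    rng <- range(values)
    values <- if (rng[2] > rng[1]) (values - rng[1]) / (rng[2] - rng[1])
              else array(0, dim(values))
  } else if (min(values) < 0 || max(values) > 1) {
    stop("intensities must lie in [0, 1] when normalize = FALSE")
  }
  structure(list(values = values, pixel_size = pixel_size),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d, pixel size %g um, range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              min(x$values), max(x$values)))
  invisible(x)
}

as_intensity_image <- function(x, pixel_size = 0.16, normalize = TRUE) {
  if (inherits(x, "intensity_image")) x
  else intensity_image(x, pixel_size = pixel_size, normalize = normalize)
}
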