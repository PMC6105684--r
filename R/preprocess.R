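# Intensity pre-processing: grey conversion and within-mask z-normalisation.
#
# Normalising each fin to zero mean / unit standard deviation over the fin
# pixels is the mechanism by which the pipeline absorbs camera exposure and
# global illumination differences: any positive affine change of the raw
# intensities (gain/offset) yields the identical normalised fin.

#' Convert an image to grey-scale
#'
#' Uses the ITU-R BT.601 luminance weights (0.299, 0.587, 0.114). A
#' single-channel input passes through unchanged.
#'
#' @param pixels A numeric matrix (grey) or an `nr x nc x 3` array (RGB).
#' @return A numeric matrix of luminance values in the input's units.
#' @export
to_grey <- function(pixels) {
  if (is.matrix(pixels)) return(pixels)
  if (is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L) {
    return(0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3])
  }
  stop("`pixels` must have 1 or 3 channels")
}

#' Normalise fin-pixel intensities to zero mean and unit variance
#'
#' Subtracts the mean and divides by the standard deviation of all pixels
#' inside the fin mask. The standard deviation uses the population
#' convention (divide by n). Background pixels carry no value (NA), so no
#' downstream statistic can mix background into a patch.
#'
#' @param pixels Numeric grey matrix.
#' @param mask Logical matrix of the same shape, `TRUE` = fin.
#' @return A `normalised_fin`: list with `values` (matrix, NA off-fin),
#'   `mask`, `source_mean`, `source_sd`.
#' @export
normalise_fin <- function(pixels, mask) {
  pixels <- to_grey(pixels)
  stopifnot(is.matrix(pixels), is.logical(mask))
  if (!identical(dim(pixels), dim(mask)))
    stop("pixels and mask dimensions differ")
  v <- pixels[mask]
  if (length(v) < 2L) stop("mask has fewer than 2 fin pixels")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s <= 0) stop("degenerate intensity: constant fin")
  values <- matrix(NA_real_, nrow(pixels), ncol(pixels))
  values[mask] <- (v - m) / s
  structure(
    list(values = values, mask = mask, source_mean = m, source_sd = s),
    class = "normalised_fin"
  )
}

#' @export
print.normalised_fin <- function(x, ...) {
  cat(sprintf(
    "<normalised_fin> %d x %d raster, %d fin pixels, source mean %.2f sd %.2f\n",
    nrow(x$values), ncol(x$values), sum(x$mask), x$source_mean, x$source_sd
  ))
  invisible(x)
}
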