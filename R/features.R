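# The 142-dimensional pigmentation feature vector:
#   42 patches (33 grid + 9 contour) x {mean, median, IQR}  = 126
#   16 inter-patch summaries of those statistics             = 16
# Quantiles use linear interpolation between order statistics at rank
# (n - 1) * p (R's default type 7), pinned so that independent oracles
# agree bit-for-bit. Standard deviations in the inter-patch block use the
# population convention (divide by n).

PATCH_STAT_NAMES <- c("mean", "median", "iqr")

INTERPATCH_NAMES <- c(
  "std_gridMeans", "std_gridMedians", "std_gridIQRs",
  "iqr_gridMeans", "iqr_gridMedians", "iqr_gridIQRs",
  "mean_gridIQRs", "median_gridIQRs",
  "std_contMeans", "std_contMedians", "std_contIQRs",
  "iqr_contMeans", "iqr_contMedians", "iqr_contIQRs",
  "mean_contIQRs", "median_contIQRs"
)

#' Names of the 142 pigmentation features, in their frozen order
#'
#' Grid patches 1-33 x (mean, median, iqr), contour patches 1-9 x
#' (mean, median, iqr), then the 16 inter-patch features.
#' @return Character vector of length 142.
#' @export
feature_names <- function() {
  g <- as.vector(t(outer(sprintf("grid%02d", 1:33), PATCH_STAT_NAMES,
                         paste, sep = "_")))
  ct <- as.vector(t(outer(sprintf("cont%d", 1:9), PATCH_STAT_NAMES,
                          paste, sep = "_")))
  c(g, ct, INTERPATCH_NAMES)
}

N_FEATURES <- 142L

iqr7 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Summary statistics of one patch
#'
#' @param values Numeric vector of normalised intensities (may be empty).
#' @return Named numeric `c(mean, median, iqr)`; all NA for an empty patch.
#' @export
patch_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    return(c(mean = NA_real_, median = NA_real_, iqr = NA_real_))
  c(mean = mean(values), median = stats::median(values), iqr = iqr7(values))
}

#' The 16 inter-patch features
#'
#' Spread and location summaries of the per-patch statistics: population
#' standard deviation and IQR of the grid/contour patch means, medians and
#' IQRs, plus the mean and median of the patch IQRs. Missing patch entries
#' are excluded; a spread over fewer than 2 available entries is missing.
#'
#' @param grid_stats 33 x 3 matrix (columns mean, median, iqr).
#' @param cont_stats 9 x 3 matrix.
#' @return Named numeric vector of length 16 in the frozen order.
#' @export
interpatch_features <- function(grid_stats, cont_stats) {
  stopifnot(nrow(grid_stats) == 33L, nrow(cont_stats) == 9L)
  spread_iqr <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else iqr7(x)
  }
  loc <- function(x, f) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_real_ else f(x)
  }
  block <- function(m) {
    c(sd_pop(m[, 1]), sd_pop(m[, 2]), sd_pop(m[, 3]),
      spread_iqr(m[, 1]), spread_iqr(m[, 2]), spread_iqr(m[, 3]),
      loc(m[, 3], mean), loc(m[, 3], stats::median))
  }
  stats::setNames(c(block(grid_stats), block(cont_stats)), INTERPATCH_NAMES)
}

#' Extract the full 142-dimensional feature vector of one fin
#'
#' @param fin A `normalised_fin`.
#' @param grid A `grid_partition` computed on the same mask.
#' @param cont A `contour_partition` computed on the same mask.
#' @param max_missing Error when more than this fraction of features is
#'   missing (default 0.25).
#' @return A `feature_vector`: list with `values` (named numeric, length
#'   142, NA = missing) and `missing_mask` (logical, length 142).
#' @export
extract_feature_vector <- function(fin, grid, cont, max_missing = 0.25) {
  gs <- t(vapply(seq_len(33L), function(p) patch_stats(patch_values(fin, grid, p)),
                 numeric(3)))
  cs <- t(vapply(seq_len(9L), function(p) patch_stats(patch_values(fin, cont, p)),
                 numeric(3)))
  values <- stats::setNames(
    c(as.vector(t(gs)), as.vector(t(cs)), interpatch_features(gs, cs)),
    feature_names()
  )
  missing <- is.na(values)
  if (mean(missing) > max_missing)
    stop(sprintf("unusable image: %.0f%% of features missing", 100 * mean(missing)))
  structure(list(values = values, missing_mask = missing),
            class = "feature_vector")
}

#' Full per-photo feature pipeline
#'
#' Normalises the photo, extracts its contour, estimates the base line,
#' computes both subdivisions and returns the feature vector. Set
#' `transform` to warp the normalised fin into a reference frame first
#' (pose-registered features).
#'
#' @param photo A `fin_photo` (or any list with `pixels` and `mask`).
#' @param transform Optional `projective_transform` into a reference frame.
#' @param out_dim Reference-frame dimensions when `transform` is given.
#' @param contour_points Contour resampling density.
#' @param leading Leading-edge side (see [estimate_base()]).
#' @param ... Passed to [extract_feature_vector()].
#' @return A `feature_vector`.
#' @export
photo_features <- function(photo, transform = NULL, out_dim = NULL,
                           contour_points = 400L, leading = "left", ...) {
  fin <- normalise_fin(photo$pixels, photo$mask)
  if (!is.null(transform))
    fin <- warp_fin(fin, transform, out_dim %||% dim(fin$values))
  contour <- extract_contour(fin$mask, contour_points)
  base <- estimate_base(contour, leading = leading)
  grid <- grid_subdivide(fin$mask, base)
  cont <- contour_subdivide(fin$mask, contour, base, leading = leading)
  extract_feature_vector(fin, grid, cont, ...)
}
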