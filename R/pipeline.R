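# Catalogue-level feature extraction, with optional pose registration of
# every fin into a reference frame before features are computed.

#' Extract the feature matrix of a catalogue
#'
#' Runs the per-photo pipeline (normalise, contour, base, subdivisions,
#' 142 features) over every photo. With `register = TRUE` each fin is
#' first registered to a reference fin by ICP under a projective
#' transform and warped into the reference frame; the reference is either
#' each individual's highest-PQ photo (`"individual"`) or the single
#' highest-PQ photo of the whole catalogue (`"global"`).
#'
#' @param catalogue A `fin_catalogue`.
#' @param register Register fins before feature extraction?
#' @param reference `"individual"` (default) or `"global"`.
#' @param contour_points Contour resampling density.
#' @param leading Leading-edge side (see [estimate_base()]).
#' @param strict Abort on a failing photo instead of skipping it.
#' @param verbose Log per-stage counts.
#' @return Data frame: `image_id`, `individual_id`, `date`, then the 142
#'   feature columns (NA = missing feature).
#' @export
catalogue_features <- function(catalogue, register = FALSE,
                               reference = c("individual", "global"),
                               contour_points = 400L, leading = "left",
                               strict = FALSE, verbose = FALSE) {
  reference <- match.arg(reference)
  photos <- catalogue$photos
  stopifnot(length(photos) > 0L)
  ref_of <- if (register) pick_references(photos, reference) else NULL
  ref_cache <- list()
  rows <- vector("list", length(photos))
  n_fail <- 0L
  for (k in seq_along(photos)) {
    p <- photos[[k]]
    fv <- tryCatch({
      tr <- NULL; od <- NULL
      if (register) {
        ref_id <- ref_of[[p$individual_id %||% "global"]] %||% ref_of[["global"]]
        if (!identical(ref_id, p$image_id)) {
          ref <- ref_contour(photos[[ref_id]], contour_points, ref_cache)
          ref_cache <- ref$cache
          mov <- extract_contour(p$mask, contour_points)
          tr <- icp_register(mov, ref$contour)
          od <- dim(photos[[ref_id]]$mask)
        }
      }
      suppressWarnings(photo_features(p, transform = tr, out_dim = od,
                                      contour_points = contour_points,
                                      leading = leading))
    }, error = function(e) e)
    if (inherits(fv, "error")) {
      if (strict) stop("photo ", p$image_id, " failed: ", conditionMessage(fv))
      message("skipping ", p$image_id, ": ", conditionMessage(fv))
      n_fail <- n_fail + 1L
      next
    }
    rows[[k]] <- c(list(image_id = p$image_id,
                        individual_id = p$individual_id %||% NA_character_,
                        date = format(p$date, "%Y-%m-%d")),
                   as.list(fv$values))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no photo yielded features")
  if (verbose)
    message(length(photos), " photos in, ", length(rows),
            " feature rows out (", n_fail, " skipped)")
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  rownames(out) <- NULL
  out
}

# Reference photo per individual (or one global): the highest PQ total,
# ties to the first photo in catalogue order.
pick_references <- function(photos, reference) {
  totals <- vapply(photos, function(p)
    photo_grade_total(p) %||% NA_integer_, numeric(1))
  totals[is.na(totals)] <- 0
  ids <- vapply(photos, function(p) p$individual_id %||% NA_character_,
                character(1))
  out <- list(global = names(photos)[which.max(totals)])
  if (reference == "individual") {
    for (id in unique(ids[!is.na(ids)])) {
      sel <- which(ids == id)
      out[[id]] <- names(photos)[sel[which.max(totals[sel])]]
    }
  }
  out
}

ref_contour <- function(photo, contour_points, cache) {
  key <- photo$image_id
  if (is.null(cache[[key]]))
    cache[[key]] <- extract_contour(photo$mask, contour_points)
  list(contour = cache[[key]], cache = cache)
}

#' Write a feature matrix to CSV
#'
#' First columns `image_id`, `individual_id`, `date`, then the 142 named
#' feature columns; missing features as empty cells.
#' @param features Output of [catalogue_features()].
#' @param path Output CSV path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a feature matrix CSV
#' @param path CSV written by [write_features()].
#' @return Data frame with parsed feature columns.
#' @export
read_features <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(image_id = "character",
                                        individual_id = "character",
                                        date = "character"))
  fc <- setdiff(names(out), c("image_id", "individual_id", "date"))
  out[fc] <- lapply(out[fc], as.numeric)
  out
}
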