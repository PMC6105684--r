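# Catalogue input/output and photographic-quality (PQ) grading.
#
# A catalogue pairs per-photo rasters (8-bit grey or RGB image + binary
# mask, PNG) with metadata (individual ID, encounter date, session, PQ
# category labels) in a UTF-8 CSV. Only photos graded good or excellent
# are analysed; the PQ category scores are weighted so that inadequate
# quality in any single category alone forces a poor rating.

PQ_SCORES <- list(
  clarity = c(poor = 1, reasonable = 4, excellent = 9),
  contrast = c(poor = 1, reasonable = 3, excellent = 9),
  angle = c(poor = 1, reasonable = 2, excellent = 9),
  edge = c(poor_reasonable = 1, excellent = 8)
)

PQ_GRADE_LEVELS <- c("poor", "good", "excellent")

#' Default grade thresholds
#'
#' The grade is `poor` whenever any category sits at its minimum score
#' (the weighting intent of the grading protocol); otherwise the summed
#' score is thresholded: `good` at >= `good`, `excellent` at >=
#' `excellent`.
#' @param good,excellent Total-score thresholds.
#' @return List of thresholds.
#' @export
pq_thresholds <- function(good = 20, excellent = 30) {
  list(good = good, excellent = excellent)
}

#' Photographic-quality grade of one image
#'
#' Category labels are mapped to their scores (clarity/focus 1/4/9,
#' contrast 1/3/9, orientation angle 1/2/9, edge visibility 1/8), summed
#' to a total in `[4, 35]`, and thresholded into poor/good/excellent.
#'
#' @param clarity,contrast,angle One of `"poor"`, `"reasonable"`,
#'   `"excellent"`.
#' @param edge `"poor_reasonable"` or `"excellent"`.
#' @param thresholds See [pq_thresholds()].
#' @return A `pq_grade`: list with per-category scores, `total`,
#'   `grade_label`.
#' @export
pq_score <- function(clarity, contrast, angle, edge,
                     thresholds = pq_thresholds()) {
  lab <- list(clarity = clarity, contrast = contrast, angle = angle,
              edge = edge)
  sc <- numeric(4); names(sc) <- names(PQ_SCORES)
  for (cat in names(PQ_SCORES)) {
    if (!lab[[cat]] %in% names(PQ_SCORES[[cat]]))
      stop("unknown ", cat, " label: '", lab[[cat]], "'")
    sc[cat] <- PQ_SCORES[[cat]][[lab[[cat]]]]
  }
  total <- sum(sc)
  any_min <- any(vapply(names(PQ_SCORES),
                        function(cat) sc[cat] == min(PQ_SCORES[[cat]]),
                        logical(1)))
  grade <- if (any_min) "poor"
           else if (total >= thresholds$excellent) "excellent"
           else if (total >= thresholds$good) "good"
           else "poor"
  structure(list(clarity_focus = sc[["clarity"]], contrast = sc[["contrast"]],
                 orientation_angle = sc[["angle"]],
                 edge_visibility = sc[["edge"]], total = total,
                 grade_label = grade),
            class = "pq_grade")
}

#' @export
print.pq_grade <- function(x, ...) {
  cat(sprintf("<pq_grade> total %d -> %s\n", x$total, x$grade_label))
  invisible(x)
}

photo_grade_label <- function(photo, thresholds = pq_thresholds()) {
  g <- photo$grade
  if (is.null(g)) return(NA_character_)
  if (inherits(g, "pq_grade")) return(g$grade_label)
  pq_score(g$clarity, g$contrast, g$angle, g$edge, thresholds)$grade_label
}

photo_grade_total <- function(photo, thresholds = pq_thresholds()) {
  g <- photo$grade
  if (is.null(g)) return(NA_integer_)
  if (inherits(g, "pq_grade")) return(g$total)
  pq_score(g$clarity, g$contrast, g$angle, g$edge, thresholds)$total
}

#' Keep only photos with the given grade labels
#'
#' @param catalogue A `fin_catalogue`.
#' @param grades Labels to keep (default good + excellent).
#' @param thresholds See [pq_thresholds()].
#' @return A `fin_catalogue` subset, order preserved, `individuals`
#'   recomputed. Warns when nothing survives.
#' @export
filter_by_grade <- function(catalogue, grades = c("good", "excellent"),
                            thresholds = pq_thresholds()) {
  labs <- vapply(catalogue$photos, photo_grade_label, character(1),
                 thresholds = thresholds)
  if (anyNA(labs)) stop("every photo needs a PQ grade before filtering")
  keep <- labs %in% grades
  if (!any(keep)) warning("no photos retained by grade filter")
  out <- catalogue
  out$photos <- catalogue$photos[keep]
  out$individuals <- sort(unique(vapply(out$photos, `[[`, "", "individual_id")))
  if (!is.null(out$ground_truth))
    out$ground_truth <-
      out$ground_truth[out$ground_truth$image_id %in% names(out$photos), ,
                       drop = FALSE]
  out
}

#' @export
print.fin_catalogue <- function(x, ...) {
  cat(sprintf("<fin_catalogue> %d photos of %d individuals\n",
              length(x$photos), length(x$individuals)))
  invisible(x)
}

#' @export
length.fin_catalogue <- function(x) length(x$photos)

CATALOGUE_COLUMNS <- c("image_id", "individual_id", "date", "session_id",
                       "image_file", "mask_file")

#' Write a catalogue to disk
#'
#' Layout: `metadata.csv` plus `images/` and `masks/` with 8-bit PNGs
#' (masks single-channel, 0 = background, 255 = fin). Ground truth, when
#' present, goes to `ground_truth.csv`.
#'
#' @param catalogue A `fin_catalogue`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_catalogue <- function(catalogue, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(catalogue$photos, function(p) {
    img_rel <- file.path("images", paste0(p$image_id, ".png"))
    msk_rel <- file.path("masks", paste0(p$image_id, "_mask.png"))
    png::writePNG(p$pixels / 255, file.path(dir, img_rel))
    png::writePNG(p$mask * 1.0, file.path(dir, msk_rel))
    g <- p$grade
    data.frame(image_id = p$image_id,
               individual_id = p$individual_id %||% "",
               date = format(p$date, "%Y-%m-%d"),
               session_id = p$session_id %||% "",
               image_file = img_rel, mask_file = msk_rel,
               clarity = g$clarity %||% "", contrast = g$contrast %||% "",
               angle = g$angle %||% "", edge = g$edge %||% "")
  })
  utils::write.csv(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  if (!is.null(catalogue$ground_truth))
    utils::write.csv(catalogue$ground_truth,
                     file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a catalogue from disk
#'
#' @param metadata_path Path to the metadata CSV (columns `image_id,
#'   individual_id, date, session_id, image_file, mask_file` and optional
#'   PQ columns `clarity, contrast, angle, edge`).
#' @param image_root Directory that the image/mask paths are relative to
#'   (default: the CSV's directory).
#' @param keep_largest_component Accept multi-component masks by keeping
#'   the largest 4-connected component instead of failing.
#' @return A `fin_catalogue`.
#' @export
read_catalogue <- function(metadata_path,
                           image_root = dirname(metadata_path),
                           keep_largest_component = FALSE) {
  meta <- utils::read.csv(metadata_path, colClasses = "character")
  missing_cols <- setdiff(CATALOGUE_COLUMNS, names(meta))
  if (length(missing_cols))
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$image_id))
    stop("duplicate image_id: ",
         paste(unique(meta$image_id[duplicated(meta$image_id)]), collapse = ", "))
  has_pq <- all(c("clarity", "contrast", "angle", "edge") %in% names(meta))
  photos <- vector("list", nrow(meta))
  for (r in seq_len(nrow(meta))) {
    img_path <- file.path(image_root, meta$image_file[r])
    msk_path <- file.path(image_root, meta$mask_file[r])
    for (pth in c(img_path, msk_path)) {
      if (!file.exists(pth))
        stop("row ", r, " (", meta$image_id[r], "): missing file ", pth)
    }
    pix <- png::readPNG(img_path) * 255
    if (length(dim(pix)) == 3L && dim(pix)[3] == 2L) pix <- pix[, , 1]  # GA
    if (length(dim(pix)) == 3L && dim(pix)[3] == 4L) pix <- pix[, , 1:3] # RGBA
    msk_raw <- png::readPNG(msk_path)
    if (length(dim(msk_raw)) == 3L) msk_raw <- msk_raw[, , 1]
    mask <- msk_raw > 0
    dims <- if (is.matrix(pix)) dim(pix) else dim(pix)[1:2]
    if (!identical(dims, dim(mask)))
      stop("row ", r, " (", meta$image_id[r], "): image/mask shape mismatch")
    if (!any(mask))
      stop("row ", r, " (", meta$image_id[r], "): empty mask")
    if (n_components(mask) > 1L) {
      if (keep_largest_component) mask <- largest_component(mask)
      else stop("row ", r, " (", meta$image_id[r],
                "): mask has multiple components",
                " (use keep_largest_component = TRUE to override)")
    }
    if (is.matrix(pix)) pix <- round(pix)
    grade <- if (has_pq && nzchar(meta$clarity[r]))
      list(clarity = meta$clarity[r], contrast = meta$contrast[r],
           angle = meta$angle[r], edge = meta$edge[r])
    photos[[r]] <- structure(
      list(image_id = meta$image_id[r],
           individual_id = if (nzchar(meta$individual_id[r]))
             meta$individual_id[r] else NA_character_,
           date = as.Date(meta$date[r]),
           session_id = meta$session_id[r],
           pixels = pix, mask = mask, grade = grade),
      class = "fin_photo")
  }
  names(photos) <- meta$image_id
  ids <- vapply(photos, `[[`, "", "individual_id")
  structure(
    list(photos = photos, individuals = sort(unique(ids[!is.na(ids)])),
         ground_truth = {
           gt_path <- file.path(dirname(metadata_path), "ground_truth.csv")
           if (file.exists(gt_path)) utils::read.csv(gt_path) else NULL
         }),
    class = "fin_catalogue"
  )
}

#' @export
print.fin_photo <- function(x, ...) {
  cat(sprintf("<fin_photo> %s (%s, %s): %d x %d, %d fin pixels\n",
              x$image_id, x$individual_id %||% "?", format(x$date),
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}
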