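# Subdivision of the fin interior into the two patch systems used for
# feature extraction:
#   * a grid of 33 patches anchored to the fin base (10 bands perpendicular
#     to the base, split 4/4/4/4/4/3/3/3/2/2 from the base up, with the
#     top-most half-band ignored because it often contains specular
#     highlights), and
#   * 9 contour patches from iso-level bands of the Euclidean distance
#     transform, the outer four bands split into leading/trailing halves at
#     the medial axis.

GRID_SPLITS <- c(4L, 4L, 4L, 4L, 4L, 3L, 3L, 3L, 2L, 2L)
N_GRID_PATCHES <- 33L
N_CONTOUR_PATCHES <- 9L

#' Estimate the fin base line
#'
#' The base is the line through the point where the leading edge of the fin
#' flows into the body (an inflection/corner in the outline), running
#' parallel to the body axis. The direction is the caller's hint if given,
#' otherwise the principal axis of the lowest 20% of contour points; the
#' anchor is the sharpest turn of the outline in the lower leading region,
#' falling back to the chord between the two lowermost extremes.
#'
#' @param contour A `fin_contour`.
#' @param body_direction_hint Optional unit 2-vector; returned unchanged as
#'   the base direction when supplied.
#' @param leading Which image side is the animal's front: `"left"`
#'   (default; the study photographed left-side fins) or `"right"`.
#' @return A `base_line`: list with `point`, `direction`, `normal` (unit
#'   vectors; `normal` points from the base toward the fin tip).
#' @export
estimate_base <- function(contour, body_direction_hint = NULL,
                          leading = c("left", "right")) {
  leading <- match.arg(leading)
  P <- contour$points
  ys <- P[, 2]
  lower <- P[ys >= stats::quantile(ys, 0.8), , drop = FALSE]  # y grows down
  if (!is.null(body_direction_hint)) {
    direction <- body_direction_hint
  } else {
    e <- eigen(stats::cov(lower), symmetric = TRUE)
    direction <- e$vectors[, 1]
  }
  direction <- direction / sqrt(sum(direction^2))
  if (direction[1] < 0) direction <- -direction  # point toward image-right
  normal <- c(direction[2], -direction[1])
  ctr <- colMeans(P)
  anchor <- find_base_anchor(P, leading)
  if (sum((ctr - anchor$point) * normal) < 0) normal <- -normal
  structure(
    list(point = anchor$point, direction = direction, normal = normal),
    class = "base_line"
  )
}

# Sharpest outline turn in the lower leading quarter; fallback to the more
# leading of the two lowermost points.
find_base_anchor <- function(P, leading) {
  n <- nrow(P)
  sm <- function(v) {
    # circular moving average, window 5
    vv <- c(v[(n - 1):n], v, v[1:2])
    stats::filter(vv, rep(1 / 5, 5))[3:(n + 2)]
  }
  xs <- sm(P[, 1]); ys <- sm(P[, 2])
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  v1x <- xs - xs[prv]; v1y <- ys - ys[prv]
  v2x <- xs[nxt] - xs; v2y <- ys[nxt] - ys
  turn <- abs(atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y))
  in_lower <- P[, 2] >= stats::quantile(P[, 2], 0.75)
  in_lead <- if (leading == "left") P[, 1] <= stats::median(P[, 1])
             else P[, 1] >= stats::median(P[, 1])
  cand <- which(in_lower & in_lead)
  if (length(cand) == 0L) {
    warning("no leading-edge inflection found; using lowermost extreme")
    low <- which(P[, 2] >= max(P[, 2]) - 1)
    pick <- if (leading == "left") low[which.min(P[low, 1])]
            else low[which.max(P[low, 1])]
    return(list(point = P[pick, ]))
  }
  i0 <- cand[which.max(turn[cand])]
  list(point = refine_corner(P, i0))
}

# Contour smoothing rounds the base corner; recover the un-rounded apex as
# the intersection of lines fitted to the flanking contour segments.
refine_corner <- function(P, i0, skip = 3L, span = 12L) {
  n <- nrow(P)
  wrap <- function(i) ((i - 1L) %% n) + 1L
  fit_line <- function(idx) {
    q <- P[wrap(idx), , drop = FALSE]
    ctr <- colMeans(q)
    d <- svd(sweep(q, 2, ctr))$v[, 1]
    list(p = ctr, d = d)
  }
  a <- fit_line(i0 + skip:(skip + span))
  b <- fit_line(i0 - skip:(skip + span))
  M <- cbind(a$d, -b$d)
  if (abs(det(M)) < 1e-6) return(P[i0, ])
  t_ab <- solve(M, b$p - a$p)
  apex <- a$p + t_ab[1] * a$d
  if (sqrt(sum((apex - P[i0, ])^2)) > 5) P[i0, ] else apex
}

# Base-parallel (s) and base-normal (t) coordinates of points, as offsets
# from the base anchor. Kept as explicit elementwise arithmetic so a
# per-pixel oracle reproduces the values bit-for-bit (BLAS dot products may
# round differently at bin boundaries).
base_coords <- function(pts, base) {
  dx <- pts[, 1] - base$point[1]
  dy <- pts[, 2] - base$point[2]
  cbind(s = dx * base$direction[1] + dy * base$direction[2],
        t = dx * base$normal[1] + dy * base$normal[2])
}

#' Grid subdivision of the fin into 33 patches
#'
#' The fin is divided into 10 equal-height bands along the base-normal
#' axis, plus an ignored half-band at the tip, so the band height is
#' `h = H / 10.5` where `H` is the fin's base-normal extent (pixel units,
#' extent = max - min + 1). From the base upward the bands are split into
#' 4, 4, 4, 4, 4, 3, 3, 3, 2, 2 equal-width patches along the base-parallel
#' axis, between each band's own extreme fin pixels. Patch indices run from
#' the base band upward, leading-to-trailing within a band.
#'
#' @param mask Logical fin mask.
#' @param base A `base_line`.
#' @param tip_half_band Keep the tip half-band ignored (default TRUE).
#' @return A `grid_partition`: list with `labels` (integer matrix; 1..33,
#'   0 = ignored tip, NA = background), `band_height`, `per_band_splits`,
#'   `n_patches`, `empty_patches`.
#' @export
grid_subdivide <- function(mask, base, tip_half_band = TRUE) {
  stopifnot(is.logical(mask), any(mask))
  co <- mask_coords(mask)
  st <- base_coords(co, base)
  t0 <- st[, 2] - min(st[, 2]) + 0.5
  H <- max(st[, 2]) - min(st[, 2]) + 1
  if (H <= 1) stop("fin has zero extent along the base normal")
  h <- if (tip_half_band) H / 10.5 else H / 10
  band <- pmin(floor(t0 / h) + 1L, if (tip_half_band) 11L else 10L)
  labels <- matrix(NA_integer_, nrow(mask), ncol(mask))
  offs <- c(0L, cumsum(GRID_SPLITS))
  lab <- integer(nrow(co))
  for (k in 1:10) {
    in_k <- band == k
    if (!any(in_k)) next
    s <- st[in_k, 1]
    s0 <- s - min(s) + 0.5
    W <- max(s) - min(s) + 1
    nk <- GRID_SPLITS[k]
    j <- pmin(floor(s0 / (W / nk)) + 1L, nk)
    lab[in_k] <- as.integer(offs[k] + j)
  }
  lab[band > 10L] <- 0L  # ignored tip half-band
  labels[cbind(co[, 2], co[, 1])] <- lab
  empty <- setdiff(seq_len(N_GRID_PATCHES), unique(lab))
  if (length(empty)) warning("empty grid patches: ", paste(empty, collapse = ", "))
  structure(
    list(labels = labels, band_height = h, per_band_splits = GRID_SPLITS,
         n_patches = N_GRID_PATCHES, empty_patches = empty),
    class = "grid_partition"
  )
}

#' Exact Euclidean distance transform of a fin mask
#'
#' Each fin pixel gets the Euclidean distance to the nearest outline pixel,
#' where the outline is the set of boundary pixels of the mask (fin pixels
#' with a 4-neighbour off the fin); boundary pixels therefore have distance
#' zero. Computed exactly by nearest-neighbour search against the boundary
#' set.
#'
#' @param mask Logical fin mask.
#' @return Numeric matrix of distances (NA off-fin).
#' @export
distance_transform <- function(mask) {
  stopifnot(is.logical(mask), any(mask))
  b <- mask_boundary(mask)
  bco <- mask_coords(b)
  fco <- mask_coords(mask)
  d <- FNN::get.knnx(bco, fco, k = 1)$nn.dist[, 1]
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  out[cbind(fco[, 2], fco[, 1])] <- d
  out
}

#' Contour subdivision of the fin into 9 patches
#'
#' Iso-level bands of the Euclidean distance transform divide the fin into
#' five equal-width segments running along the outline; the outer four are
#' further split into leading and trailing halves at the medial axis (the
#' set of interior points equidistant from the leading and trailing
#' edges), giving 9 patches. Labels: band b in 1..4 (outermost first) has
#' leading half `2b - 1` and trailing half `2b`; the centre-most band is
#' label 9.
#'
#' @param mask Logical fin mask.
#' @param contour A `fin_contour` of the same mask.
#' @param base A `base_line`.
#' @param leading Which image side is the animal's front (see
#'   [estimate_base()]).
#' @return A `contour_partition`: list with `labels` (integer matrix, 1..9,
#'   NA off-fin), `band_width` (= D/5), `distance` (the transform),
#'   `medial_axis` (logical matrix), `edge_side` (integer matrix; 1 =
#'   leading, 2 = trailing, NA = centre band/off-fin).
#' @export
contour_subdivide <- function(mask, contour, base, leading = c("left", "right")) {
  leading <- match.arg(leading)
  dt <- distance_transform(mask)
  fco <- mask_coords(mask)
  idx <- cbind(fco[, 2], fco[, 1])
  d <- dt[idx]
  D <- max(d)
  if (D <= 0) stop("degenerate mask: all fin pixels are outline pixels")
  band <- as.integer(pmin(floor(d / (D / 5)) + 1L, 5L))
  arcs <- split_contour_arcs(contour, base, leading)
  side <- integer(nrow(fco))
  need <- band < 5L
  lead_d <- FNN::get.knnx(arcs$leading, fco, k = 1)$nn.dist[, 1]
  trail_d <- FNN::get.knnx(arcs$trailing, fco, k = 1)$nn.dist[, 1]
  side[need] <- ifelse(lead_d[need] <= trail_d[need], 1L, 2L)
  lab <- as.integer(ifelse(band == 5L, 9L, 2L * band - 2L + side))
  labels <- matrix(NA_integer_, nrow(mask), ncol(mask))
  labels[idx] <- lab
  med <- matrix(FALSE, nrow(mask), ncol(mask))
  med[idx] <- abs(lead_d - trail_d) <= 1
  edge_side <- matrix(NA_integer_, nrow(mask), ncol(mask))
  edge_side[idx][need] <- side[need]
  structure(
    list(labels = labels, band_width = D / 5, distance = dt,
         medial_axis = med, edge_side = edge_side,
         n_patches = N_CONTOUR_PATCHES),
    class = "contour_partition"
  )
}

# Split the closed contour at the fin tip (maximal base-normal coordinate)
# and the base region (minimal base-normal coordinates) into a leading arc
# and a trailing arc, identified by their mean base-parallel coordinate.
split_contour_arcs <- function(contour, base, leading = "left") {
  P <- contour$points
  st <- base_coords(P, base)
  n <- nrow(P)
  tip <- which.max(st[, 2])
  in_base <- st[, 2] <= min(st[, 2]) + 2
  if (all(in_base) || sum(!in_base) < 4L)
    stop("cannot split contour: no tip region distinct from the base")
  walk <- function(step) {
    out <- integer(0)
    i <- tip
    repeat {
      i <- ((i - 1 + step) %% n) + 1
      if (in_base[i] || i == tip) break
      out <- c(out, i)
    }
    out
  }
  a1 <- walk(1L); a2 <- walk(-1L)
  m1 <- mean(st[a1, 1]); m2 <- mean(st[a2, 1])
  # leading side = smaller base-parallel coordinate when leading is the
  # direction the base 'direction' vector starts from (image-left default)
  lead_first <- if (leading == "left") m1 < m2 else m1 > m2
  list(
    leading = P[if (lead_first) a1 else a2, , drop = FALSE],
    trailing = P[if (lead_first) a2 else a1, , drop = FALSE]
  )
}

#' Summarise a partition
#'
#' @param partition A `grid_partition` or `contour_partition`.
#' @return A data frame with one row per patch (including empty ones):
#'   patch index, pixel count, centroid x/y.
#' @export
partition_summary <- function(partition) {
  labels <- partition$labels
  k <- partition$n_patches
  out <- data.frame(patch = seq_len(k), n_pixels = 0L,
                    centroid_x = NA_real_, centroid_y = NA_real_)
  idx <- which(!is.na(labels) & labels > 0L, arr.ind = TRUE)
  lab <- labels[idx]
  for (p in seq_len(k)) {
    sel <- lab == p
    out$n_pixels[p] <- sum(sel)
    if (any(sel)) {
      out$centroid_x[p] <- mean(idx[sel, 2])
      out$centroid_y[p] <- mean(idx[sel, 1])
    }
  }
  out
}

#' Pixels of one patch of a partition
#' @noRd
patch_values <- function(fin, partition, patch) {
  fin$values[!is.na(partition$labels) & partition$labels == patch]
}
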