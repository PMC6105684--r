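# Ground-truthed synthetic fin-photo catalogues.
#
# What the generator emulates: each individual carries a stable,
# identity-specific pigmentation pattern (a small number of light/dark
# Gaussian blobs plus a dorsal-ventral gradient) painted on a fin-shaped
# silhouette; each photograph adds nuisance -- projective pose jitter,
# illumination gain/offset, pixel noise, occasional specular highlights
# near the tip, and partial waterline occlusion of the fin base. Pigment
# lives in fin-anchored unit coordinates, so pose warps move the pigment
# with the fin, as in real photographs. Random streams are hierarchical
# (master seed -> identity seed -> photo seed) so adding photos never
# perturbs existing ones.

#' Default photo-level nuisance parameters
#'
#' @param homography_jitter Maximum projective tilt, degrees.
#' @param gain,offset Ranges (length 2) of the multiplicative and additive
#'   illumination change.
#' @param noise_sd Additive pixel noise sd, 8-bit intensity units.
#' @param highlight_prob,highlight_area_frac Probability and fin-area
#'   fraction of a specular highlight blob in the tip half.
#' @param occlusion_frac Fraction of fin rows occluded at the waterline.
#' @param drift_rate Per-encounter systematic pigment change (0 = stable).
#' @return A `photo_nuisance` list.
#' @export
photo_nuisance <- function(homography_jitter = 8, gain = c(0.7, 1.4),
                           offset = c(-20, 20), noise_sd = 4,
                           highlight_prob = 0.25, highlight_area_frac = 0.01,
                           occlusion_frac = 0.03, drift_rate = 0) {
  stopifnot(homography_jitter >= 0, noise_sd >= 0,
            highlight_prob >= 0, highlight_prob <= 1,
            highlight_area_frac >= 0, highlight_area_frac <= 1,
            occlusion_frac >= 0, occlusion_frac < 1, drift_rate >= 0)
  structure(list(homography_jitter = homography_jitter, gain = gain,
                 offset = offset, noise_sd = noise_sd,
                 highlight_prob = highlight_prob,
                 highlight_area_frac = highlight_area_frac,
                 occlusion_frac = occlusion_frac, drift_rate = drift_rate),
            class = "photo_nuisance")
}

#' Create a synthetic identity
#'
#' Draws fin-shape parameters (base width, height, rake, trailing-curve
#' depth) and an identity-fixed pigment field: `n_blobs` Gaussian blobs in
#' fin-anchored unit coordinates plus a dorsal-ventral gradient, scaled by
#' `distinctiveness` (0 = unpigmented animal).
#'
#' @param identity_id Identifier string.
#' @param seed Identity seed (field is deterministic given the seed).
#' @param distinctiveness Blob amplitude scale (default 1).
#' @param n_blobs Number of pigment blobs (default 6).
#' @return A `synthetic_identity`.
#' @export
synthetic_identity <- function(identity_id, seed, distinctiveness = 1,
                               n_blobs = 6L) {
  stopifnot(distinctiveness >= 0)
  with_seed(seed, {
    # Identity-to-identity shape spread is kept below the shape variation a
    # single fin shows under pose jitter: the species is poorly marked, so
    # the outline itself must carry ~no identity signal (an unpigmented
    # animal should be unidentifiable).
    shape <- list(
      base_width = stats::rnorm(1, 100, 3),
      height = stats::rnorm(1, 112, 4),
      rake = stats::rnorm(1, 34, 4),
      trail_depth = stats::runif(1, 11, 17)
    )
    blobs <- data.frame(
      u = stats::runif(n_blobs, 0.12, 0.88),
      v = stats::runif(n_blobs, 0.05, 0.75),
      scale = stats::runif(n_blobs, 0.09, 0.22),
      amp = sample(c(-1, 1), n_blobs, replace = TRUE) *
        stats::runif(n_blobs, 0.5, 1.5) * distinctiveness,
      drift_dir = sample(c(-1, 1), n_blobs, replace = TRUE)
    )
    grad <- stats::runif(1, 0.3, 0.8)
  })
  structure(list(identity_id = identity_id, seed = seed,
                 fin_shape_params = shape, blobs = blobs,
                 gradient = grad, distinctiveness = distinctiveness),
            class = "synthetic_identity")
}

# Closed fin outline polygon in the canonical frame (image coordinates,
# y down): base-front at (x0, y0), tip up-and-back by (rake, height),
# concave trailing edge returning to base-rear, straight base.
fin_outline <- function(shape, x0 = 22, y0 = 138) {
  h <- shape$height; rk <- shape$rake; w <- shape$base_width
  dpt <- shape$trail_depth
  tip <- c(x0 + rk, y0 - h)
  lead_ctrl <- cbind(
    x = x0 + rk * c(0, 0.18, 0.55, 1),
    y = y0 - h * c(0, 0.42, 0.78, 1)
  )
  xr <- x0 + w
  trail_ctrl <- cbind(
    x = c(tip[1], tip[1] + 0.22 * (xr - tip[1]) - 0.45 * dpt,
          tip[1] + 0.55 * (xr - tip[1]) - 0.35 * dpt, xr),
    y = c(tip[2], y0 - 0.62 * h, y0 - 0.28 * h, y0)
  )
  edge_pts <- function(ctrl, n = 80L) {
    tt <- seq(0, 1, length.out = nrow(ctrl))
    s <- seq(0, 1, length.out = n)
    cbind(stats::spline(tt, ctrl[, 1], xout = s)$y,
          stats::spline(tt, ctrl[, 2], xout = s)$y)
  }
  lead <- edge_pts(lead_ctrl)
  trail <- edge_pts(trail_ctrl)
  base_seg <- cbind(seq(xr, x0, length.out = 30L), rep(y0, 30L))
  poly <- rbind(lead, trail[-1, ], base_seg[-1, ])
  poly[-nrow(poly), , drop = FALSE]
}

# Vectorised even-odd point-in-polygon test.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Shift an identity's pigment field by systematic drift
#'
#' Blob amplitudes move linearly with the encounter index along each
#' blob's fixed drift direction; `drift_rate = 0` returns the field
#' unchanged.
#'
#' @param identity A `synthetic_identity`.
#' @param drift_rate Per-encounter magnitude (>= 0).
#' @param encounter_index 0-based encounter counter.
#' @return A `synthetic_identity` with shifted blob amplitudes.
#' @export
inject_drift <- function(identity, drift_rate, encounter_index) {
  stopifnot(drift_rate >= 0)
  if (drift_rate == 0 || encounter_index == 0) return(identity)
  identity$blobs$amp <- identity$blobs$amp +
    drift_rate * encounter_index * identity$blobs$drift_dir
  identity
}

# Pigment field value at fin-anchored unit coordinates (u along base,
# v base-to-tip), dimensionless around 0.
pigment_field <- function(identity, u, v) {
  f <- identity$gradient * (v - 0.5)
  b <- identity$blobs
  for (k in seq_len(nrow(b))) {
    f <- f + b$amp[k] *
      exp(-((u - b$u[k])^2 + (v - b$v[k])^2) / (2 * b$scale[k]^2))
  }
  f
}

# Random photo homography: rotation/scale/translation about the canvas
# centre plus projective tilt terms up to `jitter_deg`.
random_pose <- function(jitter_deg, canvas) {
  cx <- canvas[2] / 2; cy <- canvas[1] / 2
  th <- stats::runif(1, -jitter_deg, jitter_deg) * pi / 180
  sc <- exp(stats::runif(1, -0.06, 0.06) * jitter_deg / 8)
  tx <- stats::runif(1, -3, 3) * jitter_deg / 8
  ty <- stats::runif(1, -3, 3) * jitter_deg / 8
  tilt <- stats::runif(2, -1, 1) * tan(jitter_deg * pi / 180) / (2.2 * max(canvas))
  A <- sc * rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  Tc <- rbind(c(1, 0, -cx), c(0, 1, -cy), c(0, 0, 1))
  Tb <- rbind(c(1, 0, cx + tx), c(0, 1, cy + ty), c(0, 0, 1))
  P <- rbind(cbind(A, c(0, 0)), c(tilt[1], tilt[2], 1))
  H <- Tb %*% P %*% Tc
  H / H[3, 3]
}

#' Render one synthetic fin photo
#'
#' Evaluates the warped silhouette and pigment field analytically at every
#' canvas pixel (inverse mapping through the ground-truth homography, so
#' there is no resampling loss), then applies illumination gain/offset,
#' specular highlight, waterline occlusion, noise and 8-bit quantisation.
#'
#' @param identity A `synthetic_identity`.
#' @param nuisance A `photo_nuisance`.
#' @param photo_seed Seed for this photo's nuisance draws.
#' @param encounter_index 0-based encounter counter (drives drift).
#' @param canvas `c(nrow, ncol)` canvas size.
#' @param base_grey,contrast Scene base level and pigment contrast in 8-bit
#'   units. The scene is quantised to integers before the illumination
#'   gain/offset is applied (the camera's exposure acts on the scene), so
#'   integer gain/offset settings reproduce the scene exactly.
#' @return List: `pixels` (8-bit matrix), `mask` (logical), `truth` (list
#'   with the applied homography, gain, offset, encounter and drift state).
#' @export
render_photo <- function(identity, nuisance = photo_nuisance(),
                         photo_seed = 1L, encounter_index = 0L,
                         canvas = c(150L, 140L), base_grey = 128,
                         contrast = 42) {
  id_drift <- inject_drift(identity, nuisance$drift_rate, encounter_index)
  poly <- fin_outline(identity$fin_shape_params)
  sh <- identity$fin_shape_params
  x0 <- 22; y0 <- 138
  with_seed(photo_seed, {
    H <- random_pose(nuisance$homography_jitter, canvas)
    gain <- stats::runif(1, nuisance$gain[1], nuisance$gain[2])
    offset <- stats::runif(1, nuisance$offset[1], nuisance$offset[2])
    do_highlight <- stats::runif(1) < nuisance$highlight_prob
    hl_u <- stats::runif(1, 0.25, 0.75); hl_v <- stats::runif(1, 0.55, 0.9)
    noise <- matrix(stats::rnorm(canvas[1] * canvas[2], 0, nuisance$noise_sd),
                    canvas[1], canvas[2])
  })
  nr <- canvas[1]; nc <- canvas[2]
  gx <- rep(seq_len(nc), each = nr); gy <- rep(seq_len(nr), times = nc)
  src <- apply_homography(solve(H), cbind(gx, gy))
  inside <- point_in_polygon(src[, 1], src[, 2], poly)
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(gy[inside], gx[inside])] <- TRUE
  # waterline occlusion: drop the lowest fraction of fin rows
  if (nuisance$occlusion_frac > 0 && any(mask)) {
    rows <- which(rowSums(mask) > 0)
    cut <- floor(length(rows) * nuisance$occlusion_frac)
    if (cut > 0) mask[rows[(length(rows) - cut + 1):length(rows)], ] <- FALSE
  }
  mask <- largest_component(mask)
  u <- (src[inside, 1] - x0) / sh$base_width
  v <- (y0 - src[inside, 2]) / sh$height
  val <- base_grey + contrast * pigment_field(id_drift, u, v)
  img <- matrix(0, nr, nc)
  img[cbind(gy[inside], gx[inside])] <- val
  if (do_highlight && any(mask)) {
    r_hl <- sqrt(nuisance$highlight_area_frac * sum(mask) / pi)
    d2 <- (u - hl_u)^2 * sh$base_width^2 + (v - hl_v)^2 * sh$height^2
    hl <- inside
    hl[inside] <- d2 <= r_hl^2
    img[cbind(gy[hl], gx[hl])] <- 255
  }
  img <- gain * round(img) + offset + noise
  img[!mask] <- 0
  pixels <- matrix(pmin(255, pmax(0, round(img))), nr, nc)
  list(pixels = pixels, mask = mask,
       truth = list(homography = H, gain = gain, offset = offset,
                    encounter_index = encounter_index,
                    drift_rate = nuisance$drift_rate))
}

# Keep the largest 4-connected component (occlusion can split a mask).
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  comp <- mask_components(mask)
  tab <- tabulate(comp[mask])
  if (length(tab) > 1L) mask[] <- !is.na(comp) & comp == which.max(tab)
  mask
}

#' Generate a ground-truthed synthetic catalogue
#'
#' @param n_individuals Number of identities (>= 2).
#' @param photos_per_individual A count, a vector of counts, or the string
#'   `"study"` for a draw with mean 4.6 images per individual (2 + Poisson
#'   with mean 2.6), the shape of the study catalogue.
#' @param nuisance A `photo_nuisance`.
#' @param master_seed Master seed; identity and photo seeds are derived
#'   from it hierarchically.
#' @param date_span_years Span of encounter dates (default 10).
#' @param distinctiveness Identity blob amplitude scale (scalar or one per
#'   identity; 0 = unpigmented).
#' @param drift_rate Per-identity drift rates (scalar or vector),
#'   overriding `nuisance$drift_rate` per identity.
#' @param canvas Canvas size.
#' @return A `fin_catalogue`: list with `photos` (list of `fin_photo`),
#'   `individuals`, `ground_truth` (data frame with the applied
#'   homographies and drift states).
#' @export
generate_catalogue <- function(n_individuals, photos_per_individual = 5L,
                               nuisance = photo_nuisance(), master_seed = 1L,
                               date_span_years = 10, distinctiveness = 1,
                               drift_rate = NULL, canvas = c(150L, 140L)) {
  if (n_individuals < 2L) stop("need at least 2 individuals")
  counts <- if (identical(photos_per_individual, "study")) {
    with_seed(derive_seed(master_seed, 0L),
              2L + stats::rpois(n_individuals, 2.6))
  } else if (length(photos_per_individual) == 1L) {
    rep(as.integer(photos_per_individual), n_individuals)
  } else {
    stopifnot(length(photos_per_individual) == n_individuals)
    as.integer(photos_per_individual)
  }
  if (any(counts < 1L)) stop("each individual needs >= 1 photo")
  dis <- rep_len(distinctiveness, n_individuals)
  drift <- rep_len(drift_rate %||% nuisance$drift_rate, n_individuals)
  t0 <- as.Date("2002-02-01")
  span_days <- round(date_span_years * 365.25)
  photos <- list()
  gt <- list()
  for (i in seq_len(n_individuals)) {
    id <- sprintf("ID%03d", i)
    ident <- synthetic_identity(id, seed = derive_seed(master_seed, i),
                                distinctiveness = dis[i])
    dates <- with_seed(derive_seed(master_seed, i, 0L),
                       t0 + sort(sample.int(span_days, counts[i])))
    nu_i <- nuisance
    nu_i$drift_rate <- drift[i]
    for (j in seq_len(counts[i])) {
      ph <- render_photo(ident, nu_i, photo_seed = derive_seed(master_seed, i, j),
                         encounter_index = j - 1L, canvas = canvas)
      image_id <- sprintf("%s_P%02d", id, j)
      photos[[image_id]] <- structure(
        list(image_id = image_id, individual_id = id, date = dates[j],
             session_id = format(dates[j], "S%Y%m%d"),
             pixels = ph$pixels, mask = ph$mask,
             grade = synth_grade(derive_seed(master_seed, i, j, 7L))),
        class = "fin_photo")
      Hm <- ph$truth$homography
      gt[[image_id]] <- data.frame(
        image_id = image_id, individual_id = id,
        encounter_index = j - 1L, drift_rate = drift[i],
        gain = ph$truth$gain, offset = ph$truth$offset,
        h11 = Hm[1, 1], h12 = Hm[1, 2], h13 = Hm[1, 3],
        h21 = Hm[2, 1], h22 = Hm[2, 2], h23 = Hm[2, 3],
        h31 = Hm[3, 1], h32 = Hm[3, 2])
    }
  }
  structure(
    list(photos = photos,
         individuals = sort(unique(vapply(photos, `[[`, "", "individual_id"))),
         ground_truth = do.call(rbind, c(gt, list(make.row.names = FALSE)))),
    class = "fin_catalogue"
  )
}

# Plausible photographic-quality categories for a synthetic photo: mostly
# good/excellent with an occasional poor category, mirroring a curated
# catalogue with some rejects.
synth_grade <- function(seed) {
  with_seed(seed, list(
    clarity = sample(c("poor", "reasonable", "excellent"), 1,
                     prob = c(0.1, 0.35, 0.55)),
    contrast = sample(c("poor", "reasonable", "excellent"), 1,
                      prob = c(0.1, 0.35, 0.55)),
    angle = sample(c("poor", "reasonable", "excellent"), 1,
                   prob = c(0.1, 0.35, 0.55)),
    edge = sample(c("poor_reasonable", "excellent"), 1, prob = c(0.15, 0.85))
  ))
}
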