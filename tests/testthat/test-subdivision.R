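# Fin base estimation, the 33-patch grid, the distance transform, and the
# 9-patch contour partition.

test_that("estimate_base passes a hint through and is horizontal on a box", {
  ct <- extract_contour(square_mask(60L))
  hint <- c(1, 0)
  b <- estimate_base(ct, body_direction_hint = hint)
  expect_identical(b$direction, hint)
  b2 <- estimate_base(ct)
  ang <- abs(atan2(b2$direction[2], b2$direction[1])) * 180 / pi
  expect_lt(min(ang, abs(180 - ang)), 1)
  expect_equal(sum(b2$direction * b2$normal), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(b2$normal^2)), 1, tolerance = 1e-12)
})

test_that("estimate_base recovers the generator's base line", {
  for (seed in 1:5) {
    ph <- cached_fin(seed)
    b <- estimate_base(extract_contour(ph$mask))
    ang <- abs(atan2(b$direction[2], b$direction[1])) * 180 / pi
    expect_lt(ang, 5)  # generator base is horizontal
    expect_lt(sqrt(sum((b$point - c(22, 138))^2)), 3)
  }
})

test_that("grid subdivision of a rectangle matches closed-form geometry", {
  # 120 wide x 105 tall, base = bottom edge: h = 10, bottom-band patches
  # 30 x 10 = 300 px, top 5 rows ignored
  mask <- matrix(FALSE, 115, 130)
  mask[6:110, 6:125] <- TRUE
  g <- grid_subdivide(mask, bottom_base(mask))
  expect_equal(g$band_height, 10)
  cnt <- table(g$labels[!is.na(g$labels) & g$labels > 0])
  for (p in 1:4) expect_equal(unname(cnt[as.character(p)]), 300L)
  expect_equal(sum(!is.na(g$labels) & g$labels == 0L), 5L * 120L)
  expect_equal(sum(cnt), 100L * 120L)
})

test_that("grid labels match an exhaustive per-pixel oracle", {
  ph <- cached_fin(6)
  ct <- extract_contour(ph$mask)
  b <- estimate_base(ct)
  g <- grid_subdivide(ph$mask, b)
  # independent per-pixel reassignment with plain loops
  splits <- c(4, 4, 4, 4, 4, 3, 3, 3, 2, 2)
  offs <- c(0, cumsum(splits))
  pix <- which(ph$mask, arr.ind = TRUE)
  s <- t <- numeric(nrow(pix))
  for (k in seq_len(nrow(pix))) {
    dx <- pix[k, 2] - b$point[1]; dy <- pix[k, 1] - b$point[2]
    s[k] <- dx * b$direction[1] + dy * b$direction[2]
    t[k] <- dx * b$normal[1] + dy * b$normal[2]
  }
  H <- max(t) - min(t) + 1
  h <- H / 10.5
  t0 <- t - min(t) + 0.5
  band <- pmin(floor(t0 / h) + 1, 11)
  want <- integer(nrow(pix))
  for (k in seq_len(nrow(pix))) {
    if (band[k] > 10) { want[k] <- 0L; next }
    in_band <- which(band == band[k])
    s0 <- s[k] - min(s[in_band]) + 0.5
    W <- max(s[in_band]) - min(s[in_band]) + 1
    nk <- splits[band[k]]
    want[k] <- offs[band[k]] + min(floor(s0 / (W / nk)) + 1, nk)
  }
  expect_identical(g$labels[pix], as.integer(want))
})

test_that("grid always yields 33 patches with the 4/4/4/4/4/3/3/3/2/2 splits", {
  splits <- c(4, 4, 4, 4, 4, 3, 3, 3, 2, 2)
  offs <- c(0, cumsum(splits))
  for (seed in 11:15) {
    ph <- test_fin_photo(seed, photo_nuisance(noise_sd = 0, highlight_prob = 0,
                                              occlusion_frac = 0))
    b <- estimate_base(extract_contour(ph$mask))
    g <- suppressWarnings(grid_subdivide(ph$mask, b))
    lab <- g$labels[!is.na(g$labels)]
    expect_setequal(setdiff(unique(lab), 0L), 1:33)
    # per-band patch counts
    for (k in 1:10)
      expect_equal(sum(unique(lab) > offs[k] & unique(lab) <= offs[k + 1]),
                   splits[k])
    # conservation: labelled + ignored = fin mask
    expect_equal(length(lab), sum(ph$mask))
  }
})

test_that("distance transform equals O(n^2) brute force on a 60x60 fin", {
  ph <- test_fin_photo(21, canvas = c(60L, 60L))
  expect_gt(sum(ph$mask), 100)
  dt <- distance_transform(ph$mask)
  bnd <- which(finpigment:::mask_boundary(ph$mask), arr.ind = TRUE)
  pix <- which(ph$mask, arr.ind = TRUE)
  for (k in seq_len(nrow(pix))) {
    want <- sqrt(min((pix[k, 1] - bnd[, 1])^2 + (pix[k, 2] - bnd[, 2])^2))
    expect_equal(dt[pix[k, , drop = FALSE]], want, tolerance = 1e-12)
  }
})

test_that("contour subdivision partitions the fin into 9 patches", {
  for (seed in c(7, 8)) {
    ph <- cached_fin(seed)
    ct <- extract_contour(ph$mask)
    b <- estimate_base(ct)
    cp <- contour_subdivide(ph$mask, ct, b)
    lab <- cp$labels[!is.na(cp$labels)]
    expect_setequal(unique(lab), 1:9)
    # exact partition: every fin pixel labelled once, background NA
    expect_equal(sum(!is.na(cp$labels)), sum(ph$mask))
    expect_true(all(!is.na(cp$labels[ph$mask])))
    # bands 1-4 have both halves nonempty
    for (bd in 1:4) {
      expect_gt(sum(lab == 2 * bd - 1), 0)
      expect_gt(sum(lab == 2 * bd), 0)
    }
    # band index consistent with distance value
    d <- cp$distance[ph$mask]
    D <- max(d)
    band_of <- pmin(floor(d / (D / 5)) + 1, 5)
    expect_true(all(lab[band_of == 5] == 9L))
    expect_true(all(ceiling(lab[band_of < 5] / 2) == band_of[band_of < 5]))
  }
})

test_that("contour bands are robust to a moderate projective warp", {
  ph <- cached_fin(9)
  ct <- extract_contour(ph$mask)
  b <- estimate_base(ct)
  cp <- contour_subdivide(ph$mask, ct, b)
  # ~10 degree tilt warp
  th <- 10 * pi / 180
  H <- rbind(c(cos(th), -sin(th), 10), c(sin(th), cos(th), 2),
             c(2.0e-4, -1.2e-4, 1))
  fin <- normalise_fin(ph$pixels, ph$mask)
  wf <- warp_fin(fin, H)
  wct <- extract_contour(wf$mask)
  wb <- estimate_base(wct)
  wcp <- contour_subdivide(wf$mask, wct, wb)
  pix <- which(ph$mask, arr.ind = TRUE)
  dst <- round(apply_homography(H, cbind(pix[, 2], pix[, 1])))
  ok <- dst[, 1] >= 1 & dst[, 1] <= ncol(wf$mask) &
    dst[, 2] >= 1 & dst[, 2] <= nrow(wf$mask)
  band_src <- ceiling(cp$labels[pix][ok] / 2); band_src[cp$labels[pix][ok] == 9] <- 5
  wl <- wcp$labels[cbind(dst[ok, 2], dst[ok, 1])]
  band_dst <- ceiling(wl / 2); band_dst[!is.na(wl) & wl == 9] <- 5
  agree <- mean(!is.na(band_dst) & band_dst == band_src)
  expect_gte(agree, 0.9)
})

test_that("partition_summary conserves pixel counts", {
  ph <- cached_fin(2)
  ct <- extract_contour(ph$mask)
  b <- estimate_base(ct)
  g <- grid_subdivide(ph$mask, b)
  cp <- contour_subdivide(ph$mask, ct, b)
  sg <- partition_summary(g)
  sc <- partition_summary(cp)
  expect_equal(nrow(sg), 33L)
  expect_equal(nrow(sc), 9L)
  expect_equal(sum(sg$n_pixels), sum(!is.na(g$labels) & g$labels > 0))
  expect_equal(sum(sc$n_pixels), sum(ph$mask))
})
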