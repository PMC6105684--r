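# Pose registration: fin contours, homography estimation, iterative closest
# point alignment, and image warping into a reference frame.
#
# Coordinate convention throughout: origin at the top-left, x to the right
# (matrix column), y down (matrix row), pixel centres at integer
# coordinates. Homographies are 3x3 matrices acting on homogeneous
# (x, y, 1) column vectors, normalised so the bottom-right entry is 1.

#' Apply a homography to a set of 2-D points
#'
#' @param H 3x3 homography matrix.
#' @param pts n x 2 matrix of (x, y) points.
#' @return n x 2 matrix of transformed points.
#' @export
apply_homography <- function(H, pts) {
  pts <- rbind(t(pts), 1)
  out <- H %*% pts
  cbind(out[1, ] / out[3, ], out[2, ] / out[3, ])
}

# Hartley-normalised direct linear transform: least-squares homography from
# point correspondences src -> dst. Errors out on (near-)collinear inputs.
fit_homography_dlt <- function(src, dst) {
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 4L)
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- sqrt(2) / max(mean(d), 1e-12)
    T <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
    list(T = T, p = apply_homography(T, p))
  }
  collinear <- function(p) {
    sv <- svd(sweep(p, 2, colMeans(p)))$d
    sv[2] < 1e-8 * max(sv[1], 1)
  }
  if (collinear(src) || collinear(dst))
    stop("degenerate point configuration: points are collinear")
  ns <- norm_pts(src); nd <- norm_pts(dst)
  x <- ns$p[, 1]; y <- ns$p[, 2]; u <- nd$p[, 1]; v <- nd$p[, 2]
  zero <- numeric(length(x)); one <- zero + 1
  A <- rbind(
    cbind(-x, -y, -one, zero, zero, zero, u * x, u * y, u),
    cbind(zero, zero, zero, -x, -y, -one, v * x, v * y, v)
  )
  h <- svd(A, nu = 0)$v[, 9]
  H <- solve(nd$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% ns$T
  H / H[3, 3]
}

#' Extract the sub-pixel outline of a fin mask
#'
#' Traces the 0.5 iso-level of the binary mask (marching-squares via
#' [grDevices::contourLines()]) and resamples it uniformly by arc length.
#' The winding is made consistent (positive shoelace area in the image
#' coordinate frame).
#'
#' @param mask Logical matrix, `TRUE` = fin; must be a single 4-connected
#'   component.
#' @param n_points Number of resampled contour points (default 400).
#' @return A `fin_contour`: list with `points` (n x 2 matrix of (x, y)).
#' @export
extract_contour <- function(mask, n_points = 400L) {
  stopifnot(is.logical(mask), any(mask))
  if (n_components(mask) != 1L)
    stop("mask has more than one connected component")
  nr <- nrow(mask); nc <- ncol(mask)
  z <- matrix(0, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- as.numeric(mask)
  # contourLines expects z[i, j] at x[i], y[j]; our matrix is [row=y, col=x]
  cl <- grDevices::contourLines(x = 0:(nr + 1L), y = 0:(nc + 1L),
                                z = z, levels = 0.5)
  if (length(cl) == 0L) stop("no contour found")
  if (length(cl) > 1L) {
    lens <- vapply(cl, function(l) length(l$x), numeric(1))
    warning("mask outline has ", length(cl), " loops; keeping the longest")
    cl <- cl[which.max(lens)]
  }
  pts <- cbind(x = cl[[1]]$y, y = cl[[1]]$x)  # swap back to (x=col, y=row)
  # drop duplicated closing point if present
  n <- nrow(pts)
  if (n > 1L && all(abs(pts[1, ] - pts[n, ]) < 1e-12)) pts <- pts[-n, , drop = FALSE]
  # consistent winding: positive shoelace area
  xs <- pts[, 1]; ys <- pts[, 2]
  a2 <- sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)
  if (a2 < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  # the 0.5 iso-level of a binary raster staircases along diagonal runs,
  # biasing curved perimeters upward by a few percent; Taubin lambda/mu
  # smoothing removes the staircase without shrinking the outline
  pts <- smooth_closed(pts)
  pts <- resample_closed(pts, n_points)
  structure(list(points = pts), class = "fin_contour")
}

# Taubin lambda/mu smoothing of a closed polyline: alternating positive and
# negative Laplacian steps low-pass the staircase while keeping the outline
# from shrinking (corners and overall scale survive).
smooth_closed <- function(pts, iters = 10L, lambda = 0.5, mu = -0.53) {
  n <- nrow(pts)
  if (n < 8L) return(pts)
  for (it in seq_len(iters)) {
    for (f in c(lambda, mu)) {
      nb <- (pts[c(2:n, 1L), , drop = FALSE] +
               pts[c(n, 1:(n - 1L)), , drop = FALSE]) / 2
      pts <- pts + f * (nb - pts)
    }
  }
  colnames(pts) <- c("x", "y")
  pts
}

# Uniform arc-length resampling of a closed polyline.
resample_closed <- function(pts, n_points) {
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  keep <- seg > 1e-12
  if (!all(keep)) {
    closed <- closed[c(keep, TRUE), , drop = FALSE]
    seg <- seg[keep]
  }
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n_points + 1L)[-(n_points + 1L)]
  xi <- stats::approx(s, closed[, 1], xout = target)$y
  yi <- stats::approx(s, closed[, 2], xout = target)$y
  cbind(x = xi, y = yi)
}

#' Contour perimeter
#' @param contour A `fin_contour`.
#' @return Perimeter length in pixels.
#' @export
contour_perimeter <- function(contour) {
  p <- contour$points
  sum(sqrt(rowSums((rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]) - p)^2)))
}

# Nearest point on a closed polyline for each query point: find the nearest
# vertex, then project onto its two incident segments. Projected (rather
# than vertex) targets let ICP slide tangentially out of the off-by-one
# local minima that pure point-to-point matching falls into.
closest_on_polyline <- function(poly, query) {
  n <- nrow(poly)
  i <- FNN::get.knnx(poly, query, k = 1)$nn.index[, 1]
  prv <- ((i - 2L) %% n) + 1L
  nxt <- (i %% n) + 1L
  proj_seg <- function(a, b) {
    ab <- b - a
    len2 <- pmax(rowSums(ab^2), 1e-12)
    t_ <- pmin(pmax(rowSums((query - a) * ab) / len2, 0), 1)
    q <- a + ab * t_
    list(q = q, d2 = rowSums((query - q)^2))
  }
  s1 <- proj_seg(poly[prv, , drop = FALSE], poly[i, , drop = FALSE])
  s2 <- proj_seg(poly[i, , drop = FALSE], poly[nxt, , drop = FALSE])
  use1 <- s1$d2 <= s2$d2
  q <- s2$q
  q[use1, ] <- s1$q[use1, ]
  list(target = q, dist = sqrt(pmin(s1$d2, s2$d2)))
}

# Closed-form similarity (rotation + isotropic scale + translation) used to
# initialise ICP: aligns centroids, RMS radii and principal axes. Both the
# principal-axis direction and its 180-degree flip are returned; the caller
# keeps whichever gives the lower residual.
similarity_inits <- function(moving, reference) {
  pa <- function(p) {
    e <- eigen(stats::cov(p), symmetric = TRUE)
    atan2(e$vectors[2, 1], e$vectors[1, 1])
  }
  cm <- colMeans(moving); cr <- colMeans(reference)
  sm <- sqrt(mean(rowSums(sweep(moving, 2, cm)^2)))
  sr <- sqrt(mean(rowSums(sweep(reference, 2, cr)^2)))
  s <- sr / max(sm, 1e-12)
  base_ang <- pa(reference) - pa(moving)
  lapply(c(base_ang, base_ang + pi), function(a) {
    R <- s * rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
    t <- cr - R %*% cm
    rbind(cbind(R, t), c(0, 0, 1))
  })
}

#' Register a moving fin contour to a reference contour with ICP
#'
#' Alternates closest-point correspondence (each moving point is matched to
#' its nearest point on the reference polyline, projecting onto segments so
#' the match can slide tangentially) with least-squares re-estimation of a
#' full projective transform (normalised DLT) until the
#' relative residual change falls below `tol` or `max_iter` is reached.
#' Initialised by a similarity alignment of centroids, scale and principal
#' axes. A trimmed variant (discarding the worst `trim` fraction of
#' correspondences) is on by default to tolerate segmentation errors from
#' specular highlights or water obstruction. Iterations that would increase
#' the residual are rejected, so the reported residual history is
#' non-increasing.
#'
#' @param moving,reference `fin_contour` objects.
#' @param tol Relative residual-change convergence threshold.
#' @param max_iter Maximum ICP iterations.
#' @param trim Fraction of worst correspondences discarded each iteration.
#' @return A `projective_transform`: list with `matrix` (3x3, `[3,3] == 1`),
#'   `residual` (mean closest-point distance, px), `iterations`,
#'   `converged`, `residual_history`.
#' @export
icp_register <- function(moving, reference, tol = 1e-4, max_iter = 100L,
                         trim = 0.1) {
  M <- moving$points; R <- reference$points
  near_line <- function(p) {
    sv <- svd(sweep(p, 2, colMeans(p)))$d
    sv[2] < 1e-8 * max(sv[1], 1)
  }
  if (near_line(M) || near_line(R))
    stop("degenerate point configuration: points are collinear")
  inits <- similarity_inits(M, R)
  res_of <- function(H) {
    P <- apply_homography(H, M)
    mean(closest_on_polyline(R, P)$dist)
  }
  H_cur <- inits[[which.min(vapply(inits, res_of, numeric(1)))]]
  res_cur <- res_of(H_cur)
  H_best <- H_cur; best_res <- res_cur
  history <- best_res  # best-so-far: non-increasing by construction
  converged <- FALSE
  iter <- 0L
  stall <- 0L
  n_keep <- max(4L, floor(nrow(M) * (1 - trim)))
  while (iter < max_iter) {
    iter <- iter + 1L
    P <- apply_homography(H_cur, M)
    nn <- closest_on_polyline(R, P)
    keep <- order(nn$dist)[seq_len(n_keep)]
    H_new <- tryCatch(
      fit_homography_dlt(M[keep, , drop = FALSE],
                         nn$target[keep, , drop = FALSE]),
      error = function(e) NULL
    )
    if (is.null(H_new)) break
    res_new <- res_of(H_new)
    change <- abs(res_cur - res_new) / max(res_cur, 1e-12)
    H_cur <- H_new; res_cur <- res_new
    if (res_new < best_res * (1 - tol)) stall <- 0L else stall <- stall + 1L
    if (res_new < best_res) {
      H_best <- H_new
      best_res <- res_new
    }
    history <- c(history, best_res)
    # converged when the step is tiny, the fit is far below any physical
    # sub-pixel meaning (5e-3 px), or the best residual has plateaued
    # (oscillating correspondences at the optimum)
    if (change < tol || best_res < 5e-3 || stall >= 5L) {
      converged <- TRUE
      break
    }
  }
  if (!converged && iter >= max_iter)
    warning("ICP did not converge in ", max_iter, " iterations")
  structure(
    list(matrix = H_best / H_best[3, 3], residual = best_res,
         iterations = iter, converged = converged,
         residual_history = history),
    class = "projective_transform"
  )
}

#' @export
print.projective_transform <- function(x, ...) {
  cat(sprintf("<projective_transform> residual %.4f px after %d iterations (%s)\n",
              x$residual, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Warp a normalised fin into a reference frame
#'
#' Resamples intensities by inverse mapping with mask-aware bilinear
#' interpolation (off-fin neighbours get zero weight); the mask is warped
#' with nearest-neighbour lookup and re-binarised. The warped fin is
#' re-normalised to zero mean / unit sd over the warped mask.
#'
#' @param fin A `normalised_fin`.
#' @param transform A `projective_transform` (or bare 3x3 matrix) mapping
#'   the fin's frame into the reference frame.
#' @param out_dim `c(nrow, ncol)` of the reference frame; defaults to the
#'   input dimensions.
#' @return A `normalised_fin` in the reference frame.
#' @export
warp_fin <- function(fin, transform, out_dim = dim(fin$values)) {
  H <- if (inherits(transform, "projective_transform")) transform$matrix else transform
  Hi <- solve(H)
  nr <- out_dim[1]; nc <- out_dim[2]
  g <- cbind(x = rep(seq_len(nc), each = nr), y = rep(seq_len(nr), times = nc))
  src <- apply_homography(Hi, g)
  sx <- src[, 1]; sy <- src[, 2]
  nr_in <- nrow(fin$values); nc_in <- ncol(fin$values)
  # nearest-neighbour mask warp
  rx <- round(sx); ry <- round(sy)
  in_b <- rx >= 1 & rx <= nc_in & ry >= 1 & ry <= nr_in
  wmask_v <- logical(nr * nc)
  wmask_v[in_b] <- fin$mask[cbind(ry[in_b], rx[in_b])]
  wmask <- matrix(wmask_v, nr, nc)
  if (!any(wmask)) stop("warped mask is empty")
  # mask-aware bilinear intensity warp
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- numeric(nr * nc); wtot <- numeric(nr * nc)
  for (k in 1:4) {
    dx <- c(0, 1, 0, 1)[k]; dy <- c(0, 0, 1, 1)[k]
    xx <- x0 + dx; yy <- y0 + dy
    w <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
    ok <- xx >= 1 & xx <= nc_in & yy >= 1 & yy <= nr_in
    idx <- cbind(yy[ok], xx[ok])
    v <- fin$values[idx]
    good <- !is.na(v)
    okk <- which(ok)[good]
    val[okk] <- val[okk] + w[okk] * v[good]
    wtot[okk] <- wtot[okk] + w[okk]
  }
  out <- rep(NA_real_, nr * nc)
  nz <- wtot > 1e-9
  out[nz] <- val[nz] / wtot[nz]
  values <- matrix(out, nr, nc)
  wmask <- wmask & !is.na(values)
  if (sum(wmask) < 2L) stop("warped mask is empty")
  values[!wmask] <- NA_real_
  normalise_fin(ifelse(is.na(values), 0, values), wmask)
}
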