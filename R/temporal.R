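# Pigmentation stability over time. For each selected individual the
# date-ordered feature vectors are tested for seriation: if pigmentation is
# stable, the photographic order (by date) is arbitrary. The test is a
# Mantel-type permutation test of the Spearman association between
# pairwise feature-space distances and pairwise time-rank distances, with
# family-wise error control across individuals by the Sidak correction.

#' Sidak-corrected per-test significance level
#'
#' `alpha = 1 - (1 - fwer)^(1/m)`, so that m independent tests at this
#' level give family-wise error `fwer` exactly.
#'
#' @param m Number of tests (>= 1).
#' @param fwer Family-wise error rate in (0, 1).
#' @return Per-test alpha.
#' @export
sidak_alpha <- function(m, fwer = 0.05) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("`m` must be a positive integer")
  if (!is.numeric(fwer) || fwer <= 0 || fwer >= 1)
    stop("`fwer` must be in (0, 1)")
  1 - (1 - fwer)^(1 / m)
}

#' Seriation test for one individual
#'
#' Observed statistic: Spearman rank correlation between the condensed
#' pairwise Euclidean distances of the feature vectors and the pairwise
#' time-rank distances `|i - j|` of their date order. The null distribution
#' permutes the time order `n_permutations` times; the p-value is the
#' add-one estimator `(1 + #{null >= observed}) / (1 + n_permutations)`,
#' one-sided (directional drift predicts a positive association).
#'
#' @param vectors n x p matrix of feature vectors, rows in date order
#'   (or supply `dates` to have them ordered here).
#' @param dates Optional vector of dates used to order the rows.
#' @param n_permutations Number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return A `seriation_result`: list with `n_images`, `statistic`,
#'   `p_value`, `n_permutations`, `seed` (plus `individual_id`,
#'   `alpha_sidak`, `reject` filled by [stability_screen()]).
#' @export
seriation_test <- function(vectors, dates = NULL, n_permutations = 999L,
                           seed = 1L) {
  X <- as.matrix(vectors)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 images")
  if (!is.null(dates)) X <- X[order(dates), , drop = FALSE]
  d <- as.vector(stats::dist(X))
  if (all(d < 1e-12)) {
    warning("all feature vectors identical; p = 1")
    return(structure(list(individual_id = NA_character_, n_images = n,
                          statistic = 0, p_value = 1,
                          alpha_sidak = NA_real_, reject = NA,
                          n_permutations = n_permutations, seed = seed),
                     class = "seriation_result"))
  }
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # stats::dist condensed order: pairs (i, j), i < j, sorted by i then j
  ord <- order(pair[, 1], pair[, 2])
  i_idx <- pair[ord, 1]; j_idx <- pair[ord, 2]
  rd <- rank(d)
  td_obs <- abs(i_idx - j_idx)
  obs <- stats::cor(rd, rank(td_obs))
  perms <- with_seed(seed, replicate(n_permutations, sample.int(n)))
  TD <- abs(perms[i_idx, , drop = FALSE] - perms[j_idx, , drop = FALSE])
  TR <- apply(TD, 2, rank)
  # Pearson on ranks = Spearman; vectorised over permutations
  rdc <- rd - mean(rd)
  TRc <- sweep(TR, 2, colMeans(TR))
  null_stats <- as.vector(crossprod(rdc, TRc)) /
    (sqrt(sum(rdc^2)) * sqrt(colSums(TRc^2)))
  p <- (1 + sum(null_stats >= obs - 1e-12)) / (1 + n_permutations)
  structure(list(individual_id = NA_character_, n_images = n,
                 statistic = obs, p_value = p, alpha_sidak = NA_real_,
                 reject = NA, n_permutations = n_permutations, seed = seed),
            class = "seriation_result")
}

#' @export
print.seriation_result <- function(x, ...) {
  cat(sprintf("<seriation_result> %s: n = %d, rho = %.3f, p = %.4f%s\n",
              x$individual_id %||% "?", x$n_images, x$statistic, x$p_value,
              if (isTRUE(x$reject)) " [reject]" else ""))
  invisible(x)
}

#' Screen a catalogue for pigmentation change over time
#'
#' Selects the `top_n` individuals with (a) the longest time span of images
#' and (b) the most images (span first, count as tie-break, then ID), runs
#' [seriation_test()] on each, and applies the Sidak-corrected level
#' `sidak_alpha(m, fwer)` where `m` is the number of individuals actually
#' tested.
#'
#' @param features Data frame with columns `individual_id`, `date`, and
#'   feature columns; or a matrix plus `labels`/`dates` columns supplied
#'   via the data frame form.
#' @param top_n Number of individuals to test (default 15).
#' @param fwer Family-wise error rate (default 0.05).
#' @param n_permutations,seed Passed to [seriation_test()] (per-individual
#'   seeds are derived from `seed`).
#' @return A `stability_report`: list with `results` (list of
#'   `seriation_result`), `table` (data frame), `alpha_sidak`, `m`.
#' @export
stability_screen <- function(features, top_n = 15L, fwer = 0.05,
                             n_permutations = 999L, seed = 1L) {
  stopifnot(is.data.frame(features),
            all(c("individual_id", "date") %in% names(features)))
  fcols <- setdiff(names(features), c("image_id", "individual_id", "date",
                                      "session_id"))
  ids <- split(seq_len(nrow(features)), features$individual_id)
  ids <- ids[vapply(ids, length, integer(1)) >= 3L]
  if (length(ids) == 0L) stop("no individual has >= 3 dated images")
  span <- vapply(ids, function(ix)
    as.numeric(diff(range(as.Date(features$date[ix])))), numeric(1))
  count <- vapply(ids, length, integer(1))
  sel <- names(ids)[order(-span, -count, names(ids))]
  if (length(sel) < top_n)
    warning("only ", length(sel), " eligible individuals (requested ",
            top_n, "); alpha recomputed accordingly")
  sel <- sel[seq_len(min(top_n, length(sel)))]
  m <- length(sel)
  alpha <- sidak_alpha(m, fwer)
  results <- lapply(seq_along(sel), function(k) {
    ix <- ids[[sel[k]]]
    dts <- as.Date(features$date[ix])
    sess <- if (is.null(features$session_id)) rep("", length(ix))
            else features$session_id[ix]
    img <- if (is.null(features$image_id)) as.character(ix)
           else features$image_id[ix]
    o <- order(dts, sess, img)
    r <- seriation_test(as.matrix(features[ix[o], fcols, drop = FALSE]),
                        n_permutations = n_permutations,
                        seed = derive_seed(seed, k))
    r$individual_id <- sel[k]
    r$alpha_sidak <- alpha
    r$reject <- r$p_value < alpha
    r
  })
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(individual_id = r$individual_id, n_images = r$n_images,
               statistic = r$statistic, p_value = r$p_value,
               alpha_sidak = r$alpha_sidak, reject = r$reject)))
  structure(list(results = results, table = tab, alpha_sidak = alpha, m = m),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d individuals, alpha_sidak = %.6f, %d rejections\n",
              x$m, x$alpha_sidak, sum(x$table$reject)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Per-image coordinates on the first two linear discriminant axes
#'
#' Fits the identity model to the selected individuals and projects each
#' image onto the leading discriminant axes (eigenvectors of the
#' between-class scatter in the whitened space of the shrunk pooled
#' covariance). With two classes only one axis exists and `axis2` is 0.
#' Joining each individual's points in date order visualises drift.
#'
#' @param features n x p matrix.
#' @param labels Individual IDs (>= 3 individuals recommended, >= 2 required).
#' @param dates Dates, same length.
#' @param image_id Optional image identifiers.
#' @return Data frame `image_id, individual_id, date, axis1, axis2`,
#'   ordered by individual then date.
#' @export
lda_trajectory <- function(features, labels, dates, image_id = NULL) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  model <- fit_identity_model(X, labels)
  K <- length(model$class_ids)
  e <- eigen(model$sigma, symmetric = TRUE)
  Wh <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)
  Mw <- model$class_means %*% Wh
  B <- stats::cov(Mw) * (K - 1) / K
  eb <- eigen(B, symmetric = TRUE)
  n_axes <- min(2L, K - 1L)
  A <- Wh %*% eb$vectors[, seq_len(n_axes), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(A))) {
    mj <- which.max(abs(A[, j]))
    if (A[mj, j] < 0) A[, j] <- -A[, j]
  }
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- model$imputation_means[nas[, 2]]
  ctr <- sweep(X, 2, colMeans(model$class_means))
  coords <- ctr %*% A
  out <- data.frame(
    image_id = image_id %||% as.character(seq_len(nrow(X))),
    individual_id = labels,
    date = dates,
    axis1 = coords[, 1],
    axis2 = if (n_axes >= 2L) coords[, 2] else 0
  )
  out[order(out$individual_id, out$date, out$image_id), , drop = FALSE]
}

#' Plot LDA-space trajectories
#'
#' Scatter of the first two discriminant axes with each individual's images
#' joined in date order.
#'
#' @param traj Output of [lda_trajectory()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_trajectory <- function(traj, ...) {
  ids <- unique(traj$individual_id)
  cols <- grDevices::hcl.colors(max(3L, length(ids)), "Dark 3")
  graphics::plot(traj$axis1, traj$axis2, type = "n",
                 xlab = "LDA axis 1", ylab = "LDA axis 2", ...)
  for (k in seq_along(ids)) {
    sub <- traj[traj$individual_id == ids[k], ]
    graphics::lines(sub$axis1, sub$axis2, col = cols[k])
    graphics::points(sub$axis1, sub$axis2, col = cols[k], pch = 19, cex = 0.7)
  }
  invisible(traj)
}
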