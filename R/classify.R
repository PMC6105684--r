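# Individual identification with a shrinkage-regularised linear
# discriminant classifier. With 142 features and only a handful of images
# per animal the pooled covariance is singular; the off-diagonal of its
# correlation is shrunk toward the identity with an analytically estimated
# intensity (James-Stein / Schafer-Strimmer style), keeping the empirical
# variances on the diagonal.

#' Shrinkage estimate of a covariance matrix
#'
#' Shrinks the empirical correlation matrix toward the identity target with
#' an analytic intensity estimated from the data, then rescales by the
#' empirical standard deviations:
#' `Sigma* = D ((1 - lambda) R + lambda I) D`. The intensity is
#' `lambda = sum_{i != j} Var(r_ij) / sum_{i != j} r_ij^2`, clipped to
#' `[0, 1]`. This pulls the off-diagonal entries toward zero, trading bias
#' for a large variance reduction when features outnumber samples.
#'
#' @param centered_data n x p matrix of residuals (already centred; for a
#'   pooled within-class estimate, centred by class means).
#' @param df Degrees of freedom for the variance/correlation denominators
#'   (default `n - 1`; use `n - K` for data centred by `K` class means).
#' @param lambda Optional fixed intensity overriding the analytic estimate.
#' @param var_floor Zero-variance features get their variance floored at
#'   this value, with a warning.
#' @return List with `sigma` (p x p), `lambda`, `variances`.
#' @export
shrink_covariance <- function(centered_data, df = nrow(centered_data) - 1L,
                              lambda = NULL, var_floor = 1e-8) {
  X <- as.matrix(centered_data)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 2L, df >= 1L)
  vars <- colSums(X^2) / df
  if (any(vars < var_floor)) {
    warning(sum(vars < var_floor), " zero-variance features floored")
    vars <- pmax(vars, var_floor)
  }
  sdv <- sqrt(vars)
  Xs <- sweep(X, 2, sdv, "/")
  R <- crossprod(Xs) / df
  diag(R) <- 1
  if (is.null(lambda)) {
    # Var-hat of the correlation entries from the products w_kij = x_ki x_kj:
    # sum_k w^2 = crossprod(Xs^2); mean w = crossprod(Xs) / n
    W2 <- crossprod(Xs^2)
    Wb <- crossprod(Xs) / n
    varR <- n / (df^3) * (W2 - n * Wb^2)
    off <- upper.tri(R)
    denom <- sum(R[off]^2)
    lambda <- if (denom <= 0) 1 else sum(varR[off]) / denom
    lambda <- min(1, max(0, lambda))
  }
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  sigma <- Rs * tcrossprod(sdv)
  list(sigma = sigma, lambda = lambda, variances = vars)
}

#' Fit an identity model (regularised LDA)
#'
#' Class means plus a pooled within-class covariance estimated by
#' [shrink_covariance()] on the class-centred residuals (denominator
#' `n - K`). Missing feature cells are imputed with the training-set
#' per-feature means before fitting; the same means are stored for
#' imputing queries.
#'
#' @param features n x p numeric matrix (NA = missing).
#' @param labels Individual IDs, length n.
#' @param priors `"uniform"` (default) or `"empirical"`.
#' @param lambda Optional fixed shrinkage intensity.
#' @return An `identity_model`.
#' @export
fit_identity_model <- function(features, labels,
                               priors = c("uniform", "empirical"),
                               lambda = NULL) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  classes <- sort(unique(labels))
  K <- length(classes)
  if (K < 2L) stop("need at least 2 classes")
  imput <- colMeans(X, na.rm = TRUE)
  imput[is.na(imput)] <- 0
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- imput[nas[, 2]]
  means <- t(matrix(vapply(classes,
                           function(k) colMeans(X[labels == k, , drop = FALSE]),
                           numeric(ncol(X))), nrow = ncol(X)))
  centred <- X - means[match(labels, classes), , drop = FALSE]
  sc <- shrink_covariance(centred, df = max(1L, nrow(X) - K), lambda = lambda)
  pr <- if (is.numeric(priors)) priors / sum(priors)
        else if (match.arg(priors) == "uniform") rep(1 / K, K)
        else as.numeric(table(factor(labels, classes))) / length(labels)
  ch <- chol(sc$sigma)
  sigma_inv <- chol2inv(ch)
  W <- sigma_inv %*% t(means)                       # p x K
  const <- -0.5 * colSums(t(means) * W) + log(pr)   # length K
  structure(
    list(class_ids = classes, class_means = means, sigma = sc$sigma,
         lambda = sc$lambda, priors = pr, imputation_means = imput,
         discriminant_w = W, discriminant_const = const,
         feature_names = colnames(X)),
    class = "identity_model"
  )
}

#' @export
print.identity_model <- function(x, ...) {
  cat(sprintf("<identity_model> %d classes, %d features, lambda = %.3f\n",
              length(x$class_ids), ncol(x$class_means), x$lambda))
  invisible(x)
}

#' Predict identities from feature vectors
#'
#' Linear discriminant scores
#' `delta_k(x) = x' Sigma^-1 mu_k - mu_k' Sigma^-1 mu_k / 2 + log pi_k`,
#' with posteriors by softmax over classes and the ranking by decreasing
#' posterior (ties broken by class ID order).
#'
#' @param object An `identity_model`.
#' @param newdata A numeric vector (one photo), a matrix, or a
#'   `feature_vector`.
#' @param ... Unused.
#' @return An `identity_prediction`: list with `posteriors` (n x K matrix),
#'   `ranking` (n x K matrix of class IDs, best first).
#' @export
predict.identity_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_vector")) newdata <- newdata$values
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- object$imputation_means[nas[, 2]]
  scores <- X %*% object$discriminant_w +
    matrix(object$discriminant_const, nrow(X), length(object$class_ids),
           byrow = TRUE)
  mx <- apply(scores, 1, max)
  es <- exp(scores - mx)
  post <- es / rowSums(es)
  colnames(post) <- object$class_ids
  ranking <- t(apply(post, 1, function(p)
    object$class_ids[order(-p, object$class_ids)]))
  structure(list(posteriors = post, ranking = ranking,
                 class_ids = object$class_ids),
            class = "identity_prediction")
}

#' Leave-one-out cross-validation of the identity classifier
#'
#' Each photo of a class with at least 2 photos is held out in turn; the
#' model (class means, shrinkage intensity and imputation means) is refit
#' from scratch on the remaining photos, so the held-out photo contributes
#' nothing to its own fold. Singleton classes are never held out but stay
#' in the training set as legitimate candidate answers.
#'
#' @param features n x p matrix.
#' @param labels Individual IDs.
#' @param k_list Ranks at which to report top-k accuracy.
#' @param priors,lambda Passed to [fit_identity_model()].
#' @return A `cv_report`: list with `top_k` (named accuracies),
#'   `top1_accuracy`, `top5_accuracy`, `lift_uniform`, `lift_empirical`,
#'   `confusion` (K x K), `ranks` (per-image data frame), `n_classes`,
#'   `n_evaluated`.
#' @export
loocv <- function(features, labels, k_list = c(1L, 5L),
                  priors = "uniform", lambda = NULL) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  K <- length(classes)
  tab <- table(labels)
  eligible <- which(labels %in% names(tab)[tab >= 2L])
  if (length(eligible) < length(labels))
    warning(length(labels) - length(eligible),
            " singleton-class photos excluded from held-out evaluation")
  if (length(eligible) == 0L) stop("no class has >= 2 photos")
  ranks <- integer(length(eligible))
  pred1 <- character(length(eligible))
  for (ii in seq_along(eligible)) {
    i <- eligible[ii]
    fit <- fit_identity_model(X[-i, , drop = FALSE], labels[-i],
                              priors = priors, lambda = lambda)
    pr <- predict(fit, X[i, ])
    ranks[ii] <- match(labels[i], pr$ranking[1, ])
    pred1[ii] <- pr$ranking[1, 1]
  }
  top_k <- vapply(k_list, function(k) mean(ranks <= k), numeric(1))
  names(top_k) <- paste0("top", k_list)
  top1 <- mean(ranks <= 1L)
  p_emp <- as.numeric(tab) / length(labels)
  confusion <- table(factor(labels[eligible], classes), factor(pred1, classes))
  structure(
    list(top_k = top_k,
         top1_accuracy = top1,
         top5_accuracy = if ("top5" %in% names(top_k)) top_k[["top5"]] else NA_real_,
         lift_uniform = top1 * K,
         lift_empirical = top1 / sum(p_emp^2),
         confusion = confusion,
         ranks = data.frame(index = eligible, true_id = labels[eligible],
                            rank = ranks,
                            top5_hit = ranks <= 5L),
         n_classes = K, n_evaluated = length(eligible)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d photos, %d classes\n", x$n_evaluated, x$n_classes))
  for (nm in names(x$top_k))
    cat(sprintf("  %s accuracy: %.1f%%\n", nm, 100 * x$top_k[[nm]]))
  cat(sprintf("  lift: %.1f (uniform baseline), %.1f (empirical)\n",
              x$lift_uniform, x$lift_empirical))
  invisible(x)
}
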