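# Shared fixtures: all synthetic, generated in code at test time.

# Nuisance-free rendering: pose, illumination, highlights and occlusion off.
quiet_nuisance <- function(...) {
  photo_nuisance(homography_jitter = 0, noise_sd = 0, highlight_prob = 0,
                 occlusion_frac = 0, ...)
}

test_fin_photo <- function(seed = 1, nuisance = quiet_nuisance(), ...) {
  render_photo(synthetic_identity(paste0("T", seed), seed), nuisance,
               photo_seed = seed, ...)
}

# Fin masks are reused heavily; cache nuisance-free renders per seed.
.fin_cache <- new.env(parent = emptyenv())
cached_fin <- function(seed = 1) {
  key <- as.character(seed)
  if (is.null(.fin_cache[[key]])) .fin_cache[[key]] <- test_fin_photo(seed)
  .fin_cache[[key]]
}

disc_mask <- function(r, pad = 4L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  xx <- matrix(rep(seq_len(n), each = n), n)
  yy <- matrix(rep(seq_len(n), times = n), n)
  (xx - ctr)^2 + (yy - ctr)^2 <= r^2
}

square_mask <- function(side, pad = 4L) {
  n <- side + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1L):(pad + side), (pad + 1L):(pad + side)] <- TRUE
  m
}

# Bottom-edge base line of an axis-aligned mask.
bottom_base <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  structure(list(point = c(x = min(cols), y = max(rows)),
                 direction = c(1, 0), normal = c(0, -1)),
            class = "base_line")
}

# Quick labelled feature matrix: Gaussian classes around distinct means.
toy_classes <- function(K = 3L, n_per = 5L, p = 4L, sep = 6, sd = 1,
                        seed = 1L) {
  set.seed(seed)
  mu <- matrix(rnorm(K * p, sd = sep), K, p)
  X <- mu[rep(seq_len(K), each = n_per), ] + matrix(rnorm(K * n_per * p, sd = sd),
                                                    K * n_per, p)
  list(X = X, y = rep(sprintf("C%d", seq_len(K)), each = n_per), mu = mu)
}
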