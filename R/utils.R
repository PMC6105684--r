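# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers never disturb
#' the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Derive a child seed from a master seed and stream indices
#'
#' Hierarchical streams (master -> identity -> photo) so that adding photos
#' or identities never perturbs the draws of existing ones. Uses a simple
#' Lehmer-style mix kept below 2^31 - 1 (R integers are 32-bit).
#' @noRd
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- (abs(as.double(master)) + 1) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + (as.double(k) + 1) * 99991) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Frontier-based flood fill over column-major indices (4-connectivity).
# Returns a logical vector over cells reachable from `start`.
flood_fill <- function(mask_vec, nr, start) {
  visited <- logical(length(mask_vec))
  frontier <- start
  visited[start] <- TRUE
  while (length(frontier)) {
    row <- (frontier - 1L) %% nr + 1L
    nbr <- c(frontier[row > 1L] - 1L, frontier[row < nr] + 1L,
             frontier - nr, frontier + nr)
    nbr <- nbr[nbr >= 1L & nbr <= length(mask_vec)]
    nbr <- unique(nbr[mask_vec[nbr] & !visited[nbr]])
    visited[nbr] <- TRUE
    frontier <- nbr
  }
  visited
}

#' Label 4-connected components of a binary mask
#'
#' Repeated flood fill; returns an integer matrix of component labels
#' (NA off-mask).
#' @noRd
mask_components <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask)
  mv <- as.vector(mask)
  lab <- integer(length(mv))
  todo <- which(mv)
  comp <- 0L
  while (length(todo)) {
    comp <- comp + 1L
    vis <- flood_fill(mv, nr, todo[1L])
    lab[vis] <- comp
    todo <- todo[!vis[todo]]
  }
  out <- matrix(NA_integer_, nr, ncol(mask))
  out[mask] <- lab[mv]
  out
}

#' Number of 4-connected components in a mask
#' @noRd
n_components <- function(mask) {
  if (!any(mask)) return(0L)
  max(mask_components(mask), na.rm = TRUE)
}

#' Boundary pixels of a mask (fin pixels with a 4-neighbour off the fin
#' or on the image border)
#' @noRd
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !interior
}

#' Pixel-centre coordinates (x = column, y = row) of TRUE entries
#' @noRd
mask_coords <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

#' Population standard deviation (divide by n)
#' @noRd
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
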