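# Internal numerical helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Deterministic 32-bit sub-seed derived from a master seed and an index.
# Keeps per-cell / per-stage RNG streams independent of evaluation order.
.sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647L)
}

# Normalised 1D Gaussian kernel, radius 3 sigma (in pixels).
.gaussian_kernel <- function(sigma_px) {
  .assert(sigma_px > 0, "sigma must be positive")
  r <- max(1L, ceiling(3 * sigma_px))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Dense band matrix implementing zero-padded 1D convolution of length-n
# signals with an odd-length kernel; used as M %*% x.
.conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    M[cbind(idx[ok], src[ok])] <- M[cbind(idx[ok], src[ok])] + kernel[j]
  }
  M
}

# Separable convolution of a 2D matrix (rows then columns), zero-padded.
.conv_sep_2d <- function(x, kernel_row, kernel_col) {
  Mr <- .conv_matrix(nrow(x), kernel_row)
  Mc <- .conv_matrix(ncol(x), kernel_col)
  Mr %*% x %*% t(Mc)
}

# Convolve a 3D array along one axis with an odd kernel, zero-padded.
.conv_axis_3d <- function(a, kernel, axis) {
  d <- dim(a)
  perm <- switch(axis, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  m <- .conv_matrix(d[axis], kernel) %*% m
  ap <- array(m, dim = d[perm])
  aperm(ap, order(perm))
}

# Second difference along an axis with replicated borders, divided by h^2.
# Works for 2D matrices (axis 1 = rows) and 3D arrays.
.second_diff <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  idx_up <- pmin(seq_len(n) + 1L, n)
  idx_dn <- pmax(seq_len(n) - 1L, 1L)
  slice <- function(i) {
    args <- rep(list(quote(expr = )), length(d))
    args[[axis]] <- i
    do.call(`[`, c(list(a), args, list(drop = FALSE)))
  }
  (slice(idx_up) - 2 * a + slice(idx_dn)) / h^2
}

# Logical array of local maxima over the full (8- or 26-) neighbourhood.
# Exact ties (plateaus, e.g. a peak centred on a pixel boundary) are broken
# deterministically in favour of the lowest linear index, so a two-pixel
# plateau yields exactly one maximum.
.local_maxima <- function(a) {
  d <- dim(a)
  nd <- length(d)
  shifts <- expand.grid(rep(list(-1:1), nd))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  lin <- array(seq_along(a), d)
  out <- array(TRUE, dim = d)
  for (s in seq_len(nrow(shifts))) {
    idx <- lapply(seq_len(nd), function(ax) {
      i <- seq_len(d[ax]) + shifts[s, ax]
      pmin(pmax(i, 1L), d[ax])
    })
    shifted <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    # replicated borders compare a voxel with itself; only genuine
    # neighbours participate in the comparison
    nb <- do.call(`[`, c(list(lin), idx, list(drop = FALSE)))
    genuine <- array(nb != seq_along(a), dim = d)
    wins <- (a > shifted) | (a == shifted & array(seq_along(a) < nb, dim = d))
    out <- out & (!genuine | wins)
  }
  out
}

# Euclidean norm of rows of a matrix.
.row_norms <- function(m) sqrt(rowSums(m^2))

# Normalise rows to unit length (zero rows left untouched).
.unit_rows <- function(m) {
  n <- .row_norms(m)
  n[n == 0] <- 1
  m / n
}
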