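# Small deterministic configurations used across tests.

tiny_config <- function(n_cells = 5, regime = "motile", n_frames = 8, seed = 1,
                        noise_free = FALSE, protrusion = NULL, ...) {
  args <- utils::modifyList(
    list(n_cells = n_cells, regime = regime, n_frames = n_frames,
         seed = seed, field_size = c(x = 120, y = 120, z = 40)),
    list(...))
  if (noise_free)
    args$noise <- list(background = 0, signal = 200, shot_noise = FALSE)
  if (!is.null(protrusion))
    args$protrusion_amplitude <- c(motile = protrusion, arrested = protrusion)
  do.call(simulation_config, args)
}

# single cell pinned at a given position, optionally stationary
one_cell_truth <- function(cfg, x, y, z = 20) {
  truth <- simulate_tracks(cfg)
  truth$tracks$x_um <- x
  truth$tracks$y_um <- y
  truth$tracks$z_um <- z
  truth
}

# brute-force IoU by explicit pixel loop (independent of iou_pair)
iou_bruteforce <- function(a, b) {
  inter <- 0L; union <- 0L
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1L
    if (a[i] || b[i]) union <- union + 1L
  }
  if (union == 0L) 1 else inter / union
}

# brute-force Otsu: exhaustive scan of intra-class variance over candidates;
# a tied optimal plateau (e.g. across empty bins) resolves to its midpoint
otsu_bruteforce <- function(v, candidates = 0:255) {
  vals <- vapply(candidates, function(th) {
    lo <- v[v <= th]; hi <- v[v > th]
    if (!length(lo) || !length(hi)) return(Inf)
    (length(lo) * .pop_var(lo) + length(hi) * .pop_var(hi)) / length(v)
  }, numeric(1))
  best <- which(vals <= min(vals) + 1e-12 * max(1, abs(min(vals))))
  mean(candidates[range(best)])
}
.pop_var <- function(x) mean((x - mean(x))^2)

# brute-force clipped-window binary median filter
median_filter_bruteforce <- function(mask, k) {
  r <- (k - 1) %/% 2
  out <- mask
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    win <- mask[max(1, i - r):min(nrow(mask), i + r),
                max(1, j - r):min(ncol(mask), j + r)]
    out[i, j] <- stats::median(win) > 0.5
  }
  out
}

# brute-force anisotropic EDT: nearest structure voxel centre search
edt_bruteforce <- function(mask, voxel_size) {
  d <- dim(mask)
  occ <- which(mask, arr.ind = TRUE)   # (z, y, x) indices
  pz <- voxel_size[["z"]]; py <- voxel_size[["y"]]; px <- voxel_size[["x"]]
  out <- array(NA_real_, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    dz <- (occ[, 1] - z) * pz
    dy <- (occ[, 2] - y) * py
    dx <- (occ[, 3] - x) * px
    out[z, y, x] <- sqrt(min(dz^2 + dy^2 + dx^2))
  }
  out
}
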