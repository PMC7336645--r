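#' Detect cells as fixed-scale bright spots
#'
#' Single-scale Laplacian-of-Gaussian blob detection matched to the
#' nominal cell diameter (10 um in the intravital experiments): the image
#' is smoothed with an anisotropy-aware Gaussian of physical scale
#' `sigma = diameter / (2 * sqrt(2))`, the scale-normalized negative
#' Laplacian is computed with physical spacings, and strict local maxima
#' above the response threshold are returned as centroids with per-axis
#' quadratic sub-pixel refinement.
#'
#' @param img numeric matrix (`Y x X`, a MIP frame) or 3D array
#'   (`Z x Y x X` volume).
#' @param voxel_size named numeric `c(x, y)` or `c(x, y, z)` pitch in um
#'   (a scalar is recycled).
#' @param diameter nominal spot diameter in um (default 10).
#' @param threshold absolute response threshold; if `NULL`,
#'   `rel_threshold * max(response)` is used.
#' @param rel_threshold relative threshold used when `threshold` is `NULL`.
#' @return data frame with columns `x_um`, `y_um` (and `z_um` for
#'   volumes) and `response`, sorted lexicographically by coordinates.
#' @export
detect_spots <- function(img, voxel_size, diameter = 10,
                         threshold = NULL, rel_threshold = 0.2) {
  nd <- length(dim(img))
  .assert(nd %in% c(2L, 3L), "img must be a 2D matrix or 3D array")
  axes <- if (nd == 2L) c("x", "y") else c("x", "y", "z")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, length(axes))
  if (is.null(names(voxel_size))) names(voxel_size) <- axes
  .assert(all(voxel_size[axes] > 0), "voxel size must be positive")
  if (any(diameter / voxel_size[axes] < 2))
    stop("sub-resolution: diameter spans fewer than 2 pixels on some axis",
         call. = FALSE)
  resp <- .log_response(img, voxel_size, diameter)
  if (is.null(threshold)) threshold <- rel_threshold * max(resp, 0)
  cand <- .local_maxima(resp) & (resp > threshold)
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    out <- data.frame(x_um = numeric(0), y_um = numeric(0), response = numeric(0))
    if (nd == 3L) out$z_um <- numeric(0)
    return(out[, c(axes[axes != "z"] |> paste0("_um"),
                   if (nd == 3L) "z_um", "response")])
  }
  # sub-pixel quadratic refinement per axis
  d <- dim(resp)
  offs <- matrix(0, nrow(idx), nd)
  for (ax in seq_len(nd)) {
    i0 <- idx[, ax]
    interior <- i0 > 1L & i0 < d[ax]
    if (any(interior)) {
      ip <- idx; im <- idx
      ip[, ax] <- pmin(ip[, ax] + 1L, d[ax])
      im[, ax] <- pmax(im[, ax] - 1L, 1L)
      fp <- resp[ip]; fm <- resp[im]; f0 <- resp[idx]
      den <- fm - 2 * f0 + fp
      off <- ifelse(interior & den < 0, 0.5 * (fm - fp) / den, 0)
      offs[, ax] <- pmin(pmax(off, -0.5), 0.5)
    }
  }
  # array axes: 2D = (y, x); 3D = (z, y, x)
  if (nd == 2L) {
    out <- data.frame(
      x_um = (idx[, 2] - 0.5 + offs[, 2]) * voxel_size[["x"]],
      y_um = (idx[, 1] - 0.5 + offs[, 1]) * voxel_size[["y"]],
      response = resp[idx])
    out <- out[order(out$x_um, out$y_um), , drop = FALSE]
  } else {
    out <- data.frame(
      x_um = (idx[, 3] - 0.5 + offs[, 3]) * voxel_size[["x"]],
      y_um = (idx[, 2] - 0.5 + offs[, 2]) * voxel_size[["y"]],
      z_um = (idx[, 1] - 0.5 + offs[, 1]) * voxel_size[["z"]],
      response = resp[idx])
    out <- out[order(out$x_um, out$y_um, out$z_um), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# scale-normalized negative LoG response at sigma = diameter / (2 sqrt 2)
.log_response <- function(img, voxel_size, diameter) {
  sigma <- diameter / (2 * sqrt(2))
  nd <- length(dim(img))
  if (nd == 2L) {
    ky <- .gaussian_kernel(sigma / voxel_size[["y"]])
    kx <- .gaussian_kernel(sigma / voxel_size[["x"]])
    sm <- .conv_sep_2d(img, ky, kx)
    lap <- .second_diff(sm, 1L, voxel_size[["y"]]) +
      .second_diff(sm, 2L, voxel_size[["x"]])
  } else {
    vz <- c(voxel_size[["z"]], voxel_size[["y"]], voxel_size[["x"]])
    sm <- img
    for (ax in 1:3) sm <- .conv_axis_3d(sm, .gaussian_kernel(sigma / vz[ax]), ax)
    lap <- .second_diff(sm, 1L, vz[1]) + .second_diff(sm, 2L, vz[2]) +
      .second_diff(sm, 3L, vz[3])
  }
  -sigma^2 * lap
}

#' Detect spots in every frame of a movie
#'
#' Applies [detect_spots()] frame by frame with one movie-global response
#' threshold (`rel_threshold` times the maximum response over all frames),
#' so detections are comparable across time.
#'
#' @param movie a [timelapse_movie()].
#' @param channel channel role to detect in (default `"green"`).
#' @param mode `"mip"` (2D detection on the projection, the default for
#'   motility analysis) or `"3d"`.
#' @inheritParams detect_spots
#' @return object of class `spot_set`: list with `frames` (one centroid
#'   data frame per time point), `diameter`, `voxel_size`,
#'   `frame_interval`.
#' @export
detect_movie_spots <- function(movie, channel = "green", mode = c("mip", "3d"),
                               diameter = 10, threshold = NULL,
                               rel_threshold = 0.2) {
  stopifnot(inherits(movie, "timelapse_movie"))
  mode <- match.arg(mode)
  if (mode == "mip") movie <- movie_mip(movie)
  ch <- get_channel(movie, channel)      # T x Z x Y x X
  d <- dim(ch)
  frames <- lapply(seq_len(d[1]), function(t) {
    if (d[2] == 1L) matrix(ch[t, 1, , ], d[3], d[4]) else
      array(ch[t, , , ], dim = d[2:4])
  })
  if (is.null(threshold)) {
    rmax <- max(vapply(frames, function(f)
      max(.log_response(f, movie$voxel_size, diameter)), numeric(1)), 0)
    threshold <- rel_threshold * rmax
  }
  spots <- lapply(frames, detect_spots, voxel_size = movie$voxel_size,
                  diameter = diameter, threshold = threshold)
  structure(list(frames = spots, diameter = diameter,
                 voxel_size = movie$voxel_size,
                 frame_interval = movie$frame_interval),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  n <- vapply(x$frames, nrow, integer(1))
  cat(sprintf("spot_set: %d frames, %d detections (%.1f per frame)\n",
              length(n), sum(n), mean(n)))
  invisible(x)
}

#' Link detected spots into tracks
#'
#' Frame-to-frame greedy nearest-neighbour assignment: candidate links
#' between consecutive frames are sorted by distance (ties broken by
#' lexicographic coordinate order, making the result independent of
#' detection order) and accepted while both endpoints are unassigned and
#' the distance does not exceed `max_step`. Unlinked detections start new
#' tracks; there is no gap closing.
#'
#' @param spots a `spot_set` from [detect_movie_spots()], or a list of
#'   per-frame centroid data frames (`x_um`, `y_um`, optionally `z_um`).
#' @param max_step maximum link length in um (> 0).
#' @return data frame with columns `track_id`, `frame`, `x_um`, `y_um`
#'   (and `z_um` when present).
#' @export
link_tracks <- function(spots, max_step) {
  .assert(max_step > 0, "max_step must be positive")
  frames <- if (inherits(spots, "spot_set")) spots$frames else spots
  .assert(length(frames) >= 2, "need detections from at least two frames")
  cols <- intersect(c("x_um", "y_um", "z_um"), names(frames[[1]]))
  coords <- lapply(frames, function(f) as.matrix(f[, cols, drop = FALSE]))

  next_id <- 0L
  cur_ids <- integer(nrow(coords[[1]]))
  if (length(cur_ids)) cur_ids <- seq_len(nrow(coords[[1]]))
  next_id <- length(cur_ids)
  rows <- list()
  if (length(cur_ids))
    rows[[1]] <- data.frame(track_id = cur_ids, frame = 1L, coords[[1]])

  for (t in seq_len(length(frames) - 1L)) {
    a <- coords[[t]]; b <- coords[[t + 1L]]
    na <- nrow(a); nb <- nrow(b)
    new_ids <- integer(nb)
    if (na > 0 && nb > 0) {
      dmat <- sqrt(pmax(outer(rowSums(a^2), rep(1, nb)) +
                          outer(rep(1, na), rowSums(b^2)) - 2 * a %*% t(b), 0))
      cand <- which(dmat <= max_step, arr.ind = TRUE)
      if (nrow(cand)) {
        key_a <- do.call(order, as.data.frame(a))    # lexicographic ranks
        key_b <- do.call(order, as.data.frame(b))
        rank_a <- order(key_a); rank_b <- order(key_b)
        ord <- order(dmat[cand], rank_a[cand[, 1]], rank_b[cand[, 2]])
        used_a <- logical(na); used_b <- logical(nb)
        for (ci in ord) {
          i <- cand[ci, 1]; j <- cand[ci, 2]
          if (!used_a[i] && !used_b[j]) {
            used_a[i] <- TRUE; used_b[j] <- TRUE
            new_ids[j] <- cur_ids[i]
          }
        }
      }
    }
    for (j in seq_len(nb)) {
      if (new_ids[j] == 0L) {
        next_id <- next_id + 1L
        new_ids[j] <- next_id
      }
    }
    if (nb > 0)
      rows[[t + 1L]] <- data.frame(track_id = new_ids, frame = t + 1L,
                                   coords[[t + 1L]])
    cur_ids <- new_ids
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(track_id = integer(0), frame = integer(0))
    for (cl in cols) out[[cl]] <- numeric(0)
    return(out)
  }
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean migration speed of one track
#'
#' Total Euclidean path length divided by elapsed time
#' (`n_steps * frame_interval`).
#'
#' @param track data frame with `frame` and coordinate columns for a
#'   single track.
#' @param frame_interval frame spacing in minutes.
#' @return speed in um/min.
#' @export
mean_track_speed <- function(track, frame_interval) {
  .assert(nrow(track) >= 2, "a speed requires at least two track points")
  .assert(frame_interval > 0, "frame_interval must be positive")
  track <- track[order(track$frame), , drop = FALSE]
  cols <- intersect(c("x_um", "y_um", "z_um"), names(track))
  m <- as.matrix(track[, cols, drop = FALSE])
  steps <- .row_norms(diff(m))
  sum(steps) / ((nrow(track) - 1) * frame_interval)
}

#' Per-track speed summary
#'
#' Computes [mean_track_speed()] for every track of at least `min_length`
#' frames; shorter tracks are excluded from speed statistics (suppressing
#' spurious one-link tracks) and their count is reported in the
#' `n_excluded` attribute.
#'
#' @param tracks data frame from [link_tracks()].
#' @param frame_interval frame spacing in minutes.
#' @param min_length minimum track length in frames (default 5).
#' @return data frame `track_id, n_frames, mean_speed_um_min`.
#' @export
track_speeds <- function(tracks, frame_interval, min_length = 5L) {
  counts <- table(tracks$track_id)
  keep <- names(counts)[counts >= min_length]
  res <- lapply(keep, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    data.frame(track_id = as.integer(id), n_frames = nrow(tr),
               mean_speed_um_min = mean_track_speed(tr, frame_interval))
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(track_id = integer(0), n_frames = integer(0),
               mean_speed_um_min = numeric(0))
  out <- out[order(out$track_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- length(counts) - length(keep)
  out
}
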