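#' Construct a calibrated time-lapse movie object
#'
#' The package's raw-input container: a `T x C x Z x Y x X` non-negative
#' intensity array with physical calibration. `Z = 1` denotes a
#' maximum-intensity-projection (MIP) movie.
#'
#' @param data numeric array, dimensions `T x C x Z x Y x X`.
#' @param channels named integer vector mapping the roles `green` (tumor
#'   cells), `red` (vessels) and `blue` (bone) to channel indices; each
#'   role exactly once.
#' @param voxel_size named numeric triple `c(x, y, z)` in um.
#' @param frame_interval frame spacing in minutes.
#' @return an object of class `timelapse_movie`.
#' @export
timelapse_movie <- function(data, channels = c(green = 1L, red = 2L, blue = 3L),
                            voxel_size = c(x = 1, y = 1, z = 1),
                            frame_interval = 1) {
  .assert(length(dim(data)) == 5, "data must be a T x C x Z x Y x X array")
  .assert(all(data >= 0), "intensities must be non-negative")
  .assert(all(voxel_size > 0) && frame_interval > 0,
          "calibration must be strictly positive")
  .assert(setequal(names(channels), c("green", "red", "blue")) &&
            !anyDuplicated(channels),
          "channels must map green/red/blue to distinct indices")
  .assert(all(channels >= 1 & channels <= dim(data)[2]),
          "channel indices out of range")
  structure(list(data = data, channels = channels,
                 voxel_size = stats::setNames(as.numeric(voxel_size), c("x", "y", "z")),
                 frame_interval = frame_interval),
            class = "timelapse_movie")
}

#' @export
print.timelapse_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("timelapse_movie: %d frames, %d channels, %d x %d x %d voxels (Z,Y,X)\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat("  voxel (um):", paste(x$voxel_size, collapse = " x "),
      "; frame interval:", x$frame_interval, "min\n")
  invisible(x)
}

#' Extract one channel of a movie by role
#'
#' @param movie a [timelapse_movie()].
#' @param role one of `"green"`, `"red"`, `"blue"`.
#' @return `T x Z x Y x X` array.
#' @export
get_channel <- function(movie, role = "green") {
  stopifnot(inherits(movie, "timelapse_movie"))
  ci <- movie$channels[[role]]
  d <- dim(movie$data)
  array(movie$data[, ci, , , , drop = FALSE], dim = d[-2])
}

#' Maximum-intensity projection of a movie along Z
#'
#' @param movie a [timelapse_movie()].
#' @return a [timelapse_movie()] with `Z = 1`.
#' @export
movie_mip <- function(movie) {
  stopifnot(inherits(movie, "timelapse_movie"))
  d <- dim(movie$data)
  if (d[3] == 1) return(movie)
  out <- array(0, dim = c(d[1], d[2], 1, d[4], d[5]))
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) {
    vol <- array(movie$data[t, ch, , , ], dim = d[3:5])
    out[t, ch, 1, , ] <- apply(vol, c(2, 3), max)
  }
  timelapse_movie(out, movie$channels, movie$voxel_size, movie$frame_interval)
}

# voxel-center coordinates (um) along one axis
.axis_centers <- function(n, pitch) (seq_len(n) - 0.5) * pitch

#' Render a synthetic multichannel movie from ground-truth tracks
#'
#' The green channel is the sum of quasi-spherical cell kernels: a logistic
#' radial profile of nominal radius `cell_diameter / 2`, perturbed each
#' frame by a protrusion lobe of random in-plane direction and amplitude up
#' to the regime's `protrusion_amplitude`, so that motile cells fluctuate
#' in shape more than arrested ones independently of centroid motion. The
#' red channel is the blurred vessel tube occupancy and the blue channel
#' the blurred bone slab. Optional Poisson shot noise is applied on top of
#' a constant background and intensities are clipped to the 16-bit range.
#'
#' @param truth a `ground_truth` from [simulate_tracks()].
#' @param config the generating [simulation_config()].
#' @param mode `"mip"` renders the maximum-intensity projection directly
#'   (`Z = 1`, the default for motility analysis); `"3d"` renders the full
#'   volume (used for distance analysis).
#' @param frames optional integer vector of frames to render (default all).
#' @return a [timelapse_movie()] with integer-valued intensities.
#' @export
render_movie <- function(truth, config = truth$config,
                         mode = c("mip", "3d"), frames = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  mode <- match.arg(mode)
  vx <- config$voxel_size
  if (any(vx > config$cell_diameter))
    warning("voxel size exceeds the cell diameter: cells are sub-resolution")
  frames <- frames %||% seq_len(config$n_frames)
  nt <- length(frames)
  nx <- max(1L, round(config$field_size["x"] / vx["x"]))
  ny <- max(1L, round(config$field_size["y"] / vx["y"]))
  nz <- if (mode == "mip") 1L else max(1L, round(config$field_size["z"] / vx["z"]))
  n <- config$n_cells
  r0 <- config$cell_diameter / 2
  edge <- 1.0  # um, softness of the cell boundary
  sig <- config$noise$signal

  # per-cell, per-frame protrusion direction (in-plane) and amplitude
  prot_phi <- matrix(0, config$n_frames, n)
  prot_amp <- matrix(0, config$n_frames, n)
  for (i in seq_len(n)) {
    set.seed(.sub_seed(config$seed, 200000L + i))
    prot_phi[, i] <- stats::runif(config$n_frames, 0, 2 * pi)
    prot_amp[, i] <- config$protrusion_amplitude[[config$regime[i]]] *
      stats::runif(config$n_frames)
  }

  xs <- .axis_centers(nx, vx["x"])
  ys <- .axis_centers(ny, vx["y"])
  zs <- .axis_centers(nz, vx["z"])

  # static structural channels (before noise)
  red <- .render_vessels(config, xs, ys, zs, mode)
  blue <- .render_bone(config, xs, ys, zs, mode)

  pos <- truth$tracks
  data <- array(0, dim = c(nt, 3L, nz, ny, nx))
  for (ti in seq_len(nt)) {
    t <- frames[ti]
    green <- array(0, dim = c(nz, ny, nx))
    rows <- pos[pos$frame == t, ]
    for (i in seq_len(n)) {
      ci <- c(rows$x_um[i], rows$y_um[i], rows$z_um[i])
      amp <- prot_amp[t, i]
      u <- c(cos(prot_phi[t, i]), sin(prot_phi[t, i]), 0)
      rad <- r0 + amp + 4 * edge
      ix <- which(abs(xs - ci[1]) <= rad)
      iy <- which(abs(ys - ci[2]) <= rad)
      iz <- if (mode == "mip") 1L else which(abs(zs - ci[3]) <= rad)
      if (!length(ix) || !length(iy) || !length(iz)) next
      g <- expand.grid(z = iz, y = iy, x = ix)
      dx <- xs[g$x] - ci[1]
      dy <- ys[g$y] - ci[2]
      dz <- if (mode == "mip") 0 else zs[g$z] - ci[3]
      d <- sqrt(dx^2 + dy^2 + dz^2)
      cosang <- ifelse(d > 0, (dx * u[1] + dy * u[2] + dz * u[3]) / d, 1)
      r_eff <- r0 + amp * pmax(0, cosang)
      val <- sig * stats::plogis((r_eff - d) / edge)
      idx <- cbind(g$z, g$y, g$x)
      green[idx] <- green[idx] + val
    }
    data[ti, 1, , , ] <- green
    data[ti, 2, , , ] <- red
    data[ti, 3, , , ] <- blue
  }

  # noise and 16-bit clipping
  set.seed(.sub_seed(config$seed, 3L))
  bg <- config$noise$background
  lam <- data + bg
  if (isTRUE(config$noise$shot_noise)) {
    data <- array(stats::rpois(length(lam), lam), dim = dim(lam))
  } else {
    data <- round(lam)
  }
  data <- pmin(pmax(data, 0), 65535)
  timelapse_movie(data, c(green = 1L, red = 2L, blue = 3L),
                  vx, config$frame_interval)
}

# vessel tube occupancy (axis parallel to the imaging plane), blurred
.render_vessels <- function(config, xs, ys, zs, mode) {
  nz <- length(zs); ny <- length(ys); nx <- length(xs)
  occ <- array(0, dim = c(nz, ny, nx))
  sig <- config$noise$signal
  for (v in config$vessels) {
    u <- v$direction / sqrt(sum(v$direction^2))
    if (mode == "mip") {
      # projection: 2D distance from (x, y) to the projected axis line
      g <- expand.grid(y = ys, x = xs)
      rel <- cbind(g$x - v$point[1], g$y - v$point[2])
      proj <- rel %*% u[1:2]
      perp <- rel - proj %*% t(u[1:2])
      inside <- sqrt(rowSums(perp^2)) <= v$radius
      occ[1, , ] <- pmax(occ[1, , ], sig * array(inside, c(ny, nx)))
    } else {
      g <- expand.grid(z = zs, y = ys, x = xs)
      rel <- cbind(g$x - v$point[1], g$y - v$point[2], g$z - v$point[3])
      proj <- rel %*% u
      perp <- rel - proj %*% t(u)
      inside <- sqrt(rowSums(perp^2)) <= v$radius
      occ <- pmax(occ, sig * array(inside, c(nz, ny, nx)))
    }
  }
  .blur_structure(occ, mode)
}

# bone slab occupancy (z <= z_top), blurred; constant under MIP
.render_bone <- function(config, xs, ys, zs, mode) {
  nz <- length(zs); ny <- length(ys); nx <- length(xs)
  occ <- array(0, dim = c(nz, ny, nx))
  if (is.null(config$bone)) return(occ)
  sig <- config$noise$signal
  if (mode == "mip") {
    occ[1, , ] <- sig   # the slab spans the whole field in projection
    return(occ)
  }
  occ[zs <= config$bone$z_top, , ] <- sig
  .blur_structure(occ, mode)
}

.blur_structure <- function(occ, mode) {
  k <- .gaussian_kernel(0.8)
  if (mode == "mip" || dim(occ)[1] == 1) {
    sl <- .conv_sep_2d(occ[1, , ], k, k)
    occ[1, , ] <- sl
    return(occ)
  }
  for (ax in 1:3) occ <- .conv_axis_3d(occ, k, ax)
  occ
}

#' Simulate tracks and render the movie in one call
#'
#' @inheritParams render_movie
#' @param config a [simulation_config()].
#' @return list with elements `truth` and `movie`.
#' @export
simulate_movie <- function(config, mode = c("mip", "3d"), frames = NULL) {
  truth <- simulate_tracks(config)
  list(truth = truth, movie = render_movie(truth, config, mode, frames))
}
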