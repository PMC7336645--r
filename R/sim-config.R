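#' Simulation configuration for synthetic intravital movies
#'
#' Defines the study conditions for the synthetic generator: a population of
#' amoeboid tumor cells performing a persistent random walk in the imaging
#' plane, close to a bone surface (a slab at low z) and a blood vessel (a
#' tube running parallel to the imaging plane). Two motility regimes are
#' supported: `"motile"` cells (proliferative phase, mean speed above
#' 1 um/min) and `"arrested"` cells (cytoreductive phase, below 1 um/min).
#'
#' @param n_cells number of cells to simulate.
#' @param regime character vector of per-cell regimes, recycled to
#'   `n_cells`; values must be `"motile"` or `"arrested"`.
#' @param target_speed named numeric, mean migration speed per regime in
#'   um/min. Defaults place the two regimes on either side of the 1 um/min
#'   boundary that separates active from passive migration.
#' @param persistence directional correlation of the walk in `[0, 1]`;
#'   1 is ballistic, 0 is uncorrelated.
#' @param protrusion_amplitude named numeric, per-regime radial shape
#'   fluctuation of the rendered cell body in um. Affects mask shape (hence
#'   the displacement-area ratio) without moving the centroid.
#' @param cell_diameter nominal cell diameter in um (default 10).
#' @param field_size numeric triple `c(x, y, z)`, field of view in um.
#' @param voxel_size numeric triple `c(x, y, z)`, voxel pitch in um.
#' @param n_frames number of time points (at least 2).
#' @param frame_interval time between frames in minutes.
#' @param vessels list of tubes, each `list(point, direction, radius)` with
#'   `point`/`direction` length-3 in um (direction need not be unit length;
#'   it must be parallel to the imaging plane) and `radius` in um.
#' @param bone `list(z_top = )`: the bone slab occupies `z <= z_top`.
#'   `NULL` for no bone.
#' @param placement_fractions list with optional entries `bone` and
#'   `vessel`, each `list(threshold, fraction)`: the requested fraction of
#'   cells placed within `threshold` um of that surface at frame 1.
#' @param noise `list(background, signal, shot_noise)`: background offset
#'   and cell peak intensity (arbitrary units, clipped to 16-bit), and
#'   whether Poisson shot noise is applied.
#' @param seed integer master seed; identical config and seed give
#'   bit-identical ground truth and movies.
#'
#' @return an object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(n_cells = 5, n_frames = 10, seed = 1)
#' truth <- simulate_tracks(cfg)
#' @export
simulation_config <- function(n_cells = 50,
                              regime = "motile",
                              target_speed = c(motile = 1.5, arrested = 0.5),
                              persistence = 0.7,
                              protrusion_amplitude = c(motile = 2, arrested = 0.5),
                              cell_diameter = 10,
                              field_size = c(x = 400, y = 400, z = 40),
                              voxel_size = c(x = 2, y = 2, z = 2),
                              n_frames = 61,
                              frame_interval = 1,
                              vessels = lapply(seq(40, 360, by = 80),
                                               function(y0) list(
                                                 point = c(200, y0, 20),
                                                 direction = c(1, 0, 0),
                                                 radius = 6)),
                              bone = list(z_top = 6),
                              placement_fractions = list(
                                bone = list(threshold = 15, fraction = 0.5),
                                vessel = list(threshold = 5, fraction = 0.6)),
                              noise = list(background = 10, signal = 200,
                                           shot_noise = TRUE),
                              seed = 1L) {
  .assert(n_cells >= 1, "n_cells must be >= 1")
  regime <- rep_len(as.character(regime), n_cells)
  .assert(all(regime %in% c("motile", "arrested")),
          "regime must be 'motile' or 'arrested'")
  .assert(all(target_speed >= 0), "target_speed must be >= 0")
  .assert(all(regime %in% names(target_speed)),
          "target_speed must name every regime used")
  .assert(persistence >= 0 && persistence <= 1, "persistence must be in [0, 1]")
  .assert(cell_diameter > 0, "cell_diameter must be positive")
  .assert(length(field_size) == 3 && all(field_size > 0),
          "field_size must be a positive triple")
  .assert(length(voxel_size) == 3 && all(voxel_size > 0),
          "voxel_size must be positive componentwise")
  .assert(n_frames >= 2, "n_frames must be >= 2 (no displacement definable otherwise)")
  .assert(frame_interval > 0, "frame_interval must be positive")
  field_size <- stats::setNames(as.numeric(field_size), c("x", "y", "z"))
  voxel_size <- stats::setNames(as.numeric(voxel_size), c("x", "y", "z"))
  for (v in vessels) {
    .assert(all(c("point", "direction", "radius") %in% names(v)),
            "each vessel needs point, direction and radius")
    .assert(v$radius > 0, "vessel radius must be positive")
    .assert(abs(v$direction[3]) < 1e-8,
            "vessel axes must be parallel to the imaging plane")
  }
  if (!is.null(bone)) .assert(bone$z_top > 0 && bone$z_top < field_size["z"],
                              "bone z_top must lie inside the field")
  for (nm in names(placement_fractions)) {
    pf <- placement_fractions[[nm]]
    .assert(pf$fraction >= 0 && pf$fraction <= 1,
            "placement fractions must be in [0, 1]")
    .assert(pf$threshold > 0, "placement thresholds must be positive")
    .assert(pf$threshold < max(field_size),
            "placement threshold exceeds the field size")
  }
  structure(list(
    n_cells = as.integer(n_cells), regime = regime,
    target_speed = target_speed, persistence = persistence,
    protrusion_amplitude = protrusion_amplitude,
    cell_diameter = cell_diameter, field_size = field_size,
    voxel_size = voxel_size, n_frames = as.integer(n_frames),
    frame_interval = frame_interval, vessels = vessels, bone = bone,
    placement_fractions = placement_fractions, noise = noise,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:", x$n_cells, "cells,", x$n_frames, "frames @",
      x$frame_interval, "min\n")
  cat("  regimes:", paste(sprintf("%s=%d", names(table(x$regime)),
                                  as.integer(table(x$regime))), collapse = ", "), "\n")
  cat("  field:", paste(x$field_size, collapse = " x "), "um; voxel:",
      paste(x$voxel_size, collapse = " x "), "um; seed:", x$seed, "\n")
  invisible(x)
}

# ---- analytic niche geometry -------------------------------------------

#' Analytic distance from points to the bone surface
#'
#' The bone is a slab occupying `z <= z_top`; points inside the slab get
#' distance 0, matching the unsigned distance-to-occupancy convention used
#' throughout the package.
#'
#' @param pos n x 3 matrix of positions (um, columns x/y/z).
#' @param bone `list(z_top = )` or `NULL`.
#' @return numeric vector of distances (um), or `NA` if no bone is defined.
#' @export
bone_distance <- function(pos, bone) {
  if (is.null(bone)) return(rep(NA_real_, nrow(pos)))
  pmax(0, pos[, 3] - bone$z_top)
}

#' Analytic distance from points to the nearest vessel surface
#'
#' Vessels are infinite cylinders; the distance is to the tube surface,
#' with points inside the lumen assigned 0.
#'
#' @param pos n x 3 matrix of positions (um).
#' @param vessels list of `list(point, direction, radius)`.
#' @return numeric vector of distances (um), or `NA` if no vessels.
#' @export
vessel_distance <- function(pos, vessels) {
  if (length(vessels) == 0) return(rep(NA_real_, nrow(pos)))
  d <- rep(Inf, nrow(pos))
  for (v in vessels) {
    u <- v$direction / sqrt(sum(v$direction^2))
    rel <- sweep(pos, 2, v$point)
    proj <- rel %*% u
    perp <- rel - proj %*% t(u)
    d <- pmin(d, pmax(0, .row_norms(perp) - v$radius))
  }
  d
}
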