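#' Run the full motility / localization experiment over grouped movies
#'
#' Orchestrates the pipeline for a set of experimental groups (e.g.
#' untreated day 21, cytarabine-treated day 21, treated day 28): for each
#' group the displacement-area-ratio series, spot tracks and per-track
#' mean speeds are computed on the MIP movie, and — when a 3D volume is
#' available — bone and vessel surfaces are segmented, distance fields
#' built and per-cell niche distances sampled. Group comparisons (one-way
#' ANOVA for three or more groups, Kolmogorov-Smirnov for two, mirroring
#' the conventions of the underlying experiments) are run on speeds and
#' displacement ratios, and everything is written as CSV/JSON with a
#' manifest carrying parameters, seed information and file checksums so a
#' rerun can be verified byte for byte.
#'
#' @param groups named list; each element is either a
#'   [simulation_config()] (the synthetic movie is generated and analysed)
#'   or a path to a movie readable by [read_movie()].
#' @param out_dir output directory (created if needed).
#' @param median_kernel median-filter width for the displacement stage.
#' @param diameter spot diameter in um.
#' @param max_step tracking gate in um; default `NULL` uses three times
#'   the expected per-frame step of the fastest configured regime, or
#'   5 um for file inputs.
#' @param min_track_length minimum frames for a track to contribute a
#'   speed.
#' @param thresholds named um thresholds for the localization fractions.
#' @param localization run the 3D distance stage (skipped with a warning
#'   for movies with a single Z plane).
#' @return invisibly, a list with per-group results and the group
#'   statistics; files are written to `out_dir`.
#' @export
run_experiment <- function(groups, out_dir,
                           median_kernel = 3L, diameter = 10,
                           max_step = NULL, min_track_length = 5L,
                           thresholds = c(bone = 15, vessel = 5),
                           localization = TRUE) {
  .assert(length(names(groups)) == length(groups) && all(nzchar(names(groups))),
          "groups must be a named list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  disp_rows <- list(); speed_rows <- list(); track_rows <- list()
  dist_rows <- list(); per_group <- list()
  for (g in names(groups)) {
    spec <- groups[[g]]
    if (inherits(spec, "simulation_config")) {
      truth <- simulate_tracks(spec)
      movie <- render_movie(truth, spec, "mip")
      gate <- max_step %||%
        (3 * max(spec$target_speed[unique(spec$regime)]) * spec$frame_interval)
      vol <- if (localization) render_movie(truth, spec, "3d", frames = 1L) else NULL
    } else {
      movie <- read_movie(spec)
      gate <- max_step %||% 5
      vol <- if (localization && dim(movie$data)[3] > 1) movie else NULL
      if (localization && is.null(vol))
        warning("group ", g, ": distance analysis requires Z > 1; stage skipped")
    }
    message(sprintf("[%s] movie: %d frames", g, dim(movie$data)[1]))

    disp <- displacement_analysis(movie, kernel = median_kernel)
    disp_rows[[g]] <- cbind(group = g, disp$pairs)

    spots <- detect_movie_spots(movie, diameter = diameter)
    tracks <- link_tracks(spots, max_step = gate)
    speeds <- track_speeds(tracks, movie$frame_interval, min_track_length)
    message(sprintf("[%s] %d detections, %d tracks kept, %d excluded (< %d frames)",
                    g, sum(vapply(spots$frames, nrow, integer(1))),
                    nrow(speeds), attr(speeds, "n_excluded"), min_track_length))
    track_rows[[g]] <- cbind(group = g, tracks)
    speed_rows[[g]] <- cbind(group = g, speeds)

    dist_smp <- NULL
    if (!is.null(vol)) {
      dist_smp <- tryCatch(
        .localize_cells(vol, diameter, g),
        error = function(e) {
          warning("group ", g, ": distance stage skipped: ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(dist_smp)) dist_rows[[g]] <- dist_smp
    }
    per_group[[g]] <- list(displacement = disp, speeds = speeds,
                           distances = dist_smp)
  }

  disp_df <- do.call(rbind, disp_rows)
  speed_df <- do.call(rbind, speed_rows)
  track_df <- do.call(rbind, track_rows)
  utils::write.csv(disp_df, file.path(out_dir, "displacement.csv"), row.names = FALSE)
  utils::write.csv(track_df, file.path(out_dir, "tracks.csv"), row.names = FALSE)
  utils::write.csv(speed_df, file.path(out_dir, "speeds.csv"), row.names = FALSE)
  if (length(dist_rows)) {
    dist_df <- do.call(rbind, dist_rows)
    utils::write.csv(dist_df, file.path(out_dir, "distances.csv"), row.names = FALSE)
  }

  stats_out <- .group_statistics(disp_df, speed_df,
                                 if (length(dist_rows)) do.call(rbind, dist_rows),
                                 thresholds)
  jsonlite::write_json(stats_out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  csvs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ivmotion")),
    parameters = list(median_kernel = median_kernel, diameter_um = diameter,
                      max_step_um = max_step, min_track_length = min_track_length,
                      thresholds_um = as.list(thresholds),
                      localization = localization),
    groups = lapply(groups, function(s)
      if (inherits(s, "simulation_config")) unclass(s) else s),
    checksums = as.list(tools::md5sum(csvs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(per_group = per_group, statistics = stats_out,
                 out_dir = out_dir))
}

# 3D localization stage on a single-time-point volume
.localize_cells <- function(vol_movie, diameter, group) {
  d <- dim(vol_movie$data)
  .assert(d[3] > 1, "distance analysis requires Z > 1")
  red <- array(get_channel(vol_movie, "red")[1, , , ], dim = d[3:5])
  blue <- array(get_channel(vol_movie, "blue")[1, , , ], dim = d[3:5])
  green <- array(get_channel(vol_movie, "green")[1, , , ], dim = d[3:5])
  fields <- list()
  fields$bone <- distance_field(segment_structure(blue), vol_movie$voxel_size)
  fields$vessel <- distance_field(segment_structure(red), vol_movie$voxel_size)
  spots <- detect_spots(green, vol_movie$voxel_size, diameter = diameter)
  .assert(nrow(spots) > 0, "no cells detected in the volume")
  sample_spot_distances(spots, fields, vol_movie$voxel_size, group = group)
}

.group_statistics <- function(disp_df, speed_df, dist_df, thresholds) {
  out <- list()
  out$displacement_summary <- group_summary(disp_df$displacement_ratio, disp_df$group)
  out$speed_summary <- group_summary(speed_df$mean_speed_um_min, speed_df$group)
  disp_groups <- split(disp_df$displacement_ratio, disp_df$group)
  speed_groups <- split(speed_df$mean_speed_um_min, speed_df$group)
  strip <- function(tr) unclass(tr)
  if (length(disp_groups) >= 3) {
    out$displacement_test <- strip(anova_oneway(disp_groups))
    out$speed_test <- strip(anova_oneway(speed_groups))
  } else if (length(disp_groups) == 2) {
    out$displacement_test <- strip(ks_two_sample(disp_groups[[1]], disp_groups[[2]]))
    out$speed_test <- strip(ks_two_sample(speed_groups[[1]], speed_groups[[2]]))
  }
  if (!is.null(dist_df)) {
    ds <- summarize_distances(dist_df, thresholds)
    out$distances <- lapply(ds, function(e) {
      e$groups <- lapply(e$groups, function(s) s[c("n", "mean_um", "frac_within",
                                                   "threshold_um")])
      if (!is.null(e$ks)) e$ks <- strip(e$ks)
      e
    })
  }
  out
}
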