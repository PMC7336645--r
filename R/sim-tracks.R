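#' Place cells so that requested niche-proximity fractions hold exactly
#'
#' Draws initial positions such that the realized number of cells within
#' each configured distance threshold of the bone and/or vessel surface
#' equals `round(n * fraction)`. When both a bone and a vessel fraction are
#' requested the joint counts are resolved with the minimal overlap that
#' satisfies both marginals, and positions are rejection-sampled inside the
#' corresponding regions.
#'
#' @param config a [simulation_config()].
#' @return `n_cells` x 3 matrix of positions in um (columns x, y, z).
#' @examples
#' cfg <- simulation_config(n_cells = 10, seed = 2)
#' pos <- place_cells(cfg)
#' sum(bone_distance(pos, cfg$bone) <= 15)   # round(10 * 0.5)
#' @export
place_cells <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_cells
  pf <- config$placement_fractions
  margin <- config$cell_diameter / 2
  fs <- config$field_size
  z_floor <- if (!is.null(config$bone)) config$bone$z_top else margin

  want_bone <- !is.null(pf$bone)
  want_vessel <- !is.null(pf$vessel)
  if (want_bone && is.null(config$bone))
    stop("a bone placement fraction was requested but no bone is configured",
         call. = FALSE)
  if (want_vessel && length(config$vessels) == 0)
    stop("a vessel placement fraction was requested but no vessels are configured",
         call. = FALSE)

  in_bone <- function(p) bone_distance(p, config$bone) <= pf$bone$threshold
  in_vessel <- function(p) vessel_distance(p, config$vessels) <= pf$vessel$threshold

  # joint category counts: (bone?, vessel?) with minimal forced overlap
  kb <- if (want_bone) round(n * pf$bone$fraction) else NA_integer_
  kv <- if (want_vessel) round(n * pf$vessel$fraction) else NA_integer_
  if (want_bone && want_vessel) {
    n11 <- max(0L, kb + kv - n)
    counts <- c(n11 = n11, n10 = kb - n11, n01 = kv - n11,
                n00 = n - kb - kv + n11)
    preds <- list(
      n11 = function(p) in_bone(p) & in_vessel(p),
      n10 = function(p) in_bone(p) & !in_vessel(p),
      n01 = function(p) !in_bone(p) & in_vessel(p),
      n00 = function(p) !in_bone(p) & !in_vessel(p))
  } else if (want_bone) {
    counts <- c(yes = kb, no = n - kb)
    preds <- list(yes = in_bone, no = function(p) !in_bone(p))
  } else if (want_vessel) {
    counts <- c(yes = kv, no = n - kv)
    preds <- list(yes = in_vessel, no = function(p) !in_vessel(p))
  } else {
    counts <- c(any = n)
    preds <- list(any = function(p) rep(TRUE, nrow(p)))
  }

  set.seed(.sub_seed(config$seed, 1L))
  draw <- function(m) {
    cbind(stats::runif(m, margin, fs["x"] - margin),
          stats::runif(m, margin, fs["y"] - margin),
          stats::runif(m, z_floor, fs["z"] - margin))
  }
  # cells are solid bodies: enforce a hard-core exclusion of one diameter.
  # The exclusion acts in the imaging (xy) plane, matching the planar
  # motion model and guaranteeing cells remain resolvable in projections.
  min_sep <- config$cell_diameter
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  placed <- 0L
  row <- 1L
  for (cat in names(counts)) {
    need <- counts[[cat]]
    got <- 0L
    tries <- 0L
    while (got < need) {
      tries <- tries + 1L
      if (tries > 200000L)
        stop("unable to satisfy placement constraints (region may be empty ",
             "or too crowded): ", cat, call. = FALSE)
      batch <- draw(max(64L, 4L * (need - got)))
      keep <- which(preds[[cat]](batch))
      for (b in keep) {
        if (got >= need) break
        p <- batch[b, ]
        if (placed > 0L) {
          prev <- out[seq_len(placed), 1:2, drop = FALSE]
          if (min(.row_norms(sweep(prev, 2, p[1:2]))) < min_sep) next
        }
        out[row + got, ] <- p
        got <- got + 1L
        placed <- placed + 1L
      }
    }
    row <- row + need
  }
  out
}

#' Simulate ground-truth cell tracks
#'
#' Each cell performs a persistent random walk in the imaging (xy) plane:
#' the heading is rotated each frame by Gaussian angular noise whose spread
#' shrinks with `persistence`, and step lengths are gamma-distributed with
#' mean `target_speed * frame_interval`. Walks are reflected at the field
#' boundary. The z coordinate is fixed at the initial placement, emulating
#' cells crawling along vessels that run parallel to the imaging plane; a
#' consequence is that speeds measured on maximum-intensity projections
#' agree with the 3D ground truth.
#'
#' @param config a [simulation_config()].
#' @return an object of class `ground_truth`: a list with `tracks` (data
#'   frame: `track_id, frame, x_um, y_um, z_um, regime`), `regime` (per
#'   cell), `mean_speed` (true path length / elapsed time per cell,
#'   um/min), `d_bone0` and `d_vessel0` (analytic distances at frame 1),
#'   and the generating `config`.
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_cells
  tf <- config$n_frames
  dt <- config$frame_interval
  fs <- config$field_size
  margin <- config$cell_diameter / 2
  lo <- c(margin, margin)
  hi <- c(fs["x"] - margin, fs["y"] - margin)
  sigma_theta <- (1 - config$persistence) * pi

  start <- place_cells(config)
  # pre-draw each cell's step lengths and heading noise from its own
  # deterministic sub-stream, then integrate all cells frame by frame so
  # that excluded-volume interactions can be resolved jointly
  steps <- matrix(0, tf - 1L, n)
  dtheta <- matrix(0, tf - 1L, n)
  theta <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(.sub_seed(config$seed, 1000L + i))
    speed <- config$target_speed[[config$regime[i]]]
    mean_step <- speed * dt
    theta[i] <- stats::runif(1, 0, 2 * pi)
    if (mean_step > 0)
      steps[, i] <- stats::rgamma(tf - 1L, shape = 4, scale = mean_step / 4)
    dtheta[, i] <- stats::rnorm(tf - 1L, 0, sigma_theta)
  }

  min_sep <- config$cell_diameter  # cells are solid: centres stay a diameter apart
  # deterministic deflection angles tried when a step would collide
  deflect <- c(0, pi / 6, -pi / 6, pi / 3, -pi / 3, pi / 2, -pi / 2,
               2 * pi / 3, -2 * pi / 3, 5 * pi / 6, -5 * pi / 6, pi)
  pos <- array(NA_real_, c(tf, n, 3))
  pos[1, , ] <- start
  step_sum <- numeric(n)
  cur <- start[, 1:2, drop = FALSE]
  for (t in seq_len(tf - 1L)) {
    for (i in seq_len(n)) {
      theta[i] <- theta[i] + dtheta[t, i]
      len <- steps[t, i]
      placed <- FALSE
      for (dphi in deflect) {
        th <- theta[i] + dphi
        p <- cur[i, ] + len * c(cos(th), sin(th))
        # reflect at field boundaries; path length is preserved
        for (ax in 1:2) {
          if (p[ax] < lo[ax]) { p[ax] <- 2 * lo[ax] - p[ax]; th <- if (ax == 1) pi - th else -th }
          if (p[ax] > hi[ax]) { p[ax] <- 2 * hi[ax] - p[ax]; th <- if (ax == 1) pi - th else -th }
          p[ax] <- min(max(p[ax], lo[ax]), hi[ax])
        }
        others <- cur[-i, , drop = FALSE]
        if (n == 1L || len == 0 ||
            min(.row_norms(sweep(others, 2, p))) >= min_sep) {
          cur[i, ] <- p
          theta[i] <- th
          step_sum[i] <- step_sum[i] + len
          placed <- TRUE
          break
        }
      }
      # fully blocked: the cell pauses this frame (no path length accrued)
      if (!placed) next
    }
    pos[t + 1L, , 1:2] <- cur
    pos[t + 1L, , 3] <- start[, 3]
  }

  tracks <- data.frame(
    track_id = rep(seq_len(n), each = tf),
    frame = rep(seq_len(tf), times = n),
    x_um = as.vector(pos[, , 1]), y_um = as.vector(pos[, , 2]),
    z_um = as.vector(pos[, , 3]),
    regime = rep(config$regime, each = tf))
  structure(list(
    tracks = tracks,
    regime = config$regime,
    mean_speed = step_sum / ((tf - 1) * dt),
    d_bone0 = bone_distance(start, config$bone),
    d_vessel0 = vessel_distance(start, config$vessels),
    config = config
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$regime), "tracks,",
      x$config$n_frames, "frames\n")
  sp <- tapply(x$mean_speed, x$regime, mean)
  cat("  true mean speed (um/min):",
      paste(sprintf("%s %.3f", names(sp), sp), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a two-group survival table
#'
#' Event times are exponential with the given per-group hazards and are
#' right-censored at the end of follow-up, emulating a treatment-versus-
#' control survival experiment.
#'
#' @param hazards named numeric vector of hazards (1/day) per group.
#' @param n_per_group integer, subjects per group (recycled).
#' @param follow_up follow-up horizon in days (> 0).
#' @param seed integer seed.
#' @return data frame with columns `time` (days), `event` (1 died,
#'   0 censored) and `group`.
#' @export
simulate_survival <- function(hazards, n_per_group, follow_up, seed = 1L) {
  .assert(all(hazards > 0), "hazards must be positive")
  .assert(follow_up > 0, "follow_up must be positive (time > 0 required)")
  n_per_group <- rep_len(as.integer(n_per_group), length(hazards))
  set.seed(as.integer(seed))
  out <- lapply(seq_along(hazards), function(g) {
    t_true <- stats::rexp(n_per_group[g], rate = hazards[[g]])
    data.frame(time = pmin(t_true, follow_up),
               event = as.integer(t_true <= follow_up),
               group = names(hazards)[g])
  })
  do.call(rbind, out)
}
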