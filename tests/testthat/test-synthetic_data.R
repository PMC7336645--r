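test_that("zero target speed gives constant tracks with zero true speed", {
  cfg <- tiny_config(n_cells = 3, target_speed = c(motile = 0, arrested = 0))
  truth <- simulate_tracks(cfg)
  expect_equal(truth$mean_speed, rep(0, 3))
  for (id in 1:3) {
    tr <- truth$tracks[truth$tracks$track_id == id, ]
    expect_equal(diff(range(tr$x_um)), 0)
    expect_equal(diff(range(tr$y_um)), 0)
  }
})

test_that("true track speeds calibrate to the regime target", {
  cfg <- simulation_config(n_cells = 100, regime = "motile", n_frames = 61,
                           frame_interval = 1, seed = 7)
  truth <- simulate_tracks(cfg)
  expect_equal(mean(truth$mean_speed), 1.5, tolerance = 0.1)
  cfg2 <- simulation_config(n_cells = 100, regime = "arrested", n_frames = 61,
                            frame_interval = 1, seed = 7)
  truth2 <- simulate_tracks(cfg2)
  expect_equal(mean(truth2$mean_speed), 0.5, tolerance = 0.1)
  # regime separation: the two true-speed distributions sit on either side
  expect_gt(min(truth$mean_speed), max(truth2$mean_speed))
})

test_that("identical config and seed reproduce ground truth and movie bitwise", {
  cfg <- tiny_config(seed = 42)
  t1 <- simulate_tracks(cfg); t2 <- simulate_tracks(cfg)
  expect_identical(t1, t2)
  m1 <- render_movie(t1, cfg); m2 <- render_movie(t2, cfg)
  expect_identical(m1$data, m2$data)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(n_frames = 1), "n_frames")
  expect_error(simulation_config(frame_interval = 0), "frame_interval")
  expect_error(simulation_config(persistence = 1.5), "persistence")
  expect_error(simulation_config(voxel_size = c(1, -1, 1)), "voxel_size")
})

test_that("excluded-volume walk keeps cell centres at least a diameter apart", {
  cfg <- tiny_config(n_cells = 12, n_frames = 12, seed = 3)
  truth <- simulate_tracks(cfg)
  for (t in unique(truth$tracks$frame)) {
    p <- truth$tracks[truth$tracks$frame == t, c("x_um", "y_um")]
    D <- as.matrix(dist(p))   # exclusion acts in the imaging plane
    diag(D) <- Inf
    expect_gte(min(D), cfg$cell_diameter - 1e-9)
  }
})

test_that("placement realizes requested niche fractions exactly", {
  cfg <- simulation_config(n_cells = 10, seed = 2,
    placement_fractions = list(vessel = list(threshold = 5, fraction = 0.6)))
  pos <- place_cells(cfg)
  expect_identical(sum(vessel_distance(pos, cfg$vessels) <= 5), 6L)

  cfg_all <- simulation_config(n_cells = 7, seed = 4,
    placement_fractions = list(bone = list(threshold = 15, fraction = 1.0)))
  pos_all <- place_cells(cfg_all)
  expect_true(all(bone_distance(pos_all, cfg_all$bone) <= 15))

  # joint bone/vessel request: both marginals hold
  cfg_j <- simulation_config(n_cells = 20, seed = 5)
  pos_j <- place_cells(cfg_j)
  expect_identical(sum(bone_distance(pos_j, cfg_j$bone) <= 15), 10L)
  expect_identical(sum(vessel_distance(pos_j, cfg_j$vessels) <= 5), 12L)
})

test_that("unsatisfiable placement constraints raise errors", {
  expect_error(
    simulation_config(n_cells = 5, vessels = list(),
                      placement_fractions = list(
                        vessel = list(threshold = 5, fraction = 0.5))) |>
      place_cells(),
    "no vessels")
  expect_error(
    simulation_config(placement_fractions = list(
      bone = list(threshold = 1000, fraction = 0.5))),
    "exceeds the field")
})

test_that("noise-free stationary cell renders identically in all frames", {
  cfg <- tiny_config(n_cells = 1, n_frames = 4, noise_free = TRUE,
                     protrusion = 0,
                     target_speed = c(motile = 0, arrested = 0),
                     placement_fractions = list())
  truth <- simulate_tracks(cfg)
  m <- render_movie(truth, cfg)
  for (t in 2:4) expect_identical(m$data[t, 1, , , ], m$data[1, 1, , , ])
})

test_that("rendered kernel centroid matches the true centroid", {
  cfg <- tiny_config(n_cells = 1, n_frames = 2, noise_free = TRUE,
                     protrusion = 0, placement_fractions = list())
  truth <- one_cell_truth(cfg, x = 61.3, y = 57.8)
  m <- render_movie(truth, cfg)
  g <- m$data[1, 1, 1, , ]
  ys <- (seq_len(nrow(g)) - 0.5) * cfg$voxel_size[["y"]]
  xs <- (seq_len(ncol(g)) - 0.5) * cfg$voxel_size[["x"]]
  cy <- sum(rowSums(g) * ys) / sum(g)
  cx <- sum(colSums(g) * xs) / sum(g)
  expect_lt(abs(cx - 61.3), 0.5 * cfg$voxel_size[["x"]])
  expect_lt(abs(cy - 57.8), 0.5 * cfg$voxel_size[["y"]])
})

test_that("simulated survival respects censoring and hazard ordering", {
  expect_error(simulate_survival(c(a = 0.1, b = 0.1), 5, follow_up = 0),
               "follow_up")
  sv <- simulate_survival(c(ctrl = 0.05, rx = 0.05), 25, follow_up = 40, seed = 1)
  expect_true(all(sv$time > 0 & sv$time <= 40))
  expect_true(all(sv$event %in% 0:1))
  # hazard ratio 3: the faster-dying arm has the lower median in >= 95% of reps
  wins <- 0L
  for (r in 1:200) {
    s <- simulate_survival(c(fast = 0.15, slow = 0.05), 20, follow_up = 100,
                           seed = r)
    med <- tapply(s$time, s$group, stats::median)
    wins <- wins + (med[["fast"]] < med[["slow"]])
  }
  expect_gte(wins / 200, 0.95)
})
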