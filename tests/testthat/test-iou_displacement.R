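test_that("pooled Otsu separates a perfectly bimodal stack", {
  frames <- array(c(rep(10, 50), rep(200, 50)), dim = c(2, 5, 10))
  thr <- pooled_otsu_threshold(frames)
  expect_gt(thr, 10); expect_lt(thr, 200)
  masks <- binarize_and_denoise(frames, thr, kernel = 1L)
  expect_identical(masks$masks, array(frames == 200, dim = dim(frames)))
})

test_that("pooled Otsu equals the exhaustive intra-class-variance scan", {
  for (seed in 1:5) {
    set.seed(seed)
    frames <- array(sample(0:255, 3 * 16 * 16, replace = TRUE,
                           prob = c(rep(4, 64), rep(1, 128), rep(4, 64))),
                    dim = c(3, 16, 16))
    expect_equal(pooled_otsu_threshold(frames),
                 otsu_bruteforce(as.vector(frames)), tolerance = 1e-12)
  }
})

test_that("constant stacks are rejected as degenerate", {
  expect_error(pooled_otsu_threshold(array(7, dim = c(2, 4, 4))), "degenerate")
})

test_that("median denoising matches the per-pixel clipped-window oracle", {
  # isolated pixel removed
  fr <- array(0, dim = c(1, 7, 7)); fr[1, 4, 4] <- 10
  fr <- array(rep(fr, 2), dim = c(2, 7, 7))
  m <- binarize_and_denoise(fr, threshold = 5, kernel = 3L)
  expect_false(any(m$masks))
  # solid square: interior preserved, corners eroded, matching brute force
  fr2 <- array(0, dim = c(2, 14, 14))
  fr2[, 3:12, 3:12] <- 10
  m2 <- binarize_and_denoise(fr2, threshold = 5, kernel = 3L)
  oracle <- median_filter_bruteforce(fr2[1, , ] > 5, 3)
  expect_identical(m2$masks[1, , ], oracle)
  expect_true(all(m2$masks[1, 4:11, 4:11]))
  # seeded random masks, kernels 3 and 5
  for (seed in 1:5) for (k in c(3L, 5L)) {
    set.seed(seed * 10 + k)
    fr3 <- array(stats::runif(2 * 12 * 12) * 10, dim = c(2, 12, 12))
    m3 <- binarize_and_denoise(fr3, threshold = 5, kernel = k)
    expect_identical(m3$masks[2, , ],
                     median_filter_bruteforce(fr3[2, , ] > 5, k))
  }
})

test_that("kernel 1 is the identity and even kernels are rejected", {
  set.seed(9)
  fr <- array(stats::runif(2 * 8 * 8) * 10, dim = c(2, 8, 8))
  m <- binarize_and_denoise(fr, threshold = 5, kernel = 1L)
  expect_identical(m$masks, array(fr > 5, dim = dim(fr)))
  expect_error(binarize_and_denoise(fr, threshold = 5, kernel = 4L), "odd")
})

test_that("iou_pair handles identity, disjoint, shifted and empty masks", {
  a <- matrix(FALSE, 6, 6); a[2:3, 2:3] <- TRUE
  expect_identical(iou_pair(a, a), 1)
  b <- matrix(FALSE, 6, 6); b[5:6, 5:6] <- TRUE
  expect_identical(iou_pair(a, b), 0)
  shifted <- matrix(FALSE, 6, 6); shifted[2:3, 3:4] <- TRUE
  expect_equal(iou_pair(a, shifted), 1 / 3)   # 2 px intersection, 6 px union
  empty <- matrix(FALSE, 6, 6)
  expect_warning(expect_identical(iou_pair(empty, empty), 1), "both masks empty")
  expect_warning(expect_identical(iou_pair(a, empty), 0), "one mask empty")
  expect_error(iou_pair(a, matrix(FALSE, 5, 6)), "shapes differ")
})

test_that("iou_pair equals brute-force pixel counting and is symmetric", {
  for (seed in 1:10) {
    set.seed(seed)
    a <- matrix(stats::runif(32 * 32) > 0.6, 32, 32)
    b <- matrix(stats::runif(32 * 32) > 0.6, 32, 32)
    expect_identical(iou_pair(a, b), iou_bruteforce(a, b))
    expect_identical(iou_pair(a, b), iou_pair(b, a))
  }
})

test_that("displacement series covers static and fully-moving movies", {
  m <- array(FALSE, dim = c(4, 5, 5)); m[, 2:3, 2:3] <- TRUE
  res <- displacement_series(structure(list(masks = m, threshold_used = 0,
                                            kernel_used = 1L),
                                       class = "binary_mask_sequence"))
  expect_equal(res$pairs$displacement_ratio, rep(0, 3))
  alt <- array(FALSE, dim = c(4, 5, 5))
  alt[c(1, 3), 1:2, 1:2] <- TRUE; alt[c(2, 4), 4:5, 4:5] <- TRUE
  res2 <- displacement_series(structure(list(masks = alt, threshold_used = 0,
                                             kernel_used = 1L),
                                        class = "binary_mask_sequence"))
  expect_equal(res2$pairs$displacement_ratio, rep(1, 3))
  expect_true(all(res2$pairs$iou + res2$pairs$displacement_ratio == 1))
})

test_that("IoU of a rendered cell never increases with translation", {
  cfg <- tiny_config(n_cells = 1, n_frames = 2, noise_free = TRUE,
                     protrusion = 0, placement_fractions = list())
  base <- one_cell_truth(cfg, x = 40, y = 60)
  m0 <- render_movie(base, cfg)
  ref <- m0$data[1, 1, 1, , ] > 100
  ious <- vapply(seq(0, 10, by = 2), function(dx) {
    tr <- one_cell_truth(cfg, x = 40 + dx, y = 60)
    m <- render_movie(tr, cfg)
    iou_pair(ref, m$data[1, 1, 1, , ] > 100)
  }, numeric(1))
  expect_true(all(diff(ious) <= 1e-12))
  expect_identical(ious[1], 1)
})

test_that("arrested movies show lower displacement ratios than motile ones", {
  cfg_m <- tiny_config(n_cells = 8, regime = "motile", n_frames = 10, seed = 21)
  cfg_a <- tiny_config(n_cells = 8, regime = "arrested", n_frames = 10, seed = 22)
  r_m <- displacement_analysis(render_movie(simulate_tracks(cfg_m), cfg_m))
  r_a <- displacement_analysis(render_movie(simulate_tracks(cfg_a), cfg_a))
  expect_lt(r_a$mean_ratio, r_m$mean_ratio)
  expect_true(all(r_m$pairs$iou >= 0 & r_m$pairs$iou <= 1))
})
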