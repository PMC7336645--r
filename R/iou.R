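#' Calibrated maximum-intensity-projection sequence
#'
#' Thin container for the green-channel MIP frames on which the
#' displacement-area statistic is computed.
#'
#' @param frames numeric `T x Y x X` array of non-negative intensities.
#' @param pixel_size pixel pitch in um.
#' @param frame_interval frame spacing in minutes.
#' @return object of class `mip_sequence`.
#' @export
mip_sequence <- function(frames, pixel_size = 1, frame_interval = 1) {
  .assert(length(dim(frames)) == 3, "frames must be a T x Y x X array")
  .assert(dim(frames)[1] >= 2, "at least two frames are required")
  .assert(all(frames >= 0), "intensities must be non-negative")
  .assert(pixel_size > 0 && frame_interval > 0, "calibration must be positive")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval), class = "mip_sequence")
}

#' Extract the green-channel MIP sequence from a movie
#'
#' @param movie a [timelapse_movie()].
#' @return a [mip_sequence()].
#' @export
as_mip_sequence <- function(movie) {
  stopifnot(inherits(movie, "timelapse_movie"))
  movie <- movie_mip(movie)
  g <- get_channel(movie, "green")          # T x 1 x Y x X
  d <- dim(g)
  mip_sequence(array(g, dim = d[c(1, 3, 4)]),
               pixel_size = movie$voxel_size[["x"]],
               frame_interval = movie$frame_interval)
}

.pooled_values <- function(seq) {
  if (inherits(seq, "mip_sequence")) as.vector(seq$frames) else as.vector(seq)
}

#' Pooled Otsu threshold over all frames of a movie
#'
#' All frames are pooled into one intensity histogram and the Otsu
#' threshold — the cut minimizing the weighted intra-class intensity
#' variance (equivalently maximizing the between-class variance) — is
#' computed on it, giving a single global threshold per movie so that
#' frame-to-frame mask changes reflect cell displacement rather than
#' thresholding drift. Foreground is strictly greater than the threshold.
#'
#' Intensities are binned at integer resolution for integer-valued data
#' (the native case for camera counts) and into 256 equal-width bins
#' otherwise; the returned threshold is a bin boundary on the intensity
#' scale.
#'
#' @param seq a [mip_sequence()], a [timelapse_movie()] (green channel
#'   used), or a numeric array.
#' @return the scalar threshold.
#' @export
pooled_otsu_threshold <- function(seq) {
  if (inherits(seq, "timelapse_movie")) seq <- as_mip_sequence(seq)
  v <- .pooled_values(seq)
  .assert(length(unique(v)) >= 2,
          "degenerate histogram: pooled intensities are constant")
  integerish <- all(v == round(v)) && diff(range(v)) <= 65535
  if (integerish) {
    levels <- as.numeric(seq(min(v), max(v)))
    counts <- tabulate(v - min(v) + 1L, nbins = length(levels))
  } else {
    h <- graphics::hist(v, breaks = seq(min(v), max(v), length.out = 257),
                        plot = FALSE)
    levels <- h$mids
    counts <- h$counts
  }
  p <- counts / sum(counts)
  omega <- cumsum(p)                       # class-0 weight for cut after level k
  mu <- cumsum(p * levels)
  mu_total <- mu[length(mu)]
  # between-class variance for every candidate cut (foreground > levels[k])
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, length(levels))
  sigma_b[valid] <- (mu_total * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  # on a tied plateau (perfectly separated classes) take its midpoint
  best <- which(sigma_b >= max(sigma_b) - 1e-12 * abs(max(sigma_b)))
  mean(levels[range(best)])
}

#' Binarize frames at a threshold and denoise with a median filter
#'
#' Each frame is thresholded (`intensity > threshold`) and the binary mask
#' is cleaned with a square median filter: a pixel is foreground when
#' foreground pixels form a strict majority of the `kernel x kernel`
#' window, clipped at the image border. `kernel = 1` is the identity.
#'
#' @param seq a [mip_sequence()], movie, or `T x Y x X` array.
#' @param threshold intensity threshold (typically from
#'   [pooled_otsu_threshold()]).
#' @param kernel odd window width in pixels (default 3).
#' @return object of class `binary_mask_sequence`: list with `masks`
#'   (logical `T x Y x X`), `threshold_used`, `kernel_used`.
#' @export
binarize_and_denoise <- function(seq, threshold = pooled_otsu_threshold(seq),
                                 kernel = 3L) {
  if (inherits(seq, "timelapse_movie")) seq <- as_mip_sequence(seq)
  frames <- if (inherits(seq, "mip_sequence")) seq$frames else seq
  .assert(length(dim(frames)) == 3, "expected a T x Y x X array")
  .assert(kernel >= 1 && kernel %% 2 == 1, "kernel must be odd and >= 1")
  tN <- dim(frames)[1]
  masks <- array(FALSE, dim = dim(frames))
  for (t in seq_len(tN)) {
    m <- matrix(frames[t, , ] > threshold, dim(frames)[2], dim(frames)[3])
    masks[t, , ] <- if (kernel == 1L) m else .median_filter_binary(m, kernel)
  }
  structure(list(masks = masks, threshold_used = threshold,
                 kernel_used = as.integer(kernel)),
            class = "binary_mask_sequence")
}

# Majority vote over the border-clipped k x k window, via integral images.
.median_filter_binary <- function(mask, k) {
  r <- (k - 1L) %/% 2L
  ny <- nrow(mask); nx <- ncol(mask)
  # summed-area table with a zero border
  sat <- matrix(as.numeric(mask), ny, nx)
  if (ny > 1L) sat <- apply(sat, 2, cumsum)
  sat <- matrix(sat, ny, nx)
  if (nx > 1L) sat <- t(apply(sat, 1, cumsum))
  sat <- matrix(sat, ny, nx)
  S <- matrix(0, ny + 1L, nx + 1L)
  S[-1L, -1L] <- sat
  y0 <- pmax(seq_len(ny) - r, 1L); y1 <- pmin(seq_len(ny) + r, ny)
  x0 <- pmax(seq_len(nx) - r, 1L); x1 <- pmin(seq_len(nx) + r, nx)
  cnt <- S[y1 + 1L, x1 + 1L] - S[y0, x1 + 1L] - S[y1 + 1L, x0] + S[y0, x0]
  nwin <- outer(y1 - y0 + 1L, x1 - x0 + 1L)
  cnt * 2 > nwin
}

#' Intersection over union of two binary masks
#'
#' `|A and B| / |A or B|`. Two empty masks have IoU 1 by convention (no
#' cells implies no displacement); exactly one empty mask gives 0. Both
#' degenerate cases raise a warning.
#'
#' @param a,b logical matrices/arrays of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
iou_pair <- function(a, b) {
  .assert(identical(dim(a), dim(b)), "mask shapes differ")
  inter <- sum(a & b)
  union <- sum(a | b)
  if (union == 0) {
    warning("both masks empty: IoU defined as 1")
    return(1)
  }
  if (sum(a) == 0 || sum(b) == 0) {
    warning("one mask empty: IoU defined as 0")
    return(0)
  }
  inter / union
}

#' Displacement-area ratio series of a mask sequence
#'
#' For each successive frame pair the IoU of the foreground masks is
#' computed; the displacement-area ratio is `1 - IoU`. Low ratios indicate
#' migration arrest (the masks barely move between frames); high ratios
#' indicate active shape change and translocation.
#'
#' @param masks a `binary_mask_sequence` from [binarize_and_denoise()].
#' @return object of class `displacement_result`: list with `pairs` (data
#'   frame `frame_pair, iou, displacement_ratio`) and `mean_ratio`, the
#'   per-movie summary.
#' @export
displacement_series <- function(masks) {
  stopifnot(inherits(masks, "binary_mask_sequence"))
  m <- masks$masks
  tN <- dim(m)[1]
  .assert(tN >= 2, "need at least two frames")
  iou <- vapply(seq_len(tN - 1), function(t) {
    iou_pair(m[t, , ], m[t + 1, , ])
  }, numeric(1))
  pairs <- data.frame(frame_pair = seq_len(tN - 1), iou = iou,
                      displacement_ratio = 1 - iou)
  structure(list(pairs = pairs, mean_ratio = mean(pairs$displacement_ratio)),
            class = "displacement_result")
}

#' @export
print.displacement_result <- function(x, ...) {
  cat(sprintf("displacement_result: %d frame pairs, mean displacement ratio %.4f\n",
              nrow(x$pairs), x$mean_ratio))
  invisible(x)
}

#' Full displacement-area analysis of a movie
#'
#' Convenience wrapper: pooled Otsu threshold, binarization, median
#' denoising and the successive-frame IoU series.
#'
#' @param movie a [timelapse_movie()] or [mip_sequence()].
#' @param kernel median filter width (odd, default 3).
#' @return a `displacement_result` (with the mask sequence attached as
#'   attribute `masks`).
#' @export
displacement_analysis <- function(movie, kernel = 3L) {
  seq <- if (inherits(movie, "timelapse_movie")) as_mip_sequence(movie) else movie
  thr <- pooled_otsu_threshold(seq)
  masks <- binarize_and_denoise(seq, thr, kernel)
  res <- displacement_series(masks)
  attr(res, "masks") <- masks
  res
}
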