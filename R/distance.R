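#' Segment a structural channel into an occupancy mask
#'
#' Otsu-thresholds a single-channel volume (bone/SHG or vessel channel)
#' and returns the foreground occupancy. Optionally keeps only the largest
#' 6-connected component to drop speckle.
#'
#' @param volume numeric 3D array (`Z x Y x X`) or 2D matrix.
#' @param largest_component keep only the largest connected component
#'   (default `FALSE`).
#' @return logical array of the same shape.
#' @export
segment_structure <- function(volume, largest_component = FALSE) {
  .assert(length(unique(as.vector(volume))) >= 2,
          "constant channel: nothing to segment")
  thr <- pooled_otsu_threshold(as.vector(volume))
  mask <- array(volume > thr, dim = dim(volume))
  if (largest_component) mask <- .largest_component(mask)
  mask
}

# largest 6-connected (4-connected in 2D) component of a logical array
.largest_component <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  lab <- array(0L, dim = d)
  idx_all <- which(mask)
  if (!length(idx_all)) return(mask)
  strides <- cumprod(c(1L, d[-nd]))
  cur <- 0L
  best_lab <- 0L; best_size <- 0L
  arr_ind <- arrayInd(idx_all, d)
  pos_of <- integer(prod(d)); pos_of[idx_all] <- seq_along(idx_all)
  for (s in seq_along(idx_all)) {
    if (lab[idx_all[s]] != 0L) next
    cur <- cur + 1L
    queue <- idx_all[s]
    lab[queue] <- cur
    size <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      ai <- arrayInd(v, d)
      for (ax in seq_len(nd)) for (dlt in c(-1L, 1L)) {
        ni <- ai
        ni[ax] <- ni[ax] + dlt
        if (ni[ax] < 1L || ni[ax] > d[ax]) next
        lin <- 1L + sum((ni - 1L) * strides)
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- cur
          queue <- c(queue, lin)
        }
      }
    }
    if (size > best_size) { best_size <- size; best_lab <- cur }
  }
  array(lab == best_lab, dim = d)
}

#' Anisotropic exact Euclidean distance transform
#'
#' Per-voxel Euclidean distance in um to the nearest structure voxel,
#' honouring (possibly different) voxel pitches along each axis. Uses the
#' separable lower-envelope algorithm on squared distances, so the result
#' is exact on the voxel-centre grid.
#'
#' @param mask logical array (`Z x Y x X`, or a matrix) of structure
#'   occupancy; must contain at least one `TRUE` voxel.
#' @param voxel_size named numeric `c(x, y, z)` (or `c(x, y)` for 2D)
#'   pitch in um.
#' @return numeric array of distances; 0 on structure voxels.
#' @export
distance_field <- function(mask, voxel_size) {
  .assert(any(mask), "empty mask: distance field undefined")
  d <- dim(mask)
  nd <- length(d)
  # array axis order is (z,)y,x; map pitches accordingly
  pitches <- if (nd == 2L) c(voxel_size[["y"]], voxel_size[["x"]]) else
    c(voxel_size[["z"]], voxel_size[["y"]], voxel_size[["x"]])
  LARGE <- 1e30
  g <- array(ifelse(mask, 0, LARGE), dim = d)
  for (ax in seq_len(nd)) {
    g <- .dt_axis(g, ax, pitches[ax])
  }
  array(sqrt(g), dim = d)
}

# apply the 1D squared-distance transform along one axis of an array
.dt_axis <- function(g, axis, h) {
  d <- dim(g)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  gp <- aperm(g, perm)
  m <- matrix(gp, nrow = d[axis])
  for (j in seq_len(ncol(m))) m[, j] <- .dt1d(m[, j], h)
  gp <- array(m, dim = d[perm])
  aperm(gp, order(perm))
}

# Felzenszwalb-Huttenlocher 1D squared distance transform with spacing h
.dt1d <- function(f, h) {
  n <- length(f)
  if (n == 1L) return(f)
  x <- seq_len(n) * h
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2L:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * x[q] - 2 * x[p])
      if (s <= z[k]) {
        k <- k - 1L
      } else {
        k <- k + 1L
        v[k] <- q
        z[k] <- s
        z[k + 1L] <- Inf
        break
      }
    }
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    out[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  out
}

#' Sample distance fields at spot centroids
#'
#' Trilinearly interpolates each named distance field at every spot
#' position. Spots outside the calibrated volume are excluded with a
#' warning reporting the count.
#'
#' @param spots data frame of centroids (`x_um`, `y_um`, `z_um`; `z_um`
#'   may be absent for 2D fields).
#' @param fields named list of distance fields from [distance_field()]
#'   (e.g. `list(bone = ..., vessel = ...)`).
#' @param voxel_size named numeric `c(x, y, z)` pitch in um.
#' @param group optional group label attached to every row.
#' @return data frame `spot_id, group, d_<name>_um ...`.
#' @export
sample_spot_distances <- function(spots, fields, voxel_size, group = NA_character_) {
  .assert(length(fields) >= 1, "at least one distance field is required")
  d <- dim(fields[[1]])
  nd <- length(d)
  # fractional voxel-centre indices, array order (z,)y,x
  fx <- spots$x_um / voxel_size[["x"]] + 0.5
  fy <- spots$y_um / voxel_size[["y"]] + 0.5
  fz <- if (nd == 3L) spots$z_um / voxel_size[["z"]] + 0.5 else NULL
  nx <- d[nd]; ny <- d[nd - 1L]; nz <- if (nd == 3L) d[1L] else 1L
  inb <- fx >= 0.5 - 1e-9 & fx <= nx + 0.5 + 1e-9 &
    fy >= 0.5 - 1e-9 & fy <= ny + 0.5 + 1e-9
  if (nd == 3L) inb <- inb & fz >= 0.5 - 1e-9 & fz <= nz + 0.5 + 1e-9
  if (any(!inb))
    warning(sum(!inb), " spot(s) outside the calibrated volume excluded")
  out <- data.frame(spot_id = which(inb), group = group)
  for (nm in names(fields)) {
    out[[paste0("d_", nm, "_um")]] <- .interp_field(
      fields[[nm]], fx[inb], fy[inb], if (nd == 3L) fz[inb] else NULL)
  }
  out
}

# multilinear interpolation at fractional voxel-centre indices (clamped)
.interp_field <- function(field, fx, fy, fz = NULL) {
  d <- dim(field)
  nd <- length(d)
  clamp <- function(v, n) pmin(pmax(v, 1), n)
  interp_axis <- function(v, n) {
    v <- clamp(v, n)
    i0 <- pmin(floor(v), n - ifelse(n > 1, 1, 0))
    list(i0 = as.integer(pmax(i0, 1L)), w = v - pmax(i0, 1L))
  }
  if (nd == 2L) {
    ay <- interp_axis(fy, d[1]); ax <- interp_axis(fx, d[2])
    val <- 0
    for (dy in 0:1) for (dx in 0:1) {
      w <- (ifelse(dy == 1, ay$w, 1 - ay$w)) * (ifelse(dx == 1, ax$w, 1 - ax$w))
      iy <- pmin(ay$i0 + dy, d[1]); ix <- pmin(ax$i0 + dx, d[2])
      val <- val + w * field[cbind(iy, ix)]
    }
    return(val)
  }
  az <- interp_axis(fz, d[1]); ay <- interp_axis(fy, d[2]); ax <- interp_axis(fx, d[3])
  val <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (ifelse(dz == 1, az$w, 1 - az$w)) *
      (ifelse(dy == 1, ay$w, 1 - ay$w)) *
      (ifelse(dx == 1, ax$w, 1 - ax$w))
    iz <- pmin(az$i0 + dz, d[1]); iy <- pmin(ay$i0 + dy, d[2]); ix <- pmin(ax$i0 + dx, d[3])
    val <- val + w * field[cbind(iz, iy, ix)]
  }
  val
}

#' Summarize cell-to-niche distance samples
#'
#' Per group and structure: sample size, mean distance, fraction of cells
#' within the structure's threshold (bone default 15 um, vessel default
#' 5 um — the thresholds of the localization claims this statistic
#' addresses), and a fixed-width histogram. With exactly two groups a
#' two-sample Kolmogorov-Smirnov comparison is run per structure.
#'
#' @param samples data frame from [sample_spot_distances()] (columns
#'   `group` and one or more `d_<structure>_um`).
#' @param thresholds named numeric, um threshold per structure.
#' @param bin_width histogram bin width in um (default 5).
#' @return object of class `distance_summary`: nested list
#'   `structure -> group -> (n, mean_um, frac_within, hist)`, plus `ks`
#'   per structure when two groups are present.
#' @export
summarize_distances <- function(samples, thresholds = c(bone = 15, vessel = 5),
                                bin_width = 5) {
  .assert(nrow(samples) >= 1, "no distance samples")
  dcols <- grep("^d_.*_um$", names(samples), value = TRUE)
  .assert(length(dcols) >= 1, "no distance columns found")
  groups <- unique(samples$group)
  out <- list()
  for (col in dcols) {
    structure_name <- sub("^d_(.*)_um$", "\\1", col)
    thr <- thresholds[[structure_name]] %||% NA_real_
    per_group <- lapply(groups, function(g) {
      v <- samples[[col]][samples$group == g]
      v <- v[!is.na(v)]
      brks <- seq(0, max(c(v, bin_width)) + bin_width, by = bin_width)
      list(n = length(v), mean_um = mean(v),
           frac_within = if (is.na(thr)) NA_real_ else mean(v <= thr),
           threshold_um = thr,
           hist = graphics::hist(v, breaks = brks, plot = FALSE)$counts)
    })
    names(per_group) <- groups
    entry <- list(groups = per_group)
    if (length(groups) == 2) {
      a <- samples[[col]][samples$group == groups[1]]
      b <- samples[[col]][samples$group == groups[2]]
      entry$ks <- ks_two_sample(a[!is.na(a)], b[!is.na(b)])
    }
    out[[structure_name]] <- entry
  }
  structure(out, class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  for (nm in names(x)) {
    cat(nm, ":\n", sep = "")
    for (g in names(x[[nm]]$groups)) {
      s <- x[[nm]]$groups[[g]]
      cat(sprintf("  %s: n=%d mean=%.2f um, %.0f%% within %s um\n",
                  g, s$n, s$mean_um, 100 * s$frac_within,
                  format(s$threshold_um)))
    }
    if (!is.null(x[[nm]]$ks))
      cat(sprintf("  KS: D=%.3f p=%.4f\n", x[[nm]]$ks$statistic, x[[nm]]$ks$p_value))
  }
  invisible(x)
}
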