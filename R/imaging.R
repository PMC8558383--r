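#' THz reflection-image cube
#'
#' Raster-scanned reflection data: one reflected waveform per pixel.
#' Pixel indices are 1-based `(row, col)` with the origin at the
#' top-left; the physical coordinate of pixel `(i, j)` is
#' `((i - 1) * dx_mm, (j - 1) * dy_mm)`.
#'
#' @param cube numeric 3-D array, `nx x ny x n_time`.
#' @param time numeric vector of length `n_time` (ps).
#' @param dx_mm,dy_mm raster step (mm, > 0; default 0.2).
#' @return An object of class `thz_cube`.
#' @export
thz_cube <- function(cube, time, dx_mm = 0.2, dy_mm = 0.2) {
  if (!is.array(cube) || length(dim(cube)) != 3L) {
    stop_invalid("'cube' must be a 3-D array (nx x ny x n_time)")
  }
  if (length(time) != dim(cube)[3L]) {
    stop_invalid("'time' length must equal the cube's third dimension")
  }
  if (!is_scalar_num(dx_mm) || dx_mm <= 0 || !is_scalar_num(dy_mm) ||
      dy_mm <= 0) {
    stop_invalid("'dx_mm' and 'dy_mm' must be positive")
  }
  structure(list(cube = cube, time = as.double(time),
                 dx_mm = dx_mm, dy_mm = dy_mm),
            class = "thz_cube")
}

#' @export
print.thz_cube <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<thz_cube> %d x %d pixels (%.2g mm step), %d time samples\n",
              d[1], d[2], x$dx_mm, d[3]))
  invisible(x)
}

#' Per-pixel scalar map
#'
#' @param values numeric matrix, `nx x ny`.
#' @param statistic the statistic that produced the values.
#' @return An object of class `grayscale_map` with `values` and the
#'   observed `value_range`.
#' @export
grayscale_map_values <- function(values, statistic = "peak") {
  values <- as.matrix(values)
  structure(list(values = values, value_range = range(values),
                 statistic = statistic),
            class = "grayscale_map")
}

#' @export
print.grayscale_map <- function(x, ...) {
  cat(sprintf("<grayscale_map> %d x %d (%s), range %.4g-%.4g\n",
              nrow(x$values), ncol(x$values), x$statistic,
              x$value_range[1], x$value_range[2]))
  invisible(x)
}

#' Mean waveform of a circular region of interest
#'
#' Averages the waveforms of all pixels whose centers fall inside the
#' circle (the usual way to compare the ~100-pixel insect and tea
#' regions of a scan).
#'
#' @param cube a [thz_cube].
#' @param center `c(row, col)` in 1-based pixel units.
#' @param radius_px circle radius in pixels.
#' @return A [thz_trace]; `metadata$n_pixels` records how many pixels
#'   were averaged.
#' @export
roi_mean_waveform <- function(cube, center, radius_px) {
  stopifnot(inherits(cube, "thz_cube"))
  d <- dim(cube$cube)
  rr <- matrix(seq_len(d[1]), d[1], d[2])
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  inside <- (rr - center[1])^2 + (cc - center[2])^2 <= radius_px^2
  if (!any(inside)) {
    stop_invalid("the region of interest contains no pixel center")
  }
  flat <- matrix(cube$cube, d[1] * d[2], d[3])
  wf <- colMeans(flat[which(inside), , drop = FALSE])
  thz_trace(cube$time, wf, metadata = list(n_pixels = sum(inside),
                                           center = center,
                                           radius_px = radius_px))
}

#' Per-pixel grayscale map of a cube
#'
#' Reduces every pixel's waveform to one scalar: `peak` (max |E(t)|,
#' the default — insect bodies attenuate the reflection, so they appear
#' dark), `peak_to_peak` (max - min) or `energy` (sum of squares).
#'
#' @param cube a [thz_cube].
#' @param statistic `"peak"`, `"peak_to_peak"` or `"energy"`.
#' @return A `grayscale_map`.
#' @export
grayscale_map <- function(cube, statistic = c("peak", "peak_to_peak",
                                              "energy")) {
  stopifnot(inherits(cube, "thz_cube"))
  statistic <- match.arg(statistic)
  d <- dim(cube$cube)
  flat <- matrix(cube$cube, d[1] * d[2], d[3])
  v <- switch(statistic,
              peak = apply(abs(flat), 1L, max),
              peak_to_peak = apply(flat, 1L, max) - apply(flat, 1L, min),
              energy = rowSums(flat^2))
  grayscale_map_values(matrix(v, d[1], d[2]), statistic)
}

#' Per-pixel pulse-arrival (time-of-flight) map
#'
#' The arrival time of each pixel's pulse, taken as the time of maximum
#' |E(t)| refined by 3-point parabolic interpolation around the discrete
#' argmax.  Pixels overlying denser material (insect bodies) show later
#' arrivals.  An all-zero waveform gets the first sample time by
#' convention.
#'
#' @param cube a [thz_cube].
#' @return A `grayscale_map` of arrival times (ps).
#' @export
delay_map <- function(cube) {
  stopifnot(inherits(cube, "thz_cube"))
  d <- dim(cube$cube)
  if (d[3] < 2L) stop_invalid("at least two time samples are required")
  dt <- cube$time[2] - cube$time[1]
  flat <- abs(matrix(cube$cube, d[1] * d[2], d[3]))
  idx <- max.col(flat, ties.method = "first")
  v <- cube$time[idx]
  # parabolic refinement where the argmax has two interior neighbours
  ok <- idx > 1L & idx < d[3]
  if (any(ok)) {
    i <- which(ok)
    sel <- cbind(i, idx[i])
    y0 <- flat[cbind(i, idx[i] - 1L)]
    y1 <- flat[sel]
    y2 <- flat[cbind(i, idx[i] + 1L)]
    denom <- y0 - 2 * y1 + y2
    shift <- ifelse(abs(denom) > 0, 0.5 * (y0 - y2) / denom, 0)
    v[i] <- v[i] + pmin(pmax(shift, -0.5), 0.5) * dt
  }
  zero <- rowSums(flat) == 0
  v[zero] <- cube$time[1L]
  grayscale_map_values(matrix(v, d[1], d[2]), "delay")
}

#' Grayscale windowing
#'
#' Clamps map values to `[lo, hi]` and rescales the window linearly to
#' `[0, 1]`; values outside the window saturate at 0 or 1.  Narrow
#' windows (e.g. 80-120 on an instrument scale of 68-1272) reveal
#' low-contrast structures such as buried insect bodies.
#'
#' @param map a `grayscale_map`.
#' @param lo,hi window limits, `lo < hi`.
#' @return The windowed `grayscale_map` (values in `[0, 1]`).
#' @export
window_grayscale <- function(map, lo, hi) {
  stopifnot(inherits(map, "grayscale_map"))
  if (!is_scalar_num(lo) || !is_scalar_num(hi) || lo >= hi) {
    stop_invalid("'lo' must be smaller than 'hi'")
  }
  v <- (pmin(pmax(map$values, lo), hi) - lo) / (hi - lo)
  out <- grayscale_map_values(v, map$statistic)
  out$window <- c(lo, hi)
  out
}

# 8-connected component labeling (EBImage::bwlabel is 4-connected)
label_components_8 <- function(mask) {
  nx <- nrow(mask)
  ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pr <- ((p - 1L) %% nx) + 1L
      pc <- ((p - 1L) %/% nx) + 1L
      nr <- pr + off_r
      nc <- pc + off_c
      okn <- nr >= 1L & nr <= nx & nc >= 1L & nc <= ny
      nidx <- (nc[okn] - 1L) * nx + nr[okn]
      nidx <- nidx[mask[nidx] & lab[nidx] == 0L]
      if (length(nidx)) {
        lab[nidx] <- cur
        queue <- c(queue, nidx)
      }
    }
  }
  lab
}

# convex-hull pixel count for solidity; hull vertices are pixel centers
convex_area_px <- function(r, c) {
  if (length(r) <= 2L) return(length(r))
  h <- grDevices::chull(r, c)
  hr <- r[h]
  hc <- c[h]
  box_r <- seq(min(r), max(r))
  box_c <- seq(min(c), max(c))
  gr <- rep(box_r, times = length(box_c))
  gc <- rep(box_c, each = length(box_r))
  inside <- rep(TRUE, length(gr))
  nh <- length(hr)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    # cross product sign; chull returns vertices clockwise
    cr <- (hc[j] - hc[i]) * (gr - hr[i]) - (hr[j] - hr[i]) * (gc - hc[i])
    inside <- inside & cr >= -1e-9
  }
  sum(inside)
}

component_features <- function(lab) {
  n_comp <- max(lab)
  if (n_comp == 0L) {
    return(data.frame(label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = integer(0),
                      eccentricity = numeric(0), solidity = numeric(0)))
  }
  out <- vector("list", n_comp)
  for (lb in seq_len(n_comp)) {
    px <- which(lab == lb, arr.ind = TRUE)
    r <- px[, 1L]
    c <- px[, 2L]
    area <- length(r)
    mr <- mean(r)
    mc <- mean(c)
    # eccentricity from second central moments (+1/12 per-pixel variance
    # so single-pixel rows do not degenerate)
    mu20 <- mean((r - mr)^2) + 1 / 12
    mu02 <- mean((c - mc)^2) + 1 / 12
    mu11 <- mean((r - mr) * (c - mc))
    common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
    l1 <- (mu20 + mu02 + common) / 2
    l2 <- (mu20 + mu02 - common) / 2
    ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
    sol <- area / max(convex_area_px(r, c), area)
    out[[lb]] <- data.frame(label = lb, centroid_row = mr, centroid_col = mc,
                            area_px = area, eccentricity = ecc,
                            solidity = sol)
  }
  do.call(rbind, out)
}

#' Detect foreign bodies in a grayscale map
#'
#' Insect bodies attenuate the reflected pulse, so candidate pixels are
#' those *below* the intensity threshold.  The candidate mask is cleaned
#' by a 3 x 3 morphological opening, labeled with 8-connectivity, and
#' each component is gated on area, eccentricity and solidity; the
#' survivors are flagged as accepted foreign bodies.
#'
#' @param map a `grayscale_map` (typically windowed to `[0, 1]` first).
#' @param threshold numeric cut, or `"auto"` for Otsu's threshold on the
#'   map values.
#' @param min_area_px smallest accepted component area (default 20).
#' @param max_eccentricity largest accepted eccentricity (default 0.97;
#'   worm-like elongated blobs pass, line artifacts do not).
#' @param min_solidity smallest accepted solidity (default 0.5).
#' @return An object of class `detection_result`: `mask` (all candidate
#'   components after opening), `components` (data frame of shape
#'   features with an `accepted` flag), `accepted_mask` (accepted
#'   components only), and the `threshold` used.
#' @export
detect_foreign_bodies <- function(map, threshold = "auto",
                                  min_area_px = 20L,
                                  max_eccentricity = 0.97,
                                  min_solidity = 0.5) {
  stopifnot(inherits(map, "grayscale_map"))
  v <- map$values
  if (identical(threshold, "auto")) {
    rng <- range(v)
    if (rng[1] == rng[2]) {
      threshold <- rng[1]        # flat map: nothing below the threshold
    } else {
      threshold <- EBImage::otsu(EBImage::Image(v), range = rng)
    }
  } else if (!is_scalar_num(threshold)) {
    stop_invalid("'threshold' must be numeric or \"auto\"")
  }
  cand <- v < threshold
  opened <- EBImage::opening(EBImage::Image(cand * 1),
                             EBImage::makeBrush(3, "box"))
  opened <- matrix(as.numeric(opened) > 0.5, nrow(v), ncol(v))
  lab <- label_components_8(opened)
  comp <- component_features(lab)
  comp$accepted <- comp$area_px >= min_area_px &
    comp$eccentricity <= max_eccentricity &
    comp$solidity >= min_solidity
  accepted_mask <- matrix(FALSE, nrow(v), ncol(v))
  if (any(comp$accepted)) {
    accepted_mask <- matrix(lab %in% comp$label[comp$accepted],
                            nrow(v), ncol(v))
  }
  structure(list(mask = lab > 0L, labels = lab, components = comp,
                 accepted_mask = accepted_mask, threshold = threshold),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d component(s), %d accepted (thr %.4g)\n",
              nrow(x$components), sum(x$components$accepted), x$threshold))
  invisible(x)
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b logical matrices of equal dimension.
#' @return IoU in `[0, 1]`; 1 if both masks are empty.
#' @export
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop_invalid("mask dimensions differ")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
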