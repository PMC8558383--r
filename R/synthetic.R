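#' Phenomenological THz pulse model
#'
#' A single-cycle THz pulse is modeled as the first derivative of a
#' Gaussian, normalized so that the positive lobe peaks at exactly
#' `amplitude_scale`.  Denser, more absorbing media (insect chitin, fat
#' and protein versus loose tea powder) are emulated by a smaller
#' `amplitude_scale` and a positive `delay_shift` added to `center_time`
#' (longer optical path / time of flight).
#'
#' @param amplitude_scale positive peak amplitude (arbitrary units).
#' @param center_time pulse center (ps).
#' @param pulse_width Gaussian width parameter sigma (ps).
#' @param delay_shift extra delay added to `center_time` (ps).
#' @return An object of class `pulse_model`.
#' @export
#' @examples
#' tea    <- pulse_model()
#' insect <- pulse_model(amplitude_scale = 0.6, delay_shift = 0.8)
pulse_model <- function(amplitude_scale = 1, center_time = 10,
                        pulse_width = 0.5, delay_shift = 0) {
  if (!is_scalar_num(amplitude_scale) || amplitude_scale < 0) {
    stop_invalid("'amplitude_scale' must be a nonnegative number")
  }
  if (!is_scalar_num(pulse_width) || pulse_width <= 0) {
    stop_invalid("'pulse_width' must be positive")
  }
  if (!is_scalar_num(center_time) || !is_scalar_num(delay_shift)) {
    stop_invalid("'center_time' and 'delay_shift' must be numbers")
  }
  structure(list(amplitude_scale = amplitude_scale,
                 center_time = center_time,
                 pulse_width = pulse_width,
                 delay_shift = delay_shift),
            class = "pulse_model")
}

#' Evaluate a pulse model on a time grid
#'
#' @param model a [pulse_model].
#' @param time numeric vector of times (ps).
#' @return The noise-free pulse waveform; its maximum equals
#'   `amplitude_scale` (attained at `center_time + delay_shift -
#'   pulse_width`).
#' @export
pulse_waveform <- function(model, time) {
  stopifnot(inherits(model, "pulse_model"))
  u <- (time - model$center_time - model$delay_shift) / model$pulse_width
  # derivative-of-Gaussian, rescaled so max = amplitude_scale
  model$amplitude_scale * (-u) * exp(0.5 - u^2 / 2)
}

#' Smooth additive baseline-drift model
#'
#' Scattering at medium boundaries adds a slow additive drift to the
#' recorded signal.  The drift is a degree-3 polynomial in the
#' normalized axis u in [-1, 1] plus one sinusoid whose period is at
#' least half the record length, so all drift content stays well below
#' the pulse's own spectral band.
#'
#' @param polynomial_coefficients numeric vector `c(c0, c1, c2, c3)` of
#'   the polynomial in u.
#' @param sine_amplitude amplitude of the sinusoidal component.
#' @param sine_period period in axis units (must be positive).
#' @param sine_phase phase offset (radians).
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(polynomial_coefficients = c(0, 0, 0, 0),
                        sine_amplitude = 0, sine_period = 40,
                        sine_phase = 0) {
  if (!is.numeric(polynomial_coefficients) ||
      length(polynomial_coefficients) < 1L) {
    stop_invalid("'polynomial_coefficients' must be a numeric vector")
  }
  if (!is_scalar_num(sine_period) || sine_period <= 0) {
    stop_invalid("'sine_period' must be positive")
  }
  structure(list(polynomial_coefficients = as.double(polynomial_coefficients),
                 sine_amplitude = sine_amplitude,
                 sine_period = sine_period,
                 sine_phase = sine_phase),
            class = "drift_model")
}

#' Evaluate a drift model on an axis
#'
#' @param model a [drift_model].
#' @param axis numeric vector (the axis of the signal the drift corrupts).
#' @return The drift values.
#' @export
drift_waveform <- function(model, axis) {
  stopifnot(inherits(model, "drift_model"))
  rng <- range(axis)
  u <- if (rng[2] > rng[1]) 2 * (axis - rng[1]) / (rng[2] - rng[1]) - 1 else axis * 0
  z <- numeric(length(axis))
  for (k in seq_along(model$polynomial_coefficients)) {
    z <- z + model$polynomial_coefficients[k] * u^(k - 1)
  }
  z + model$sine_amplitude *
    sin(2 * pi * axis / model$sine_period + model$sine_phase)
}

#' Generate one synthetic THz trace with ground truth
#'
#' Trace = pulse + drift + white Gaussian noise.  The ground truth keeps
#' each additive component, so `pulse + true_baseline + noise`
#' reconstructs the trace exactly — the property baseline-recovery
#' benchmarks rely on.
#'
#' @param model a [pulse_model].
#' @param drift a [drift_model].
#' @param noise_sd standard deviation of the additive noise (>= 0).
#' @param n_points number of samples (>= 64).
#' @param t_max record length (ps, > 0); the time axis is
#'   `seq(0, t_max, length.out = n_points)`.
#' @param seed optional integer seed; identical seeds and parameters give
#'   bit-identical traces.
#' @return A list with `trace` (a [thz_trace]) and `truth` (list with
#'   `true_baseline`, `pulse`, `noise`).
#' @export
#' @examples
#' g <- generate_trace(pulse_model(), drift_model(c(0.1, 0, -0.05, 0)),
#'                     noise_sd = 0.01, seed = 7)
generate_trace <- function(model, drift = drift_model(), noise_sd = 0.01,
                           n_points = 2048, t_max = 40, seed = NULL) {
  stopifnot(inherits(model, "pulse_model"), inherits(drift, "drift_model"))
  if (!is_count(n_points, min = 64)) {
    stop_invalid("'n_points' must be an integer >= 64")
  }
  if (!is_scalar_num(t_max) || t_max <= 0) {
    stop_invalid("'t_max' must be positive")
  }
  if (!is_scalar_num(noise_sd) || noise_sd < 0) {
    stop_invalid("'noise_sd' must be nonnegative")
  }
  time <- seq(0, t_max, length.out = n_points)
  pulse <- pulse_waveform(model, time)
  base <- drift_waveform(drift, time)
  noise <- with_seed_if(seed, rnorm(n_points, 0, noise_sd))
  if (noise_sd == 0) noise <- numeric(n_points)
  trace <- thz_trace(time, pulse + base + noise,
                     metadata = list(seed = seed, noise_sd = noise_sd))
  list(trace = trace,
       truth = list(true_baseline = base, pulse = pulse, noise = noise))
}

# stratified largest-remainder calibration counts so the default
# 88 + 88 study yields exactly the 125/51 two-population design
split_counts <- function(n_by_class, fraction) {
  total <- round(fraction * sum(n_by_class))
  raw <- fraction * n_by_class
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  pmin(pmax(base, 0), n_by_class)
}

#' Generate a labeled synthetic tea / insect dataset
#'
#' Draws `n_tea + n_insect` time traces: each sample gets its own random
#' drift (polynomial coefficients and sinusoid amplitude ~ N(0,
#' drift_sd^2), sinusoid period uniform in `[t_max/2, t_max]`) and white
#' noise.  The class contrast is fixed by observation: insect spectra
#' have lower intensity and a delayed pulse relative to tea, so the
#' insect model must have a smaller `amplitude_scale` and larger
#' `delay_shift` than the tea model.  A deterministic stratified
#' calibration/prediction split (default fraction 125/176) is stored
#' with the data so every downstream model sees the same two
#' populations.
#'
#' @param n_tea,n_insect class sizes (each >= 1); defaults give the
#'   125-calibration / 51-prediction study.
#' @param tea_model,insect_model [pulse_model]s for the two classes.
#' @param drift_sd scale of the per-sample drift coefficients; the
#'   default 0.05 makes the drift peak-to-peak about 15% of the tea
#'   pulse peak.
#' @param noise_sd additive noise sd (default 1% of the tea peak).
#' @param n_points,t_max time grid (see [generate_trace()]).
#' @param calibration_fraction fraction of each class assigned to the
#'   calibration population.
#' @param seed integer seed; all randomness flows from it.
#' @return A list with `data` (a [spectral_set] of time traces) and
#'   `truth` (per-sample list of `true_baseline`, `pulse`, `noise`,
#'   `true_label`).
#' @export
generate_dataset <- function(n_tea = 88, n_insect = 88,
                             tea_model = pulse_model(),
                             insect_model = pulse_model(amplitude_scale = 0.6,
                                                        delay_shift = 0.8),
                             drift_sd = 0.05, noise_sd = 0.01,
                             n_points = 2048, t_max = 40,
                             calibration_fraction = 125 / 176,
                             seed = 1) {
  if (!is_count(n_tea) || !is_count(n_insect)) {
    stop_invalid("'n_tea' and 'n_insect' must be integers >= 1")
  }
  if (insect_model$amplitude_scale >= tea_model$amplitude_scale ||
      insect_model$delay_shift <= tea_model$delay_shift) {
    stop_invalid(paste("class contrast violated: the insect model must have",
                       "lower amplitude_scale and larger delay_shift than",
                       "the tea model"),
                 class = "thzfb_class_contrast")
  }
  if (!is_scalar_num(drift_sd) || drift_sd < 0) {
    stop_invalid("'drift_sd' must be nonnegative")
  }
  n <- n_tea + n_insect
  labels <- factor(rep(c("tea", "insect"), c(n_tea, n_insect)),
                   levels = c("tea", "insect"))
  models <- c(rep(list(tea_model), n_tea), rep(list(insect_model), n_insect))
  time <- seq(0, t_max, length.out = n_points)

  draws <- with_seed_if(seed, {
    lapply(seq_len(n), function(i) {
      list(poly = rnorm(4, 0, drift_sd),
           amp = rnorm(1, 0, drift_sd),
           period = runif(1, t_max / 2, t_max),
           phase = runif(1, 0, 2 * pi),
           noise = if (noise_sd > 0) rnorm(n_points, 0, noise_sd)
                   else numeric(n_points))
    })
  })

  features <- matrix(0, n, n_points)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    d <- draws[[i]]
    dm <- drift_model(d$poly, sine_amplitude = d$amp,
                      sine_period = d$period, sine_phase = d$phase)
    base <- drift_waveform(dm, time)
    pulse <- pulse_waveform(models[[i]], time)
    features[i, ] <- pulse + base + d$noise
    truth[[i]] <- list(true_baseline = base, pulse = pulse, noise = d$noise,
                       true_label = as.character(labels[i]))
  }

  n_cal <- split_counts(c(n_tea, n_insect), calibration_fraction)
  split <- c(rep(c("calibration", "prediction"), c(n_cal[1], n_tea - n_cal[1])),
             rep(c("calibration", "prediction"), c(n_cal[2], n_insect - n_cal[2])))

  data <- spectral_set(features, labels, time, split, axis_unit = "ps",
                       metadata = list(seed = seed, drift_sd = drift_sd,
                                       noise_sd = noise_sd,
                                       tea_model = tea_model,
                                       insect_model = insect_model))
  list(data = data, truth = truth)
}

#' Default implanted-insect ellipses for a 96 x 96 scan
#'
#' Two worm-shaped (elongated) regions placed apart on the grid, the
#' two-foreign-body layout of the reflection-imaging experiment.
#'
#' @param nx,ny grid size the ellipses are scaled for.
#' @return List of ellipses, each `list(center = c(row, col),
#'   axes = c(a, b), angle = radians)` in 1-based pixel units.
#' @export
default_insect_ellipses <- function(nx = 96, ny = 96) {
  s <- min(nx, ny) / 96
  list(
    list(center = c(30, 30) * s, axes = c(13, 5) * s, angle = 0.5),
    list(center = c(64, 62) * s, axes = c(11, 6) * s, angle = -0.8)
  )
}

ellipse_mask <- function(nx, ny, ellipses) {
  mask <- matrix(FALSE, nx, ny)
  if (length(ellipses) == 0L) return(mask)
  rr <- matrix(seq_len(nx), nx, ny)
  cc <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  for (e in ellipses) {
    if (e$center[1] < 1 || e$center[1] > nx ||
        e$center[2] < 1 || e$center[2] > ny) {
      stop_invalid("ellipse center lies outside the image grid")
    }
    if (any(e$axes <= 0)) stop_invalid("ellipse axes must be positive")
    dr <- rr - e$center[1]
    dc <- cc - e$center[2]
    x1 <- dr * cos(e$angle) + dc * sin(e$angle)
    x2 <- -dr * sin(e$angle) + dc * cos(e$angle)
    mask <- mask | (x1 / e$axes[1])^2 + (x2 / e$axes[2])^2 <= 1
  }
  mask
}

#' Generate a synthetic THz reflection-image cube
#'
#' Raster-scan emulation: every pixel records a reflected waveform; the
#' pixels inside any implanted ellipse carry the insect pulse (delayed,
#' attenuated), the rest the tea pulse.  Per-pixel multiplicative
#' lognormal speckle emulates scattering off randomly oriented leaves,
#' and white noise is added per sample.
#'
#' @param nx,ny,n_time cube dimensions.
#' @param insect_ellipses list of ellipses (see
#'   [default_insect_ellipses()]); must lie within the grid.
#' @param tea_model,insect_model [pulse_model]s.
#' @param noise_sd additive white-noise sd.
#' @param speckle_sdlog log-scale sd of the per-pixel multiplicative
#'   speckle; 0 turns speckle off.
#' @param t_max record length (ps).
#' @param dx_mm,dy_mm raster step (mm); 0.2 mm is the usual bench value.
#' @param seed integer seed.
#' @return A list with `cube` (class `thz_cube`: `cube` nx x ny x n_time
#'   array, `time`, `dx_mm`, `dy_mm`) and `truth` (list with `true_mask`
#'   and the programmed `delay_ps`).
#' @export
generate_image_cube <- function(nx = 96, ny = 96, n_time = 512,
                                insect_ellipses = default_insect_ellipses(nx, ny),
                                tea_model = pulse_model(),
                                insect_model = pulse_model(amplitude_scale = 0.6,
                                                           delay_shift = 0.8),
                                noise_sd = 0.01, speckle_sdlog = 0.1,
                                t_max = 40, dx_mm = 0.2, dy_mm = 0.2,
                                seed = 1) {
  if (!is_count(nx, 2) || !is_count(ny, 2) || !is_count(n_time, 2)) {
    stop_invalid("'nx', 'ny' and 'n_time' must be integers >= 2")
  }
  time <- seq(0, t_max, length.out = n_time)
  mask <- ellipse_mask(nx, ny, insect_ellipses)
  tea_w <- pulse_waveform(tea_model, time)
  insect_w <- pulse_waveform(insect_model, time)

  cube <- with_seed_if(seed, {
    speckle <- if (speckle_sdlog > 0) {
      matrix(rlnorm(nx * ny, 0, speckle_sdlog), nx, ny)
    } else {
      matrix(1, nx, ny)
    }
    vol <- outer(speckle * !mask, tea_w) + outer(speckle * mask, insect_w)
    if (noise_sd > 0) {
      vol <- vol + array(rnorm(nx * ny * n_time, 0, noise_sd),
                         dim = c(nx, ny, n_time))
    }
    vol
  })

  list(cube = thz_cube(cube, time, dx_mm = dx_mm, dy_mm = dy_mm),
       truth = list(true_mask = mask,
                    ellipse_masks = lapply(insect_ellipses, function(e)
                      ellipse_mask(nx, ny, list(e))),
                    delay_ps = insect_model$delay_shift - tea_model$delay_shift))
}
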