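#' Time-domain THz trace
#'
#' Container for a uniformly sampled terahertz electric-field pulse E(t).
#' Times are in picoseconds (ps); field amplitude is in arbitrary units
#' (the photoconductive detector voltage is uncalibrated).
#'
#' @param time strictly increasing numeric vector of sample times (ps);
#'   spacing must be uniform within `1e-9` relative tolerance.
#' @param field numeric vector of electric-field values, same length.
#' @param metadata named list of free-form annotations.
#' @return An object of class `thz_trace` with elements `time`, `field`,
#'   `metadata`.
#' @export
#' @examples
#' tr <- thz_trace(seq(0, 40, length.out = 128), rnorm(128))
thz_trace <- function(time, field, metadata = list()) {
  if (!is.numeric(time) || !is.numeric(field)) {
    stop_invalid("'time' and 'field' must be numeric")
  }
  if (length(time) != length(field)) {
    stop_invalid("'time' and 'field' must have equal length")
  }
  if (length(time) < 2L) stop_invalid("a trace needs at least two samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop_invalid("'time' must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9 * mean(dt)) {
    stop_invalid("'time' must be uniformly sampled (1e-9 relative tolerance)",
                 class = "thzfb_nonuniform_sampling")
  }
  structure(list(time = as.double(time), field = as.double(field),
                 metadata = metadata),
            class = "thz_trace")
}

#' @export
print.thz_trace <- function(x, ...) {
  cat(sprintf("<thz_trace> %d samples, %.3g-%.3g ps (dt = %.4g ps)\n",
              length(x$time), x$time[1], x$time[length(x$time)],
              x$time[2] - x$time[1]))
  invisible(x)
}

trace_dt <- function(trace) trace$time[2] - trace$time[1]

#' Average replicate traces
#'
#' Element-wise mean of replicate acquisitions of the same sample (two
#' pulses are typically recorded per tablet and averaged before
#' modeling).
#'
#' @param traces list of [thz_trace] objects sharing one time axis.
#' @return A [thz_trace] whose field is the element-wise mean;
#'   `metadata$n_replicates` records the replicate count.
#' @export
average_replicates <- function(traces) {
  if (inherits(traces, "thz_trace")) traces <- list(traces)
  if (!is.list(traces) || length(traces) < 1L ||
      !all(vapply(traces, inherits, logical(1), "thz_trace"))) {
    stop_invalid("'traces' must be a non-empty list of thz_trace objects")
  }
  t0 <- traces[[1L]]$time
  for (tr in traces[-1L]) {
    if (length(tr$time) != length(t0) || any(tr$time != t0)) {
      stop_invalid("replicates must share an identical time axis",
                   class = "thzfb_axis_mismatch")
    }
  }
  fields <- vapply(traces, `[[`, numeric(length(t0)), "field")
  avg <- if (is.matrix(fields)) rowMeans(fields) else fields
  md <- traces[[1L]]$metadata
  md$n_replicates <- length(traces)
  thz_trace(t0, avg, md)
}

#' One-sided FFT amplitude/phase spectrum of a trace
#'
#' Converts a time-domain pulse E(t) to its frequency-domain
#' representation A(f)·exp(-i·phi(f)) by discrete Fourier transform.
#' The spectrum is one-sided with the non-DC, non-Nyquist bins doubled,
#' so a unit-amplitude cosine at a grid frequency has amplitude 1.
#' Times in ps give frequencies directly in THz.
#'
#' @param trace a [thz_trace].
#' @param zero_pad_to optional integer; zero-pad the field to this length
#'   before transforming (finer frequency grid, same content). Must be at
#'   least the trace length.
#' @param window `"none"` (rectangular, the default) or `"hann"`.
#' @return An object of class `frequency_spectrum` with elements
#'   `frequency` (THz), `complex_amplitude`, `amplitude` (modulus),
#'   `phase` (negative argument, the engineering sign convention for a
#'   delay-induced linear phase), and `metadata`.
#' @export
#' @examples
#' t <- seq(0, 40, length.out = 2048)
#' sp <- fft_spectrum(thz_trace(t, cos(2 * pi * 0.5 * t)))
#' sp$frequency[which.max(sp$amplitude)]  # ~0.5 THz
fft_spectrum <- function(trace, zero_pad_to = NULL,
                         window = c("none", "hann")) {
  stopifnot(inherits(trace, "thz_trace"))
  window <- match.arg(window)
  y <- trace$field
  n0 <- length(y)
  if (window == "hann") {
    y <- y * (0.5 - 0.5 * cos(2 * pi * seq_len(n0) / (n0 + 1)))
  }
  n <- n0
  if (!is.null(zero_pad_to)) {
    if (!is_count(zero_pad_to, min = n0)) {
      stop_invalid("'zero_pad_to' must be an integer >= the trace length")
    }
    n <- as.integer(zero_pad_to)
    y <- c(y, numeric(n - n0))
  }
  dt <- trace_dt(trace)
  ft <- stats::fft(y)
  nf <- n %/% 2L + 1L
  scale <- rep(2 / n, nf)
  scale[1L] <- 1 / n
  if (n %% 2L == 0L) scale[nf] <- 1 / n
  ca <- scale * ft[seq_len(nf)]
  structure(list(
    frequency = (seq_len(nf) - 1L) / (n * dt),
    complex_amplitude = ca,
    amplitude = Mod(ca),
    phase = -Arg(ca),
    metadata = c(trace$metadata,
                 list(n_time = n0, n_fft = n, dt_ps = dt, window = window))
  ), class = "frequency_spectrum")
}

#' @export
print.frequency_spectrum <- function(x, ...) {
  cat(sprintf("<frequency_spectrum> %d bins, 0-%.3g THz (df = %.4g THz)\n",
              length(x$frequency), max(x$frequency),
              x$frequency[2] - x$frequency[1]))
  invisible(x)
}

#' Signal energy computed from a one-sided spectrum
#'
#' Evaluates the Parseval sum for the package's one-sided doubling
#' convention: `sum(E(t)^2)` equals
#' `n * (A_0^2 + A_nyq^2 + sum(A_mid^2) / 2)` where the middle bins carry
#' doubled amplitudes.  Useful as an energy bookkeeping check.
#'
#' @param spectrum a `frequency_spectrum`.
#' @return Scalar time-domain energy implied by the spectrum.
#' @export
spectral_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  a <- spectrum$amplitude
  n <- spectrum$metadata$n_fft
  nf <- length(a)
  edge <- a[1L]^2
  mid <- seq(2L, nf)
  if (n %% 2L == 0L) {
    edge <- edge + a[nf]^2
    mid <- if (nf > 2L) seq(2L, nf - 1L) else integer(0)
  }
  n * (edge + sum(a[mid]^2) / 2)
}

#' Labeled spectral dataset
#'
#' Feature matrix (one sample per row: a time trace or an amplitude
#' spectrum) with class labels, the shared variable axis, and a fixed
#' calibration/prediction partition so every model sees the same two
#' sample populations.
#'
#' @param features numeric matrix, samples x variables.
#' @param labels factor (or vector coercible to one) of class labels,
#'   one per row.
#' @param variable_axis numeric vector, one value per column (ps or THz).
#' @param split character/factor per row, `"calibration"` or
#'   `"prediction"`.
#' @param axis_unit `"ps"` or `"THz"`.
#' @param metadata named list of annotations (e.g. correction provenance).
#' @return An object of class `spectral_set`.
#' @export
spectral_set <- function(features, labels, variable_axis, split,
                         axis_unit = c("THz", "ps"), metadata = list()) {
  axis_unit <- match.arg(axis_unit)
  features <- as.matrix(features)
  if (!is.numeric(features)) stop_invalid("'features' must be numeric")
  labels <- as.factor(labels)
  split <- as.character(split)
  if (nrow(features) != length(labels) || nrow(features) != length(split)) {
    stop_invalid("row count, label count and split count must agree")
  }
  if (length(variable_axis) != ncol(features)) {
    stop_invalid("'variable_axis' length must equal the column count")
  }
  if (!all(split %in% c("calibration", "prediction"))) {
    stop_invalid("'split' entries must be 'calibration' or 'prediction'")
  }
  structure(list(features = features, labels = labels,
                 variable_axis = as.double(variable_axis), split = split,
                 axis_unit = axis_unit, metadata = metadata),
            class = "spectral_set")
}

#' @export
print.spectral_set <- function(x, ...) {
  cat(sprintf("<spectral_set> %d samples x %d variables (%s axis)\n",
              nrow(x$features), ncol(x$features), x$axis_unit))
  print(table(label = x$labels, split = x$split))
  invisible(x)
}

#' Convert a set of time traces to amplitude spectra
#'
#' Applies [fft_spectrum()] row-wise to a `spectral_set` holding time
#' traces and returns the set of one-sided amplitude spectra on the
#' common frequency axis.
#'
#' @param data a `spectral_set` with a ps axis (rows are traces).
#' @param zero_pad_to,window passed to [fft_spectrum()].
#' @return A `spectral_set` with a THz axis; labels and split carried
#'   over unchanged.
#' @export
spectra_from_traces <- function(data, zero_pad_to = NULL,
                                window = c("none", "hann")) {
  stopifnot(inherits(data, "spectral_set"))
  if (data$axis_unit != "ps") {
    stop_invalid("'data' must hold time traces (ps axis)")
  }
  window <- match.arg(window)
  sp1 <- fft_spectrum(thz_trace(data$variable_axis, data$features[1L, ]),
                      zero_pad_to = zero_pad_to, window = window)
  amps <- t(apply(data$features, 1L, function(f) {
    fft_spectrum(thz_trace(data$variable_axis, f),
                 zero_pad_to = zero_pad_to, window = window)$amplitude
  }))
  md <- data$metadata
  md$domain <- "frequency"
  spectral_set(amps, data$labels, sp1$frequency, data$split,
               axis_unit = "THz", metadata = md)
}

#' Restrict a spectral set to an analysis band
#'
#' Keeps the columns whose axis value lies in the closed interval
#' `[f_min, f_max]` (the discriminative band for tea vs insect material
#' is 0.3-1.0 THz; 0.3-1.2 THz is also in common use).
#'
#' @param data a `spectral_set`.
#' @param f_min,f_max band limits in the axis unit, `f_min < f_max`.
#' @return The band-restricted `spectral_set`.  Selecting a band that
#'   contains no grid point raises an empty-selection error.
#' @export
band_select <- function(data, f_min = 0.3, f_max = 1.0) {
  stopifnot(inherits(data, "spectral_set"))
  if (!is_scalar_num(f_min) || !is_scalar_num(f_max) || f_min >= f_max) {
    stop_invalid("'f_min' must be smaller than 'f_max'")
  }
  tol <- 1e-9 * max(abs(f_min), abs(f_max), 1)   # closed interval on a float grid
  keep <- data$variable_axis >= f_min - tol & data$variable_axis <= f_max + tol
  if (!any(keep)) {
    stop_invalid(sprintf("band [%g, %g] contains no axis point",
                         f_min, f_max),
                 class = "thzfb_empty_selection")
  }
  out <- data
  out$features <- data$features[, keep, drop = FALSE]
  out$variable_axis <- data$variable_axis[keep]
  out$metadata$band <- c(f_min, f_max)
  out
}
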