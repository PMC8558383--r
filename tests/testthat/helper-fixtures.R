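# shared fixtures, all generated in code

default_models <- function() {
  list(tea = pulse_model(),
       insect = pulse_model(amplitude_scale = 0.6, delay_shift = 0.8))
}

# a smooth random drift (generator draw, rescaled to a target
# peak-to-peak) plus a single positive Gaussian peak of unit height --
# the canonical baseline-recovery benchmark signal
drift_peak_signal <- function(seed, n = 2048, t_max = 40, drift_p2p = 0.3,
                              peak_t = 15, peak_w = 0.5, peak_height = 1) {
  ds <- generate_dataset(n_tea = 1, n_insect = 1, seed = seed,
                         n_points = n, t_max = t_max)
  drift <- ds$truth[[1]]$true_baseline
  drift <- drift * drift_p2p / diff(range(drift))
  x <- seq(0, t_max, length.out = n)
  list(x = x, drift = drift,
       y = drift + peak_height * exp(-((x - peak_t) / peak_w)^2))
}

# small, fast study configuration for pipeline determinism tests
small_config <- function(seed = 1, ...) {
  thzfb_config(seed = seed, n_tea = 8L, n_insect = 8L, n_points = 256L,
               corrections = c("none", "airpls"),
               calibration_fraction = 0.75,
               cube = list(nx = 48L, ny = 48L, n_time = 256L), ...)
}
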