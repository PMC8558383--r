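test_that("noise-free, drift-free trace equals the analytic pulse", {
  m <- pulse_model(amplitude_scale = 1, center_time = 10, pulse_width = 0.5)
  g <- generate_trace(m, drift_model(), noise_sd = 0, n_points = 512,
                      t_max = 40)
  t <- g$trace$time
  u <- (t - 10) / 0.5
  expect_equal(g$trace$field, -u * exp(0.5 - u^2 / 2), tolerance = 1e-14)
  # peak normalization: the analytic maximum (at center - width) is
  # exactly the amplitude scale; the grid maximum cannot exceed it
  expect_equal(pulse_waveform(m, 10 - 0.5), 1)
  expect_lte(max(g$trace$field), 1)
  expect_gt(max(g$trace$field), 0.99)
})

test_that("zero-amplitude pulse with constant drift gives a constant trace", {
  g <- generate_trace(pulse_model(amplitude_scale = 0), drift_model(c(5)),
                      noise_sd = 0, n_points = 128, t_max = 10)
  expect_equal(g$trace$field, rep(5, 128))
  expect_equal(g$truth$true_baseline, rep(5, 128))
})

test_that("trace generation is bit-reproducible under a fixed seed", {
  m <- pulse_model()
  d <- drift_model(c(0.1, -0.05, 0, 0.02), sine_amplitude = 0.03,
                   sine_period = 25)
  g1 <- generate_trace(m, d, noise_sd = 0.05, n_points = 256, seed = 11)
  g2 <- generate_trace(m, d, noise_sd = 0.05, n_points = 256, seed = 11)
  expect_identical(g1$trace$field, g2$trace$field)
  g3 <- generate_trace(m, d, noise_sd = 0.05, n_points = 256, seed = 12)
  expect_false(identical(g1$trace$field, g3$trace$field))
})

test_that("invalid trace arguments are rejected", {
  expect_error(generate_trace(pulse_model(), n_points = 32),
               class = "thzfb_invalid_argument")
  expect_error(generate_trace(pulse_model(), t_max = -1),
               class = "thzfb_invalid_argument")
  expect_error(generate_trace(pulse_model(), noise_sd = -0.1),
               class = "thzfb_invalid_argument")
})

test_that("dataset bookkeeping: counts, labels and split sizes", {
  ds <- generate_dataset(n_tea = 3, n_insect = 2, seed = 5, n_points = 128)
  expect_equal(nrow(ds$data$features), 5L)
  expect_equal(sum(ds$data$labels == "insect"), 2L)
  expect_length(ds$truth, 5L)

  # default study realizes the 125 / 51 two-population design
  ds <- generate_dataset(seed = 2, n_points = 128)
  expect_equal(sum(ds$data$split == "calibration"), 125L)
  expect_equal(sum(ds$data$split == "prediction"), 51L)
  # split is stratified: both classes present in both populations
  expect_true(all(table(ds$data$labels, ds$data$split) > 0))
})

test_that("with no randomness every trace of a class is identical", {
  ds <- generate_dataset(n_tea = 3, n_insect = 3, drift_sd = 0, noise_sd = 0,
                         seed = 1, n_points = 128)
  tea <- ds$data$features[ds$data$labels == "tea", ]
  ins <- ds$data$features[ds$data$labels == "insect", ]
  expect_equal(max(abs(sweep(tea, 2, tea[1, ]))), 0)
  expect_equal(max(abs(sweep(ins, 2, ins[1, ]))), 0)
  expect_false(isTRUE(all.equal(tea[1, ], ins[1, ])))
})

test_that("class-contrast direction is enforced", {
  expect_error(
    generate_dataset(n_tea = 2, n_insect = 2,
                     insect_model = pulse_model(amplitude_scale = 1.2,
                                                delay_shift = 0.8),
                     n_points = 128),
    class = "thzfb_class_contrast")
  expect_error(
    generate_dataset(n_tea = 2, n_insect = 2,
                     insect_model = pulse_model(amplitude_scale = 0.6,
                                                delay_shift = 0),
                     n_points = 128),
    class = "thzfb_class_contrast")
})

test_that("ground truth reconstructs each trace exactly", {
  ds <- generate_dataset(n_tea = 4, n_insect = 4, seed = 9, n_points = 256)
  for (i in seq_len(8)) {
    tr <- ds$truth[[i]]
    expect_identical(ds$data$features[i, ],
                     tr$pulse + tr$true_baseline + tr$noise)
  }
})

test_that("default study is linearly separable in band-mean amplitude", {
  ds <- generate_dataset(seed = 4)
  sp <- band_select(spectra_from_traces(ds$data), 0.3, 1.0)
  band_mean <- rowMeans(sp$features)
  # exhaustive pairwise scan: every tea sample above every insect sample
  expect_gt(min(band_mean[sp$labels == "tea"]),
            max(band_mean[sp$labels == "insect"]))
})

test_that("noise-free class contrast: amplitude and arrival time", {
  for (seed in c(3, 17)) {
    ds <- generate_dataset(n_tea = 5, n_insect = 5, seed = seed,
                           n_points = 512)
    peak_amp <- vapply(ds$truth, function(tr) max(tr$pulse), numeric(1))
    peak_t <- vapply(ds$truth, function(tr) which.max(tr$pulse), numeric(1))
    tea <- ds$data$labels == "tea"
    expect_gt(mean(peak_amp[tea]), mean(peak_amp[!tea]))
    expect_gt(mean(peak_t[!tea]), mean(peak_t[tea]))
  }
})

test_that("homogeneous cube: every pixel shares one waveform", {
  g <- generate_image_cube(nx = 8, ny = 8, n_time = 64,
                           insect_ellipses = list(), noise_sd = 0,
                           speckle_sdlog = 0, seed = 1)
  flat <- matrix(g$cube$cube, 64, 64)
  expect_equal(max(abs(sweep(flat, 2, flat[1, ]))), 0)
  expect_false(any(g$truth$true_mask))
})

test_that("grid-covering ellipse yields an all-ones mask", {
  g <- generate_image_cube(nx = 16, ny = 16, n_time = 64,
                           insect_ellipses = list(list(center = c(8, 8),
                                                       axes = c(50, 50),
                                                       angle = 0)),
                           noise_sd = 0, speckle_sdlog = 0, seed = 1)
  expect_true(all(g$truth$true_mask))
})

test_that("out-of-grid ellipse is rejected", {
  expect_error(
    generate_image_cube(nx = 16, ny = 16, n_time = 64,
                        insect_ellipses = list(list(center = c(40, 8),
                                                    axes = c(3, 2),
                                                    angle = 0))),
    class = "thzfb_invalid_argument")
})

test_that("per-pixel peak time inside the ellipse lags by the programmed delay", {
  # noise-free so the per-pixel argmax is exact; speckle stays on (it
  # scales amplitudes without moving the arrival time)
  g <- generate_image_cube(nx = 48, ny = 48, n_time = 256,
                           insect_ellipses = list(list(center = c(24, 24),
                                                       axes = c(10, 6),
                                                       angle = 0.3)),
                           noise_sd = 0, seed = 6)
  d <- dim(g$cube$cube)
  flat <- matrix(g$cube$cube, d[1] * d[2], d[3])
  peak_t <- g$cube$time[max.col(flat, ties.method = "first")]
  dt <- g$cube$time[2] - g$cube$time[1]
  inside <- as.vector(g$truth$true_mask)
  ref_out <- stats::median(peak_t[!inside])
  # exhaustive over inside pixels: each lags the tea arrival by the
  # programmed delay to within one sample interval
  expect_true(all(abs(peak_t[inside] - ref_out - g$truth$delay_ps) <= dt))
})
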