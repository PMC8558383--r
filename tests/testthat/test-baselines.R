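test_that("Whittaker smoother: constants pass through, small-lambda limit", {
  y <- rep(3.7, 40)
  for (lam in c(1, 1e4, 1e8)) {
    # constants are in the null space of the difference penalty; at the
    # largest lambda the attainable precision is set by conditioning
    expect_equal(whittaker_smooth(y, lam = lam), y, tolerance = 1e-6)
  }
  set.seed(5)
  y <- rnorm(60)
  expect_equal(whittaker_smooth(y, lam = 1e-10), y, tolerance = 1e-8)
})

test_that("banded solve matches a dense normal-equations solve", {
  set.seed(14)
  for (ord in c(1L, 2L, 3L)) {
    y <- rnorm(50)
    w <- runif(50, 0.1, 2)
    z <- whittaker_smooth(y, w, lam = 100, diff_order = ord)
    D <- diff(diag(50), differences = ord)
    z_dense <- solve(diag(w) + 100 * crossprod(D), w * y)
    expect_equal(z, z_dense, tolerance = 1e-9)
  }
})

test_that("Whittaker output is the unique minimizer of the objective", {
  set.seed(23)
  y <- rnorm(50)
  w <- runif(50, 0.2, 1)
  lam <- 50
  D <- diff(diag(50), differences = 2)
  obj <- function(z) sum(w * (y - z)^2) + lam * sum((D %*% z)^2)
  z <- whittaker_smooth(y, w, lam)
  f0 <- obj(z)
  for (i in 1:100) {
    expect_gt(obj(z + rnorm(50, 0, 0.01)), f0)
  }
})

test_that("degenerate Whittaker inputs are rejected", {
  expect_error(whittaker_smooth(rnorm(2), lam = 1, diff_order = 2),
               class = "thzfb_invalid_argument")
  expect_error(whittaker_smooth(rnorm(10), weights = rep(0, 10), lam = 0),
               class = "thzfb_singular_system")
  expect_error(whittaker_smooth(rnorm(10), weights = rep(-1, 10)),
               class = "thzfb_invalid_argument")
})

test_that("AsLS with p = 1/2 reduces to the symmetric Whittaker smoother", {
  set.seed(3)
  y <- rnorm(80) + seq(0, 2, length.out = 80)
  fit <- asls(y, lam = 1e3, p = 0.5)
  # weights stabilize at 1/2 everywhere, i.e. the symmetric smoother at
  # an effective doubled penalty
  expect_equal(fit$baseline, whittaker_smooth(y, rep(0.5, 80), 1e3),
               tolerance = 1e-10)
  expect_true(fit$converged)
  expect_equal(unname(unique(fit$weights)), 0.5)
})

test_that("AsLS recovers drift under a positive peak (seeded oracle)", {
  sig <- drift_peak_signal(seed = 1)
  fit <- asls(sig$y)   # spec-range defaults: lam 1e5, p 0.01
  expect_lt(sqrt(mean((fit$baseline - sig$drift)^2)), 0.02)
  expect_true(fit$converged)
  # decomposition identity holds to machine precision
  expect_equal(fit$baseline + fit$corrected, sig$y, tolerance = 1e-14)
})

test_that("AsLS on pure drift leaves almost nothing in the corrected signal", {
  ds <- generate_dataset(n_tea = 1, n_insect = 1, seed = 2, n_points = 2048)
  y <- ds$truth[[1]]$true_baseline + 1   # offset so the bound is meaningful
  # penalty matched to the drift band absorbs the whole drift
  fit <- asls(y, lam = 1e4)
  expect_lt(max(abs(fit$corrected)), 1e-3 * max(abs(y)))
})

test_that("AirPLS: zero input converges immediately to a zero baseline", {
  fit <- airpls(numeric(64))
  expect_equal(fit$baseline, numeric(64))
  expect_equal(fit$n_iterations, 1L)
  expect_true(fit$converged)
})

test_that("AirPLS recovers a pure sinusoidal drift to better than 1%", {
  x <- seq(0, 40, length.out = 2048)
  drift <- 0.5 * sin(2 * pi * x / 25 + 0.4)
  fit <- airpls(drift, lam = 1e4)
  expect_lt(sqrt(mean((fit$baseline - drift)^2)), 0.01 * 0.5)
})

test_that("AirPLS final weights vanish exactly at peak points", {
  sig <- drift_peak_signal(seed = 4)
  fit <- airpls(sig$y)
  at_or_above <- sig$y >= fit$baseline
  expect_true(all(fit$weights[at_or_above] == 0))
  expect_true(all(fit$weights[!at_or_above] > 0))
  expect_true(all(fit$weights <= 1))
})

test_that("AsLS and AirPLS are translation-equivariant in the signal value", {
  set.seed(8)
  y <- rnorm(120) + 2 * exp(-((seq_len(120) - 60) / 5)^2)
  for (shift in c(-5, 13.7)) {
    expect_equal(asls(y + shift)$baseline, asls(y)$baseline + shift,
                 tolerance = 1e-7)
    expect_equal(airpls(y + shift)$baseline, airpls(y)$baseline + shift,
                 tolerance = 1e-7)
  }
})

test_that("BEADS: zero input decomposes to zeros", {
  d <- beads(numeric(100))
  expect_equal(d$sparse_signal, numeric(100))
  expect_equal(d$baseline, numeric(100))
  expect_equal(d$noise, numeric(100))
})

test_that("BEADS reconstruction x + f + w = y is exact by construction", {
  set.seed(21)
  x <- seq(0, 1, length.out = 300)
  for (i in 1:3) {
    y <- 0.4 * sin(2 * pi * x + i) + rnorm(300, 0, 0.05) +
      2 * exp(-((x - 0.3 * i) / 0.01)^2)
    d <- suppressWarnings(beads(y))
    recon <- d$sparse_signal + d$baseline + d$noise
    expect_lt(max(abs(recon - y)), 1e-10 * max(abs(y)))
  }
})

test_that("BEADS routes a peak-free low-frequency signal into the baseline", {
  x <- seq(0, 1, length.out = 500)
  y <- 0.5 * sin(2 * pi * x)
  d <- suppressWarnings(beads(y))
  expect_lt(max(abs(d$sparse_signal)), 0.05 * max(abs(y)))
  expect_lt(sqrt(mean((d$baseline - y)^2)), 0.1 * 0.5)
})

test_that("BEADS parameter validation", {
  y <- rnorm(50)
  expect_error(beads(y[1:4]), class = "thzfb_invalid_argument")
  expect_error(beads(y, cutoff = 0.7), class = "thzfb_invalid_argument")
  expect_error(beads(y, r = -1), class = "thzfb_invalid_argument")
  expect_error(beads(y, delta = 0), class = "thzfb_invalid_argument")
})

test_that("correct_set: identity, row independence, provenance", {
  ds <- generate_dataset(n_tea = 3, n_insect = 2, seed = 6, n_points = 256)
  none <- correct_set(ds$data, "none")
  expect_identical(none$features, ds$data$features)
  expect_equal(none$metadata$correction$method, "none")

  corr <- correct_set(ds$data, "asls", lam = 1e4)
  for (i in seq_len(5)) {
    expect_equal(corr$features[i, ],
                 asls(ds$data$features[i, ], lam = 1e4)$corrected)
  }
  expect_equal(corr$metadata$correction$params$lam, 1e4)

  expect_error(correct_set(ds$data, "asls", cutoff = 0.1),
               class = "thzfb_invalid_argument")
})

test_that("correction shrinks the corrected-vs-true-signal error on a drifting set", {
  # positive-peaked rows (spectrum-like) with known per-row drift
  sigs <- lapply(1:6, function(s) drift_peak_signal(seed = s, n = 1024))
  feats <- do.call(rbind, lapply(sigs, `[[`, "y"))
  true_signal <- do.call(rbind, lapply(sigs, function(s) s$y - s$drift))
  set <- spectral_set(feats, rep(c("a", "b"), 3), sigs[[1]]$x,
                      rep("calibration", 6), axis_unit = "ps")
  rmse <- function(m) sqrt(rowMeans((m - true_signal)^2))
  uncorrected <- mean(rmse(correct_set(set, "none")$features))
  corrected <- mean(rmse(correct_set(set, "airpls")$features))
  expect_lt(corrected, uncorrected)
})
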