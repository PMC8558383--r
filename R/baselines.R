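# sparse (n - order) x n finite-difference matrix with the alternating
# binomial stencil, e.g. order 2 -> rows (1, -2, 1)
diff_matrix <- function(n, order) {
  stencil <- (-1)^(order:0) * choose(order, 0:order)
  Matrix::bandSparse(n - order, n, k = 0:order,
                     diagonals = lapply(stencil, rep, n - order))
}

#' Whittaker smoother (weighted penalized least squares)
#'
#' Solves the penalized least-squares problem
#' \deqn{\min_z \sum_i \omega_i (y_i - z_i)^2 + \lambda \|D z\|^2}
#' whose normal equations are `(W + lambda * D'D) z = W y`, with `D` the
#' `diff_order`-th finite-difference matrix.  The system is banded
#' (bandwidth `diff_order`) and is solved with a sparse Cholesky
#' factorization, so the cost is linear in `length(y)`.
#'
#' @param y numeric signal.
#' @param weights nonnegative weights, same length as `y` (default all 1).
#' @param lam smoothness penalty lambda (> 0 unless some weight is
#'   positive).
#' @param diff_order order of the difference penalty (default 2).
#' @return The smoothed sequence `z`, the exact minimizer.
#' @export
#' @examples
#' z <- whittaker_smooth(rnorm(100) + sin(seq(0, 3, length.out = 100)),
#'                       lam = 100)
whittaker_smooth <- function(y, weights = rep(1, length(y)), lam = 1e5,
                             diff_order = 2L) {
  n <- length(y)
  if (!is_count(diff_order, min = 1)) {
    stop_invalid("'diff_order' must be a positive integer")
  }
  if (n < diff_order + 1L) {
    stop_invalid("signal shorter than diff_order + 1")
  }
  if (length(weights) != n || any(weights < 0) || anyNA(weights)) {
    stop_invalid("'weights' must be nonnegative and match 'y' in length")
  }
  if (!is_scalar_num(lam) || lam < 0) stop_invalid("'lam' must be >= 0")
  if (all(weights == 0) && lam == 0) {
    stop_invalid("all-zero weights with lam = 0: singular system",
                 class = "thzfb_singular_system")
  }
  D <- diff_matrix(n, diff_order)
  C <- Matrix::Diagonal(n, x = weights) + lam * Matrix::crossprod(D)
  as.vector(Matrix::solve(C, weights * y))
}

#' Container for an iterative baseline fit
#' @noRd
baseline_fit <- function(y, baseline, weights, n_iterations, converged,
                         method, params) {
  structure(list(baseline = baseline, corrected = y - baseline,
                 weights = weights, n_iterations = n_iterations,
                 converged = converged, method = method, params = params),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> method=%s, %d iteration(s), converged=%s\n",
              x$method, x$n_iterations, x$converged))
  invisible(x)
}

#' Asymmetric least squares (AsLS) baseline estimation
#'
#' Iterated Whittaker smoothing with asymmetric weights: points above
#' the current baseline (peak candidates) get the small weight `p`,
#' points on or below it get `1 - p`.  With `p << 1` the fit hugs the
#' lower envelope of the signal — the slowly varying scattering drift —
#' while ignoring positive peaks.  Iteration stops when the weight
#' vector changes by at most `tol` (default: not at all) or after
#' `max_iter` rounds.
#'
#' @param y numeric signal (a spectrum or a trace).
#' @param lam smoothness penalty (default 1e5).
#' @param p asymmetry parameter in (0, 1); commonly 0.001-0.1
#'   (default 0.01).
#' @param diff_order difference order of the penalty (default 2).
#' @param max_iter iteration cap (default 50).
#' @param tol maximum allowed absolute weight change for convergence
#'   (default 0, i.e. exact weight equality).
#' @return A `baseline_fit` with elements `baseline`, `corrected`
#'   (`y - baseline`), final `weights`, `n_iterations`, `converged`.
#' @export
#' @examples
#' x <- seq(0, 1, length.out = 400)
#' y <- 0.3 * x^3 + exp(-((x - 0.5) / 0.02)^2)
#' fit <- asls(y, lam = 1e4, p = 0.01)
asls <- function(y, lam = 1e5, p = 0.01, diff_order = 2L, max_iter = 50L,
                 tol = 0) {
  if (!is_scalar_num(p) || p <= 0 || p >= 1) {
    stop_invalid("'p' must lie strictly between 0 and 1")
  }
  if (!is_count(max_iter)) stop_invalid("'max_iter' must be >= 1")
  n <- length(y)
  w <- rep(1, n)
  z <- y
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    z <- whittaker_smooth(y, w, lam, diff_order)
    w_new <- ifelse(y > z, p, 1 - p)
    if (max(abs(w_new - w)) <= tol) {
      converged <- TRUE
      w <- w_new
      break
    }
    w <- w_new
  }
  baseline_fit(y, z, w, iter, converged, "asls",
               list(lam = lam, p = p, diff_order = diff_order,
                    max_iter = max_iter, tol = tol))
}

#' Adaptive iteratively reweighted penalized least squares (AirPLS)
#'
#' Baseline fitting in which the weights are re-derived at every
#' iteration from the negative residuals only: points at or above the
#' current baseline are treated as peak contributions and get weight 0;
#' points below it get weight `exp(t * (y_i - z_i) / |d|)`, where `t` is
#' the iteration number and `|d|` the L1 norm of the negative residual
#' vector.  Iteration ends when `|d| < 0.001 * |y|` (L1 norms) or at
#' `max_iter`.
#'
#' @param y numeric signal.
#' @param lam smoothness penalty (default 1e4).
#' @param diff_order difference order (default 2).
#' @param max_iter iteration cap (default 50).
#' @return A `baseline_fit`; `weights` is the final weight vector
#'   (exactly 0 wherever `y >= baseline`).
#' @export
airpls <- function(y, lam = 1e4, diff_order = 2L, max_iter = 50L) {
  if (!is_count(max_iter)) stop_invalid("'max_iter' must be >= 1")
  n <- length(y)
  w <- rep(1, n)
  z <- numeric(n)
  abs_y <- sum(abs(y))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    z <- whittaker_smooth(y, w, lam, diff_order)
    r <- y - z
    neg <- r < 0
    dnorm1 <- sum(abs(r[neg]))
    if (dnorm1 == 0 || dnorm1 < 0.001 * abs_y) {
      converged <- TRUE
      w[!neg] <- 0
      w[neg] <- exp(iter * r[neg] / max(dnorm1, .Machine$double.xmin))
      break
    }
    w[!neg] <- 0
    w[neg] <- exp(iter * r[neg] / dnorm1)
  }
  baseline_fit(y, z, w, iter, converged, "airpls",
               list(lam = lam, diff_order = diff_order, max_iter = max_iter))
}

# Banded high-pass filter matrices for BEADS: H = B A^{-1}.
# Stencils follow the standard zero-phase construction: B is the
# 2*order-th difference high-pass numerator, A = B + t * lowpass with
# t = ((1 - cos wc) / (1 + cos wc))^order fixing the cut-off.
beads_filters <- function(n, filter_order, cutoff) {
  b <- c(1, -1)
  if (filter_order > 1) {
    for (i in seq_len(filter_order - 1L)) b <- convolve(b, rev(c(-1, 2, -1)),
                                                        type = "open")
  }
  b <- convolve(b, rev(c(-1, 1)), type = "open")
  a <- 1
  for (i in seq_len(filter_order)) a <- convolve(a, rev(c(1, 2, 1)),
                                                 type = "open")
  omc <- 2 * pi * cutoff
  tt <- ((1 - cos(omc)) / (1 + cos(omc)))^filter_order
  a <- b + tt * a
  ks <- -filter_order:filter_order
  A <- Matrix::bandSparse(n, n, k = ks,
                          diagonals = lapply(seq_along(ks), function(i)
                            rep(a[i], n - abs(ks[i]))))
  B <- Matrix::bandSparse(n, n, k = ks,
                          diagonals = lapply(seq_along(ks), function(i)
                            rep(b[i], n - abs(ks[i]))))
  list(A = A, B = B)
}

#' BEADS: joint baseline estimation and denoising using sparsity
#'
#' Decomposes a spectrum as `y = x + f + w`: sparse peaks `x` with
#' sparse derivatives, a low-pass baseline `f`, and noise `w`.  The
#' peaks are recovered by majorization-minimization of an asymmetric
#' penalized criterion built on a banded zero-phase high-pass filter
#' `H = B A^{-1}`; each iteration forms the diagonal majorizer of the
#' smoothed absolute-value penalties (signal term and derivative orders
#' 1..2) and solves one banded system.  The baseline is then read off as
#' `f = y - x - H(y - x)` and the noise as `w = H(y - x)`, so the
#' decomposition reconstructs `y` exactly by construction.
#'
#' @param y numeric signal, length >= 8.
#' @param filter_order high-pass filter order (1 or 2; default 1).
#' @param cutoff normalized cut-off frequency in (0, 0.5) cycles/sample
#'   (default 0.006).
#' @param r asymmetry ratio (> 0): negative excursions of `x` are
#'   penalized `r` times more than positive ones; default 6 suits
#'   positive-peaked amplitude spectra.
#' @param lam0,lam1,lam2 nonnegative regularization weights for the
#'   signal and its first/second differences.  Defaults scale with the
#'   signal amplitude: `a = 0.02 * max(abs(y))`, `lam0 = 0.5 a`,
#'   `lam1 = 5 a`, `lam2 = 4 a`.
#' @param delta smoothing floor for the non-differentiable penalty
#'   (|v| replaced by max(|v|, delta); default 1e-6).
#' @param max_iter MM iteration cap (default 30).
#' @param tol relative-change stopping tolerance on `x` (default 1e-3;
#'   the MM tail is sublinear near the delta-smoothed kink of the
#'   penalty, and step changes at this level are far below the noise
#'   floor of any realistic spectrum).
#' @return An object of class `beads_decomposition` with
#'   `sparse_signal` (x), `baseline` (f), `noise` (w), `n_iterations`,
#'   `converged`.  A warning is emitted if `max_iter` is reached without
#'   meeting `tol`.
#' @export
beads <- function(y, filter_order = 1L, cutoff = 0.006, r = 6,
                  lam0 = NULL, lam1 = NULL, lam2 = NULL,
                  delta = 1e-6, max_iter = 30L, tol = 1e-3) {
  n <- length(y)
  if (n < 8L) stop_invalid("'y' must have length >= 8")
  if (!is_count(filter_order) || filter_order > 2) {
    stop_invalid("'filter_order' must be 1 or 2")
  }
  if (!is_scalar_num(cutoff) || cutoff <= 0 || cutoff >= 0.5) {
    stop_invalid("'cutoff' must lie in (0, 0.5)")
  }
  if (!is_scalar_num(r) || r <= 0) stop_invalid("'r' must be positive")
  if (!is_scalar_num(delta) || delta <= 0) {
    stop_invalid("'delta' must be positive")
  }
  amp <- 0.02 * max(abs(y))
  if (is.null(lam0)) lam0 <- 0.5 * amp
  if (is.null(lam1)) lam1 <- 5 * amp
  if (is.null(lam2)) lam2 <- 4 * amp
  if (lam0 < 0 || lam1 < 0 || lam2 < 0) {
    stop_invalid("regularization weights must be nonnegative")
  }

  filt <- beads_filters(n, filter_order, cutoff)
  A <- filt$A
  B <- filt$B
  BTB <- Matrix::crossprod(B)
  D1 <- diff_matrix(n, 1L)
  D2 <- diff_matrix(n, 2L)

  # pre-iteration vector: BTB A^{-1} y minus the asymmetry offset
  # lam0 * A' * (1 - r)/2 * 1 (A' per the original BEADS formulation)
  dvec <- as.vector(BTB %*% Matrix::solve(A, y)) -
    lam0 * as.vector(Matrix::t(A) %*% rep((1 - r) / 2, n))

  x <- y
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # diagonal majorizers of the smoothed |.| penalties
    psi <- (1 + r) / (4 * pmax(abs(x), delta))
    l1 <- 1 / pmax(abs(as.vector(D1 %*% x)), delta)
    l2 <- 1 / pmax(abs(as.vector(D2 %*% x)), delta)
    M <- Matrix::Diagonal(n, 2 * lam0 * psi) +
      lam1 * Matrix::crossprod(D1, Matrix::Diagonal(n - 1, l1) %*% D1) +
      lam2 * Matrix::crossprod(D2, Matrix::Diagonal(n - 2, l2) %*% D2)
    C <- BTB + Matrix::crossprod(A, M %*% A)
    x_new <- as.vector(A %*% Matrix::solve(C, dvec))
    step <- sqrt(sum((x_new - x)^2))
    x <- x_new
    if (step <= tol * max(sqrt(sum(x^2)), .Machine$double.xmin)) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max(abs(y)) > 0) {
    warning("beads: maximum iterations reached without convergence",
            call. = FALSE)
  }
  if (max(abs(y)) == 0) converged <- TRUE

  hp <- as.vector(B %*% Matrix::solve(A, y - x))
  f <- y - x - hp
  structure(list(sparse_signal = x, baseline = f, noise = hp,
                 n_iterations = iter, converged = converged,
                 params = list(filter_order = filter_order, cutoff = cutoff,
                               r = r, lam0 = lam0, lam1 = lam1, lam2 = lam2,
                               delta = delta, max_iter = max_iter)),
            class = "beads_decomposition")
}

#' @export
print.beads_decomposition <- function(x, ...) {
  cat(sprintf("<beads_decomposition> %d samples, %d iteration(s)\n",
              length(x$sparse_signal), x$n_iterations))
  invisible(x)
}

#' Baseline-correct every row of a spectral set
#'
#' Applies one of the baseline-correction algorithms independently to
#' each sample (row); `method = "none"` is the identity.  For
#' [asls()]/[airpls()] the corrected row is `y - baseline`; for
#' [beads()] it is the sparse peak component `x`.  Provenance (method
#' and parameters) is recorded in the set metadata.
#'
#' @param data a [spectral_set].
#' @param method `"none"`, `"asls"`, `"airpls"` or `"beads"`.
#' @param ... method parameters forwarded to the estimator (e.g. `lam`,
#'   `p` for AsLS).  Passing a parameter the method does not accept is
#'   an error.
#' @return The corrected [spectral_set].
#' @export
#' @examples
#' ds <- generate_dataset(n_tea = 4, n_insect = 4, seed = 3,
#'                        n_points = 256)
#' corr <- correct_set(ds$data, "airpls", lam = 1e4)
correct_set <- function(data, method = c("none", "asls", "airpls", "beads"),
                        ...) {
  stopifnot(inherits(data, "spectral_set"))
  method <- match.arg(method)
  params <- list(...)
  out <- data
  if (method != "none") {
    fun <- switch(method, asls = asls, airpls = airpls, beads = beads)
    ok <- names(params) %in% names(formals(fun))[-1L]
    if (length(params) && (!all(nzchar(names(params))) || !all(ok))) {
      stop_invalid(sprintf("invalid parameter(s) for method '%s': %s", method,
                           paste(names(params)[!ok], collapse = ", ")))
    }
    out$features <- t(apply(data$features, 1L, function(row) {
      fit <- do.call(fun, c(list(row), params))
      if (method == "beads") fit$sparse_signal else fit$corrected
    }))
  }
  out$metadata$correction <- list(method = method, params = params)
  out
}
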