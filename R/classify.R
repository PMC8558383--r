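#' Fit (store) a k-nearest-neighbour model
#'
#' KNN is a lazy learner: fitting stores the calibration features and
#' labels verbatim.
#'
#' @param features numeric matrix, samples x variables.
#' @param labels class labels, one per row (factor or coercible).
#' @param k number of neighbours, `1 <= k <= nrow(features)`.
#' @return An object of class `knn_model`.
#' @export
knn_fit <- function(features, labels, k = 3L) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  if (nrow(features) != length(labels)) {
    stop_invalid("label count must equal the row count")
  }
  if (!is_count(k) || k > nrow(features)) {
    stop_invalid("'k' must be an integer between 1 and the number of rows")
  }
  structure(list(training_features = features, training_labels = labels,
                 k = as.integer(k)),
            class = "knn_model")
}

#' Classify queries by majority vote among Euclidean nearest neighbours
#'
#' For each query row, the Euclidean distances to every training row
#' are computed and the k smallest vote with equal weight.  Vote ties
#' are broken by the class of the nearest neighbour among the tied
#' classes, then by the lowest class index — a deterministic rule.
#'
#' @param model a `knn_model`.
#' @param queries numeric matrix (or vector for a single query) with the
#'   training column count.
#' @return Factor of predicted labels with the training levels.
#' @export
#' @examples
#' m <- knn_fit(rbind(c(0, 0), c(1, 0), c(5, 5)), c("A", "A", "B"), k = 3)
#' knn_predict(m, c(0.4, 0))
knn_predict <- function(model, queries) {
  stopifnot(inherits(model, "knn_model"))
  X <- model$training_features
  if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1L)
  queries <- as.matrix(queries)
  if (ncol(queries) != ncol(X)) {
    stop_invalid("query column count must match the training column count")
  }
  lev <- levels(model$training_labels)
  lab_int <- as.integer(model$training_labels)
  k <- model$k
  # squared distances via the expansion |q - x|^2 = |q|^2 - 2 q.x + |x|^2
  x2 <- rowSums(X^2)
  d2 <- outer(rowSums(queries^2), x2, "+") - 2 * queries %*% t(X)
  pred <- integer(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    ord <- order(d2[i, ], lab_int)      # distance, then class index
    nn <- ord[seq_len(k)]
    votes <- tabulate(lab_int[nn], nbins = length(lev))
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      # nearest neighbour among the tied classes decides
      first_hit <- lab_int[nn][match(TRUE, lab_int[nn] %in% top)]
      top <- first_hit
    }
    pred[i] <- top
  }
  factor(lev[pred], levels = lev)
}

#' Fit a two-class PLS-DA model
#'
#' Partial least squares regression of a 0/1 dummy-coded class response
#' on mean-centered features, followed by thresholding of the predicted
#' response.  Components are extracted sequentially: each weight vector
#' is the dominant covariance direction between the feature residuals
#' and the response residuals, scores are projected out (deflation), and
#' the accumulated decomposition is collapsed into one regression
#' vector.  Features are centered only — amplitude magnitude is the
#' discriminative signal, so no unit-variance scaling is applied.
#'
#' @param features numeric matrix, samples x variables.
#' @param labels labels with exactly two classes present; the first
#'   factor level is coded 0, the second 1.
#' @param n_components number of latent components (>= 1, at most the
#'   rank of the centered feature matrix).
#' @param threshold response cut separating the classes (default 0.5).
#' @return An object of class `plsda_model` with the latent
#'   decomposition (`x_weights`, `x_loadings`, `y_loadings`), the
#'   collapsed `coefficients`, centers and `threshold`.
#' @export
plsda_fit <- function(features, labels, n_components = 2L, threshold = 0.5) {
  X <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) {
    stop_invalid("exactly two classes must be present")
  }
  if (nrow(X) != length(labels)) {
    stop_invalid("label count must equal the row count")
  }
  if (!is_count(n_components)) {
    stop_invalid("'n_components' must be a positive integer")
  }
  y <- as.double(as.integer(labels) - 1L)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  n_var <- ncol(X)
  W <- P <- matrix(0, n_var, n_components)
  q <- numeric(n_components)
  tol <- 1e-12 * max(1, sum(Xc^2))
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xc, yc))
    wn <- sqrt(sum(w^2))
    if (wn^2 <= tol || sum(Xc^2) <= tol) {
      stop_invalid(sprintf(
        "rank deficiency: only %d component(s) supported by the data", a - 1L),
        class = "thzfb_rank_deficiency")
    }
    w <- w / wn
    tt <- drop(Xc %*% w)
    tt2 <- sum(tt^2)
    p <- drop(crossprod(Xc, tt)) / tt2
    qa <- sum(yc * tt) / tt2
    Xc <- Xc - tcrossprod(tt, p)
    yc <- yc - qa * tt
    W[, a] <- w
    P[, a] <- p
    q[a] <- qa
  }
  coeff <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(n_components = n_components, x_mean = x_mean,
                 y_mean = y_mean, x_weights = W, x_loadings = P,
                 y_loadings = q, coefficients = coeff,
                 threshold = threshold, levels = levels(labels)),
            class = "plsda_model")
}

#' Predict the continuous PLS-DA response
#'
#' @param model a `plsda_model`.
#' @param queries numeric matrix (or single-query vector).
#' @return Numeric vector of predicted responses on the 0/1 dummy scale.
#' @export
plsda_response <- function(model, queries) {
  stopifnot(inherits(model, "plsda_model"))
  if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1L)
  queries <- as.matrix(queries)
  if (ncol(queries) != length(model$x_mean)) {
    stop_invalid("query column count must match the training column count")
  }
  drop(sweep(queries, 2L, model$x_mean) %*% model$coefficients) + model$y_mean
}

#' Classify queries with a fitted PLS-DA model
#'
#' Assigns the second class (dummy code 1) when the predicted response
#' strictly exceeds the threshold; a response exactly at the threshold
#' goes to the first class (deterministic boundary rule).
#'
#' @inheritParams plsda_response
#' @return Factor of predicted labels.
#' @export
plsda_predict <- function(model, queries) {
  resp <- plsda_response(model, queries)
  factor(model$levels[ifelse(resp > model$threshold, 2L, 1L)],
         levels = model$levels)
}

#' Choose the PLS-DA component count by stratified cross-validation
#'
#' Stratified `folds`-fold cross-validation on the calibration data,
#' picking the component count (up to `max_components`) with the
#' highest CV accuracy; ties go to the smaller count.  Fold assignment
#' is seeded, so the selection is reproducible.
#'
#' @param features,labels calibration data (two classes).
#' @param max_components largest count tried (capped at the data rank).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return The selected component count (integer).
#' @export
plsda_select_ncomp <- function(features, labels, max_components = 10L,
                               folds = 5L, seed = 1L) {
  X <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  n <- nrow(X)
  cap <- max(1L, min(max_components, ncol(X), n - ceiling(n / folds) - 1L))
  fold_id <- with_seed_if(seed, {
    id <- integer(n)
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
  acc <- numeric(cap)
  for (nc in seq_len(cap)) {
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- tryCatch(plsda_fit(X[tr, , drop = FALSE], labels[tr], nc),
                      error = function(e) NULL)
      if (is.null(fit)) next
      hits <- hits + sum(plsda_predict(fit, X[!tr, , drop = FALSE]) ==
                           labels[!tr])
    }
    acc[nc] <- hits / n
  }
  which.max(acc)  # first maximum = smallest count on ties
}

predict_labels <- function(model, features) {
  if (inherits(model, "knn_model")) {
    knn_predict(model, features)
  } else if (inherits(model, "plsda_model")) {
    plsda_predict(model, features)
  } else {
    stop_invalid("unsupported model type")
  }
}

#' Calibration/prediction evaluation report
#'
#' Applies a fitted model to both populations of a labeled set and
#' tabulates, per split, the misclassification count, the accuracy as a
#' percentage rounded half-up to two decimals (so 46/51 correct prints
#' as 90.20), and the 2 x 2 confusion table.
#'
#' @param model a `knn_model` or `plsda_model`.
#' @param data a [spectral_set] carrying a calibration/prediction split.
#' @return An object of class `evaluation_report` with fields
#'   `n_misclassified_calibration`, `accuracy_calibration`,
#'   `n_misclassified_prediction`, `accuracy_prediction`, and
#'   `confusion` (named list of tables).
#' @export
evaluate <- function(model, data) {
  stopifnot(inherits(data, "spectral_set"))
  out <- list()
  for (sp in c("calibration", "prediction")) {
    rows <- data$split == sp
    if (!any(rows)) {
      stop_invalid(sprintf("the %s split is empty", sp))
    }
    truth <- factor(as.character(data$labels[rows]),
                    levels = levels(data$labels))
    pred <- factor(as.character(
      predict_labels(model, data$features[rows, , drop = FALSE])),
      levels = levels(data$labels))
    mis <- sum(pred != truth)
    out[[sp]] <- list(
      n = sum(rows), mis = mis,
      acc = round_half_up(100 * (1 - mis / sum(rows)), 2),
      confusion = table(truth = truth, predicted = pred)
    )
  }
  structure(list(
    n_misclassified_calibration = out$calibration$mis,
    accuracy_calibration = out$calibration$acc,
    n_misclassified_prediction = out$prediction$mis,
    accuracy_prediction = out$prediction$acc,
    n_calibration = out$calibration$n,
    n_prediction = out$prediction$n,
    confusion = list(calibration = out$calibration$confusion,
                     prediction = out$prediction$confusion)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> calibration: %d/%d misclassified (%.2f%%); %s",
    x$n_misclassified_calibration, x$n_calibration, x$accuracy_calibration,
    sprintf("prediction: %d/%d misclassified (%.2f%%)\n",
            x$n_misclassified_prediction, x$n_prediction,
            x$accuracy_prediction)))
  invisible(x)
}
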