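#' SVM configuration
#'
#' Configuration for the RBF-kernel support vector classifiers used
#' throughout the package. The kernel is fixed to the radial basis function
#' and probabilities come from a sigmoid fit on cross-validated decision
#' values; the tunables are the grid of regularization parameters `c` and
#' kernel widths `g` searched by cross-validated accuracy. Defaults are the
#' canonical coarse libsvm grid. Ties in grid accuracy resolve to the
#' smallest `c`, then the smallest `g`. Composition features already lie in
#' [0, 1], so no feature scaling is applied anywhere.
#'
#' @param c_grid Positive regularization parameter values (default
#'   `2^seq(-5, 15, 2)`).
#' @param g_grid Positive RBF width values (default `2^seq(-15, 3, 2)`).
#' @param cv_folds_for_grid Folds for the grid-search cross-validation
#'   (default 5).
#' @return An object of class `svm_config`.
#' @examples
#' svm_config(c_grid = 2^c(1, 3), g_grid = 2^c(-5, -3))
#' @export
svm_config <- function(c_grid = 2^seq(-5, 15, 2),
                       g_grid = 2^seq(-15, 3, 2),
                       cv_folds_for_grid = 5L) {
  stopifnot(length(c_grid) >= 1L, all(c_grid > 0),
            length(g_grid) >= 1L, all(g_grid > 0),
            cv_folds_for_grid >= 2L)
  structure(list(kernel = "RBF",
                 c_grid = sort(unique(as.numeric(c_grid))),
                 g_grid = sort(unique(as.numeric(g_grid))),
                 cv_folds_for_grid = as.integer(cv_folds_for_grid),
                 probability_calibration = "sigmoid-on-decision-values"),
            class = "svm_config")
}

#' Reduced grid-search configuration
#'
#' A 4 x 4 subgrid of the canonical grid, centered on the region where
#' composition features (vectors in \[0, 1\] with row norms at most 1)
#' place the optimum. Used for the heavier protocols (per-pair feature
#' selection, ensemble cross-validation, permutation tests) where the full
#' 11 x 10 grid buys little accuracy at 7x the cost.
#'
#' @return An `svm_config` with `c_grid = 2^c(-1, 1, 3, 5)` and
#'   `g_grid = 2^c(-7, -5, -3, -1)`.
#' @export
svm_config_reduced <- function() {
  svm_config(c_grid = 2^c(-1, 1, 3, 5), g_grid = 2^c(-7, -5, -3, -1))
}

# Fixed single-cell configuration used to score candidate features during
# forward selection; see select_features() for the rationale.
svm_config_selection <- function() {
  svm_config(c_grid = 8, g_grid = 2^-3)
}

# Stratified k-fold partition: returns a list of k held-out index vectors.
# Classes are shuffled independently and dealt round-robin so every fold has
# the same class balance up to rounding.
make_stratified_folds <- function(y, k) {
  stopifnot(is.logical(y), k >= 2L, k <= length(y))
  folds <- rep(list(integer(0)), k)
  offset <- 0L
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(y == cls))
    # continue the round-robin across classes so no fold is left empty when
    # k approaches the sample count (leave-one-out)
    assignment <- (offset + seq_along(idx) - 1L) %% k + 1L
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assignment == f])
    offset <- offset + length(idx)
  }
  lapply(folds, sort)
}

# y is logical (TRUE = positive). Factor levels are fixed so that libsvm's
# internal class order is stable, but orientation is still read back from the
# decision-value column name rather than assumed.
fit_rbf <- function(X, y, cost, gamma) {
  if (length(unique(y)) < 2L) stop("cannot fit a classifier on single-class labels")
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("pos", "neg"))
  e1071::svm(X, yf, type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

# Oriented decision values: positive value => positive class, regardless of
# libsvm's internal class order.
decision_values <- function(model, X) {
  pr <- predict(model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  sgn <- if (identical(first, "pos")) 1 else -1
  sgn * as.numeric(dv[, 1])
}

# orientation of the raw libsvm dual expansion (t(coefs) %*% K - rho) for a
# fitted model; +1 when a positive raw value means the positive class
model_orientation <- function(model) {
  if (identical(model$levels[1], "pos")) 1 else -1
}

# Mean held-out accuracy over the given folds at fixed (cost, gamma).
cv_accuracy <- function(X, y, cost, gamma, folds) {
  accs <- vapply(folds, function(test) {
    fit <- fit_rbf(X[-test, , drop = FALSE], y[-test], cost, gamma)
    mean((decision_values(fit, X[test, , drop = FALSE]) >= 0) == y[test])
  }, numeric(1))
  mean(accs)
}

# Held-out oriented decision values pooled over folds, plus per-fold accuracy.
cv_decision_values <- function(X, y, cost, gamma, folds) {
  dec <- numeric(length(y))
  accs <- numeric(length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    fit <- fit_rbf(X[-test, , drop = FALSE], y[-test], cost, gamma)
    dec[test] <- decision_values(fit, X[test, , drop = FALSE])
    accs[f] <- mean((dec[test] >= 0) == y[test])
  }
  list(decision_values = dec, fold_accuracies = accs)
}

# Grid search by cross-validated accuracy; ties go to the smallest cost, then
# the smallest gamma (grids are sorted ascending and only strict improvements
# replace the incumbent).
grid_search <- function(X, y, config, folds) {
  best <- list(cost = NA_real_, gamma = NA_real_, accuracy = -Inf)
  grid <- expand.grid(gamma = config$g_grid, cost = config$c_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("cost", "gamma")]
  grid$accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    acc <- cv_accuracy(X, y, grid$cost[i], grid$gamma[i], folds)
    grid$accuracy[i] <- acc
    if (acc > best$accuracy) {
      best <- list(cost = grid$cost[i], gamma = grid$gamma[i], accuracy = acc)
    }
  }
  best$grid <- grid
  best
}

# Platt sigmoid calibration on decision values (Newton iteration with
# backtracking, the standard libsvm formulation). Returns c(A, B) such that
# P(positive | f) = 1 / (1 + exp(A * f + B)).
platt_fit <- function(dec, y, maxiter = 100L, minstep = 1e-10, sigma = 1e-12) {
  stopifnot(length(dec) == length(y), is.logical(y))
  prior1 <- sum(y); prior0 <- sum(!y)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  tt <- ifelse(y, hi, lo)

  nll <- function(A, B) {
    fApB <- dec * A + B
    sum(ifelse(fApB >= 0,
               tt * fApB + log1p(exp(-fApB)),
               (tt - 1) * fApB + log1p(exp(fApB))))
  }

  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- nll(A, B)
  for (it in seq_len(maxiter)) {
    fApB <- dec * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    d2 <- p * q
    h11 <- sigma + sum(dec * dec * d2)
    h22 <- sigma + sum(d2)
    h21 <- sum(dec * d2)
    d1 <- tt - p
    g1 <- sum(dec * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    stepsize <- 1
    while (stepsize >= minstep) {
      newA <- A + stepsize * dA
      newB <- B + stepsize * dB
      newf <- nll(newA, newB)
      if (newf < fval + 1e-4 * stepsize * gd) {
        A <- newA; B <- newB; fval <- newf
        break
      }
      stepsize <- stepsize / 2
    }
    if (stepsize < minstep) break
  }
  c(A = A, B = B)
}

platt_predict <- function(ab, dec) {
  fApB <- dec * ab[["A"]] + ab[["B"]]
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

# Cross squared Euclidean distances between rows of X (m x d) and SV (s x d),
# clamped at zero against cancellation.
cross_sqdist <- function(X, SV) {
  d2 <- outer(rowSums(X^2), rowSums(SV^2), "+") - 2 * tcrossprod(X, SV)
  d2[d2 < 0] <- 0
  d2
}

# RBF dual-expansion decision values from stored submodel state.
rbf_decision <- function(X, SV, coefs, rho, gamma, orientation) {
  K <- exp(-gamma * cross_sqdist(X, SV))
  unname(orientation * (drop(K %*% coefs) - rho))
}
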