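# NIPALS PLS1 on column-centered X and centered y (no variance scaling).
# Returns the regression coefficient matrix for every component count
# 1..ncomp (column a = coefficients using a components, on the original
# variable scale) plus intercepts, so cross-validation over a component
# grid costs one decomposition per fold.
pls1_nipals <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  ncomp <- min(ncomp, n - 1L, k)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - ybar
  W <- P <- matrix(0, k, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  a <- 0L
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break          # X deflated to noise floor
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-28) break
    p <- drop(crossprod(Xc, t)) / tt
    qh <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, p)
    yc <- yc - qh * t
    W[, h] <- w; P[, h] <- p; Tm[, h] <- t; q[h] <- qh
    a <- h
  }
  if (a == 0L) stop("degenerate X: no usable latent variable (zero variance)")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]
  # B_a = W (P'W)^{-1} q, accumulated per component count via
  # back-substitution on the unit-upper-triangular P'W
  PtW <- crossprod(P, W)
  B <- matrix(0, k, a)
  R <- matrix(0, k, a)             # R = W (P'W)^{-1}, built column by column
  for (h in seq_len(a)) {
    r <- W[, h]
    if (h > 1L) {
      r <- r - R[, seq_len(h - 1L), drop = FALSE] %*% PtW[seq_len(h - 1L), h]
    }
    R[, h] <- r
    B[, h] <- (if (h > 1L) B[, h - 1L] else 0) + R[, h] * q[h]
  }
  list(coefficients = B, intercept = ybar - drop(crossprod(B, xbar)),
       n_components = a, x_means = xbar, y_mean = ybar)
}

# Deterministic contiguous-block K-fold assignment by index.
block_folds <- function(n, folds) {
  folds <- min(folds, n)
  sort(rep(seq_len(folds), length.out = n))
}

# RMSECV per component count (1..ncomp) by K-fold CV with contiguous
# blocks. Rows with too few training samples cap the usable component count;
# unreachable counts get the error of the largest reachable one.
pls_rmsecv <- function(X, y, ncomp, folds) {
  n <- nrow(X)
  fold_id <- block_folds(n, folds)
  sse <- numeric(ncomp)
  for (f in unique(fold_id)) {
    test <- fold_id == f
    fit <- pls1_nipals(X[!test, , drop = FALSE], y[!test], ncomp)
    pred <- X[test, , drop = FALSE] %*% fit$coefficients
    pred <- sweep(pred, 2L, fit$intercept, `+`)
    a <- fit$n_components
    if (a < ncomp) {               # pad with the deepest available model
      pred <- cbind(pred, matrix(pred[, a], sum(test), ncomp - a))
    }
    sse <- sse + colSums((pred - y[test])^2)
  }
  sqrt(sse / n)
}

#' Partial least squares calibration with RMSECV component selection
#'
#' Fits a PLS1 model (NIPALS, column centering, no variance scaling) on the
#' full wavelength grid. The latent-variable count is chosen by minimizing
#' the root mean square error of cross-validation (RMSECV) over
#' `1..max_components`, computed with deterministic contiguous-block K-fold
#' assignment by sample index; ties resolve toward fewer components. The
#' returned model is refit on all calibration rows at the chosen count.
#'
#' @param X calibration spectra matrix `n x k`.
#' @param y nitrogen values, length `n`.
#' @param max_components largest candidate latent-variable count; capped at
#'   `min(n - 1, k)`.
#' @param folds number of CV folds (>= 2), default 10.
#' @param seed kept for interface symmetry and provenance; the block-fold
#'   assignment is deterministic so the seed does not alter the fit.
#' @return list with elements `model` (a `CalibrationModel` of kind
#'   `"PLS"`) and `cv` (a `CVResult`: `component_grid`, `rmsecv`, `chosen`).
#' @export
fit_pls <- function(X, y, max_components = 10L, folds = 10L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (folds < 2L) stop("folds must be >= 2")
  ncomp <- min(max_components, n - 1L, k)
  if (ncomp < 1L) stop("not enough samples/variables for PLS")
  rmsecv <- pls_rmsecv(X, y, ncomp, folds)
  chosen <- which.min(rmsecv)      # which.min: lowest index (fewest) on ties
  fit <- pls1_nipals(X, y, chosen)
  a <- fit$n_components
  model <- new_calibration_model(
    "PLS", seq_len(k), fit$coefficients[, a], fit$intercept[a],
    n_components = a,
    training_meta = list(P = k, folds = folds, seed = seed,
                         x_means = fit$x_means, y_mean = fit$y_mean))
  cv <- structure(list(component_grid = seq_len(ncomp), rmsecv = rmsecv,
                       chosen = chosen), class = "CVResult")
  list(model = model, cv = cv)
}
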