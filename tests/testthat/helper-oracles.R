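# Independent oracle implementations used to cross-check the package's
# algorithms. These deliberately use the most direct (slow, explicit)
# formulation of each computation and share no code with R/.

# Savitzky-Golay by explicit windowed least squares: at each point fit a
# polynomial over the (possibly truncated) window with lm() and take the
# fitted value at the point.
oracle_sg <- function(x, window, polyorder) {
  P <- length(x)
  w <- (window - 1L) %/% 2L
  out <- numeric(P)
  for (k in seq_len(P)) {
    lo <- max(1L, k - w); hi <- min(P, k + w)
    idx <- lo:hi
    d <- min(polyorder, length(idx) - 1L)
    if (d == 0L) {
      out[k] <- mean(x[idx])
    } else {
      fit <- stats::lm(y ~ stats::poly(t, d, raw = TRUE),
                       data = data.frame(t = idx, y = x[idx]))
      out[k] <- unname(stats::predict(fit, newdata = data.frame(t = k)))
    }
  }
  out
}

# SPXY joint distance by explicit double loop.
oracle_joint_distance <- function(X, y) {
  n <- nrow(X)
  dx <- dy <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dx[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    dy[i, j] <- abs(y[i] - y[j])
  }
  d <- matrix(0, n, n)
  if (max(dx) > 0) d <- d + dx / max(dx)
  if (max(dy) > 0) d <- d + dy / max(dy)
  d
}

# Kennard-Stone max-min selection by explicit search with explicit
# tie-breaking (lowest index).
oracle_kennard_stone <- function(d, n_select) {
  n <- nrow(d)
  best <- c(NA, NA); bestd <- -Inf
  for (j in 2:n) for (i in 1:(j - 1)) {
    if (d[i, j] > bestd) { bestd <- d[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_select) {
    cand <- setdiff(seq_len(n), sel)
    scores <- vapply(cand, function(c) min(d[c, sel]), numeric(1L))
    sel <- c(sel, cand[which.max(scores)])
  }
  sel
}

# Minimal NIPALS PLS1 (centering only), fixed component count; returns
# predictions for new data. Written independently of the package's
# accumulation scheme (explicit deflation, coefficients via solve()).
oracle_pls_predict <- function(Xtr, ytr, Xnew, a) {
  xbar <- colMeans(Xtr); ybar <- mean(ytr)
  E <- sweep(Xtr, 2, xbar); f <- ytr - ybar
  W <- P <- NULL; q <- c()
  for (h in seq_len(a)) {
    w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w); tt <- sum(t^2)
    p <- drop(crossprod(E, t)) / tt
    qh <- sum(f * t) / tt
    E <- E - outer(t, p); f <- f - qh * t
    W <- cbind(W, w); P <- cbind(P, p); q <- c(q, qh)
  }
  B <- W %*% solve(crossprod(P, W), q)
  drop(sweep(Xnew, 2, xbar) %*% B) + ybar
}

# K-fold RMSECV over a component grid, contiguous blocks by index,
# using the oracle PLS above.
oracle_rmsecv <- function(X, y, ncomp, folds) {
  n <- nrow(X)
  fold_id <- sort(rep(seq_len(folds), length.out = n))
  sapply(seq_len(ncomp), function(a) {
    sse <- 0
    for (f in seq_len(folds)) {
      test <- fold_id == f
      pred <- oracle_pls_predict(X[!test, , drop = FALSE], y[!test],
                                 X[test, , drop = FALSE], a)
      sse <- sse + sum((pred - y[test])^2)
    }
    sqrt(sse / n)
  })
}

# SPA by brute-force enumeration: for every start column and chain length,
# grow the chain with explicit qr-based orthogonal projections, fit lm()
# on the chain, score on validation; return the winner under the package's
# tie-break (shorter chain, then lower start).
oracle_spa <- function(Xcal, ycal, Xval, yval, max_vars) {
  k <- ncol(Xcal)
  xbar <- colMeans(Xcal)
  Xc <- sweep(Xcal, 2, xbar)
  best <- list(rmse = Inf, chain = integer(), start = Inf)
  for (j in seq_len(k)) {
    if (sum(Xc[, j]^2) < 1e-24) next
    chain <- j
    for (m in seq_len(max_vars)) {
      if (m > 1) {
        Q <- qr.Q(qr(Xc[, chain, drop = FALSE]))
        resid_norm <- vapply(seq_len(k), function(c) {
          if (c %in% chain) return(-Inf)
          r <- Xc[, c] - Q %*% crossprod(Q, Xc[, c])
          sum(r^2)
        }, numeric(1L))
        nxt <- which.max(resid_norm)
        if (resid_norm[nxt] < 1e-24) break
        chain <- c(chain, nxt)
      }
      beta <- stats::coef(stats::lm.fit(cbind(1, Xcal[, chain,
                                                      drop = FALSE]), ycal))
      pred <- drop(cbind(1, Xval[, chain, drop = FALSE]) %*% beta)
      r <- sqrt(mean((pred - yval)^2))
      better <- r < best$rmse - 1e-12 ||
        (abs(r - best$rmse) <= 1e-12 &&
           (length(chain) < length(best$chain) ||
              (length(chain) == length(best$chain) && j < best$start)))
      if (better) best <- list(rmse = r, chain = chain, start = j)
    }
  }
  best$chain
}

# Small noiseless single-band SpectraSet factory for recovery tests.
toy_profile <- function(soil = "loess", treatment = "95C",
                        scatter_sd = 0, noise_sd = 0,
                        sensitivity = 0.08, replicates = 16L,
                        n_gradients = 11L) {
  soil_profile(soil, treatment,
               baseline_level = 0.55, baseline_slope = 6e-5,
               bands = list(c(1000, 60, 0.02)),
               nitrogen_band = c(1160, 30, sensitivity),
               water_band = c(1385, 50, 0.02),
               scatter_sd = scatter_sd, noise_sd = noise_sd,
               nitrogen_min = 0.09, nitrogen_max = 0.93,
               n_gradients = n_gradients, replicates = replicates)
}
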