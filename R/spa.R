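#' Successive projections algorithm (SPA) wavelength selection
#'
#' Classic SPA forward selection: for every admissible starting column `j`,
#' a chain of up to `max_vars` columns is grown by repeatedly projecting
#' all remaining (column-centered) calibration columns onto the orthogonal
#' complement of the selected span and appending the column of maximal
#' residual norm - the mechanism that minimizes collinearity among chosen
#' wavelengths. Every prefix `chain[1:m]`, `m = 1..max_vars`, of every
#' chain is scored by fitting MLR (with intercept) on the calibration rows
#' and measuring RMSE on the held-out validation rows; the prefix with
#' minimal validation RMSE wins. Ties break toward the shorter chain, then
#' the lower starting index. All-zero (after centering: constant) columns
#' are excluded from candidacy.
#'
#' @param Xcal,ycal calibration spectra matrix and nitrogen vector.
#' @param Xval,yval validation spectra matrix and nitrogen vector, on the
#'   same wavelength grid.
#' @param max_vars largest chain length; default 30. Must satisfy
#'   `1 <= max_vars <= min(k, n_cal - 1)`.
#' @return integer vector of selected wavelength column indices (the
#'   winning chain, in selection order).
#' @export
spa_select <- function(Xcal, ycal, Xval, yval, max_vars = 30L) {
  Xcal <- as.matrix(Xcal); Xval <- as.matrix(Xval)
  n <- nrow(Xcal); k <- ncol(Xcal)
  max_vars <- as.integer(max_vars)
  if (max_vars < 1L || max_vars > min(k, n - 1L)) {
    stop("max_vars must satisfy 1 <= max_vars <= min(k, n_cal - 1)")
  }
  xbar <- colMeans(Xcal)
  Xc <- sweep(Xcal, 2L, xbar)
  Xv <- sweep(Xval, 2L, xbar)
  ybar <- mean(ycal)
  yc <- ycal - ybar
  norms0 <- colSums(Xc^2)
  admissible <- which(norms0 > 1e-24)
  if (length(admissible) == 0L) stop("all columns are zero: nothing to select")

  best <- list(rmse = Inf, chain = integer(), start = Inf)
  for (j in admissible) {
    res <- spa_chain_scores(Xc, yc, Xv, yval, ybar, j, max_vars)
    for (m in seq_along(res$rmse)) {
      r <- res$rmse[m]
      better <- r < best$rmse - 1e-12 ||
        (abs(r - best$rmse) <= 1e-12 &&
           (m < length(best$chain) ||
              (m == length(best$chain) && j < best$start)))
      if (better) {
        best <- list(rmse = r, chain = res$chain[seq_len(m)], start = j)
      }
    }
  }
  best$chain
}

# Grow one projection chain from start column j and return, for every
# prefix length, the validation RMSE of the MLR fit on that prefix.
# The Gram-Schmidt basis produced by the projections doubles as the QR
# factorization of the chain, so validation predictions accumulate one
# orthogonal component at a time (exactly OLS at every length).
spa_chain_scores <- function(Xc, yc, Xv, yval, ybar, j, max_vars) {
  n <- nrow(Xc); k <- ncol(Xc)
  chain <- integer(max_vars)
  rmse <- rep(Inf, max_vars)
  Xres <- Xc                       # calibration columns, progressively
  Vres <- Xv                       # orthogonalized; same transform applied
  pred <- rep(ybar, nrow(Xv))      # to the validation columns
  cur <- j
  for (m in seq_len(max_vars)) {
    chain[m] <- cur
    qcal <- Xres[, cur]
    qq <- sum(qcal^2)
    if (qq < 1e-24) { m <- m - 1L; break }
    gamma <- sum(qcal * yc) / qq
    pred <- pred + Vres[, cur] * gamma
    rmse[m] <- sqrt(mean((pred - yval)^2))
    if (m == max_vars) break
    # project remaining columns onto the orthogonal complement of qcal
    proj <- drop(crossprod(Xres, qcal)) / qq
    Xres <- Xres - tcrossprod(qcal, proj)
    Vres <- Vres - tcrossprod(Vres[, cur], proj)
    norms <- colSums(Xres^2)
    norms[chain[seq_len(m)]] <- -Inf
    nxt <- which.max(norms)
    if (norms[nxt] < 1e-24) break  # nothing independent remains
    cur <- nxt
  }
  keep <- which(is.finite(rmse))
  list(chain = chain[keep], rmse = rmse[keep])
}
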