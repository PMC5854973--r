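#' CARS exponentially decreasing function (EDF) retained counts
#'
#' The fraction of wavelengths eligible after the enforced shrink of
#' iteration `i` is `r_i = a * exp(-b * i)` with `a`, `b` fixed by the
#' boundary conditions `r_1 = 1` (all `k` variables) and
#' `r_{n_runs} = 2 / k` (two variables). Counts are the ceiling of
#' `r_i * k`, giving exactly `k` at the first iteration and 2 at the last.
#'
#' @param k number of wavelength variables.
#' @param n_runs number of CARS iterations.
#' @return integer vector of length `n_runs`, non-increasing from `k` to 2.
#' @export
cars_edf_counts <- function(k, n_runs) {
  stopifnot(k >= 3L, n_runs >= 2L)
  b <- log(k / 2) / (n_runs - 1)
  a <- exp(b)
  i <- seq_len(n_runs)
  # the boundary values k and 2 are exact in theory; guard the ceiling
  # against upward floating-point drift (e.g. 2 + 4e-16 -> 3)
  pmin(as.integer(ceiling(a * exp(-b * i) * k - 1e-9)), k)
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' Iterative Monte Carlo wavelength selection driven by PLS regression
#' coefficients. Each of the `n_runs` iterations: (1) draws `mc_fraction`
#' (default 80%) of the calibration rows without replacement; (2) fits PLS
#' (at most `max_components` latent variables) on the rows and the current
#' variable subset; (3) enforced shrink - keeps the top `ceiling(r_i * k)`
#' variables by absolute regression coefficient, with `r_i` following the
#' exponentially decreasing function of [cars_edf_counts()]; (4) adaptive
#' reweighted sampling - draws that many variables with probability
#' proportional to the absolute coefficient and keeps the distinct draws,
#' usually pruning further; (5) records the K-fold RMSECV of a PLS model on
#' the surviving subset over the full calibration set. After all runs the
#' subset with minimal RMSECV wins (ties to the earliest iteration). Fully
#' reproducible given `seed`. If a subset would collapse below 2 variables
#' the run terminates early at the last valid subset.
#'
#' @param Xcal calibration spectra matrix `n x k`, `k >= 3`.
#' @param ycal nitrogen vector, length `n`.
#' @param n_runs number of Monte Carlo iterations (>= 2); default 500.
#' @param folds RMSECV folds; default 10.
#' @param seed integer seed making the Monte Carlo draws reproducible.
#' @param max_components latent-variable cap for the per-iteration PLS
#'   fits and the RMSECV scoring.
#' @param mc_fraction fraction of calibration rows drawn per iteration.
#' @return list with `selected_idx` (sorted winning subset) and `trace` (a
#'   `SelectionTrace`: per-iteration `retained_count`, `edf_count`,
#'   `sampled_rows`, `rmsecv`, `subset_idx` and the `chosen_iteration`).
#' @export
cars_select <- function(Xcal, ycal, n_runs = 500L, folds = 10L, seed = 1L,
                        max_components = 10L, mc_fraction = 0.8) {
  Xcal <- as.matrix(Xcal)
  n <- nrow(Xcal); k <- ncol(Xcal)
  if (k < 3L) stop("CARS needs at least 3 wavelength variables")
  if (n_runs < 2L) stop("n_runs must be >= 2")
  if (folds < 2L) stop("folds must be >= 2")
  edf <- cars_edf_counts(k, n_runs)
  n_mc <- max(2L, round(mc_fraction * n))

  with_seed(seed, {
    subset <- seq_len(k)
    records <- vector("list", n_runs)
    for (i in seq_len(n_runs)) {
      rows <- sort(sample.int(n, n_mc))
      fit <- pls1_nipals(Xcal[rows, subset, drop = FALSE], ycal[rows],
                         max_components)
      coef_abs <- abs(fit$coefficients[, fit$n_components])
      # (3) enforced shrink: EDF cap applies to the global variable budget
      keep_n <- min(edf[i], length(subset))
      ord <- order(coef_abs, decreasing = TRUE)
      survivors <- subset[ord[seq_len(keep_n)]]
      w <- coef_abs[ord[seq_len(keep_n)]]
      # (4) adaptive reweighted sampling: keep_n weighted draws with
      # replacement; the distinct draws survive (prunes further)
      if (any(w > 0)) {
        draw <- sample.int(keep_n, keep_n, replace = TRUE, prob = w)
        candidate <- sort(unique(survivors[draw]))
      } else {
        candidate <- sort(survivors)
      }
      if (length(candidate) < 2L) break  # collapse: stop at last valid subset
      subset <- candidate
      rmsecv <- pls_rmsecv(Xcal[, subset, drop = FALSE], ycal,
                           min(max_components, length(subset), n - 1L),
                           folds)
      records[[i]] <- list(retained_count = length(subset),
                           edf_count = edf[i],
                           sampled_rows = rows,
                           rmsecv = min(rmsecv),
                           subset_idx = subset)
    }
    records <- records[!vapply(records, is.null, logical(1L))]
    rmsecv_path <- vapply(records, `[[`, numeric(1L), "rmsecv")
    chosen <- which.min(rmsecv_path)
    trace <- structure(
      list(iterations = records, chosen_iteration = chosen),
      class = "SelectionTrace")
    list(selected_idx = records[[chosen]]$subset_idx, trace = trace)
  })
}

#' @export
print.SelectionTrace <- function(x, ...) {
  it <- x$iterations
  cat(sprintf(
    "SelectionTrace: %d iterations, best RMSECV %.4g at iteration %d (%d variables)\n",
    length(it), it[[x$chosen_iteration]]$rmsecv, x$chosen_iteration,
    it[[x$chosen_iteration]]$retained_count))
  invisible(x)
}
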