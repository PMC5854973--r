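#' Savitzky-Golay parameters
#'
#' @param window odd integer window length in points (the classical `2w + 1`
#'   for half-width `w`); must be >= 3.
#' @param polyorder degree of the local least-squares polynomial,
#'   `0 <= polyorder < window`.
#' @return an `SGParams` object.
#' @export
sg_params <- function(window = 11L, polyorder = 2L) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 3")
  }
  if (polyorder < 0L || polyorder >= window) {
    stop("polyorder must satisfy 0 <= polyorder < window")
  }
  structure(list(window = window, polyorder = polyorder),
            class = "SGParams")
}

# Least-squares fitted value at position `at` (1-based, within the window)
# of a degree-`polyorder` polynomial over `m` equally spaced points,
# expressed as a weight vector over the window: the `at`-th row of the hat
# matrix A (A'A)^{-1} A'.
sg_weights <- function(m, polyorder, at) {
  A <- outer(seq_len(m) - at, 0:polyorder, `^`)
  drop(A[at, , drop = FALSE] %*% solve(crossprod(A), t(A)))
}

#' Savitzky-Golay smoothing of a SpectraSet
#'
#' Replaces each spectrum by its Savitzky-Golay smoothed version: at each
#' point the value of a local least-squares polynomial of degree
#' `polyorder`, fitted over a centered window of `window` points. The
#' classical formulation is a weighted moving average
#' `x_smooth[k] = (1/H) * sum_i h_i x[k+i]` over `i = -w..w`; the weights
#' `h_i / H` are the polynomial projection coefficients computed here. Near
#' the edges the window is truncated to the available one-sided points (no
#' reflection padding) and the polynomial is refitted on the truncated
#' window.
#'
#' @param spectra a `SpectraSet`.
#' @param params an [sg_params()].
#' @return a `SpectraSet` with smoothed reflectance; grid, nitrogen and
#'   metadata unchanged.
#' @export
savitzky_golay_smooth <- function(spectra, params = sg_params()) {
  validate_spectra_set(spectra)
  stopifnot(inherits(params, "SGParams"))
  P <- length(spectra$wavelengths)
  m <- params$window
  d <- params$polyorder
  if (m > P) stop("window must not exceed the number of spectral points")
  w <- (m - 1L) %/% 2L
  X <- spectra$reflectance

  # interior: one convolution weight vector applied by matrix product
  W <- matrix(0, P, P)
  cw <- sg_weights(m, d, w + 1L)
  for (k in (w + 1L):(P - w)) W[(k - w):(k + w), k] <- cw
  # edges: truncated one-sided windows, refit on what is available
  for (k in seq_len(w)) {
    mk <- k + w                              # points 1..k+w
    W[seq_len(mk), k] <- sg_weights(mk, min(d, mk - 1L), k)
    pos <- (P - k + 1L - w):P                # mirrored window at right edge
    W[pos, P - k + 1L] <- rev(sg_weights(mk, min(d, mk - 1L), k))
  }
  out <- spectra
  out$reflectance <- X %*% W
  # smoothing of a positive signal can graze zero only in pathological
  # cases; keep the container invariant
  out$reflectance[out$reflectance <= 0] <- 1e-4
  validate_spectra_set(out)
  out
}

#' Reflectance to apparent absorbance
#'
#' Applies the common chemometric transform `A = log10(1/R)`. The pipeline
#' models reflectance directly by default; this transform is opt-in.
#'
#' @param spectra a `SpectraSet` with strictly positive reflectance.
#' @return a `SpectraSet` whose matrix holds `log10(1/R)` values. The
#'   container's positivity check is bypassed (absorbance of `R = 1` is 0),
#'   so the result is intended for modeling, not for re-simulation.
#' @export
reflectance_to_absorbance <- function(spectra) {
  validate_spectra_set(spectra)
  if (any(spectra$reflectance <= 0)) {
    stop("all reflectance values must be > 0 for the absorbance transform")
  }
  out <- unclass(spectra)
  out$reflectance <- log10(1 / spectra$reflectance)
  structure(out, class = c("AbsorbanceSet", "SpectraSet"))
}

#' Apparent absorbance back to reflectance
#' @param spectra an object produced by [reflectance_to_absorbance()].
#' @return the reflectance-scale `SpectraSet` (exact inverse).
#' @export
absorbance_to_reflectance <- function(spectra) {
  out <- unclass(spectra)
  out$reflectance <- 10^(-spectra$reflectance)
  structure(out, class = "SpectraSet")
}
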