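# Unit-height Gaussian absorption shape.
gaussian_band <- function(lambda, center, width) {
  exp(-0.5 * ((lambda - center) / width)^2)
}

# Evaluate/restore .Random.seed around a seeded computation so generator
# calls never disturb the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default 400-point wavelength grid (900-1700 nm)
#' @param P number of spectral points.
#' @return numeric vector of length `P`, uniformly spaced from 900 to 1700 nm.
#' @export
default_wavelengths <- function(P = 400L) seq(900, 1700, length.out = P)

#' Generate synthetic soil spectra for one soil/treatment cell
#'
#' Draws `n_gradients x replicates` diffuse-reflectance spectra from the
#' generative model
#' \deqn{R(\lambda) = s \left[ b_0 + b_1 (\lambda - 900)
#'   - \sum_k d_k G(\lambda; c_k, w_k)
#'   - \alpha N \, G(\lambda; c_N, w_N)
#'   - A \, G(\lambda; c_w, w_w) \right] + \epsilon}
#' where `G` is a unit-height Gaussian, `s` is a per-sample log-normal
#' scatter factor (`sdlog = scatter_sd`, mean log 0) and `eps` is i.i.d.
#' Gaussian noise per spectral point. Nitrogen takes `n_gradients` equally
#' spaced values from `nitrogen_min` to `nitrogen_max` inclusive, each
#' repeated `replicates` times. Reflectance is floored at `clip_floor` so it
#' stays strictly positive. Identical `(profile, seed)` pairs give
#' bit-identical output.
#'
#' @param profile a valid [soil_profile()].
#' @param seed integer seed for the scatter and noise draws.
#' @param wavelengths wavelength grid (nm), default [default_wavelengths()].
#' @param clip_floor lower clipping bound for reflectance.
#' @return a [spectra_set()] with `n_gradients * replicates` samples.
#' @export
generate_soil_spectra <- function(profile, seed,
                                  wavelengths = default_wavelengths(),
                                  clip_floor = 1e-4) {
  validate_soil_profile(profile)
  p <- profile
  lam <- wavelengths
  nitro_levels <- seq(p$nitrogen_min, p$nitrogen_max,
                      length.out = p$n_gradients)
  nitrogen <- rep(nitro_levels, each = p$replicates)
  n <- length(nitrogen)

  clean <- p$baseline_level + p$baseline_slope * (lam - 900)
  for (b in p$bands) clean <- clean - b[3L] * gaussian_band(lam, b[1L], b[2L])
  clean <- clean - p$water_band[3L] *
    gaussian_band(lam, p$water_band[1L], p$water_band[2L])
  nb <- p$nitrogen_band
  # n x P deterministic part: shared clean curve minus the nitrogen band
  det <- matrix(clean, n, length(lam), byrow = TRUE) -
    outer(nitrogen, nb[3L] * gaussian_band(lam, nb[1L], nb[2L]))

  R <- with_seed(seed, {
    scatter <- if (p$scatter_sd > 0) {
      stats::rlnorm(n, meanlog = 0, sdlog = p$scatter_sd)
    } else rep(1, n)
    eps <- if (p$noise_sd > 0) {
      matrix(stats::rnorm(n * length(lam), sd = p$noise_sd), n)
    } else 0
    det * scatter + eps
  })
  R[R < clip_floor] <- clip_floor

  spectra_set(lam, R, nitrogen, soil_type = p$soil_name,
              treatment = p$treatment)
}
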