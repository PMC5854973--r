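#' Construct a SpectraSet
#'
#' A `SpectraSet` is the package's central container: a wavelength grid, a
#' reflectance matrix (one row per sample), the nitrogen reference values
#' (g/kg), and per-sample metadata. It plays the role of the `X` (spectra)
#' and `Y` (nitrogen) of every calibration model.
#'
#' @param wavelengths numeric vector, strictly increasing wavelength grid (nm).
#' @param reflectance numeric matrix, `n x length(wavelengths)`, finite values
#'   in `(0, 1.5)` (mildly super-unity values can arise from additive noise).
#' @param nitrogen numeric vector of length `n`, nitrogen content in g/kg,
#'   non-negative.
#' @param soil_type character vector of length `n` (recycled if length 1).
#' @param treatment character vector of length `n` (recycled if length 1).
#' @param sample_id character vector of unique sample labels; generated as
#'   `<soil>_<treatment>_s<i>` when omitted.
#' @return An object of class `SpectraSet`.
#' @export
spectra_set <- function(wavelengths, reflectance, nitrogen,
                        soil_type = "unknown", treatment = "unknown",
                        sample_id = NULL) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  nitrogen <- as.numeric(nitrogen)
  n <- nrow(reflectance)
  if (length(soil_type) == 1L) soil_type <- rep(soil_type, n)
  if (length(treatment) == 1L) treatment <- rep(treatment, n)
  if (is.null(sample_id)) {
    sample_id <- sprintf("%s_%s_s%03d", soil_type, treatment, seq_len(n))
  }
  x <- structure(
    list(wavelengths = wavelengths, reflectance = unname(reflectance),
         nitrogen = nitrogen, soil_type = as.character(soil_type),
         treatment = as.character(treatment),
         sample_id = as.character(sample_id)),
    class = "SpectraSet")
  validate_spectra_set(x)
  x
}

#' Validate a SpectraSet's invariants
#'
#' Checks the grid is strictly increasing, the reflectance matrix is finite
#' and positive (values up to 1.5 are tolerated), nitrogen is non-negative,
#' and all per-sample vectors are consistent in length with unique ids.
#'
#' @param x a `SpectraSet`.
#' @return `x`, invisibly; signals an error on any violation.
#' @export
validate_spectra_set <- function(x) {
  stopifnot(inherits(x, "SpectraSet"))
  w <- x$wavelengths
  if (length(w) < 2L || any(diff(w) <= 0)) {
    stop("wavelengths must be strictly increasing with length >= 2")
  }
  R <- x$reflectance
  if (!is.matrix(R) || ncol(R) != length(w)) {
    stop("reflectance must be a matrix with one column per wavelength")
  }
  if (any(!is.finite(R))) stop("reflectance must be finite")
  if (any(R <= 0) || any(R >= 1.5)) {
    stop("reflectance values must lie in (0, 1.5)")
  }
  n <- nrow(R)
  if (length(x$nitrogen) != n || length(x$soil_type) != n ||
      length(x$treatment) != n || length(x$sample_id) != n) {
    stop("per-sample fields must all have length nrow(reflectance)")
  }
  if (any(!is.finite(x$nitrogen)) || any(x$nitrogen < 0)) {
    stop("nitrogen must be finite and >= 0")
  }
  if (anyDuplicated(x$sample_id)) stop("sample_id must be unique")
  invisible(x)
}

#' Number of samples in a SpectraSet
#' @param x a `SpectraSet`.
#' @return integer sample count.
#' @export
n_samples <- function(x) nrow(x$reflectance)

#' @export
print.SpectraSet <- function(x, ...) {
  w <- x$wavelengths
  cat(sprintf(
    "SpectraSet: %d samples x %d wavelengths (%.1f-%.1f nm)\n",
    n_samples(x), length(w), w[1L], w[length(w)]))
  cat(sprintf("  soils: %s | treatments: %s\n",
              paste(unique(x$soil_type), collapse = ", "),
              paste(unique(x$treatment), collapse = ", ")))
  cat(sprintf("  nitrogen: %.3f-%.3f g/kg\n",
              min(x$nitrogen), max(x$nitrogen)))
  invisible(x)
}

#' Subset a SpectraSet by sample index
#' @param x a `SpectraSet`.
#' @param idx integer vector of sample indices.
#' @return a `SpectraSet` containing the selected samples, in `idx` order.
#' @export
subset_samples <- function(x, idx) {
  spectra_set(x$wavelengths, x$reflectance[idx, , drop = FALSE],
              x$nitrogen[idx], x$soil_type[idx], x$treatment[idx],
              x$sample_id[idx])
}

#' Combine SpectraSets sharing a wavelength grid
#' @param ... `SpectraSet` objects on identical grids.
#' @return a single row-bound `SpectraSet`.
#' @export
bind_spectra <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !inherits(xs[[1L]], "SpectraSet")) {
    xs <- xs[[1L]]
  }
  w <- xs[[1L]]$wavelengths
  for (x in xs) {
    if (!isTRUE(all.equal(x$wavelengths, w))) {
      stop("all SpectraSets must share one wavelength grid")
    }
  }
  spectra_set(w,
              do.call(rbind, lapply(xs, `[[`, "reflectance")),
              unlist(lapply(xs, `[[`, "nitrogen")),
              unlist(lapply(xs, `[[`, "soil_type")),
              unlist(lapply(xs, `[[`, "treatment")),
              unlist(lapply(xs, `[[`, "sample_id")))
}

#' Write a SpectraSet as a wide CSV
#'
#' Columns: `sample_id, soil_type, treatment, nitrogen_g_kg` followed by one
#' reflectance column per wavelength, headed `R_<wavelength>` with the
#' wavelength printed to two decimals. Numeric values are written with 17
#' significant digits so that [read_spectra_csv()] round-trips exactly.
#'
#' @param x a `SpectraSet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  validate_spectra_set(x)
  hdr <- c("sample_id", "soil_type", "treatment", "nitrogen_g_kg",
           sprintf("R_%.2f", x$wavelengths))
  num <- function(v) formatC(v, digits = 17, format = "g")
  rows <- cbind(x$sample_id, x$soil_type, x$treatment, num(x$nitrogen),
                matrix(num(x$reflectance), nrow = n_samples(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  writeLines(apply(rows, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read a SpectraSet from a wide CSV
#'
#' Inverse of [write_spectra_csv()]. The wavelength grid is recovered from the
#' `R_<wavelength>` headers; because headers carry only two decimals, a
#' uniformly spaced grid consistent with the printed values (to within
#' rounding) is reconstructed exactly as `seq(first, last, length.out = P)`,
#' which restores the generator's grid bit-for-bit.
#'
#' @param path CSV file written by [write_spectra_csv()].
#' @return a `SpectraSet`.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(sample_id = "character",
                                       soil_type = "character",
                                       treatment = "character"))
  wcols <- grep("^R_", names(df))
  if (length(wcols) < 2L) stop("no R_<wavelength> columns found")
  w_printed <- as.numeric(sub("^R_", "", names(df)[wcols]))
  P <- length(w_printed)
  w_exact <- seq(w_printed[1L], w_printed[P], length.out = P)
  # headers carry 2 decimals; accept the uniform reconstruction when it
  # matches every printed value to rounding precision, else keep as printed
  w <- if (max(abs(round(w_exact, 2) - w_printed)) < 1e-9) w_exact else w_printed
  spectra_set(w, as.matrix(df[, wcols]), df$nitrogen_g_kg,
              df$soil_type, df$treatment, df$sample_id)
}
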