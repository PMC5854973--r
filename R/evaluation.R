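#' Pearson correlation coefficient
#'
#' @param y,yhat numeric vectors of equal length >= 3; both non-constant.
#' @return the Pearson product-moment correlation.
#' @export
pearson_r <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 3L) stop("need at least 3 observations")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(y, yhat)
}

#' Root mean square error
#' @param y,yhat numeric vectors of equal length >= 1 (g/kg).
#' @return `sqrt(mean((y - yhat)^2))`, g/kg.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 1L) stop("need at least 1 observation")
  sqrt(mean((y - yhat)^2))
}

#' Residual predictive deviation (RPD)
#'
#' The sample standard deviation (n-1 denominator) of the validation
#' reference values divided by the RMSEP.
#'
#' @param y_val validation nitrogen values, length >= 2, non-constant.
#' @param rmsep root mean square error of prediction, > 0 (g/kg).
#' @return RPD, unitless.
#' @export
rpd <- function(y_val, rmsep) {
  if (length(y_val) < 2L) stop("need at least 2 validation values")
  s <- stats::sd(y_val)
  if (s == 0) stop("RPD undefined: validation reference values are constant")
  if (rmsep == 0) stop("RPD infinite: rmsep is zero")
  if (rmsep < 0) stop("rmsep must be > 0")
  s / rmsep
}

#' RPD quality category
#'
#' Conventional interpretation bands: RPD of at least 3 marks a model fit
#' for agricultural application; between 2 and 3 a model with good
#' prediction ability; between 1.4 and 2 an intermediate model needing
#' improvement; below 1.4 poor predictive ability. Boundary values 1.4 and
#' 2.0 fall to the lower band; 3.0 counts as agriculture-grade.
#'
#' @param rpd positive scalar.
#' @return one of `"agriculture-grade"`, `"good"`, `"intermediate"`,
#'   `"poor"`.
#' @export
rpd_category <- function(rpd) {
  stopifnot(is.finite(rpd), rpd > 0)
  if (rpd >= 3) "agriculture-grade"
  else if (rpd > 2) "good"
  else if (rpd > 1.4) "intermediate"
  else "poor"
}

#' Evaluate a fitted calibration model on a split
#'
#' Computes R_c / RMSEC on the calibration members and R_p / RMSEP / RPD
#' (with its category) on the validation members. A perfect validation fit
#' (RMSEP = 0) is reported with `rpd = Inf` and category
#' `"agriculture-grade"` rather than raised as an error; an undefined
#' correlation (constant predictions, e.g. an intercept-only model) is
#' surfaced as `NA` with a note in `flags`.
#'
#' @param model a `CalibrationModel`.
#' @param spectra the full-cell `SpectraSet` the split indexes into.
#' @param split a `SplitResult`.
#' @param algorithm label stored in the report (defaults to `model$kind`).
#' @return an `EvaluationReport`: one-row data frame with columns
#'   `soil_type, treatment, algorithm, n_cal, n_val, R_c, RMSEC, R_p,
#'   RMSEP, RPD, rpd_category, n_components, n_selected, flags`.
#' @export
evaluate_model <- function(model, spectra, split,
                           algorithm = model$kind) {
  validate_spectra_set(spectra)
  idx_all <- sort(c(split$calibration_idx, split$validation_idx))
  if (!identical(idx_all, seq_len(n_samples(spectra)))) {
    stop("split does not cover the SpectraSet exactly")
  }
  flags <- character()
  safe_r <- function(y, yhat) {
    if (length(y) < 3L || stats::sd(yhat) == 0 || stats::sd(y) == 0) {
      flags <<- c(flags, "undefined-correlation")
      return(NA_real_)
    }
    pearson_r(y, yhat)
  }
  ycal <- spectra$nitrogen[split$calibration_idx]
  yval <- spectra$nitrogen[split$validation_idx]
  phat_cal <- predict(model, spectra$reflectance[split$calibration_idx, ,
                                                 drop = FALSE])
  phat_val <- predict(model, spectra$reflectance[split$validation_idx, ,
                                                 drop = FALSE])
  rmsec <- rmse(ycal, phat_cal)
  rmsep <- rmse(yval, phat_val)
  if (rmsep == 0) {
    flags <- c(flags, "infinite-rpd")
    rpd_val <- Inf
    cat_val <- "agriculture-grade"
  } else {
    rpd_val <- rpd(yval, rmsep)
    cat_val <- rpd_category(rpd_val)
  }
  out <- data.frame(
    soil_type = spectra$soil_type[1L], treatment = spectra$treatment[1L],
    algorithm = algorithm,
    n_cal = length(ycal), n_val = length(yval),
    R_c = safe_r(ycal, phat_cal), RMSEC = rmsec,
    R_p = safe_r(yval, phat_val), RMSEP = rmsep,
    RPD = rpd_val, rpd_category = cat_val,
    n_components = model$n_components %||% NA_integer_,
    n_selected = length(model$selected_idx),
    flags = paste(unique(flags), collapse = ";"),
    stringsAsFactors = FALSE)
  class(out) <- c("EvaluationReport", "data.frame")
  out
}
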