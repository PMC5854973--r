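new_calibration_model <- function(kind, selected_idx, coefficients,
                                  intercept, n_components = NULL,
                                  training_meta = list()) {
  stopifnot(length(selected_idx) >= 1L,
            !anyDuplicated(selected_idx),
            length(coefficients) == length(selected_idx))
  structure(
    list(kind = kind, selected_idx = as.integer(selected_idx),
         coefficients = as.numeric(coefficients),
         intercept = as.numeric(intercept),
         n_components = if (is.null(n_components)) NULL
                        else as.integer(n_components),
         training_meta = training_meta),
    class = "CalibrationModel")
}

#' @export
print.CalibrationModel <- function(x, ...) {
  cat(sprintf("CalibrationModel [%s]: %d variables%s\n", x$kind,
              length(x$selected_idx),
              if (is.null(x$n_components)) ""
              else sprintf(", %d latent variables", x$n_components)))
  invisible(x)
}

#' Multiple linear regression by ordinary least squares
#'
#' Fits `y = b0 + X b` by least squares. Requires more samples than
#' variables (`n > k`), the classical applicability condition of MLR on
#' selected wavelengths; a rank-deficient design yields the minimal-norm
#' solution via the pseudoinverse.
#'
#' @param X numeric matrix `n x k` of predictors (typically a few selected
#'   wavelength columns).
#' @param y numeric response of length `n`.
#' @param selected_idx wavelength indices the columns of `X` correspond to
#'   (defaults to `1:k`); stored so the model predicts from full spectra.
#' @return a `CalibrationModel` of kind `"MLR"`.
#' @export
fit_mlr <- function(X, y, selected_idx = seq_len(ncol(X))) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n <= k) {
    stop("MLR requires more samples than variables (n > k); ",
         "reduce variables first (e.g. with SPA)")
  }
  A <- cbind(1, X)
  qa <- qr(A)
  if (qa$rank == ncol(A)) {
    beta <- qr.coef(qa, y)
  } else {
    # minimal-norm solution for rank-deficient designs
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    beta <- drop(beta)
  }
  beta[is.na(beta)] <- 0
  new_calibration_model("MLR", selected_idx, beta[-1L], beta[1L],
                        training_meta = list(n = n, k = k))
}

#' Predict from a CalibrationModel
#'
#' Computes `yhat = intercept + X[, selected_idx] %*% coefficients`. `X`
#' must have the full training grid's column count so that the stored
#' wavelength indices address the same variables.
#'
#' @param object a `CalibrationModel`.
#' @param X numeric matrix on the training wavelength grid, or a
#'   `SpectraSet`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.CalibrationModel <- function(object, X, ...) {
  if (inherits(X, "SpectraSet")) X <- X$reflectance
  X <- as.matrix(X)
  P <- object$training_meta$P %||% max(object$selected_idx)
  if (ncol(X) < P) {
    stop(sprintf("X has %d columns; the training grid had at least %d",
                 ncol(X), P))
  }
  if (!is.null(object$training_meta$P) &&
      ncol(X) != object$training_meta$P) {
    stop(sprintf("X has %d columns but the model was trained on %d",
                 ncol(X), object$training_meta$P))
  }
  drop(X[, object$selected_idx, drop = FALSE] %*% object$coefficients) +
    object$intercept
}

`%||%` <- function(a, b) if (is.null(a)) b else a
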