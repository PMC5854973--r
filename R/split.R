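#' Joint spectral-concentration (SPXY) distance matrix
#'
#' Computes the SPXY distance
#' `d_xy(i,j) = d_x(i,j) / max d_x + d_y(i,j) / max d_y`,
#' where `d_x` is the Euclidean distance between spectra and
#' `d_y(i,j) = |N_i - N_j|` the absolute nitrogen difference; each term is
#' normalized by its maximum over all pairs so spectral and concentration
#' space carry equal weight. If one normalizer is zero (all spectra
#' identical, or all nitrogen identical) that term is dropped; if both
#' vanish the distance is degenerate and an error is raised.
#'
#' @param spectra a `SpectraSet` with `n >= 2` samples.
#' @return symmetric `n x n` matrix with zero diagonal, values in `[0, 2]`.
#' @export
joint_distance_matrix <- function(spectra) {
  validate_spectra_set(spectra)
  n <- n_samples(spectra)
  if (n < 2L) stop("need at least 2 samples")
  dx <- as.matrix(stats::dist(spectra$reflectance))
  dy <- abs(outer(spectra$nitrogen, spectra$nitrogen, `-`))
  mx <- max(dx)
  my <- max(dy)
  if (mx == 0 && my == 0) {
    stop("degenerate distances: all spectra and all nitrogen values identical")
  }
  d <- 0
  if (mx > 0) d <- d + dx / mx
  if (my > 0) d <- d + dy / my
  dimnames(d) <- NULL
  d
}

# Kennard-Stone greedy max-min selection on a precomputed distance matrix.
# Seeds with the maximally distant pair (lowest indices on ties), then
# repeatedly adds the candidate whose minimal distance to the selected set
# is maximal (ties to the lowest index).
kennard_stone <- function(d, n_select) {
  n <- nrow(d)
  stopifnot(n_select >= 2L, n_select <= n)
  # seed pair: first (in column-major order) occurrence of the max distance
  up <- which(upper.tri(d) & d == max(d), arr.ind = TRUE)
  seedpair <- up[order(up[, 2L], up[, 1L])[1L], ]
  selected <- c(seedpair[[1L]], seedpair[[2L]])
  mind <- pmin(d[, selected[1L]], d[, selected[2L]])
  while (length(selected) < n_select) {
    mind[selected] <- -Inf
    nxt <- which.max(mind)      # which.max takes the lowest index on ties
    selected <- c(selected, nxt)
    mind <- pmin(mind, d[, nxt])
  }
  selected
}

#' SPXY calibration/validation split
#'
#' Partitions the samples into a calibration set (N1) and validation set
#' (N2) by Kennard-Stone selection on the joint SPXY distance of
#' [joint_distance_matrix()]: the maximally distant pair seeds the
#' calibration set, and candidates maximizing their minimal distance to the
#' selected set are added until the calibration size is reached. For a
#' `c:v` ratio the validation size is `floor(n * v / (c + v))` and the
#' calibration set takes the remainder - at the conventional 2:1 ratio, 176
#' samples split into 118 calibration / 58 validation. Deterministic given
#' input order; ties break toward the lowest index.
#'
#' @param spectra a `SpectraSet` with `n >= 3` samples.
#' @param ratio length-2 numeric `c(calibration, validation)` proportion,
#'   default `c(2, 1)`.
#' @return a `SplitResult`: list with `calibration_idx`, `validation_idx`
#'   (1-based, each sorted increasing), and `ratio`.
#' @export
spxy_split <- function(spectra, ratio = c(2, 1)) {
  n <- n_samples(spectra)
  if (n < 3L) stop("need at least 3 samples to split")
  stopifnot(length(ratio) == 2L, all(ratio > 0))
  n_val <- floor(n * ratio[2L] / sum(ratio))
  n_cal <- n - n_val
  d <- joint_distance_matrix(spectra)
  cal <- sort(kennard_stone(d, n_cal))
  structure(
    list(calibration_idx = cal,
         validation_idx = setdiff(seq_len(n), cal),
         ratio = ratio),
    class = "SplitResult")
}

#' @export
print.SplitResult <- function(x, ...) {
  cat(sprintf("SplitResult: N1 = %d calibration, N2 = %d validation (ratio %g:%g)\n",
              length(x$calibration_idx), length(x$validation_idx),
              x$ratio[1L], x$ratio[2L]))
  invisible(x)
}

#' Persist a SplitResult as JSON
#' @param split a `SplitResult`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split_json <- function(split, path) {
  jsonlite::write_json(
    list(calibration_idx = split$calibration_idx,
         validation_idx = split$validation_idx,
         ratio = split$ratio),
    path, digits = NA)
  invisible(path)
}

#' Read a SplitResult from JSON
#' @param path file written by [write_split_json()].
#' @return a `SplitResult`.
#' @export
read_split_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(calibration_idx = as.integer(x$calibration_idx),
                 validation_idx = as.integer(x$validation_idx),
                 ratio = as.numeric(x$ratio)),
            class = "SplitResult")
}
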