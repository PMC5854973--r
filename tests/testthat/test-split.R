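two_col_set <- function(X, y) {
  spectra_set(c(1000, 1100), 0.2 + 0.1 * X, nitrogen = y)
}

test_that("joint distance matrix follows the SPXY definition", {
  # n = 2: each normalized term is 1 at its own maximum -> off-diagonal 2
  s2 <- two_col_set(rbind(c(0, 0), c(1, 1)), c(0.1, 0.2))
  d2 <- joint_distance_matrix(s2)
  expect_equal(d2, matrix(c(0, 2, 2, 0), 2))

  # identical spectra, distinct nitrogen: spectral term dropped
  si <- spectra_set(c(1000, 1100), matrix(0.5, 3, 2),
                    nitrogen = c(0.1, 0.2, 0.4))
  di <- joint_distance_matrix(si)
  dy <- abs(outer(si$nitrogen, si$nitrogen, `-`))
  expect_equal(di, dy / max(dy))

  # fully degenerate input errors
  sd0 <- spectra_set(c(1000, 1100), matrix(0.5, 3, 2),
                     nitrogen = rep(0.2, 3))
  expect_error(joint_distance_matrix(sd0), "degenerate")

  # 4-sample toy set vs the double-loop oracle
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 2))
  y <- c(0.1, 0.2, 0.3, 0.4)
  s4 <- two_col_set(X, y)
  expect_equal(joint_distance_matrix(s4),
               oracle_joint_distance(s4$reflectance, y),
               tolerance = 1e-12)
  expect_true(all(joint_distance_matrix(s4) >= 0) &&
                all(joint_distance_matrix(s4) <= 2))
})

test_that("SPXY split reproduces the published 118/58 partition of 176 samples", {
  s <- generate_soil_spectra(default_profiles()$calcium_50C, seed = 3)
  sp <- spxy_split(s, ratio = c(2, 1))
  expect_length(sp$calibration_idx, 118L)
  expect_length(sp$validation_idx, 58L)
  expect_setequal(c(sp$calibration_idx, sp$validation_idx), 1:176)
})

test_that("SPXY selection matches brute-force Kennard-Stone on small sets", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    X <- matrix(runif(n * 3, 0.2, 0.8), n, 3)
    y <- runif(n, 0.1, 2)
    s <- spectra_set(c(1000, 1100, 1200), X, nitrogen = y)
    d <- joint_distance_matrix(s)
    for (n_cal in 3:(n - 1)) {
      oracle <- sort(oracle_kennard_stone(d, n_cal))
      n_val <- n - n_cal
      sp <- spxy_split(s, ratio = c(n_cal, n_val))
      expect_equal(sp$calibration_idx, oracle)
    }
  }
})

test_that("split invariants: extreme pair selected, n = 3 case, permutation behavior", {
  s3 <- two_col_set(rbind(c(0, 0), c(0.1, 0), c(5, 5)), c(0.1, 0.12, 0.9))
  sp3 <- spxy_split(s3, ratio = c(2, 1))
  expect_equal(sp3$calibration_idx, c(1L, 3L))  # the max-distance pair
  expect_equal(sp3$validation_idx, 2L)

  set.seed(9)
  X <- matrix(runif(12 * 4, 0.2, 0.8), 12, 4)
  y <- runif(12, 0.1, 1)
  s <- spectra_set(1000 + 1:4 * 50, X, nitrogen = y)
  sp <- spxy_split(s)
  d <- joint_distance_matrix(s)
  pair <- which(d == max(d), arr.ind = TRUE)[1, ]
  expect_true(all(pair %in% sp$calibration_idx))

  # permuting input order permutes the selected identities consistently
  perm <- sample(12)
  sp_perm <- spxy_split(subset_samples(s, perm))
  expect_setequal(perm[sp_perm$calibration_idx], sp$calibration_idx)
})

test_that("split JSON round-trips", {
  sp <- structure(list(calibration_idx = c(1L, 3L, 4L),
                       validation_idx = c(2L, 5L),
                       ratio = c(2, 1)), class = "SplitResult")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_split_json(sp, path)
  expect_equal(read_split_json(path), sp)
})
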