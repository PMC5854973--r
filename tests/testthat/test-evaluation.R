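test_that("pearson_r, rmse and rpd match their closed forms", {
  y <- c(1, 2, 3, 4)
  expect_equal(pearson_r(y, y), 1)
  expect_equal(pearson_r(y, -y), -1)
  yhat <- c(1.1, 1.9, 3.2, 3.8)
  num <- sum((y - mean(y)) * (yhat - mean(yhat)))
  den <- sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2))
  expect_equal(pearson_r(y, yhat), num / den, tolerance = 1e-12)
  expect_error(pearson_r(y, rep(1, 4)), "constant")
  expect_error(pearson_r(1:3, 1:4), "length")

  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y, y + 0.3), 0.3)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))

  expect_equal(rpd(y, sd(y)), 1)
  expect_equal(rpd(y, 0.5), sd(y) / 0.5, tolerance = 1e-12)
  expect_equal(rpd(y, 0.25), 2 * rpd(y, 0.5))
  expect_error(rpd(y, 0), "infinite")
  expect_error(rpd(rep(1, 4), 0.5), "constant")
})

test_that("RPD categories reproduce the published pairings and boundaries", {
  expect_equal(rpd_category(4.34), "agriculture-grade")
  expect_equal(rpd_category(2.82), "good")
  expect_equal(rpd_category(1.25), "poor")
  # boundary conventions: 3.0 is agriculture-grade; 2.0 and 1.4 fall low
  expect_equal(rpd_category(3), "agriculture-grade")
  expect_equal(rpd_category(2), "intermediate")
  expect_equal(rpd_category(1.4), "poor")
  expect_equal(rpd_category(1.7), "intermediate")
})

test_that("evaluate_model composes the metrics correctly", {
  # toy 6-sample fixture with a known imperfect model
  X <- matrix(c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2), 6, 1)
  X <- cbind(X, 0.5)
  s <- spectra_set(c(1000, 1100), X * 0.5, nitrogen = c(1, 2, 3, 4, 5, 6) / 4)
  split <- structure(list(calibration_idx = c(1L, 2L, 6L),
                          validation_idx = c(3L, 4L, 5L), ratio = c(2, 1)),
                     class = "SplitResult")
  m <- new_calibration_model("MLR", 1L, 2.0, 0.1,
                             training_meta = list(P = 2L))
  rep <- evaluate_model(m, s, split)
  yhat <- 0.1 + 2.0 * s$reflectance[, 1]
  ycal <- s$nitrogen[split$calibration_idx]
  yval <- s$nitrogen[split$validation_idx]
  expect_equal(rep$R_c, cor(ycal, yhat[split$calibration_idx]))
  expect_equal(rep$RMSEC, sqrt(mean((ycal - yhat[split$calibration_idx])^2)))
  expect_equal(rep$R_p, cor(yval, yhat[split$validation_idx]))
  expect_equal(rep$RMSEP, sqrt(mean((yval - yhat[split$validation_idx])^2)))
  expect_equal(rep$RPD, sd(yval) / rep$RMSEP)
  expect_equal(rep$rpd_category, rpd_category(rep$RPD))
  expect_equal(rep$n_cal, 3L)
  expect_equal(rep$n_val, 3L)

  # perfect model: zero errors, RPD flagged infinite instead of erroring
  mp <- new_calibration_model("MLR", 1L, 5, 0,
                              training_meta = list(P = 2L))
  s2 <- spectra_set(c(1000, 1100), X * 0.5, nitrogen = X[, 1] * 2.5)
  rp <- evaluate_model(mp, s2, split)
  expect_equal(rp$RMSEP, 0)
  expect_equal(rp$RPD, Inf)
  expect_match(rp$flags, "infinite-rpd")

  # intercept-only model: undefined correlation surfaced, not raised
  m0 <- new_calibration_model("MLR", 1L, 0, 0.5,
                              training_meta = list(P = 2L))
  r0 <- evaluate_model(m0, s, split)
  expect_true(is.na(r0$R_c))
  expect_match(r0$flags, "undefined-correlation")

  # report is invariant to validation-set ordering
  split_rev <- split
  split_rev$validation_idx <- rev(split$validation_idx)
  expect_equal(evaluate_model(m, s, split_rev)[, -14], rep[, -14])
})
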