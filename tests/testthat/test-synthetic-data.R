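test_that("default_profiles returns the 12-cell registry with the published design", {
  p <- default_profiles()
  expect_length(p, 12L)
  expect_setequal(
    names(p),
    paste(rep(c("black", "loess", "calcium"), each = 4),
          c("25C", "50C", "80C", "95C"), sep = "_"))

  # nitrogen ranges per soil
  expect_equal(p$loess_50C$nitrogen_min, 0.09)
  expect_equal(p$loess_50C$nitrogen_max, 0.93)
  expect_equal(p$calcium_80C$nitrogen_min, 0.32)
  expect_equal(p$calcium_80C$nitrogen_max, 1.17)
  expect_equal(p$black_95C$nitrogen_min, 0.46)
  expect_equal(p$black_95C$nitrogen_max, 2.15)

  # soil-specific nitrogen-sensitive band centers; shared water band
  expect_equal(p$black_25C$nitrogen_band[1], 1470)
  expect_equal(p$loess_25C$nitrogen_band[1], 1160)
  expect_equal(p$calcium_25C$nitrogen_band[1], 1145)
  for (pr in p) expect_equal(pr$water_band[1], 1385)

  # residual moisture ordering per soil: 25C > 50C > 80C >= 95C
  for (s in c("black", "loess", "calcium")) {
    amp <- sapply(paste0(s, "_", c("25C", "50C", "80C", "95C")),
                  function(nm) p[[nm]]$water_band[3])
    expect_true(amp[1] > amp[2] && amp[2] > amp[3] && amp[3] >= amp[4])
  }
  # black soil retains markedly more ambient moisture than the others
  expect_true(p$black_25C$water_band[3] >=
                2 * max(p$loess_25C$water_band[3],
                        p$calcium_25C$water_band[3]))
  # ambient placement inflates noise and scatter
  expect_equal(p$black_25C$noise_sd, 3 * p$black_50C$noise_sd)
  expect_equal(p$black_25C$scatter_sd, 2 * p$black_50C$scatter_sd)
})

test_that("generator honors the sample design and grid contract", {
  s <- generate_soil_spectra(default_profiles()$loess_95C, seed = 42)
  expect_equal(n_samples(s), 176L)       # 11 gradients x 16 replicates
  expect_length(s$wavelengths, 400L)
  expect_equal(s$wavelengths[1], 900)
  expect_equal(s$wavelengths[400], 1700)
  expect_equal(diff(s$wavelengths), rep(800 / 399, 399))
  expect_equal(sort(unique(s$nitrogen)), seq(0.09, 0.93, length.out = 11))
  expect_equal(as.vector(table(s$nitrogen)), rep(16L, 11L))
  expect_false(anyDuplicated(s$sample_id) > 0)
  expect_true(all(s$reflectance > 0 & s$reflectance < 1.5))
})

test_that("generator is deterministic and profile validation rejects bad inputs", {
  pr <- default_profiles()$black_50C
  a <- generate_soil_spectra(pr, seed = 7)
  b <- generate_soil_spectra(pr, seed = 7)
  expect_identical(a, b)
  c <- generate_soil_spectra(pr, seed = 8)
  expect_false(identical(a$reflectance, c$reflectance))

  expect_error(soil_profile("x", "50C", baseline_level = 1.2,
                            nitrogen_band = c(1160, 30, 0.1),
                            water_band = c(1385, 50, 0.05),
                            nitrogen_min = 0, nitrogen_max = 1),
               "baseline_level")
  expect_error(toy_profile(n_gradients = 1L), "n_gradients")
  expect_error(soil_profile("x", "50C", baseline_level = 0.5,
                            nitrogen_band = c(1160, -3, 0.1),
                            water_band = c(1385, 50, 0.05),
                            nitrogen_min = 0, nitrogen_max = 1),
               "width")
  expect_error(soil_profile("x", "40C", baseline_level = 0.5,
                            nitrogen_band = c(1160, 30, 0.1),
                            water_band = c(1385, 50, 0.05),
                            nitrogen_min = 0.2, nitrogen_max = 0.1),
               "nitrogen_min")
})

test_that("noise-free replicates are identical and the nitrogen slope is exact", {
  # no stochastic or N-dependent term -> replicate spectra identical
  pr0 <- toy_profile(sensitivity = 0)
  s0 <- generate_soil_spectra(pr0, seed = 1)
  for (lev in unique(s0$nitrogen)) {
    rows <- s0$reflectance[s0$nitrogen == lev, ]
    expect_equal(max(abs(sweep(rows, 2, rows[1, ]))), 0)
  }

  # least-squares slope of reflectance at the band center vs nitrogen
  # equals -sensitivity (closed form; regression is the independent oracle)
  pr <- toy_profile(sensitivity = 0.08)
  s <- generate_soil_spectra(pr, seed = 1)
  j <- which.min(abs(s$wavelengths - 1160))
  # use the exact center: evaluate the generative formula on a grid point
  s2 <- generate_soil_spectra(pr, seed = 1,
                              wavelengths = sort(c(default_wavelengths(),
                                                   1160)))
  j2 <- which(s2$wavelengths == 1160)
  slope <- stats::coef(stats::lm(s2$reflectance[, j2] ~ s2$nitrogen))[[2]]
  expect_equal(slope, -0.08, tolerance = 1e-9)
  # and reflectance at the band center strictly decreases in nitrogen
  prof_means <- tapply(s$reflectance[, j], s$nitrogen, mean)
  expect_true(all(diff(prof_means) < 0))
})

test_that("ambient placement depresses the 1385 nm band (monotone confounding)", {
  p <- default_profiles()
  for (s in c("black", "loess", "calcium")) {
    s25 <- generate_soil_spectra(p[[paste0(s, "_25C")]], seed = 11)
    s95 <- generate_soil_spectra(p[[paste0(s, "_95C")]], seed = 11)
    j <- which.min(abs(s25$wavelengths - 1385))
    expect_lt(mean(s25$reflectance[, j]), mean(s95$reflectance[, j]))
  }
})
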