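# surrogate peak tables only — no literature values in correctness tests
surrogate_peaks <- c(700, 950, 1180, 1420, 1700, 2100, 2600, 2950)

test_that("wavenumber calibration recovers an identity mapping", {
  fx <- make_calibration_fixtures(c(0, 1), n_pixels = 3000,
                                  peak_wavenumbers = surrogate_peaks)
  cal <- calibrate_wavenumber(fx$standard, fx$peak_table, degree = 1)
  expect_lt(cal$residual_rms, 0.5)
  expect_lt(max(abs(predict_wavenumber(cal, c(700, 1500, 2900)) -
                      c(700, 1500, 2900))), 0.5)
})

test_that("wavenumber calibration recovers a cubic mapping within 0.5 cm^-1", {
  true_coefs <- c(580, 2.1, 2e-4, -8e-8)
  fx <- make_calibration_fixtures(true_coefs, n_pixels = 1200,
                                  peak_wavenumbers = surrogate_peaks)
  cal <- calibrate_wavenumber(fx$standard, fx$peak_table, degree = 3)
  px <- seq(0, 1199, length.out = 200)
  true_map <- drop(outer(px, 0:3, `^`) %*% true_coefs)
  expect_lt(max(abs(predict_wavenumber(cal, px) - true_map)), 0.5)
})

test_that("too few matched peaks for the requested degree is an error", {
  fx <- make_calibration_fixtures(c(0, 1), n_pixels = 2000,
                                  peak_wavenumbers = c(600, 1500))
  expect_error(calibrate_wavenumber(fx$standard, fx$peak_table,
                                    degree = 3),
               "too few")
})

test_that("a non-monotone generating polynomial is rejected", {
  expect_error(
    make_calibration_fixtures(c(1000, -1), n_pixels = 256,
                              peak_wavenumbers = c(800, 900)),
    "strictly increasing")
})

test_that("intensity calibration recovers a known response curve", {
  axis <- seq(600, 3100, length.out = 800)
  fx <- make_calibration_fixtures(c(600, 2.5), n_pixels = 1000,
                                  peak_wavenumbers = surrogate_peaks,
                                  response_curve = function(w) {
                                    0.5 + 0.4 * sin(w / 400)^2
                                  },
                                  lamp_axis = axis)
  resp <- calibrate_intensity(fx$measured_lamp, fx$certified_lamp)
  corrected <- apply_response(fx$measured_lamp, resp)
  expect_lt(max(abs(corrected - fx$certified_lamp) /
                  fx$certified_lamp), 1e-6)
  expect_lt(max(abs(resp$factors - 1 / fx$truth$response)), 1e-6)
  # identity case
  resp_id <- calibrate_intensity(fx$certified_lamp, fx$certified_lamp)
  expect_equal(resp_id$factors, rep(1, length(axis)))
  expect_error(calibrate_intensity(rep(0, 100), rep(1, 100)),
               "calibration error")
})

test_that("spike removal is surgical and width-gated", {
  profile <- pollen_reference_profiles()[[3]]
  design <- spectrum_design(noise_sd = 0.01, spike_rate = 0, seed = 6)
  sp <- generate_spectrum(profile, design, seed = 6)
  clean <- remove_cosmic_spikes(sp$intensity)
  expect_identical(clean$intensity, sp$intensity)
  expect_length(clean$spikes, 0)
  # inject a single-channel spike of 50x the local amplitude
  y <- sp$intensity
  pos <- 400
  y[pos] <- y[pos] + 50 * max(abs(y[(pos - 5):(pos + 5)]))
  fixed <- remove_cosmic_spikes(y)
  expect_equal(fixed$spikes, pos)
  expect_identical(fixed$intensity[-pos], y[-pos])  # untouched elsewhere
  expect_lt(abs(fixed$intensity[pos] - sp$intensity[pos]),
            0.05 * max(sp$intensity))
  # a genuine band (width >= gate) is preserved untouched
  wide <- sp$intensity
  expect_identical(remove_cosmic_spikes(wide, width_threshold = 3,
                                        deviation_threshold = 8)$intensity,
                   wide)
})

test_that("EMSC fitting is exact on noise-free mixtures", {
  axis <- seq(600, 3100, length.out = 1000)
  r <- water_reference(axis) * 0 +
    exp(-((axis - 1400)^2) / (2 * 60^2)) +
    0.5 * exp(-((axis - 2900)^2) / (2 * 40^2))
  model <- emsc_model(r, axis)
  nu <- model$nu
  fit <- emsc_fit(r, model)
  expect_lt(abs(fit$b - 1), 1e-9)
  expect_lt(max(abs(c(fit$interferents, fit$poly))), 1e-9)
  y <- 2 * r + 0.5 * water_reference(axis) + 1 + 0.01 * nu
  fit <- emsc_fit(y, model)
  expect_lt(max(abs(c(fit$b - 2, fit$interferents["water"] - 0.5,
                      fit$poly - c(1, 0.01, 0)))), 1e-6)
})

test_that("EMSC least squares matches the normal-equations oracle", {
  set.seed(9)
  axis <- seq(600, 3100, length.out = 500)
  r <- exp(-((axis - 1200)^2) / (2 * 80^2))
  model <- emsc_model(r, axis)
  for (rep in 1:5) {
    y <- 1.5 * r + 0.3 * water_reference(axis) + rnorm(500, 0, 0.05)
    fit <- emsc_fit(y, model)
    X <- model$design
    oracle <- solve(t(X) %*% X, t(X) %*% y)   # normal equations
    expect_lt(max(abs(fit$all - as.vector(oracle))), 1e-8)
  }
})

test_that("EMSC correction inverts exact mixtures and flags degenerate fits", {
  axis <- seq(600, 3100, length.out = 800)
  r <- exp(-((axis - 1000)^2) / (2 * 50^2)) +
    0.7 * exp(-((axis - 1600)^2) / (2 * 70^2))
  model <- emsc_model(r, axis)
  expect_lt(max(abs(emsc_correct(r, model) - r)), 1e-9)
  y <- 2 * r + 0.5 * water_reference(axis) + 1 + 0.01 * model$nu
  expect_lt(max(abs(emsc_correct(y, model) - r)), 1e-6)
  # degenerate multiplicative coefficient
  flat <- 0.5 * water_reference(axis) + 0.2
  expect_error(emsc_correct(flat, model), "degenerate")
})

test_that("EMSC recovery error shrinks with the noise level", {
  axis <- seq(600, 3100, length.out = 400)
  r <- exp(-((axis - 1400)^2) / (2 * 90^2))
  model <- emsc_model(r, axis)
  mean_dev <- vapply(c(0.1, 0.02, 0.004), function(noise_sd) {
    devs <- vapply(1:50, function(seed) {
      set.seed(seed)
      y <- 1.4 * r + 0.3 * water_reference(axis) + 0.5 +
        rnorm(400, 0, noise_sd)
      mean(abs(emsc_correct(y, model) - r))
    }, numeric(1))
    mean(devs)
  }, numeric(1))
  expect_true(all(diff(mean_dev) < 0))
})

test_that("a rank-deficient EMSC design is rejected", {
  axis <- seq(600, 3100, length.out = 100)
  nu <- 2 * (axis - min(axis)) / diff(range(axis)) - 1
  expect_error(emsc_model(1 + 2 * nu, axis), "rank deficient")
})

test_that("area normalization divides by the regional sum exactly once", {
  expect_equal(area_normalize(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  set.seed(3)
  y <- runif(300, 0.1, 2)
  norm <- area_normalize(y)
  expect_lt(abs(sum(norm) - 1), 1e-12)
  expect_equal(area_normalize(norm), norm)   # idempotence
  wn <- seq(600, 3100, length.out = 300)
  reg <- area_normalize(y, wn, c(758, 1800))
  expect_lt(abs(sum(reg[wn >= 758 & wn <= 1800]) - 1), 1e-12)
  expect_error(area_normalize(rep(0, 10)), "nonpositive")
})

test_that("region cropping keeps exactly the in-bound channels", {
  wn <- seq(600, 3100, by = 2)
  y <- seq_along(wn)
  sp <- raman_spectrum(wn, y)
  full <- crop_region(sp, c(600, 3100))
  expect_equal(full$intensity, y)
  fp <- crop_region(sp, c(758, 1800))
  expect_true(all(fp$wavenumber >= 758 & fp$wavenumber <= 1800))
  # direct index computation
  expect_equal(fp$wavenumber, wn[wn >= 758 & wn <= 1800])
  lo <- min(fp$wavenumber); hi <- max(fp$wavenumber)
  expect_true(lo - 2 < 758 && hi + 2 > 1800)  # neighbours excluded
  expect_error(crop_region(sp, c(5000, 6000)), "overlap")
})

test_that("the pipeline inverts exact mixtures to the normalized reference", {
  profile <- separable_profiles(1)[[1]]
  design <- spectrum_design(n_per_class = 10, scatter_sd = 0.2,
                            noise_sd = 0, spike_rate = 0, seed = 14)
  ds <- generate_dataset(list(profile), design, keep_components = TRUE)
  pure <- attr(ds, "components")[[1]]$pure
  proc <- preprocess_pipeline(
    ds, preprocess_config(emsc_reference = pure))
  expect_equal(n_spectra(proc), 10)
  target <- area_normalize(pure)
  for (j in seq_len(10)) {
    expect_lt(max(abs(proc$intensities[, j] - target)), 1e-6)
  }
})

test_that("the pipeline records its stage order and isolates failures", {
  profiles <- separable_profiles(2)
  design <- spectrum_design(n_per_class = 5, noise_sd = 0.01, seed = 8)
  ds <- generate_dataset(profiles, design)
  # corrupt one spectrum so its EMSC multiplicative coefficient collapses
  ds$intensities[, 3] <- 0
  proc <- preprocess_pipeline(ds)
  prov <- attr(proc, "provenance")
  expect_equal(prov$stages,
               c("spike_removal", "emsc", "area_normalization"))
  expect_equal(prov$n_in, 10)
  expect_equal(prov$n_out, 9)
  expect_equal(nrow(prov$drops), 1)
  expect_equal(prov$drops$id, ds$manifest$id[3])
  # with calibrations supplied, they run first and in order
  fx <- make_calibration_fixtures(c(600, 2.5), n_pixels = 1200,
                                  peak_wavenumbers = surrogate_peaks)
  cal <- calibrate_wavenumber(fx$standard, fx$peak_table, degree = 1)
  raw <- spectral_dataset(0:(1200 - 1),
                          ds$intensities[, 1:2, drop = FALSE],
                          ds$manifest[1:2, ])
  resp <- calibrate_intensity(rep(2, 1200), rep(1, 1200))
  proc2 <- preprocess_pipeline(raw, calibration = cal, response = resp)
  expect_equal(attr(proc2, "provenance")$stages,
               c("wavenumber_calibration", "intensity_calibration",
                 "spike_removal", "emsc", "area_normalization"))
})

test_that("an empty dataset passes through the pipeline unharmed", {
  ds <- spectral_dataset(seq(600, 3100, length.out = 50),
                         matrix(numeric(0), 50, 0),
                         data.frame(id = character(0),
                                    species = character(0),
                                    genus = character(0),
                                    family = character(0),
                                    growth_habit = character(0)))
  proc <- preprocess_pipeline(ds)
  expect_equal(n_spectra(proc), 0)
})
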