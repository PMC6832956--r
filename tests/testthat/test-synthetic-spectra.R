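test_that("an empty generative model yields an all-zero spectrum", {
  profile <- pollen_class_profile("empty", "herb", "f", "g",
                                  peaks = data.frame(center = numeric(0),
                                                     amplitude = numeric(0),
                                                     width = numeric(0)))
  sp <- generate_spectrum(profile, quiet_design(), seed = 1)
  expect_true(all(sp$intensity == 0))
})

test_that("a single band peaks at the channel nearest its center", {
  profile <- pollen_class_profile(
    "one", "herb", "f", "g",
    peaks = data.frame(center = 1004, amplitude = 1, width = 8))
  design <- quiet_design()
  sp <- generate_spectrum(profile, design, seed = 1)
  axis <- sp$wavenumber
  # independent oracle: evaluate the band function directly on the axis
  oracle <- which.max(exp(-((axis - 1004)^2) / (2 * 8^2)))
  expect_equal(which.max(sp$intensity), oracle)
  expect_equal(oracle, which.min(abs(axis - 1004)))
})

test_that("spectrum generation is deterministic in the seed", {
  profile <- pollen_reference_profiles()[[1]]
  design <- spectrum_design(noise_sd = 0.05, spike_rate = 0.5, seed = 42)
  a <- generate_spectrum(profile, design, seed = 42)
  b <- generate_spectrum(profile, design, seed = 42)
  expect_identical(a$intensity, b$intensity)
  dsa <- generate_dataset(pollen_reference_profiles()[1:3],
                          spectrum_design(n_per_class = 4, seed = 9))
  dsb <- generate_dataset(pollen_reference_profiles()[1:3],
                          spectrum_design(n_per_class = 4, seed = 9))
  expect_identical(dsa$intensities, dsb$intensities)
})

test_that("generated signal equals the sum of its stored components", {
  design <- spectrum_design(noise_sd = 0.05, spike_rate = 1, seed = 11)
  for (profile in pollen_reference_profiles()[c(1, 20, 37)]) {
    for (seed in 1:5) {
      sp <- generate_spectrum(profile, design, seed = seed)
      comp <- attr(sp, "components")
      total <- comp$scattered_signal + comp$baseline + comp$water +
        comp$noise + comp$spikes
      expect_identical(sp$intensity, total)
    }
  }
})

test_that("dataset counts and manifest labels follow the design", {
  profiles <- separable_profiles(4)
  ds <- generate_dataset(profiles, spectrum_design(n_per_class = 25,
                                                   seed = 2))
  expect_equal(n_spectra(ds), 100)
  expect_equal(length(unique(ds$manifest$genus)), 4)
  expect_equal(nrow(ds$manifest), 100)
  expect_error(generate_dataset(list(), spectrum_design()),
               "at least one")
})

test_that("the taxonomy template has 37 species, 36 genera, 18 families", {
  tax <- pollen_taxonomy()
  expect_equal(nrow(tax), 37)
  expect_equal(length(unique(tax$species)), 37)
  expect_equal(length(unique(tax$genus)), 36)
  expect_equal(length(unique(tax$family)), 18)
  expect_equal(as.vector(table(tax$growth_habit)[c("grass", "herb",
                                                   "shrub", "tree")]),
               c(16, 5, 5, 11))
  ds <- generate_dataset(pollen_reference_profiles(tax),
                         spectrum_design(n_per_class = 1, seed = 1))
  expect_equal(length(unique(ds$manifest$species)), 37)
  expect_equal(length(unique(ds$manifest$genus)), 36)
  expect_equal(length(unique(ds$manifest$family)), 18)
})

test_that("noise-free class means peak within one channel of each profile band", {
  # resolvable bands (separation >> width) and no background terms, so
  # every configured center must surface as a local maximum of the mean
  centers <- c(800, 1004, 1330, 1700, 2200, 2851)
  profiles <- lapply(1:2, function(k) {
    pollen_class_profile(
      sprintf("p%d", k), "herb", "f", sprintf("g%d", k),
      peaks = data.frame(center = centers,
                         amplitude = 0.4 + 0.1 * k + 0.05 * seq_along(centers),
                         width = 7))
  })
  design <- quiet_design(n_per_class = 3, seed = 4)
  ds <- generate_dataset(profiles, design)
  axis <- ds$wavenumber
  step <- axis[2] - axis[1]
  for (p in profiles) {
    mean_sp <- rowMeans(
      ds$intensities[, ds$manifest$species == p$name, drop = FALSE])
    for (center in centers) {
      window <- which(abs(axis - center) <= 12 * step)
      local_max <- window[which.max(mean_sp[window])]
      # within one channel of the channel nearest the configured center
      expect_lte(abs(local_max - which.min(abs(axis - center))), 1)
    }
  }
})

test_that("a peak outside the axis range is an invalid profile", {
  profile <- pollen_class_profile(
    "bad", "tree", "f", "g",
    peaks = data.frame(center = 5000, amplitude = 1, width = 8))
  expect_error(generate_spectrum(profile, quiet_design(), seed = 1),
               "invalid profile")
})

test_that("profile invariants are enforced at construction", {
  expect_error(pollen_class_profile(
    "w", "herb", "f", "g",
    peaks = data.frame(center = 1000, amplitude = 1, width = 0)),
    "width")
  expect_error(pollen_class_profile(
    "a", "herb", "f", "g",
    peaks = data.frame(center = 1000, amplitude = -1, width = 5)),
    "amplitude")
  expect_error(pollen_class_profile(
    "n", "herb", "f", "g",
    peaks = data.frame(center = 1000, amplitude = 1, width = 5),
    water_weight = -1), "water_weight")
})
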