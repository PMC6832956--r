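#' Evaluate a Gaussian band profile
#'
#' @param x axis values (cm^-1).
#' @param center band center (cm^-1).
#' @param amplitude peak height (a.u.).
#' @param width Gaussian sigma (cm^-1), > 0.
#' @return numeric vector of band intensities.
#' @keywords internal
gaussian_band <- function(x, center, amplitude, width) {
  amplitude * exp(-((x - center)^2) / (2 * width^2))
}

#' Broad-band water interferent curve
#'
#' Closed-form stand-in for the Raman response of liquid water: a broad OH
#' bending band near 1640 cm^-1 plus the low-wavenumber tail of the OH
#' stretching envelope centered near 3250 cm^-1. Used as the default EMSC
#' interferent and by the spectrum generator.
#'
#' @param wavenumber axis in cm^-1.
#' @return numeric vector, unit peak height.
#' @export
water_reference <- function(wavenumber) {
  gaussian_band(wavenumber, 1640, 0.45, 90) +
    gaussian_band(wavenumber, 3250, 1.00, 220)
}

#' Define a synthetic pollen class profile
#'
#' A class profile encodes the generative model of one pollen taxon: its
#' Raman bands (Gaussian center/amplitude/width triplets), a polynomial
#' fluorescence baseline, and the weight of the water interferent.
#'
#' @param name species label.
#' @param growth_habit one of `"grass"`, `"herb"`, `"shrub"`, `"tree"`.
#' @param family,genus taxonomic labels.
#' @param peaks data.frame or matrix with columns `center`, `amplitude`,
#'   `width` (cm^-1, a.u., cm^-1). Amplitudes must be >= 0, widths > 0.
#' @param baseline_coeffs numeric coefficients (ascending order) of the
#'   fluorescence baseline, a polynomial in the axis rescaled to `[0, 1]`.
#' @param water_weight nonnegative weight of [water_reference()].
#' @return Object of class `class_profile`.
#' @export
pollen_class_profile <- function(name, growth_habit, family, genus,
                                 peaks, baseline_coeffs = 0,
                                 water_weight = 0) {
  growth_habit <- match.arg(growth_habit,
                            c("grass", "herb", "shrub", "tree"))
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) > 0) {
    stopifnot(all(c("center", "amplitude", "width") %in% names(peaks)))
    if (any(peaks$width <= 0)) stop("peak widths must be > 0", call. = FALSE)
    if (any(peaks$amplitude < 0)) {
      stop("peak amplitudes must be >= 0", call. = FALSE)
    }
  }
  if (water_weight < 0) stop("water_weight must be >= 0", call. = FALSE)
  structure(
    list(name = name, growth_habit = growth_habit, family = family,
         genus = genus, peaks = peaks,
         baseline_coeffs = as.numeric(baseline_coeffs),
         water_weight = water_weight),
    class = "class_profile"
  )
}

#' Spectral dataset design parameters
#'
#' Defaults span 600-3100 cm^-1 over 1200 channels, covering both the
#' fingerprint region (758-1800 cm^-1) and the CH-stretch band near
#' 2851 cm^-1. The per-spectrum multiplicative scatter factor has mean 1
#' and standard deviation `scatter_sd`; `noise_sd` is the additive
#' shot-noise scale and `spike_rate` the expected cosmic spikes per
#' spectrum.
#'
#' @param axis_min,axis_max axis extent, cm^-1.
#' @param n_channels number of spectral channels (>= 2).
#' @param n_per_class spectra generated per class.
#' @param scatter_sd sd of the multiplicative factor (mean 1).
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param spike_rate expected cosmic spikes per spectrum (Poisson).
#' @param seed integer seed; every generator is a pure function of its
#'   inputs and this seed.
#' @return Object of class `spectrum_design`.
#' @export
spectrum_design <- function(axis_min = 600, axis_max = 3100,
                            n_channels = 1200, n_per_class = 25,
                            scatter_sd = 0.15, noise_sd = 0.01,
                            spike_rate = 0.05, seed = 1L) {
  if (axis_min >= axis_max) stop("axis_min must be < axis_max", call. = FALSE)
  if (n_channels < 2) stop("n_channels must be >= 2", call. = FALSE)
  if (scatter_sd < 0 || noise_sd < 0 || spike_rate < 0) {
    stop("rates and standard deviations must be >= 0", call. = FALSE)
  }
  structure(
    list(axis_min = axis_min, axis_max = axis_max,
         n_channels = as.integer(n_channels),
         n_per_class = as.integer(n_per_class),
         scatter_sd = scatter_sd, noise_sd = noise_sd,
         spike_rate = spike_rate, seed = as.integer(seed)),
    class = "spectrum_design"
  )
}

#' @keywords internal
design_axis <- function(design) {
  seq(design$axis_min, design$axis_max, length.out = design$n_channels)
}

# Run code with a temporary RNG seed, restoring global RNG state afterwards
# so generators stay pure functions of (inputs, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Generator core: consumes the *current* RNG stream. Returns the spectrum and
# its exact additive decomposition (ground-truth closure).
generate_spectrum_impl <- function(profile, design) {
  axis <- design_axis(design)
  if (nrow(profile$peaks) > 0 &&
      (any(profile$peaks$center < design$axis_min) ||
       any(profile$peaks$center > design$axis_max))) {
    stop("invalid profile: peak center outside the axis range",
         call. = FALSE)
  }
  pure <- rep(0, length(axis))
  if (nrow(profile$peaks) > 0) {
    for (i in seq_len(nrow(profile$peaks))) {
      pure <- pure + gaussian_band(axis, profile$peaks$center[i],
                                   profile$peaks$amplitude[i],
                                   profile$peaks$width[i])
    }
  }
  scatter <- max(stats::rnorm(1, mean = 1, sd = design$scatter_sd), 0.05)
  u <- (axis - design$axis_min) / (design$axis_max - design$axis_min)
  baseline <- rep(0, length(axis))
  for (k in seq_along(profile$baseline_coeffs)) {
    baseline <- baseline + profile$baseline_coeffs[k] * u^(k - 1)
  }
  water <- profile$water_weight * water_reference(axis)
  noise <- if (design$noise_sd > 0) {
    stats::rnorm(length(axis), 0, design$noise_sd)
  } else {
    rep(0, length(axis))
  }
  spike_vec <- rep(0, length(axis))
  n_spikes <- stats::rpois(1, design$spike_rate)
  spikes <- data.frame(channel = integer(0), height = numeric(0))
  if (n_spikes > 0) {
    chan <- sample.int(length(axis), n_spikes)
    local_amp <- pmax(scatter * pure[chan] + baseline[chan] + water[chan],
                      0.1)
    height <- stats::runif(n_spikes, 10, 100) * local_amp
    spike_vec[chan] <- spike_vec[chan] + height
    spikes <- data.frame(channel = chan, height = height)
  }
  intensity <- scatter * pure + baseline + water + noise + spike_vec
  components <- list(scatter = scatter, pure = pure,
                     scattered_signal = scatter * pure,
                     baseline = baseline, water = water, noise = noise,
                     spikes = spike_vec, spike_table = spikes)
  sp <- raman_spectrum(axis, intensity,
                       meta = list(species = profile$name,
                                   genus = profile$genus,
                                   family = profile$family,
                                   growth_habit = profile$growth_habit))
  attr(sp, "components") <- components
  sp
}

#' Generate one synthetic Raman spectrum
#'
#' The generative model is
#' `scatter * sum(peaks) + baseline + water_weight * water + noise + spikes`,
#' with the multiplicative scatter drawn once per spectrum. The exact
#' additive decomposition is attached as `attr(, "components")` so tests can
#' verify ground-truth closure.
#'
#' @param profile a [pollen_class_profile()].
#' @param design a [spectrum_design()].
#' @param seed integer seed; defaults to `design$seed`.
#' @return A `raman_spectrum` with a `"components"` attribute.
#' @export
generate_spectrum <- function(profile, design, seed = design$seed) {
  with_seed(seed, generate_spectrum_impl(profile, design))
}

#' Generate a labeled synthetic spectral dataset
#'
#' Draws `design$n_per_class` spectra per profile and assembles them with a
#' labels manifest (id, species, genus, family, growth_habit). Deterministic
#' for a fixed `design$seed`.
#'
#' @param profiles list of [pollen_class_profile()] objects (>= 1).
#' @param design a [spectrum_design()].
#' @param keep_components if `TRUE`, attach the per-spectrum ground-truth
#'   component lists as `attr(, "components")`.
#' @return A `spectral_dataset`.
#' @export
generate_dataset <- function(profiles, design, keep_components = FALSE) {
  if (length(profiles) == 0) {
    stop("at least one class profile is required", call. = FALSE)
  }
  with_seed(design$seed, {
    axis <- design_axis(design)
    n_total <- length(profiles) * design$n_per_class
    intens <- matrix(NA_real_, nrow = design$n_channels, ncol = n_total)
    manifest <- vector("list", n_total)
    components <- if (keep_components) vector("list", n_total) else NULL
    col <- 0L
    for (p in profiles) {
      slug <- gsub("[^A-Za-z0-9]+", "_", p$name)
      for (j in seq_len(design$n_per_class)) {
        col <- col + 1L
        sp <- generate_spectrum_impl(p, design)
        intens[, col] <- sp$intensity
        manifest[[col]] <- data.frame(
          id = sprintf("%s_%03d", slug, j),
          species = p$name, genus = p$genus, family = p$family,
          growth_habit = p$growth_habit, stringsAsFactors = FALSE)
        if (keep_components) components[[col]] <- attr(sp, "components")
      }
    }
    ds <- spectral_dataset(axis, intens, do.call(rbind, manifest))
    if (keep_components) attr(ds, "components") <- components
    ds
  })
}

#' Taxonomy template: 37 pollen classes in 4 growth-habit groups
#'
#' The class list used throughout the package as the default simulation
#' template: 16 grass, 5 herb, 5 shrub (two congeneric Artemisia species)
#' and 11 tree classes — 37 species from 36 genera and 18 families.
#'
#' @return data.frame with columns `species`, `genus`, `family`,
#'   `growth_habit`.
#' @export
pollen_taxonomy <- function() {
  grass_genera <- c("Festuca", "Arrhenatherum", "Holcus", "Phleum",
                    "Lolium", "Molinia", "Elymus", "Calamagrostis", "Poa",
                    "Secale", "Phragmites", "Deschampsia", "Scirpus",
                    "Agrostis", "Bromus", "Helictotrichon")
  grass_family <- ifelse(grass_genera == "Scirpus", "Cyperaceae", "Poaceae")
  herb <- data.frame(
    species = c("Cyclamen", "Rumex", "Amaranthus", "Papaver", "Plantago"),
    genus = c("Cyclamen", "Rumex", "Amaranthus", "Papaver", "Plantago"),
    family = c("Primulaceae", "Polygonaceae", "Amaranthaceae",
               "Papaveraceae", "Plantaginaceae"),
    growth_habit = "herb", stringsAsFactors = FALSE)
  shrub <- data.frame(
    species = c("Artemisia absinthium", "Rosa", "Ambrosia", "Helianthus",
                "Artemisia vulgaris"),
    genus = c("Artemisia", "Rosa", "Ambrosia", "Helianthus", "Artemisia"),
    family = c("Asteraceae", "Rosaceae", "Asteraceae", "Asteraceae",
               "Asteraceae"),
    growth_habit = "shrub", stringsAsFactors = FALSE)
  tree_genera <- c("Alnus", "Fraxinus", "Ranunculus", "Corylus", "Sambucus",
                   "Larix", "Populus", "Platanus", "Fagus", "Ulmus",
                   "Betula")
  tree_family <- c("Betulaceae", "Oleaceae", "Ranunculaceae", "Betulaceae",
                   "Adoxaceae", "Pinaceae", "Salicaceae", "Platanaceae",
                   "Fagaceae", "Ulmaceae", "Betulaceae")
  rbind(
    data.frame(species = grass_genera, genus = grass_genera,
               family = grass_family, growth_habit = "grass",
               stringsAsFactors = FALSE),
    herb, shrub,
    data.frame(species = tree_genera, genus = tree_genera,
               family = tree_family, growth_habit = "tree",
               stringsAsFactors = FALSE)
  )
}

# Canonical pollen Raman band centers (cm^-1): nucleic-acid ring breathing
# (783), phenylalanine (1004), lipid bands (1065, 1304, 1441, 1750, 2851),
# sporopollenin aromatics (1173, 1209, 1590, 1610, 1637), amide I (1660),
# plus 1263 and 1455.
pollen_band_centers <- function() {
  c(783, 1004, 1065, 1173, 1209, 1263, 1304, 1441, 1455,
    1590, 1610, 1637, 1660, 1750, 2851)
}

#' Reference class profiles for the 37-class template
#'
#' Builds one generative profile per taxonomy row. All classes share the
#' canonical band centers; the amplitude pattern has a strong growth-habit
#' component (so unsupervised clustering recovers habit groups) plus a
#' smaller deterministic per-species modulation of size
#' `amplitude_contrast` (so supervised models can resolve species). The
#' modulation is a fixed trigonometric pattern of the species index — no
#' randomness enters the profiles themselves.
#'
#' @param taxonomy data.frame as returned by [pollen_taxonomy()].
#' @param amplitude_contrast per-species amplitude modulation depth (a.u.).
#' @return list of `class_profile` objects, one per taxonomy row.
#' @export
pollen_reference_profiles <- function(taxonomy = pollen_taxonomy(),
                                      amplitude_contrast = 0.25) {
  centers <- pollen_band_centers()
  nb <- length(centers)
  # each habit emphasizes its own subset of bands on top of a shared
  # pollen signature, so unsupervised clustering can recover the habit
  # groups while species stay resolvable within a habit
  habit_bands <- list(grass = c(1, 5, 9, 13), herb = c(2, 6, 10, 14),
                      shrub = c(3, 7, 11, 15), tree = c(4, 8, 12))
  base <- lapply(habit_bands, function(bands) {
    amp <- rep(0.45, nb)
    amp[bands] <- 1.2
    amp
  })
  widths <- ifelse(centers > 2000, 14, 7)
  profiles <- vector("list", nrow(taxonomy))
  for (k in seq_len(nrow(taxonomy))) {
    row <- taxonomy[k, ]
    mod <- amplitude_contrast *
      cos(2 * pi * k * seq_len(nb) / 37 + k / 3)
    amp <- pmax(base[[row$growth_habit]] + mod, 0.02)
    profiles[[k]] <- pollen_class_profile(
      name = row$species, growth_habit = row$growth_habit,
      family = row$family, genus = row$genus,
      peaks = data.frame(center = centers, amplitude = amp,
                         width = widths),
      baseline_coeffs = switch(row$growth_habit,
                               grass = c(0.8, 1.2, -0.9),
                               herb  = c(1.0, 0.6, -0.4),
                               shrub = c(0.6, 1.5, -1.1),
                               tree  = c(0.9, 0.8, -0.6)),
      water_weight = 0.4
    )
  }
  profiles
}

#' Build well-separated single-habit profiles for recovery studies
#'
#' Produces `n_classes` profiles of one growth habit whose band-amplitude
#' patterns differ between classes by `separation` (a.u.) on a subset of
#' bands. With additive noise of sd `noise_sd`, the peak-amplitude
#' separation-to-noise ratio is `separation / noise_sd`.
#'
#' @param n_classes number of classes (>= 2).
#' @param separation between-class amplitude difference (a.u.).
#' @param habit growth habit label for all classes.
#' @return list of `class_profile` objects.
#' @export
separable_profiles <- function(n_classes = 4, separation = 0.25,
                               habit = "herb") {
  centers <- pollen_band_centers()
  nb <- length(centers)
  widths <- ifelse(centers > 2000, 14, 7)
  base <- 0.6 + 0.3 * sin(seq(0, 2 * pi, length.out = nb))
  lapply(seq_len(n_classes), function(k) {
    # orthogonal-ish sign patterns distinguish classes
    signs <- ifelse(((seq_len(nb) %/% k) %% 2) == 0, 1, -1)
    amp <- pmax(base + separation * signs *
                  sin(pi * k * seq_len(nb) / (nb + 1)), 0.02)
    pollen_class_profile(
      name = sprintf("class_%02d", k), growth_habit = habit,
      family = sprintf("family_%02d", k), genus = sprintf("genus_%02d", k),
      peaks = data.frame(center = centers, amplitude = amp, width = widths),
      baseline_coeffs = c(0.8, 0.9, -0.6), water_weight = 0.4)
  })
}
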