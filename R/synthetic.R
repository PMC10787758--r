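#' Configuration for the synthetic egg hypercube generator
#'
#' Builds the parameter set that defines a simulated acquisition campaign:
#' labelled fertile/infertile transmission hypercubes plus the dark and
#' reference calibration frames. The generator emulates the statistical
#' structure the downstream chemometrics assumes — higher overall
#' transmission for fertile eggs, absorption valleys at fixed pigment and
#' overtone wavelengths, class-discriminative extra absorption confined to
#' narrow NIR bands, per-egg multiplicative/additive scatter, an elliptical
#' egg on a dark background, and calibration frames at distinct exposures.
#'
#' @param n_fertile,n_infertile Number of eggs per class.
#' @param rows,cols Spatial dimensions in pixels. 64 x 64 is the desk scale;
#'   set 400 x 400 for full-fidelity geometry.
#' @param n_bands Number of spectral bands after binning.
#' @param wavelength_range Length-2 nm vector, band centers span this window.
#' @param absorption_centers Wavelengths (nm) of the shared transmission
#'   valleys (yolk carotenoids at 580/634/665 nm; O-H and C-H overtone bands
#'   at 730/770/830/930 nm).
#' @param absorption_widths Gaussian sigma (nm) of each valley (recycled).
#' @param absorption_depths Fractional depth in (0,1) of each valley
#'   (recycled); shared by the two classes.
#' @param class_effect_bands List of nm intervals (length-2 vectors) where
#'   fertility expresses as extra absorption.
#' @param class_effect_size Mean fractional extra absorption applied to
#'   fertile eggs inside `class_effect_bands`, in (0,1).
#' @param class_effect_sd Per-egg sd of the expressed effect: each fertile
#'   egg absorbs `max(0, N(class_effect_size, class_effect_sd))` inside the
#'   effect bands, so weakly expressing fertile eggs overlap the infertile
#'   class (the realistic, imperfectly separable regime).
#' @param band_scatter_sd Per-egg, per-band fractional transmission jitter
#'   (spectrally white egg-to-egg variability at band scale).
#' @param fertile_transmission_gain Global multiplicative transmission gain
#'   of fertile eggs (> 1: fertile eggs transmit more overall).
#' @param scatter_slope_sd,scatter_offset_sd Per-egg multiplicative slope
#'   (around 1) and additive offset (around 0, transmittance units) scatter.
#' @param shape_poly_sd Per-egg smooth spectral shape variability: fractional
#'   sd of a random degree-3 polynomial (in the scaled wavelength) that
#'   multiplies the transmission curve, emulating egg-to-egg shell and
#'   composition differences that are not spectrally flat.
#' @param noise_sd Additive Gaussian detector noise, intensity units.
#' @param exposure_sample,exposure_reference Exposure times `e_s`, `e_r` (ms)
#'   of sample/dark and reference acquisitions.
#' @param egg_axes Length-2 pixel semi-axes (row, col) of the elliptical egg
#'   phantom, centered in the frame.
#' @param background_level Background intensity outside the egg.
#' @param dark_current Detector dark-current rate, intensity units per ms;
#'   present in every acquisition.
#' @param seed Integer; fully determines the generated dataset.
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_fertile = 131,
                         n_infertile = 96,
                         rows = 64,
                         cols = 64,
                         n_bands = 256,
                         wavelength_range = c(500, 950),
                         absorption_centers = c(580, 634, 665, 730, 770, 830, 930),
                         absorption_widths = 12,
                         absorption_depths = 0.30,
                         class_effect_bands = list(
                           c(673, 675), c(798, 800), c(813, 840), c(865, 873)
                         ),
                         class_effect_size = 0.05,
                         class_effect_sd = 0.03,
                         band_scatter_sd = 0.01,
                         fertile_transmission_gain = 1.04,
                         scatter_slope_sd = 0.05,
                         scatter_offset_sd = 0.01,
                         shape_poly_sd = 0.01,
                         noise_sd = 25,
                         exposure_sample = 100,
                         exposure_reference = 1,
                         egg_axes = c(24, 18),
                         background_level = 30,
                         dark_current = 0.2,
                         seed = 1) {
  cfg <- list(
    n_fertile = as.integer(n_fertile), n_infertile = as.integer(n_infertile),
    rows = as.integer(rows), cols = as.integer(cols),
    n_bands = as.integer(n_bands),
    wavelength_range = as.numeric(wavelength_range),
    absorption_centers = as.numeric(absorption_centers),
    absorption_widths = rep_len(as.numeric(absorption_widths), length(absorption_centers)),
    absorption_depths = rep_len(as.numeric(absorption_depths), length(absorption_centers)),
    class_effect_bands = lapply(class_effect_bands, as.numeric),
    class_effect_size = as.numeric(class_effect_size),
    class_effect_sd = as.numeric(class_effect_sd),
    band_scatter_sd = as.numeric(band_scatter_sd),
    fertile_transmission_gain = as.numeric(fertile_transmission_gain),
    scatter_slope_sd = as.numeric(scatter_slope_sd),
    scatter_offset_sd = as.numeric(scatter_offset_sd),
    shape_poly_sd = as.numeric(shape_poly_sd),
    noise_sd = as.numeric(noise_sd),
    exposure_sample = as.numeric(exposure_sample),
    exposure_reference = as.numeric(exposure_reference),
    egg_axes = as.numeric(egg_axes),
    background_level = as.numeric(background_level),
    dark_current = as.numeric(dark_current),
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_fertile < 1 || cfg$n_infertile < 1) {
    abort("Both classes must contain at least one egg.")
  }
  if (cfg$rows < 1 || cfg$cols < 1 || cfg$n_bands < 1) {
    abort("Non-positive dimensions are not allowed.")
  }
  if (diff(cfg$wavelength_range) <= 0) abort("`wavelength_range` must increase.")
  if (any(cfg$absorption_depths <= 0 | cfg$absorption_depths >= 1)) {
    abort("All absorption depths must lie in (0, 1).")
  }
  if (cfg$class_effect_size < 0 || cfg$class_effect_size >= 1) {
    abort("`class_effect_size` must lie in [0, 1).")
  }
  for (band in cfg$class_effect_bands) {
    if (length(band) != 2L || band[1] > band[2]) {
      abort("Each class-effect band must be an increasing nm pair.")
    }
    if (band[1] < cfg$wavelength_range[1] || band[2] > cfg$wavelength_range[2]) {
      abort(sprintf(
        "Class-effect band %g-%g nm lies outside the wavelength range.",
        band[1], band[2]
      ))
    }
  }
  if (cfg$exposure_sample <= 0 || cfg$exposure_reference <= 0) {
    abort("Exposure times must be positive.")
  }
  if (cfg$noise_sd < 0 || cfg$scatter_slope_sd < 0 || cfg$scatter_offset_sd < 0 ||
      cfg$shape_poly_sd < 0 || cfg$class_effect_sd < 0 || cfg$band_scatter_sd < 0) {
    abort("Noise and scatter scales must be nonnegative.")
  }
  invisible(cfg)
}

#' Band-center wavelength grid of a configuration
#'
#' Band centers of `n_bands` equal-width blocks spanning `wavelength_range`.
#'
#' @param config A `synth_config`.
#' @return Numeric vector of length `n_bands`.
#' @export
wavelength_grid <- function(config) {
  r <- config$wavelength_range
  width <- diff(r) / config$n_bands
  r[1] + (seq_len(config$n_bands) - 0.5) * width
}

#' Tungsten-halogen-like lamp spectrum
#'
#' Planck radiance at 3250 K (the blend of the study-style 3200/3270 K
#' lamps), scaled to peak at 100 flux units per ms on the 500-950 nm window.
#'
#' @param wavelengths Wavelengths in nm.
#' @return Relative spectral flux per ms, peak 100 on the window.
#' @export
lamp_spectrum <- function(wavelengths) {
  # Planck's law, wavelength in meters; constants folded into the exponent
  lam <- wavelengths * 1e-9
  temp <- 3250
  b <- 1 / (lam^5 * (exp(1.4388e-2 / (lam * temp)) - 1))
  ref <- seq(500, 950, length.out = 512) * 1e-9
  bmax <- max(1 / (ref^5 * (exp(1.4388e-2 / (ref * temp)) - 1)))
  100 * b / bmax
}

#' Closed-form egg transmission curve
#'
#' The analytic per-class transmission curve the generator modulates the lamp
#' with, before per-egg scatter and noise: a smooth sigmoidal shell/albumen
#' baseline rising toward the NIR red edge, multiplied by Gaussian absorption
#' valleys at `absorption_centers`; fertile eggs get the global transmission
#' gain and extra absorption inside `class_effect_bands`.
#'
#' @param config A `synth_config`.
#' @param class `"fertile"` or `"infertile"`.
#' @param wavelengths Optional wavelength grid; defaults to
#'   [wavelength_grid()].
#' @return A tibble with columns `wavelength`, `transmittance`, `class`;
#'   transmittance in (0, 1].
#' @export
transmission_curve <- function(config, class = c("fertile", "infertile"),
                               wavelengths = NULL) {
  class <- match.arg(class)
  wl <- wavelengths %||% wavelength_grid(config)
  base <- 0.08 + 0.47 / (1 + exp(-(wl - 690) / 55))
  absorb <- rep(1, length(wl))
  for (i in seq_along(config$absorption_centers)) {
    absorb <- absorb * (1 - config$absorption_depths[i] *
      exp(-(wl - config$absorption_centers[i])^2 / (2 * config$absorption_widths[i]^2)))
  }
  tcurve <- base * absorb
  if (class == "fertile") {
    tcurve <- tcurve * config$fertile_transmission_gain
    tcurve <- tcurve * (1 - config$class_effect_size * effect_weights(config, wl))
  }
  tcurve <- pmin(tcurve, 1)
  tibble::tibble(wavelength = wl, transmittance = tcurve, class = class)
}

#' Ground-truth egg mask of the phantom
#'
#' The discretized centered ellipse with semi-axes `egg_axes`; pixel (i, j)
#' is foreground when `((i-cr)/a)^2 + ((j-cc)/b)^2 <= 1`.
#'
#' @param config A `synth_config`.
#' @return An [egg_mask()].
#' @export
true_mask <- function(config) {
  a <- config$egg_axes[1]
  b <- config$egg_axes[2]
  cr <- (config$rows + 1) / 2
  cc <- (config$cols + 1) / 2
  if (a <= 0 || b <= 0) {
    return(egg_mask(matrix(0L, config$rows, config$cols)))
  }
  ii <- matrix(seq_len(config$rows), config$rows, config$cols)
  jj <- matrix(seq_len(config$cols), config$rows, config$cols, byrow = TRUE)
  egg_mask(((ii - cr) / a)^2 + ((jj - cc) / b)^2 <= 1)
}

# Chord-length path factor inside the ellipse, 1 at center, 0 at the rim.
path_factor <- function(config) {
  a <- config$egg_axes[1]
  b <- config$egg_axes[2]
  cr <- (config$rows + 1) / 2
  cc <- (config$cols + 1) / 2
  ii <- matrix(seq_len(config$rows), config$rows, config$cols)
  jj <- matrix(seq_len(config$cols), config$rows, config$cols, byrow = TRUE)
  r2 <- ((ii - cr) / a)^2 + ((jj - cc) / b)^2
  p <- sqrt(pmax(1 - r2, 0))
  p * (r2 <= 1)
}

#' Generate a labelled synthetic hyperspectral egg dataset
#'
#' One transmission hypercube per egg, plus dark and reference calibration
#' frames. Each cube is lamp spectrum x per-egg transmission curve x
#' per-pixel path-length factor inside the elliptical egg, background
#' outside, with dark current and additive Gaussian detector noise:
#' `I(x, y, lambda) = (lamp(lambda) * T_egg(lambda) * path(x, y) + dark_current) * e_s + noise`.
#' Per-egg scatter perturbs the class transmission curve as `a * T + b` with
#' `a ~ N(1, scatter_slope_sd)`, `b ~ N(0, scatter_offset_sd)`. The dark
#' frame is dark current at the sample exposure; the reference frame is the
#' unattenuated lamp at the (much shorter) reference exposure.
#'
#' @param config A `synth_config`.
#' @return A list with elements `cubes` (list of [hypercube()]), `labels`
#'   (tibble `sample_id`, `class`), and `calibration`
#'   ([calibration_frames()]).
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  withr_seed(config$seed)
  wl <- wavelength_grid(config)
  lamp <- lamp_spectrum(wl)
  path <- path_factor(config)
  inside <- path > 0
  labels <- tibble::tibble(
    sample_id = sprintf("egg_%03d", seq_len(config$n_fertile + config$n_infertile)),
    class = c(rep("fertile", config$n_fertile), rep("infertile", config$n_infertile))
  )
  curves <- base_class_curves(config, wl)
  eff_w <- effect_weights(config, wl)
  e_s <- config$exposure_sample
  cubes <- vector("list", nrow(labels))
  for (k in seq_len(nrow(labels))) {
    tcurve <- draw_egg_curve(config, labels$class[k], curves[[labels$class[k]]], eff_w)
    flux <- outer(as.vector(path), tcurve) # pixels x bands
    intens <- (flux * rep(lamp, each = length(path)) + config$dark_current) * e_s
    intens[!inside, ] <- config$background_level + config$dark_current * e_s
    if (config$noise_sd > 0) {
      intens <- intens + rnorm(length(intens), 0, config$noise_sd)
    }
    arr <- array(pmax(intens, 0), dim = c(config$rows, config$cols, config$n_bands))
    cubes[[k]] <- hypercube(arr, wl, e_s)
  }
  dark_i <- matrix(config$dark_current * e_s, config$rows * config$cols, config$n_bands)
  ref_i <- (rep(lamp, each = config$rows * config$cols) + config$dark_current) *
    config$exposure_reference
  ref_i <- matrix(ref_i, config$rows * config$cols, config$n_bands)
  if (config$noise_sd > 0) {
    dark_i <- dark_i + rnorm(length(dark_i), 0, config$noise_sd)
    ref_i <- ref_i + rnorm(length(ref_i), 0, config$noise_sd)
  }
  calib <- calibration_frames(
    dark = hypercube(
      array(pmax(dark_i, 0), dim = c(config$rows, config$cols, config$n_bands)),
      wl, e_s
    ),
    reference = hypercube(
      array(pmax(ref_i, 0), dim = c(config$rows, config$cols, config$n_bands)),
      wl, config$exposure_reference
    )
  )
  list(cubes = cubes, labels = labels, calibration = calib)
}

withr_seed <- function(seed) set.seed(seed)

# Per-class transmission curves *without* the fertility effect (the effect
# strength is drawn per egg), plus the band index where the effect acts.
base_class_curves <- function(config, wl) {
  cfg0 <- config
  cfg0$class_effect_size <- 0
  list(
    fertile = transmission_curve(cfg0, "fertile", wl)$transmittance,
    infertile = transmission_curve(cfg0, "infertile", wl)$transmittance
  )
}

# Spectral profile of the fertility effect: a raised-cosine lobe inside each
# effect band (absorption features are peaked, not rectangular), 1 at the
# band midpoint and 0 at its edges and outside.
effect_weights <- function(config, wl) {
  w <- rep(0, length(wl))
  for (band in config$class_effect_bands) {
    inside <- wl >= band[1] & wl <= band[2]
    if (!any(inside)) next
    mid <- mean(band)
    half <- max((band[2] - band[1]) / 2, 1e-9)
    lobe <- 0.5 * (1 + cos(pi * (wl[inside] - mid) / half))
    # rescale so the best-covered band of every interval expresses the full
    # effect (narrow intervals would otherwise sit on the lobe's skirts)
    lobe <- lobe / max(lobe)
    w[inside] <- pmax(w[inside], lobe)
  }
  w
}

# One egg's realized transmission curve: the class base curve with a per-egg
# expressed fertility effect inside the effect bands, per-egg flat scatter
# (a*T + b), a smooth random degree-3 polynomial shape factor, and per-band
# fractional jitter, clamped into (0, 1].
draw_egg_curve <- function(config, class, base_curve, eff_w) {
  tcurve <- base_curve
  if (class == "fertile" && config$class_effect_size > 0) {
    expressed <- max(0, rnorm(1, config$class_effect_size, config$class_effect_sd))
    tcurve <- tcurve * (1 - min(expressed, 0.99) * eff_w)
  }
  a <- rnorm(1, 1, config$scatter_slope_sd)
  b <- rnorm(1, 0, config$scatter_offset_sd)
  tcurve <- a * tcurve + b
  if (config$shape_poly_sd > 0) {
    u <- seq(-1, 1, length.out = length(base_curve))
    coefs <- rnorm(3, 0, config$shape_poly_sd)
    tcurve <- tcurve * (1 + coefs[1] * u + coefs[2] * (1.5 * u^2 - 0.5) +
      coefs[3] * (2.5 * u^3 - 1.5 * u))
  }
  if (config$band_scatter_sd > 0) {
    tcurve <- tcurve * (1 + rnorm(length(tcurve), 0, config$band_scatter_sd))
  }
  pmin(pmax(tcurve, 1e-6), 1)
}

#' Simulate extracted relative-transmittance spectra
#'
#' Runs the full acquisition-to-spectrum pipeline on a synthetic campaign:
#' generates each egg's hypercube, segments it on the 630 nm contrast band,
#' averages the spectra over the egg mask, and converts to relative
#' transmittance against the dark/reference frames. Cubes are generated and
#' discarded one at a time, so memory stays flat in the number of eggs.
#'
#' @param config A `synth_config`.
#' @param contrast_nm Wavelength used for segmentation (default 630).
#' @param convention Dark-exposure convention for
#'   [relative_transmittance()].
#' @return A spectrum table (see [spectra_table()]).
#' @export
simulate_spectra <- function(config, contrast_nm = 630,
                             convention = c("as_printed", "per_frame")) {
  convention <- match.arg(convention)
  validate_synth_config(config)
  withr_seed(config$seed)
  wl <- wavelength_grid(config)
  lamp <- lamp_spectrum(wl)
  path <- path_factor(config)
  inside <- path > 0
  labels <- tibble::tibble(
    sample_id = sprintf("egg_%03d", seq_len(config$n_fertile + config$n_infertile)),
    class = c(rep("fertile", config$n_fertile), rep("infertile", config$n_infertile))
  )
  curves <- base_class_curves(config, wl)
  eff_w <- effect_weights(config, wl)
  e_s <- config$exposure_sample
  out <- matrix(NA_real_, nrow(labels), config$n_bands)
  for (k in seq_len(nrow(labels))) {
    tcurve <- draw_egg_curve(config, labels$class[k], curves[[labels$class[k]]], eff_w)
    flux <- outer(as.vector(path), tcurve)
    intens <- (flux * rep(lamp, each = length(path)) + config$dark_current) * e_s
    intens[!inside, ] <- config$background_level + config$dark_current * e_s
    if (config$noise_sd > 0) {
      intens <- intens + rnorm(length(intens), 0, config$noise_sd)
    }
    cube <- hypercube(
      array(pmax(intens, 0), dim = c(config$rows, config$cols, config$n_bands)),
      wl, e_s
    )
    mask <- segment_egg(band_image(cube, contrast_nm))
    out[k, ] <- mean_roi_spectrum(cube, mask)
  }
  dark_i <- matrix(config$dark_current * e_s, config$rows * config$cols, config$n_bands)
  ref_i <- matrix(
    (rep(lamp, each = config$rows * config$cols) + config$dark_current) *
      config$exposure_reference,
    config$rows * config$cols, config$n_bands
  )
  if (config$noise_sd > 0) {
    dark_i <- dark_i + rnorm(length(dark_i), 0, config$noise_sd)
    ref_i <- ref_i + rnorm(length(ref_i), 0, config$noise_sd)
  }
  t_d <- colMeans(pmax(dark_i, 0))
  t_r <- colMeans(pmax(ref_i, 0))
  trel <- t(apply(out, 1, function(ts) {
    relative_transmittance(ts, t_d, t_r,
      e_s = e_s, e_r = config$exposure_reference,
      convention = convention
    )
  }))
  spectra_table(trel, wl, labels$class, labels$sample_id)
}

#' Write a synthetic campaign to disk
#'
#' Cubes as ENVI pairs, labels as CSV, configuration as YAML.
#'
#' @param dataset Result of [generate_dataset()].
#' @param config The generating `synth_config`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(dataset$cubes)) {
    write_envi(dataset$cubes[[k]], file.path(dir, dataset$labels$sample_id[k]))
  }
  write_envi(dataset$calibration$dark, file.path(dir, "dark"))
  write_envi(dataset$calibration$reference, file.path(dir, "reference"))
  utils::write.csv(dataset$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  cfg <- unclass(config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
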