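test_that("configuration validation rejects degenerate campaigns", {
  expect_error(synth_config(n_fertile = 0), "at least one egg")
  expect_error(synth_config(rows = 0), "Non-positive")
  expect_error(synth_config(absorption_depths = 1.2), "in \\(0, 1\\)")
  expect_error(
    synth_config(class_effect_bands = list(c(400, 450))),
    "outside the wavelength range"
  )
  expect_error(synth_config(noise_sd = -1), "nonnegative")
  expect_error(synth_config(exposure_reference = 0), "positive")
})

test_that("the seed fully determines the generated cubes", {
  cfg <- synth_config(
    n_fertile = 2, n_infertile = 1, rows = 16, cols = 16, n_bands = 32,
    egg_axes = c(6, 5), seed = 1
  )
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$cubes[[1]]$data, d2$cubes[[1]]$data)
  expect_identical(d1$calibration$T_r, d2$calibration$T_r)
  cfg2 <- synth_config(
    n_fertile = 2, n_infertile = 1, rows = 16, cols = 16, n_bands = 32,
    egg_axes = c(6, 5), seed = 2
  )
  d3 <- generate_dataset(cfg2)
  expect_false(identical(d1$cubes[[1]]$data, d3$cubes[[1]]$data))
})

test_that("with no planted effect the class transmission curves coincide", {
  cfg <- synth_config(
    noise_sd = 0, scatter_slope_sd = 0, scatter_offset_sd = 0,
    shape_poly_sd = 0, band_scatter_sd = 0,
    class_effect_size = 0, fertile_transmission_gain = 1
  )
  f <- transmission_curve(cfg, "fertile")
  i <- transmission_curve(cfg, "infertile")
  expect_equal(f$transmittance, i$transmittance)
  # and the extracted mean spectra agree too
  cfg_small <- synth_config(
    n_fertile = 2, n_infertile = 2, rows = 32, cols = 32, n_bands = 48,
    egg_axes = c(12, 9),
    noise_sd = 0, scatter_slope_sd = 0, scatter_offset_sd = 0,
    shape_poly_sd = 0, band_scatter_sd = 0,
    class_effect_size = 0, fertile_transmission_gain = 1, seed = 3
  )
  tb <- simulate_spectra(cfg_small)
  m <- spectra_matrix(tb)
  expect_equal(colMeans(m[tb$class == "fertile", ]),
               colMeans(m[tb$class == "infertile", ]))
})

test_that("the transmission curve has a local minimum near each absorption center", {
  cfg <- synth_config()
  curve <- transmission_curve(cfg, "infertile")
  wl <- curve$wavelength
  tt <- curve$transmittance
  for (i in seq_along(cfg$absorption_centers)) {
    center <- cfg$absorption_centers[i]
    width <- cfg$absorption_widths[i]
    # the valley minimum sits strictly inside +/- one absorption width of
    # the center (the sloping baseline shifts it off-center by a few nm)
    win <- which(wl >= center - width & wl <= center + width)
    jmin <- win[which.min(tt[win])]
    expect_gt(jmin, min(win))
    expect_lt(jmin, max(win))
    expect_lt(tt[jmin], tt[min(win)])
    expect_lt(tt[jmin], tt[max(win)])
  }
})

test_that("true_mask matches the discretized ellipse", {
  expect_equal(sum(true_mask(synth_config(egg_axes = c(0, 0)))), 0)
  full <- true_mask(synth_config(rows = 16, cols = 16, egg_axes = c(100, 100)))
  expect_true(all(full == 1))
  m <- true_mask(synth_config(rows = 64, cols = 64, egg_axes = c(16, 24)))
  expect_lt(abs(sum(m) - pi * 16 * 24) / (pi * 16 * 24), 0.02)
})

test_that("zero-noise zero-scatter extraction round-trips the transmission curve", {
  cfg <- synth_config(
    n_fertile = 1, n_infertile = 1, rows = 48, cols = 48, n_bands = 64,
    egg_axes = c(18, 14),
    noise_sd = 0, scatter_slope_sd = 0, scatter_offset_sd = 0,
    shape_poly_sd = 0, band_scatter_sd = 0, class_effect_sd = 0, seed = 5
  )
  ds <- generate_dataset(cfg)
  mask <- true_mask(cfg)
  calib <- ds$calibration
  for (k in seq_along(ds$cubes)) {
    cl <- ds$labels$class[k]
    ts <- mean_roi_spectrum(ds$cubes[[k]], mask)
    trel <- relative_transmittance(
      ts, calib$T_d, calib$T_r,
      e_s = ds$cubes[[k]]$exposure, e_r = calib$reference$exposure
    )
    curve <- transmission_curve(cfg, cl, wavelength_grid(cfg))$transmittance
    ratio <- trel / (curve * 100)
    # constant path-length normalization, exact at every band
    expect_lt(diff(range(ratio)), 1e-9)
    expect_true(all(ratio > 0 & ratio < 1))
  }
})

test_that("between-class distance in the effect bands grows with effect size", {
  dist_for <- function(effect) {
    cfg <- synth_config(
      n_fertile = 1, n_infertile = 1, rows = 24, cols = 24, n_bands = 128,
      egg_axes = c(9, 7),
      class_effect_size = effect, class_effect_sd = 0,
      noise_sd = 0, scatter_slope_sd = 0, scatter_offset_sd = 0,
      shape_poly_sd = 0, band_scatter_sd = 0, seed = 2
    )
    wl <- wavelength_grid(cfg)
    eff <- rep(FALSE, length(wl))
    for (b in cfg$class_effect_bands) eff <- eff | (wl >= b[1] & wl <= b[2])
    f <- transmission_curve(cfg, "fertile")$transmittance
    i <- transmission_curve(cfg, "infertile")$transmittance
    sqrt(sum((f[eff] - i[eff])^2))
  }
  d <- vapply(c(0.05, 0.15, 0.30), dist_for, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("generated cubes and calibration frames are nonnegative", {
  cfg <- synth_config(
    n_fertile = 2, n_infertile = 2, rows = 24, cols = 24, n_bands = 32,
    egg_axes = c(9, 7), noise_sd = 60, seed = 9
  )
  ds <- generate_dataset(cfg)
  expect_true(all(vapply(ds$cubes, function(cb) all(cb$data >= 0), logical(1))))
  expect_true(all(ds$calibration$dark$data >= 0))
  expect_true(all(ds$calibration$reference$data >= 0))
})

test_that("a campaign can be written to disk and read back", {
  cfg <- synth_config(
    n_fertile = 1, n_infertile = 1, rows = 8, cols = 8, n_bands = 12,
    egg_axes = c(3, 2), seed = 4
  )
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, cfg, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  back <- read_envi(file.path(dir, "egg_001"))
  expect_equal(back$data, ds$cubes[[1]]$data, tolerance = 1e-12)
  expect_equal(back$wavelengths, ds$cubes[[1]]$wavelengths)
  expect_equal(back$exposure, ds$cubes[[1]]$exposure)
})
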