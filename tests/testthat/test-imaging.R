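make_cube <- function(arr, wl = NULL, exposure = 100) {
  if (is.null(wl)) wl <- seq(500, 950, length.out = dim(arr)[3])
  hypercube(arr, wl, exposure)
}

test_that("contrast band selection is nearest-neighbour with low-index ties", {
  cube <- make_cube(array(1, dim = c(2, 2, 256)))
  idx <- select_contrast_band(cube, 630)
  expect_lte(abs(cube$wavelengths[idx] - 630), diff(cube$wavelengths)[1] / 2)
  cube3 <- make_cube(array(1, dim = c(2, 2, 3)), wl = c(500, 700, 900))
  expect_equal(select_contrast_band(cube3, 630), 2) # 700 is nearest
  expect_equal(select_contrast_band(cube3, 700), 2) # exact grid point
  expect_equal(select_contrast_band(cube3, 600), 1) # tie breaks to lower index
  expect_error(select_contrast_band(cube3, 300), "outside")
})

test_that("segmentation recovers the phantom and fails cleanly on blanks", {
  cfg <- synth_config(
    n_fertile = 1, n_infertile = 1, noise_sd = 0,
    scatter_slope_sd = 0, scatter_offset_sd = 0,
    shape_poly_sd = 0, band_scatter_sd = 0, seed = 1
  )
  truth <- true_mask(cfg)
  ds <- generate_dataset(cfg)
  mask <- segment_egg(band_image(ds$cubes[[1]], 630))
  expect_gte(mask_iou(mask, truth), 0.99)
  expect_error(segment_egg(matrix(5, 32, 32)), "constant")
})

test_that("segmentation is robust to default detector noise", {
  cfg <- synth_config(n_fertile = 1, n_infertile = 1, seed = 1)
  truth <- true_mask(cfg)
  ious <- vapply(1:10, function(s) {
    ds <- generate_dataset(synth_config(n_fertile = 1, n_infertile = 1, seed = s))
    mask_iou(segment_egg(band_image(ds$cubes[[1]], 630)), truth)
  }, numeric(1))
  expect_true(all(ious >= 0.95))
})

test_that("segmentation is idempotent under mask re-application", {
  cfg <- synth_config(n_fertile = 1, n_infertile = 1, seed = 6)
  ds <- generate_dataset(cfg)
  img <- band_image(ds$cubes[[1]], 630)
  mask <- segment_egg(img)
  remask <- segment_egg(img * mask)
  expect_gte(mask_iou(remask, mask), 0.99)
})

test_that("ROI mean spectrum equals the brute-force pixel average", {
  cube <- make_cube(array(3.5, dim = c(4, 4, 3)))
  full <- egg_mask(matrix(1, 4, 4))
  expect_equal(mean_roi_spectrum(cube, full), rep(3.5, 3))

  single <- egg_mask(matrix(c(1, rep(0, 15)), 4, 4))
  expect_equal(mean_roi_spectrum(cube, single), cube$data[1, 1, ])

  set.seed(1)
  rnd <- make_cube(array(runif(48), dim = c(4, 4, 3)))
  checker <- egg_mask(outer(1:4, 1:4, function(i, j) (i + j) %% 2))
  manual <- vapply(1:3, function(b) {
    plane <- rnd$data[, , b]
    mean(plane[checker == 1])
  }, numeric(1))
  expect_equal(mean_roi_spectrum(rnd, checker), manual)
  expect_error(mean_roi_spectrum(rnd, egg_mask(matrix(0, 4, 4))), "Empty mask")
})

test_that("relative transmittance implements the printed exposure correction", {
  # identity case: sample equals reference at equal exposure, no dark
  expect_equal(
    relative_transmittance(c(5, 7, 9), 0, c(5, 7, 9), e_s = 10, e_r = 10),
    rep(100, 3)
  )
  # sample equal to dark -> zero
  expect_equal(
    relative_transmittance(c(2, 2), c(2, 2), c(8, 9), e_s = 10, e_r = 1),
    rep(0, 2)
  )
  # hand arithmetic: (0.8 - 0.1) / (0.9 - 0.1) * 100
  expect_equal(
    relative_transmittance(80, 10, 9, e_s = 100, e_r = 10),
    87.5
  )
  expect_error(
    relative_transmittance(1, 5, 0.4, e_s = 10, e_r = 10),
    "denominator"
  )
})

test_that("relative transmittance is invariant to global detector gain", {
  ts <- c(80, 70, 60); td <- c(5, 6, 7); tr <- c(9, 9, 9)
  base <- relative_transmittance(ts, td, tr, e_s = 100, e_r = 10)
  scaled <- relative_transmittance(3.7 * ts, 3.7 * td, 3.7 * tr, e_s = 100, e_r = 10)
  expect_equal(base, scaled)
})

test_that("per-frame dark convention differs only in the denominator", {
  printed <- relative_transmittance(80, 1, 9, e_s = 100, e_r = 10)
  per_frame <- relative_transmittance(80, 1, 9,
    e_s = 100, e_r = 10,
    convention = "per_frame"
  )
  expect_equal(printed, (0.8 - 0.01) / (0.9 - 0.01) * 100)
  expect_equal(per_frame, (0.8 - 0.01) / (0.9 - 0.1) * 100)
})

test_that("band binning partitions the grid and preserves block means", {
  # 1279 -> 256: block sizes sum to the fine band count
  sizes <- c(rep(1279 %/% 256, 256))
  extra <- 1279 %% 256
  sizes[(256 - extra + 1):256] <- sizes[(256 - extra + 1):256] + 1
  expect_equal(sum(sizes), 1279)
  binned <- bin_bands(rep(2.5, 1279), seq(500, 950, length.out = 1279), 256)
  expect_equal(binned$values, rep(2.5, 256))
  expect_equal(length(binned$wavelengths), 256)

  enum <- bin_bands(0:7, 1:8, 4)
  expect_equal(enum$values, c(0.5, 2.5, 4.5, 6.5))

  expect_error(bin_bands(1:4, 1:4, 0), "at least 1")
  expect_error(bin_bands(1:3, 1:3, 5), "at least")
})

test_that("ROI averaging commutes with band binning", {
  set.seed(2)
  cube <- make_cube(array(runif(6 * 6 * 12), dim = c(6, 6, 12)))
  mask <- egg_mask(matrix(rbinom(36, 1, 0.6), 6, 6))
  mean_then_bin <- bin_bands(mean_roi_spectrum(cube, mask), cube$wavelengths, 5)
  bin_then_mean <- mean_roi_spectrum(bin_bands(cube, n_out = 5), mask)
  expect_equal(mean_then_bin$values, bin_then_mean, tolerance = 1e-9)
})
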