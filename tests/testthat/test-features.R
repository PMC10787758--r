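dp_toy <- function(dp, wl = NULL) {
  wl <- wl %||% seq_along(dp) * 10 + 500
  out <- tibble::tibble(wavelength = wl, variable = sprintf("nm_%.6f", wl), dp = dp)
  class(out) <- c("dp_profile", class(out))
  out
}

test_that("region selection returns maximal runs above threshold", {
  regs <- select_regions(dp_toy(c(1, 4, 4, 1, 5, 1)), threshold = 3)
  expect_equal(nrow(regs), 2)
  expect_equal(regs$bands[[1]], 2:3)
  expect_equal(regs$bands[[2]], 5L)
  expect_equal(regs$start_nm, c(520, 550))
  expect_equal(regs$end_nm, c(530, 550))

  expect_equal(nrow(select_regions(dp_toy(rep(2, 6)), threshold = 3)), 0)

  all_above <- select_regions(dp_toy(rep(4, 6)), threshold = 3)
  expect_equal(nrow(all_above), 1)
  expect_equal(all_above$n_bands, 6)

  # min_width drops short runs
  wide_only <- select_regions(dp_toy(c(1, 4, 4, 1, 5, 1)), threshold = 3, min_width = 2)
  expect_equal(nrow(wide_only), 1)
  expect_equal(wide_only$bands[[1]], 2:3)
})

test_that("region features restrict columns to in-region band centers", {
  set.seed(50)
  cfg <- synth_config()
  wl <- wavelength_grid(cfg)
  tbl <- toy_table(matrix(rnorm(3 * length(wl)), 3), wavelengths = wl)

  full <- region_features(tbl, tibble::tibble(start_nm = 500, end_nm = 950))
  expect_identical(names(full), names(tbl))

  one <- region_features(tbl, tibble::tibble(start_nm = wl[10], end_nm = wl[10]))
  expect_equal(ncol(one), 3) # sample_id, class, one band
  expect_equal(spectra_matrix(one)[, 1], spectra_matrix(tbl)[, 10])

  paper_regions <- tibble::tibble(
    start_nm = c(673, 813, 865), end_nm = c(675, 840, 873)
  )
  reduced <- region_features(tbl, paper_regions)
  expected_n <- sum(
    (wl >= 673 & wl <= 675) | (wl >= 813 & wl <= 840) | (wl >= 865 & wl <= 873)
  )
  expect_equal(length(spectra_wavelengths(reduced)), expected_n)

  expect_error(
    region_features(tbl, tibble::tibble(start_nm = 200, end_nm = 300)),
    "outside"
  )
  expect_error(region_features(tbl, tibble::tibble(start_nm = numeric(), end_nm = numeric())), "empty")
})

test_that("spectral differences enumerate unordered pairs with hand-checked values", {
  wl <- c(600, 700, 800, 900)
  tbl <- toy_table(matrix(c(10, 7, 4, 2), 1), wavelengths = wl)
  regions <- tibble::tibble(start_nm = 600, end_nm = 900)

  feats <- spectral_differences(tbl, regions)
  dcols <- grep("^d_", names(feats), value = TRUE)
  expect_length(dcols, choose(4, 2))

  three <- spectral_differences(
    toy_table(matrix(c(10, 7, 4), 1), wavelengths = wl[1:3]),
    tibble::tibble(start_nm = 600, end_nm = 800)
  )
  vals <- as.numeric(three[grep("^d_", names(three))])
  expect_equal(vals, c(3, 6, 3)) # (1,2), (1,3), (2,3)

  const <- spectral_differences(
    toy_table(matrix(5, 1, 4), wavelengths = wl), regions
  )
  expect_equal(as.numeric(const[grep("^d_", names(const))]), rep(0, 6))

  expect_error(
    spectral_differences(
      toy_table(matrix(1, 1, 4), wavelengths = wl),
      tibble::tibble(start_nm = 600, end_nm = 600)
    ),
    "at least 2"
  )
})

test_that("within-region scope only pairs wavelengths inside one region", {
  wl <- c(600, 610, 800, 810)
  tbl <- toy_table(matrix(c(4, 3, 2, 1), 1), wavelengths = wl)
  regions <- tibble::tibble(start_nm = c(595, 795), end_nm = c(615, 815))
  within <- spectral_differences(tbl, regions, scope = "within_region")
  dcols <- grep("^d_", names(within), value = TRUE)
  expect_length(dcols, 2) # (600,610) and (800,810) only
  all_pairs <- spectral_differences(tbl, regions, scope = "all_pairs")
  expect_length(grep("^d_", names(all_pairs)), 6)
})

test_that("adjacent-band differences track the first derivative on smooth spectra", {
  cfg <- synth_config(
    n_fertile = 3, n_infertile = 3, rows = 24, cols = 24, n_bands = 256,
    egg_axes = c(9, 7), class_effect_size = 0, fertile_transmission_gain = 1,
    noise_sd = 0, scatter_slope_sd = 0, scatter_offset_sd = 0,
    shape_poly_sd = 0, band_scatter_sd = 0, seed = 51
  )
  tbl <- simulate_spectra(cfg)
  wl <- spectra_wavelengths(tbl)
  # adjacent-pair differences across the whole grid
  x <- spectra_matrix(tbl)
  adj_diff <- x[, -ncol(x)] - x[, -1]
  d1 <- spectra_matrix(pretreat(tbl, "deriv1"))
  for (i in seq_len(nrow(x))) {
    expect_gt(abs(cor(adj_diff[i, ], -d1[i, -1])), 0.9)
  }
})
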