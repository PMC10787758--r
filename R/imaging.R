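#' Index of the band nearest a target wavelength
#'
#' The 630 nm band gives the best egg/background contrast and is the default
#' segmentation plane. Ties (a target equidistant from two band centers)
#' break toward the lower index.
#'
#' @param cube A [hypercube()].
#' @param target_nm Target wavelength in nm (default 630).
#' @return 1-based band index.
#' @export
select_contrast_band <- function(cube, target_nm = 630) {
  wl <- cube$wavelengths
  if (target_nm < min(wl) || target_nm > max(wl)) {
    abort(sprintf(
      "Target %g nm lies outside the wavelength grid (%g-%g nm).",
      target_nm, min(wl), max(wl)
    ))
  }
  which.min(abs(wl - target_nm))
}

#' Extract one spatial band plane
#'
#' @param cube A [hypercube()].
#' @param target_nm Wavelength whose nearest band is returned.
#' @return Numeric matrix rows x cols.
#' @export
band_image <- function(cube, target_nm = 630) {
  cube$data[, , select_contrast_band(cube, target_nm)]
}

#' Segment the egg from the background
#'
#' Edge-based segmentation of a single bright egg on a dark background.
#' First a Sobel gradient magnitude map, thresholded at its Otsu level,
#' morphologically closed, hole-filled and reduced to the largest connected
#' component, locates the egg region. Because a transilluminated egg fades
#' smoothly into the background at its rim (the optical path length goes to
#' zero there), the gradient band straddles the true boundary; the boundary
#' is therefore refined against the background statistics estimated outside
#' the dilated edge region: pixels brighter than the background mean plus
#' three background standard deviations are kept, closed, hole-filled, and
#' again reduced to the largest component.
#'
#' @param img 2-D nonnegative numeric matrix (a band plane).
#' @return An [egg_mask()] with 1 inside the egg.
#' @export
segment_egg <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) abort("`img` must be a numeric matrix.")
  img <- matrix(as.numeric(img), nrow(img)) # strip classes/attributes
  if (diff(range(img)) <= 0) abort("Empty segmentation: image is constant.")
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(img, sx)
  gy <- EBImage::filter2(img, t(sx))
  grad <- sqrt(gx^2 + gy^2)
  g01 <- (grad - min(grad)) / diff(range(grad))
  thr <- EBImage::otsu(EBImage::Image(g01), range = c(0, 1))
  edges <- g01 > thr
  kern <- EBImage::makeBrush(5, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(edges * 1), kern)
  filled <- EBImage::fillHull(closed)
  seed <- largest_component(filled)
  if (is.null(seed)) abort("Empty segmentation: no foreground region found.")
  # background statistics away from the egg and its gradient halo
  halo <- EBImage::imageData(EBImage::dilate(EBImage::Image(seed * 1), kern)) > 0
  bg <- img[!halo]
  if (!length(bg)) bg <- min(img)
  cut <- mean(bg) + 3 * sd_or_zero(bg) + 1e-9 * diff(range(img))
  refined <- EBImage::fillHull(EBImage::closing(EBImage::Image((img > cut) * 1),
                                                EBImage::makeBrush(3, shape = "box")))
  comp <- largest_component(refined)
  if (is.null(comp)) abort("Empty segmentation: region vanished under refinement.")
  egg_mask(matrix(as.integer(comp), nrow(img), ncol(img)))
}

largest_component <- function(binary_img) {
  lab <- EBImage::bwlabel(binary_img)
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (!length(tab) || max(tab) == 0) return(NULL)
  EBImage::imageData(lab) == which.max(tab)
}

sd_or_zero <- function(x) if (length(x) > 1) sd(x) else 0

#' Mean spectrum over the egg region
#'
#' Per-band arithmetic mean of the cube over `mask == 1` pixels — the `T_s`
#' entering the relative-transmittance calculation.
#'
#' @param cube A [hypercube()].
#' @param mask An [egg_mask()] matching the cube's spatial dimensions.
#' @return Numeric vector, one mean intensity per band.
#' @export
mean_roi_spectrum <- function(cube, mask) {
  d <- dim(cube$data)
  if (!all(dim(mask) == d[1:2])) abort("Mask shape must match cube spatial dims.")
  keep <- which(mask == 1L)
  if (!length(keep)) abort("Empty mask: no egg pixels to average.")
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  colMeans(flat[keep, , drop = FALSE])
}

#' Relative transmittance
#'
#' Converts a raw mean sample spectrum to relative transmittance in percent
#' against the dark and reference acquisitions, correcting for their
#' different exposure times:
#' \deqn{T_{rel} = \frac{T_s/e_s - T_d/e_s}{T_r/e_r - T_d/e_s} \times 100}
#' The dark term is divided by the sample exposure `e_s` in both numerator
#' and denominator (the `as_printed` convention). Since the dark frame is
#' captured at the sample exposure this is the natural normalization for the
#' numerator; `convention = "per_frame"` instead divides the denominator's
#' dark term by `e_r`, treating dark current as accumulating in the
#' reference frame over its own exposure.
#'
#' @param T_s,T_d,T_r Sample, dark and reference mean spectra on one grid.
#' @param e_s,e_r Sample and reference exposure times (ms), positive.
#' @param convention `"as_printed"` (default) or `"per_frame"`.
#' @return Relative transmittance (%) per band.
#' @export
relative_transmittance <- function(T_s, T_d, T_r, e_s, e_r,
                                   convention = c("as_printed", "per_frame")) {
  convention <- match.arg(convention)
  if (length(T_d) == 1L) T_d <- rep(T_d, length(T_s))
  if (length(T_r) == 1L) T_r <- rep(T_r, length(T_s))
  if (length(T_s) != length(T_d) || length(T_s) != length(T_r)) {
    abort("T_s, T_d, T_r must share one wavelength grid.")
  }
  if (e_s <= 0 || e_r <= 0) abort("Exposure times must be positive.")
  dark_ref <- if (convention == "as_printed") T_d / e_s else T_d / e_r
  denom <- T_r / e_r - dark_ref
  bad <- which(denom <= 0)
  if (length(bad)) {
    abort(sprintf(
      "Zero or negative reference-corrected denominator at band(s): %s",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  (T_s / e_s - T_d / e_s) / denom * 100
}

#' Bin a fine spectral grid into contiguous blocks
#'
#' Averages adjacent bands into `n_out` contiguous blocks, the operation that
#' reduces a raw 1279-band acquisition to the working 256-band grid. Blocks
#' are as equal as possible; when the band count does not divide evenly the
#' remainder bands go to the trailing blocks. The output wavelength is the
#' mean of each block's member wavelengths.
#'
#' @param x Numeric spectrum (vector), samples x bands matrix, or
#'   [hypercube()].
#' @param wavelengths Fine-grid wavelengths (not needed for a hypercube).
#' @param n_out Number of output blocks, `>= 1`.
#' @return For a vector/matrix: list with `values` and `wavelengths`; for a
#'   hypercube: a binned `hypercube`.
#' @export
bin_bands <- function(x, wavelengths = NULL, n_out) {
  if (n_out < 1) abort("`n_out` must be at least 1.")
  if (inherits(x, "hypercube")) {
    d <- dim(x$data)
    flat <- matrix(x$data, d[1] * d[2], d[3])
    res <- bin_bands(flat, x$wavelengths, n_out)
    return(hypercube(
      array(res$values, dim = c(d[1], d[2], n_out)),
      res$wavelengths, x$exposure
    ))
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  p <- ncol(m)
  if (p < n_out) abort("Fine grid must have at least `n_out` bands.")
  if (is.null(wavelengths)) wavelengths <- seq_len(p)
  sizes <- rep(p %/% n_out, n_out)
  extra <- p %% n_out
  if (extra > 0) sizes[(n_out - extra + 1):n_out] <- sizes[(n_out - extra + 1):n_out] + 1
  block <- rep(seq_len(n_out), times = sizes)
  vals <- t(apply(m, 1, function(row) tapply(row, block, mean)))
  if (n_out == 1L) vals <- matrix(rowMeans(m), ncol = 1)
  wl_out <- as.numeric(tapply(wavelengths, block, mean))
  list(
    values = if (vec) as.vector(vals) else vals,
    wavelengths = wl_out
  )
}

#' Extract relative-transmittance spectra from a set of cubes
#'
#' The acquisition-to-table step: per cube, segment on the contrast band,
#' average over the egg mask, and convert to relative transmittance with the
#' campaign's calibration frames.
#'
#' @param cubes List of [hypercube()]s.
#' @param labels Tibble with `sample_id`, `class` (one row per cube).
#' @param calibration A [calibration_frames()].
#' @param contrast_nm Segmentation wavelength (default 630).
#' @param convention Passed to [relative_transmittance()].
#' @return A spectrum table.
#' @export
extract_spectra <- function(cubes, labels, calibration, contrast_nm = 630,
                            convention = c("as_printed", "per_frame")) {
  convention <- match.arg(convention)
  stopifnot(length(cubes) == nrow(labels))
  e_r <- calibration$reference$exposure
  out <- purrr::map(cubes, function(cube) {
    mask <- segment_egg(band_image(cube, contrast_nm))
    ts <- mean_roi_spectrum(cube, mask)
    relative_transmittance(
      ts, calibration$T_d, calibration$T_r,
      e_s = cube$exposure, e_r = e_r, convention = convention
    )
  })
  spectra_table(
    do.call(rbind, out), cubes[[1]]$wavelengths,
    labels$class, labels$sample_id
  )
}
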