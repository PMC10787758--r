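#' Select effective wavebands from a discrimination-power profile
#'
#' Returns the maximal runs of consecutive bands whose discrimination power
#' exceeds the threshold (conventionally 3), as contiguous wavelength
#' regions sorted by wavelength. Runs shorter than `min_width` bands are
#' dropped; the default of 1 keeps even 2-3-band regions.
#'
#' @param profile A `dp_profile` (see [discrimination_power()]) or any
#'   tibble with `wavelength` and `dp` columns.
#' @param threshold Discrimination-power cut (default 3, or the profile's
#'   own threshold attribute).
#' @param min_width Minimum run length in bands (default 1).
#' @return A tibble: `region_id`, `start_nm`, `end_nm`, `n_bands`, `bands`
#'   (list column of band indices). Zero rows when nothing exceeds the
#'   threshold.
#' @export
select_regions <- function(profile, threshold = NULL, min_width = 1) {
  threshold <- threshold %||% attr(profile, "threshold") %||% 3
  if (any(!is.finite(profile$dp))) {
    warn("Non-finite discrimination power values present; treated as above threshold.")
  }
  above <- !is.finite(profile$dp) | profile$dp > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values & runs$lengths >= min_width)
  if (!length(keep)) {
    return(tibble::tibble(
      region_id = character(), start_nm = numeric(), end_nm = numeric(),
      n_bands = integer(), bands = list()
    ))
  }
  tibble::tibble(
    region_id = sprintf("R%d", seq_along(keep)),
    start_nm = profile$wavelength[starts[keep]],
    end_nm = profile$wavelength[ends[keep]],
    n_bands = runs$lengths[keep],
    bands = purrr::map2(starts[keep], ends[keep], seq)
  )
}

#' Restrict a spectrum table to selected wavebands
#'
#' Keeps only the spectral columns whose band centers fall inside any of the
#' selected regions (inclusive), in wavelength order — the "raw spectra of
#' the effective wavebands" feature set.
#'
#' @param tbl A spectrum table.
#' @param regions Output of [select_regions()], or any tibble with
#'   `start_nm` / `end_nm` columns.
#' @return A reduced spectrum table.
#' @export
region_features <- function(tbl, regions) {
  if (!nrow(regions)) abort("`regions` is empty: no wavebands to select.")
  wl <- spectra_wavelengths(tbl)
  if (any(regions$end_nm < min(wl) - 1e-9 | regions$start_nm > max(wl) + 1e-9)) {
    abort("A region lies outside the table's wavelength grid.")
  }
  inside <- purrr::reduce(
    purrr::map(seq_len(nrow(regions)), function(i) {
      wl >= regions$start_nm[i] - 1e-6 & wl <= regions$end_nm[i] + 1e-6
    }),
    `|`
  )
  if (!any(inside)) abort("No band centers fall inside the selected regions.")
  keep <- c(
    setdiff(names(tbl), spectra_cols(tbl)),
    spectra_cols(tbl)[inside]
  )
  tbl[keep]
}

#' All-pairs spectral-difference features
#'
#' Builds the difference feature set `T(lambda_1) - T(lambda_2)` over every
#' unordered pair of selected wavelengths (`lambda_1 < lambda_2`, each pair
#' stored once) — the paper-style stand-in for a first derivative when the
#' selected wavebands are discontinuous. With `scope = "within_region"`
#' only pairs inside one region are formed.
#'
#' @param tbl A spectrum table (raw transmittance).
#' @param regions Output of [select_regions()].
#' @param scope `"all_pairs"` (default, across the union of regions) or
#'   `"within_region"`.
#' @return A tibble with the table's metadata columns plus one
#'   `d_<lambda1>_<lambda2>` column per pair.
#' @export
spectral_differences <- function(tbl, regions,
                                 scope = c("all_pairs", "within_region")) {
  scope <- match.arg(scope)
  reduced <- region_features(tbl, regions)
  wl <- spectra_wavelengths(reduced)
  if (length(wl) < 2) abort("Need at least 2 selected wavelengths to form differences.")
  x <- spectra_matrix(reduced)
  region_of <- purrr::map_int(wl, function(w) {
    which(regions$start_nm - 1e-6 <= w & w <= regions$end_nm + 1e-6)[1]
  })
  pairs <- combn(seq_along(wl), 2)
  if (scope == "within_region") {
    pairs <- pairs[, region_of[pairs[1, ]] == region_of[pairs[2, ]], drop = FALSE]
    if (!ncol(pairs)) abort("No within-region wavelength pairs available.")
  }
  diffs <- x[, pairs[1, ], drop = FALSE] - x[, pairs[2, ], drop = FALSE]
  colnames(diffs) <- sprintf("d_%.12g_%.12g", wl[pairs[1, ]], wl[pairs[2, ]])
  meta <- reduced[setdiff(names(reduced), spectra_cols(reduced))]
  dplyr::bind_cols(meta, tibble::as_tibble(diffs))
}
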