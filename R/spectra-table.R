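#' Spectrum tables
#'
#' The pipeline's central tabular container is an ordinary tibble with one
#' row per egg: a `sample_id` column, a `class` column (`"fertile"` /
#' `"infertile"`), and one numeric column per wavelength named
#' `nm_<wavelength>` holding relative transmittance in percent. Because it is
#' a plain tibble it flows through dplyr/tidyr verbs unchanged; the helpers
#' here convert between the tibble and the samples-by-bands matrix view that
#' the chemometric fits need.
#'
#' @param x Numeric matrix, samples x bands.
#' @param wavelengths Band-center wavelengths (nm), length `ncol(x)`.
#' @param class Class label per row.
#' @param sample_id Optional ids; defaults to `egg_001`, ...
#'
#' @return A tibble with columns `sample_id`, `class`, `nm_*`.
#' @export
spectra_table <- function(x, wavelengths, class, sample_id = NULL) {
  x <- as.matrix(x)
  if (length(wavelengths) != ncol(x)) {
    abort("`wavelengths` length must equal the number of spectral columns.")
  }
  if (length(class) != nrow(x)) {
    abort("`class` length must equal the number of rows.")
  }
  if (is.null(sample_id)) {
    sample_id <- sprintf("egg_%03d", seq_len(nrow(x)))
  }
  colnames(x) <- nm_names(wavelengths)
  dplyr::bind_cols(
    tibble::tibble(sample_id = as.character(sample_id), class = as.character(class)),
    tibble::as_tibble(x)
  )
}

nm_names <- function(wavelengths) sprintf("nm_%.12g", wavelengths)

#' Extract the numeric spectra matrix from a spectrum table
#'
#' @param tbl A spectrum table (tibble with `nm_*` columns).
#' @return Numeric matrix samples x bands, rownames from `sample_id`.
#' @export
spectra_matrix <- function(tbl) {
  cols <- spectra_cols(tbl)
  m <- as.matrix(tbl[cols])
  if ("sample_id" %in% names(tbl)) rownames(m) <- tbl$sample_id
  m
}

#' Wavelength axis of a spectrum table
#'
#' @param tbl A spectrum table.
#' @return Numeric vector of band-center wavelengths in nm.
#' @export
spectra_wavelengths <- function(tbl) {
  as.numeric(sub("^nm_", "", spectra_cols(tbl)))
}

spectra_cols <- function(tbl) {
  cols <- grep("^nm_", names(tbl), value = TRUE)
  if (!length(cols)) abort("No spectral (`nm_*`) columns found.")
  cols
}

#' Extract the model feature matrix from a table
#'
#' Classifiers accept either spectral tables (`nm_*` columns) or
#' spectral-difference feature tables (`d_*` columns); this returns whichever
#' feature block the table carries, as a numeric matrix.
#'
#' @param tbl A spectrum or difference-feature table.
#' @return Numeric matrix samples x features.
#' @export
feature_matrix <- function(tbl) {
  cols <- grep("^(nm|d)_", names(tbl), value = TRUE)
  if (!length(cols)) abort("No feature (`nm_*` or `d_*`) columns found.")
  m <- as.matrix(tbl[cols])
  if ("sample_id" %in% names(tbl)) rownames(m) <- tbl$sample_id
  m
}

#' Replace the spectra matrix of a table, keeping metadata columns
#'
#' @param tbl A spectrum table.
#' @param x New matrix with `nrow(tbl)` rows.
#' @param wavelengths Wavelengths for the new columns; defaults to the old axis.
#' @return A spectrum table.
#' @export
set_spectra_matrix <- function(tbl, x, wavelengths = NULL) {
  if (is.null(wavelengths)) wavelengths <- spectra_wavelengths(tbl)
  meta <- tbl[setdiff(names(tbl), spectra_cols(tbl))]
  x <- as.matrix(x)
  colnames(x) <- nm_names(wavelengths)
  dplyr::bind_cols(meta, tibble::as_tibble(x))
}

#' Pivot a spectrum table to long format for plotting
#'
#' @param tbl A spectrum table.
#' @return A long tibble with columns `sample_id`, `class`, `wavelength`,
#'   `value`.
#' @export
spectra_long <- function(tbl) {
  tidyr::pivot_longer(
    tbl,
    cols = dplyr::starts_with("nm_"),
    names_to = "wavelength",
    names_prefix = "nm_",
    names_transform = as.numeric,
    values_to = "value"
  )
}

#' Mean spectrum per class
#'
#' @param tbl A spectrum table.
#' @return A long tibble with columns `class`, `wavelength`, `value`.
#' @export
class_mean_spectra <- function(tbl) {
  spectra_long(tbl) |>
    dplyr::group_by(.data$class, .data$wavelength) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}
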