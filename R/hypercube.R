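#' Hyperspectral transmission cube
#'
#' A hypercube is a `rows x cols x bands` array of nonnegative detector
#' intensities with a strictly increasing wavelength axis (nm, band centers)
#' and the exposure time (ms) under which it was acquired.
#'
#' @param data Numeric 3-D array, `rows x cols x bands`, nonnegative.
#' @param wavelengths Numeric vector of band-center wavelengths in nm,
#'   strictly increasing, length equal to `dim(data)[3]`.
#' @param exposure Exposure time in milliseconds, `> 0`.
#'
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, exposure) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a rows x cols x bands 3-D array.")
  }
  if (any(data < 0)) abort("Hypercube intensities must be nonnegative.")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L]) {
    abort("`wavelengths` length must equal the number of bands.")
  }
  if (any(diff(wavelengths) <= 0)) {
    abort("`wavelengths` must be strictly increasing.")
  }
  if (!is.numeric(exposure) || length(exposure) != 1L || exposure <= 0) {
    abort("`exposure` must be a single positive number (ms).")
  }
  structure(
    list(data = data, wavelengths = wavelengths, exposure = as.numeric(exposure)),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm), exposure %g ms\n",
    d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$exposure
  ))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Binary egg/background mask
#'
#' Code 1 marks egg pixels, 0 marks background.
#'
#' @param m Integer or logical matrix.
#' @return An object of class `egg_mask` (integer matrix of 0/1).
#' @export
egg_mask <- function(m) {
  if (!is.matrix(m)) abort("`m` must be a matrix.")
  m <- matrix(as.integer(m != 0), nrow = nrow(m))
  structure(m, class = c("egg_mask", "matrix", "array"))
}

#' @export
print.egg_mask <- function(x, ...) {
  cat(sprintf(
    "<egg_mask> %d x %d, %d foreground pixels\n",
    nrow(x), ncol(x), sum(x)
  ))
  invisible(x)
}

#' Dark and reference calibration acquisitions
#'
#' Bundles the dark frame (captured at the sample exposure, lamp off) and the
#' reference frame (unattenuated lamp at a much shorter exposure) together
#' with their full-frame mean spectra `T_d` and `T_r`.
#'
#' @param dark,reference `hypercube` objects sharing the sample wavelength grid.
#' @return An object of class `calibration_frames` with elements `dark`,
#'   `reference`, `T_d`, `T_r`.
#' @export
calibration_frames <- function(dark, reference) {
  stopifnot(inherits(dark, "hypercube"), inherits(reference, "hypercube"))
  if (!isTRUE(all.equal(dark$wavelengths, reference$wavelengths))) {
    abort("Dark and reference frames must share one wavelength grid.")
  }
  structure(
    list(
      dark = dark, reference = reference,
      T_d = apply(dark$data, 3, mean),
      T_r = apply(reference$data, 3, mean)
    ),
    class = "calibration_frames"
  )
}

# ---- minimal ENVI band-sequential I/O ----------------------------------------

#' Write a hypercube as an ENVI image (header + BSQ binary)
#'
#' @param cube A `hypercube`.
#' @param path Output path without extension; writes `<path>.hdr` and
#'   `<path>.raw`.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("exposure time = %g", cube$exposure),
    paste0(
      "wavelength = { ",
      paste(format(cube$wavelengths, trim = TRUE, digits = 10), collapse = ", "),
      " }"
    )
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  # BSQ: whole band planes in sequence, row-major within a plane
  for (b in seq_len(d[3])) {
    writeBin(as.vector(t(cube$data[, , b])), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a hypercube written by [write_envi()]
#'
#' @param path Path without extension, as given to [write_envi()].
#' @return A `hypercube`.
#' @export
read_envi <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  grab <- function(key) {
    line <- grep(paste0("^", key, " ="), hdr, value = TRUE)
    if (!length(line)) abort(sprintf("ENVI header missing '%s'.", key))
    trimws(sub(".*=", "", line[1]))
  }
  nr <- as.integer(grab("lines"))
  nc <- as.integer(grab("samples"))
  nb <- as.integer(grab("bands"))
  exposure <- as.numeric(grab("exposure time"))
  wl_line <- sub(".*\\{", "", paste(grep("wavelength", hdr, value = TRUE), collapse = ""))
  wl <- as.numeric(strsplit(gsub("[}{]", "", wl_line), ",")[[1]])
  con <- file(paste0(path, ".raw"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = nr * nc * nb, size = 8, endian = "little")
  arr <- array(0, dim = c(nr, nc, nb))
  for (b in seq_len(nb)) {
    plane <- raw[((b - 1) * nr * nc + 1):(b * nr * nc)]
    arr[, , b] <- t(matrix(plane, nrow = nc))
  }
  hypercube(arr, wl, exposure)
}
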