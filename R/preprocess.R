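#' Spectral pretreatments
#'
#' The seven pretreatments of the modelling grid, applied row-wise to a
#' spectrum table:
#' \describe{
#'   \item{raw}{identity.}
#'   \item{norm}{division by the row's Euclidean norm (vector
#'     normalization), suppressing overall intensity differences.}
#'   \item{snv}{standard normal variate: per-row centering and scaling to
#'     unit standard deviation.}
#'   \item{msc}{multiplicative scatter correction: each row is regressed on
#'     a reference spectrum, `x = a + b * ref`, and corrected to
#'     `(x - a) / b`. The reference is the mean spectrum of the calibration
#'     rows (never of test rows), unless supplied explicitly.}
#'   \item{baseline}{subtraction of the straight line through the row's
#'     first and last points.}
#'   \item{deriv1, deriv2}{Savitzky-Golay first/second derivative (units:
#'     per band step), window `sg_window` points, polynomial order
#'     `sg_polyorder`.}
#' }
#' Every pretreatment is row-local except MSC's reference, which is learned
#' only from `calibration` rows so no test-set information leaks into it.
#'
#' @param tbl A spectrum table.
#' @param method One of `"raw"`, `"norm"`, `"msc"`, `"snv"`, `"baseline"`,
#'   `"deriv1"`, `"deriv2"`.
#' @param sg_window Savitzky-Golay window length (odd, `> sg_polyorder`).
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param calibration Optional logical/integer index of the rows to learn
#'   the MSC reference from; defaults to all rows.
#' @param msc_reference Optional explicit reference spectrum (overrides
#'   `calibration`).
#' @return A spectrum table of the same shape.
#' @export
pretreat <- function(tbl,
                     method = c("raw", "norm", "msc", "snv", "baseline", "deriv1", "deriv2"),
                     sg_window = 11,
                     sg_polyorder = 2,
                     calibration = NULL,
                     msc_reference = NULL) {
  method <- match.arg(method)
  x <- spectra_matrix(tbl)
  if (method %in% c("deriv1", "deriv2")) {
    if (sg_window %% 2 == 0 || sg_window <= sg_polyorder) {
      abort("`sg_window` must be odd and greater than `sg_polyorder`.")
    }
    if (ncol(x) < sg_window) abort("Spectrum shorter than the Savitzky-Golay window.")
  }
  out <- switch(method,
    raw = x,
    norm = {
      nrm <- sqrt(rowSums(x^2))
      bad <- which(nrm == 0)
      if (length(bad)) {
        abort(sprintf("Zero-norm spectrum for sample(s): %s",
                      paste(tbl$sample_id[bad], collapse = ", ")))
      }
      x / nrm
    },
    snv = {
      sds <- apply(x, 1, sd)
      bad <- which(sds == 0)
      if (length(bad)) {
        abort(sprintf("Zero-variance spectrum (SNV undefined) for sample(s): %s",
                      paste(tbl$sample_id[bad], collapse = ", ")))
      }
      (x - rowMeans(x)) / sds
    },
    msc = {
      ref <- msc_reference %||% {
        idx <- calibration %||% seq_len(nrow(x))
        colMeans(x[idx, , drop = FALSE])
      }
      t(apply_msc(x, ref, tbl$sample_id))
    },
    baseline = {
      p <- ncol(x)
      t(apply(x, 1, function(row) {
        base <- row[1] + (row[p] - row[1]) * (seq_len(p) - 1) / (p - 1)
        row - base
      }))
    },
    deriv1 = sg_deriv(x, sg_window, sg_polyorder, 1),
    deriv2 = sg_deriv(x, sg_window, sg_polyorder, 2)
  )
  set_spectra_matrix(tbl, out)
}

apply_msc <- function(x, ref, ids) {
  apply_one <- function(i) {
    fit <- stats::lm.fit(cbind(1, ref), x[i, ])
    a <- fit$coefficients[1]
    b <- fit$coefficients[2]
    if (!is.finite(b) || abs(b) < 1e-12) {
      abort(sprintf("Degenerate MSC slope for sample %s.", ids[i]))
    }
    (x[i, ] - a) / b
  }
  vapply(seq_len(nrow(x)), apply_one, numeric(ncol(x)))
}

# Savitzky-Golay derivative of each row, in units of "per band step".
sg_deriv <- function(x, window, polyorder, m) {
  coefs <- signal::sgolay(p = polyorder, n = window, m = m, ts = 1)
  t(apply(x, 1, function(row) signal::sgolayfilt(row, coefs)))
}

#' Savitzky-Golay smoothing
#'
#' Plain (zeroth-derivative) Savitzky-Golay smoothing of each spectrum.
#'
#' @inheritParams pretreat
#' @return A spectrum table of the same shape.
#' @export
sg_smooth <- function(tbl, sg_window = 11, sg_polyorder = 2) {
  x <- spectra_matrix(tbl)
  if (sg_window %% 2 == 0 || sg_window <= sg_polyorder) {
    abort("`sg_window` must be odd and greater than `sg_polyorder`.")
  }
  set_spectra_matrix(tbl, sg_deriv(x, sg_window, sg_polyorder, 0))
}

#' Hotelling T-squared outlier screening
#'
#' Fits a PCA to all rows, computes each sample's Hotelling T-squared over
#' the leading `n_pcs` score dimensions, and flags samples beyond the
#' F-distribution-based limit at confidence `1 - alpha` (the samples outside
#' the 95% Hotelling ellipse, by default). Flagged rows are intended to be
#' excluded from downstream modelling.
#'
#' @param tbl A spectrum table.
#' @param n_pcs Number of score dimensions; default: components covering
#'   95% of variance, capped at 10.
#' @param alpha Flagging level (default 0.05).
#' @return A list with `kept` and `flagged` spectrum tables, a `scores`
#'   tibble (`sample_id`, `t2`, `outlier`), `n_pcs`, and the `limit` used.
#' @export
hotelling_outliers <- function(tbl, n_pcs = NULL, alpha = 0.05) {
  x <- spectra_matrix(tbl)
  n <- nrow(x)
  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (is.null(n_pcs)) {
    n_pcs <- min(which(cumsum(ev) / sum(ev) >= 0.95), 10L, rank)
  }
  n_pcs <- as.integer(n_pcs)
  if (n_pcs < 1) abort("`n_pcs` must be at least 1.")
  if (n_pcs >= rank) abort("`n_pcs` must be below the data rank.")
  if (n <= n_pcs + 1) abort("Need more rows than `n_pcs` + 1.")
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  t2 <- rowSums(sweep(scores^2, 2, ev[seq_len(n_pcs)], "/"))
  limit <- n_pcs * (n - 1) * (n + 1) / (n * (n - n_pcs)) *
    qf(1 - alpha, n_pcs, n - n_pcs)
  outlier <- t2 > limit
  list(
    kept = tbl[!outlier, , drop = FALSE],
    flagged = tbl[outlier, , drop = FALSE],
    scores = tibble::tibble(
      sample_id = tbl$sample_id, t2 = t2, outlier = outlier
    ),
    n_pcs = n_pcs,
    limit = limit
  )
}

#' Stratified calibration/test split
#'
#' Randomly partitions the samples into a calibration subset (for model
#' building) and an independent test subset, stratified by class so each
#' class contributes its share of the test fraction (within one sample of
#' the target). With the study design of 131 fertile + 96 infertile eggs and
#' a 0.2 test fraction this yields 26 fertile + 19 infertile test eggs.
#'
#' @param tbl A spectrum table with both classes present.
#' @param test_fraction Fraction held out for testing, in (0, 1).
#' @param seed Integer seed; the partition is reproducible per seed.
#' @return A list with `calibration` and `test` spectrum tables.
#' @export
split_calibration_test <- function(tbl, test_fraction = 0.2, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must lie strictly between 0 and 1.")
  }
  counts <- table(tbl$class)
  if (length(counts) < 2) abort("Both classes must be present.")
  if (any(counts < 2)) abort("Every class needs at least 2 members to split.")
  set.seed(seed)
  test_idx <- unlist(lapply(names(counts), function(cl) {
    idx <- which(tbl$class == cl)
    n_test <- round(length(idx) * test_fraction)
    n_test <- max(1L, min(n_test, length(idx) - 1L))
    sample(idx, n_test)
  }))
  list(
    calibration = tbl[-test_idx, , drop = FALSE],
    test = tbl[sort(test_idx), , drop = FALSE]
  )
}
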