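#' Two-class confusion matrix with fertile as the positive class
#'
#' TP and TN count correctly classified fertile and infertile eggs; FP
#' counts infertile eggs misclassified as fertile, FN fertile eggs
#' misclassified as infertile.
#'
#' @param truth Character vector of true classes.
#' @param estimate Character vector of predicted classes, same length.
#' @param positive Positive class label (default `"fertile"`).
#' @return An object of class `confusion_matrix` with fields `TP`, `FN`,
#'   `FP`, `TN`.
#' @export
confusion_matrix <- function(truth, estimate, positive = "fertile") {
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length.")
  }
  pos <- truth == positive
  structure(
    list(
      TP = sum(pos & estimate == positive),
      FN = sum(pos & estimate != positive),
      FP = sum(!pos & estimate == positive),
      TN = sum(!pos & estimate != positive),
      positive = positive
    ),
    class = "confusion_matrix"
  )
}

#' Build a confusion matrix directly from counts
#'
#' @param TP,FN,FP,TN Nonnegative counts.
#' @param positive Positive class label.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(TP, FN, FP, TN, positive = "fertile") {
  counts <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(counts < 0)) abort("Confusion counts must be nonnegative.")
  structure(
    c(as.list(counts), list(positive = positive)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf(
    "<confusion_matrix> positive = %s\n  TP %d  FN %d\n  FP %d  TN %d\n",
    x$positive, x$TP, x$FN, x$FP, x$TN
  ))
  invisible(x)
}

#' Classification metrics: sensitivity, specificity, precision, accuracy
#'
#' \deqn{Sen = TP/(TP+FN),\; Spe = TN/(FP+TN),\;
#'       Precis = TP/(TP+FP),\; Acc = (TP+TN)/(TP+FN+FP+TN)}
#' all reported in percent at full precision; a metric whose denominator is
#' zero is undefined and reported as `NA` (never as 0). Use
#' [format_metrics()] for 2-decimal display.
#'
#' @param cm A `confusion_matrix`.
#' @return A one-row tibble: `TP`, `FN`, `FP`, `TN`, `sen`, `spe`,
#'   `precis`, `acc` (percentages).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(
    TP = cm$TP, FN = cm$FN, FP = cm$FP, TN = cm$TN,
    sen = ratio(cm$TP, cm$TP + cm$FN),
    spe = ratio(cm$TN, cm$FP + cm$TN),
    precis = ratio(cm$TP, cm$TP + cm$FP),
    acc = ratio(cm$TP + cm$TN, cm$TP + cm$FN + cm$FP + cm$TN)
  )
}

#' Round metric percentages half-up to two decimals for display
#'
#' @param x Numeric vector of percentages.
#' @return Numeric vector rounded half-up to 2 decimals.
#' @export
format_metrics <- function(x) floor(x * 100 + 0.5) / 100

#' Run the pretreatment x classifier x feature-set experiment grid
#'
#' Orchestrates the study design end to end on one spectrum table: splits
#' calibration/test (stratified, 80/20 by default), optionally screens
#' calibration outliers, applies each pretreatment (learned on calibration
#' rows only), builds the requested feature set, fits each classifier on
#' calibration rows and scores it on the untouched test rows.
#'
#' Feature sets: `"full"` uses every band of the pretreated spectra;
#' `"regions"` restricts the *raw* spectra to the effective wavebands
#' selected from a first-derivative SIMCA discrimination-power profile
#' (threshold `dp_threshold`); `"differences"` uses all-pairs spectral
#' differences of the selected wavelengths. For the reduced feature sets
#' the pretreatment grid is ignored (the paper's rationale: derivatives are
#' ill-defined across discontinuous wavebands), so those cells run once with
#' `pretreatment = "raw"`.
#'
#' @param tbl A spectrum table (raw relative transmittance).
#' @param pretreatments Character vector from
#'   `c("raw", "norm", "msc", "snv", "baseline", "deriv1", "deriv2")`.
#' @param classifiers Character vector from
#'   `c("simca", "lda", "qda", "ann")`.
#' @param feature_sets Character vector from
#'   `c("full", "regions", "differences")`.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param seed Master seed for split, fits and networks.
#' @param remove_outliers Screen calibration rows with
#'   [hotelling_outliers()] first (default TRUE).
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param dp_threshold Discrimination-power cut for waveband selection.
#' @param simca_pcs,ann_nhl Optional fixed SIMCA component counts / hidden
#'   nodes; `NULL` selects them by cross-validation / topology search.
#' @param ann_repeats,ann_maxit Network training controls.
#' @return A tibble with one row per grid cell: `pretreatment`,
#'   `classifier`, `features`, `n_inputs`, confusion counts, `sen`, `spe`,
#'   `precis`, `acc`, `seed`, `error` (NA unless that cell failed).
#' @export
run_experiment_grid <- function(tbl,
                                pretreatments = "deriv1",
                                classifiers = c("simca", "lda", "qda"),
                                feature_sets = "full",
                                test_fraction = 0.2,
                                seed = 1,
                                remove_outliers = TRUE,
                                sg_window = 11,
                                sg_polyorder = 2,
                                dp_threshold = 3,
                                simca_pcs = NULL,
                                ann_nhl = 10,
                                ann_repeats = 3,
                                ann_maxit = 500) {
  split <- split_calibration_test(tbl, test_fraction, seed = seed)
  cal <- split$calibration
  test <- split$test
  if (remove_outliers) {
    cal <- hotelling_outliers(cal)$kept
  }

  fit_cell <- function(cal_ft, test_ft, classifier) {
    pred <- switch(classifier,
      simca = predict(
        simca_fit(cal_ft, n_pcs = simca_pcs, seed = seed), test_ft
      ),
      lda = predict(da_fit(cal_ft, "lda"), test_ft),
      qda = predict(da_fit(cal_ft, "qda"), test_ft),
      ann = {
        nhl <- ann_nhl %||% topology_search(
          cal_ft,
          nhl_range = 1:15, repeats = ann_repeats,
          seed = seed, maxit = ann_maxit
        )$best_nhl
        predict(mlp_fit(cal_ft, nhl, seed = seed, maxit = ann_maxit), test_ft)
      },
      abort(sprintf("Unknown classifier '%s'.", classifier))
    )
    metrics(confusion_matrix(test_ft$class, pred$.pred_class))
  }

  # reduced feature sets share one DP-profile selection from deriv1 SIMCA
  regions <- NULL
  if (any(feature_sets != "full")) {
    cal_d1 <- pretreat(cal, "deriv1", sg_window, sg_polyorder)
    dp <- discrimination_power(
      simca_fit(cal_d1, n_pcs = simca_pcs, seed = seed), cal_d1
    )
    regions <- select_regions(dp, threshold = dp_threshold)
  }

  cells <- tidyr::expand_grid(
    features = feature_sets,
    pretreatment = pretreatments,
    classifier = classifiers
  ) |>
    dplyr::filter(.data$features == "full" | .data$pretreatment == pretreatments[1]) |>
    dplyr::mutate(
      pretreatment = ifelse(.data$features == "full", .data$pretreatment, "raw")
    ) |>
    dplyr::distinct()

  purrr::pmap_dfr(cells, function(features, pretreatment, classifier) {
    row <- tryCatch(
      {
        if (features == "full") {
          cal_ft <- pretreat(cal, pretreatment, sg_window, sg_polyorder)
          test_ft <- pretreat(test, pretreatment, sg_window, sg_polyorder,
            msc_reference = if (pretreatment == "msc") {
              colMeans(spectra_matrix(cal))
            } else {
              NULL
            }
          )
        } else if (features == "regions") {
          if (!nrow(regions)) abort("No wavebands exceeded the DP threshold.")
          cal_ft <- region_features(cal, regions)
          test_ft <- region_features(test, regions)
        } else if (features == "differences") {
          if (!nrow(regions)) abort("No wavebands exceeded the DP threshold.")
          cal_ft <- spectral_differences(cal, regions)
          test_ft <- spectral_differences(test, regions)
        } else {
          abort(sprintf("Unknown feature set '%s'.", features))
        }
        m <- fit_cell(cal_ft, test_ft, classifier)
        dplyr::mutate(m,
          n_inputs = ncol(feature_matrix(cal_ft)), error = NA_character_
        )
      },
      error = function(e) {
        tibble::tibble(
          TP = NA_integer_, FN = NA_integer_, FP = NA_integer_, TN = NA_integer_,
          sen = NA_real_, spe = NA_real_, precis = NA_real_, acc = NA_real_,
          n_inputs = NA_integer_, error = conditionMessage(e)
        )
      }
    )
    dplyr::bind_cols(
      tibble::tibble(
        pretreatment = pretreatment, classifier = classifier,
        features = features, seed = seed
      ),
      row
    )
  })
}
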