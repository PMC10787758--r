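#' Fit one SIMCA class sub-model
#'
#' A SIMCA sub-model is a PCA of one class's calibration rows: the class
#' mean, the leading `n_pcs` loadings, the per-variable residual variances
#' `s2_j` of the reconstruction, and the pooled residual variance `s0^2`
#' against which new samples' residual distances are judged.
#'
#' With `df = "corrected"` (default) the standard SIMCA degrees of freedom
#' are used: `s2_j = sum_i e_ij^2 / (n - n_pcs - 1)` and
#' `s0^2 = sum_ij e_ij^2 / ((n - n_pcs - 1) * (p - n_pcs))`; with
#' `df = "naive"` plain mean squares over `n` rows and `p` variables.
#'
#' @param x Numeric matrix of the class's rows (samples x variables).
#' @param n_pcs Number of principal components, `< n - 1`.
#' @param label Class label carried in the model.
#' @param df Degrees-of-freedom convention, `"corrected"` or `"naive"`.
#' @return An object of class `simca_class_model`.
#' @export
simca_class_model <- function(x, n_pcs, label = "class", df = c("corrected", "naive")) {
  df <- match.arg(df)
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  n_pcs <- as.integer(n_pcs)
  if (n_pcs < 0) abort("`n_pcs` must be nonnegative.")
  if (n <= n_pcs + 1) abort("Need more rows than `n_pcs` + 1 to fit a class model.")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  if (n_pcs > 0) {
    pca <- prcomp(xc, center = FALSE, scale. = FALSE)
    loadings <- pca$rotation[, seq_len(n_pcs), drop = FALSE]
    scores <- xc %*% loadings
    resid <- xc - scores %*% t(loadings)
  } else {
    loadings <- matrix(0, p, 0)
    resid <- xc
  }
  denom_row <- if (df == "corrected") n - n_pcs - 1 else n
  denom_col <- if (df == "corrected") p - n_pcs else p
  if (denom_col <= 0) abort("`n_pcs` must be below the number of variables.")
  s2_j <- colSums(resid^2) / denom_row
  s0_sq <- sum(resid^2) / (denom_row * denom_col)
  structure(
    list(
      label = label, center = center, loadings = loadings,
      n_pcs = n_pcs, s2_j = s2_j, s0_sq = s0_sq,
      n = n, p = p, df = df,
      variables = colnames(x) %||% paste0("V", seq_len(p))
    ),
    class = "simca_class_model"
  )
}

# Per-variable mean squared residuals of rows `x` projected onto `model`,
# on the model's df convention (shared by self- and cross-projections so
# that identical inputs give a discrimination power of exactly 1).
simca_residuals <- function(model, x) {
  xc <- sweep(as.matrix(x), 2, model$center)
  if (model$n_pcs > 0) {
    resid <- xc - (xc %*% model$loadings) %*% t(model$loadings)
  } else {
    resid <- xc
  }
  resid
}

simca_cross_s2 <- function(model, x) {
  resid <- simca_residuals(model, x)
  denom <- if (model$df == "corrected") nrow(resid) - model$n_pcs - 1 else nrow(resid)
  if (denom <= 0) denom <- nrow(resid)
  colSums(resid^2) / denom
}

#' Fit a two-class SIMCA classifier
#'
#' Fits one PCA sub-model per class on the calibration rows. When `n_pcs`
#' is `NULL` the per-class component counts are chosen by cross-validated
#' misclassification on the calibration set (coordinate search over
#' 1..`max_pcs`, 5 folds), the "trial and error on calibration" route;
#' supply a named vector to pin them.
#'
#' @param tbl Calibration spectrum/feature table with a `class` column.
#' @param n_pcs `NULL`, a single count, or a named vector (one per class).
#' @param alpha F-test acceptance level for class membership.
#' @param max_pcs Upper bound of the per-class search (default 10).
#' @param df Degrees-of-freedom convention, see [simca_class_model()].
#' @param seed Seed for the cross-validation folds.
#' @return An object of class `simca_fit`.
#' @export
simca_fit <- function(tbl, n_pcs = NULL, alpha = 0.05, max_pcs = 10,
                      df = c("corrected", "naive"), seed = 1) {
  df <- match.arg(df)
  x <- feature_matrix(tbl)
  classes <- sort(unique(tbl$class))
  if (length(classes) < 2) abort("SIMCA classification needs at least 2 classes.")
  rows <- lapply(classes, function(cl) x[tbl$class == cl, , drop = FALSE])
  names(rows) <- classes
  cap <- vapply(rows, function(m) {
    as.integer(min(max_pcs, nrow(m) - 2L, ncol(m) - 1L))
  }, integer(1))
  if (any(cap < 1)) abort("Insufficient rows in a class to fit a SIMCA sub-model.")
  if (is.null(n_pcs)) {
    k <- simca_select_pcs(x, tbl$class, classes, cap, alpha, df, seed)
  } else {
    k <- rep_len(as.integer(n_pcs), length(classes))
    names(k) <- if (!is.null(names(n_pcs))) names(n_pcs) else classes
    k <- k[classes]
  }
  models <- lapply(classes, function(cl) {
    simca_class_model(rows[[cl]], k[[cl]], label = cl, df = df)
  })
  names(models) <- classes
  structure(
    list(models = models, classes = classes, alpha = alpha, df = df,
         variables = colnames(x)),
    class = "simca_fit"
  )
}

# Coordinate search over per-class PC counts, scored by 5-fold
# cross-validated forced-assignment misclassification.
simca_select_pcs <- function(x, class, classes, cap, alpha, df, seed) {
  set.seed(seed)
  n <- nrow(x)
  folds <- sample(rep(seq_len(5), length.out = n))
  cv_error <- function(k) {
    wrong <- 0
    for (f in seq_len(5)) {
      tr <- folds != f
      models <- lapply(classes, function(cl) {
        rows <- x[tr & class == cl, , drop = FALSE]
        if (nrow(rows) <= max(k) + 1) return(NULL)
        simca_class_model(rows, k[[cl]], label = cl, df = df)
      })
      if (any(vapply(models, is.null, logical(1)))) return(Inf)
      names(models) <- classes
      d <- vapply(models, function(m) {
        resid <- simca_residuals(m, x[!tr, , drop = FALSE])
        denom <- if (df == "corrected") m$p - m$n_pcs else m$p
        sqrt(rowSums(resid^2) / denom / m$s0_sq)
      }, numeric(sum(!tr)))
      if (is.null(dim(d))) d <- matrix(d, nrow = 1)
      pred <- classes[apply(d, 1, which.min)]
      wrong <- wrong + sum(pred != class[!tr])
    }
    wrong
  }
  k <- vapply(classes, function(cl) min(3L, cap[[cl]]), integer(1))
  names(k) <- classes
  for (cl in classes) {
    errs <- vapply(seq_len(cap[[cl]]), function(kk) {
      trial <- k
      trial[[cl]] <- kk
      cv_error(trial)
    }, numeric(1))
    k[[cl]] <- which.min(errs) # ties break toward fewer components
  }
  k
}

#' Classify samples with a fitted SIMCA model
#'
#' For each sample and class sub-model the projection residual variance is
#' converted to a reduced distance `d = s_sample / s0`; membership is
#' accepted when the F-statistic `d^2` stays below the `1 - alpha` quantile
#' of its F-distribution, and the forced single assignment (which fills
#' confusion matrices) is the class with the smallest reduced distance.
#' Exact distance ties fall to the first class in sorted label order and are
#' flagged ambiguous.
#'
#' @param object A `simca_fit`.
#' @param new_data Spectrum/feature table on the training grid.
#' @param ... Unused.
#' @return A tibble: `sample_id`, one `dist_<class>` and `accepted_<class>`
#'   column per class, `.pred_class`, `ambiguous`.
#' @export
predict.simca_fit <- function(object, new_data, ...) {
  x <- feature_matrix(new_data)
  if (!identical(colnames(x), object$variables)) {
    abort("Feature grid of `new_data` does not match the fitted model.")
  }
  res <- purrr::map(object$models, function(m) {
    resid <- simca_residuals(m, x)
    denom_col <- if (m$df == "corrected") m$p - m$n_pcs else m$p
    s2 <- rowSums(resid^2) / denom_col
    d <- sqrt(s2 / m$s0_sq)
    df2 <- if (m$df == "corrected") {
      (m$n - m$n_pcs - 1) * (m$p - m$n_pcs)
    } else {
      m$n * m$p
    }
    fcrit <- qf(1 - object$alpha, denom_col, df2)
    list(d = d, accepted = d^2 <= fcrit)
  })
  dmat <- do.call(cbind, lapply(res, `[[`, "d"))
  best <- apply(dmat, 1, which.min)
  ambiguous <- apply(dmat, 1, function(r) sum(r == min(r)) > 1)
  out <- tibble::tibble(
    sample_id = new_data$sample_id %||% sprintf("row_%d", seq_len(nrow(x)))
  )
  for (cl in object$classes) {
    out[[paste0("dist_", cl)]] <- unname(res[[cl]]$d)
    out[[paste0("accepted_", cl)]] <- unname(res[[cl]]$accepted)
  }
  out$.pred_class <- object$classes[best]
  out$ambiguous <- ambiguous
  out
}

#' @export
print.simca_fit <- function(x, ...) {
  cat("<simca_fit>\n")
  for (m in x$models) {
    cat(sprintf(
      "  class %-10s n = %3d, PCs = %d, s0 = %.4g\n",
      m$label, m$n, m$n_pcs, sqrt(m$s0_sq)
    ))
  }
  invisible(x)
}

#' Per-wavelength discrimination power
#'
#' The discrimination power of variable `j` between two SIMCA sub-models is
#' the cross- over within-class residual-variance ratio
#' \deqn{DP_j = \sqrt{\frac{s_j^2(A \to B) + s_j^2(B \to A)}
#'                        {s_j^2(A \to A) + s_j^2(B \to B)}}}
#' where `s_j^2(X -> M)` is the per-variable mean squared residual of class
#' X's rows projected onto model M. Values near 1 carry no discriminating
#' information; values above 3 conventionally mark wavelengths useful for
#' separating the classes. `direction = "one_way"` uses only the A-onto-B
#' projection, `sqrt(s_j^2(A -> B) / s_j^2(B -> B))`.
#'
#' @param fit A `simca_fit` (two classes).
#' @param tbl The table the sub-models were fitted on (class rows are
#'   re-projected from it).
#' @param threshold Usefulness threshold carried in the profile (default 3).
#' @param direction `"symmetric"` (default) or `"one_way"` (first class
#'   projected onto the second's model).
#' @return A `dp_profile` tibble: `wavelength` (NA for non-spectral
#'   features), `variable`, `dp`, with the threshold as an attribute.
#' @export
discrimination_power <- function(fit, tbl, threshold = 3,
                                 direction = c("symmetric", "one_way")) {
  direction <- match.arg(direction)
  if (length(fit$classes) != 2) abort("Discrimination power is defined for 2 classes.")
  x <- feature_matrix(tbl)
  if (!identical(colnames(x), fit$variables)) {
    abort("Feature grid of `tbl` does not match the fitted model.")
  }
  a <- fit$classes[1]
  b <- fit$classes[2]
  xa <- x[tbl$class == a, , drop = FALSE]
  xb <- x[tbl$class == b, , drop = FALSE]
  s_aa <- simca_cross_s2(fit$models[[a]], xa)
  s_bb <- simca_cross_s2(fit$models[[b]], xb)
  s_ab <- simca_cross_s2(fit$models[[b]], xa)
  s_ba <- simca_cross_s2(fit$models[[a]], xb)
  if (direction == "symmetric") {
    num <- s_ab + s_ba
    den <- s_aa + s_bb
  } else {
    num <- s_ab
    den <- s_bb
  }
  dp <- rep(Inf, length(num))
  ok <- den > 0
  dp[ok] <- sqrt(num[ok] / den[ok])
  if (any(!ok)) {
    warn(sprintf(
      "Zero within-class residual variance at %d variable(s); DP reported as Inf.",
      sum(!ok)
    ))
  }
  vars <- fit$variables
  wl <- suppressWarnings(as.numeric(sub("^nm_", "", vars)))
  out <- tibble::tibble(wavelength = wl, variable = vars, dp = dp)
  attr(out, "threshold") <- threshold
  class(out) <- c("dp_profile", class(out))
  out
}

#' @export
tidy.simca_fit <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble::tibble(
      class = m$label, n = m$n, n_pcs = m$n_pcs,
      s0 = sqrt(m$s0_sq)
    )
  })
}

#' @export
glance.simca_fit <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_variables = length(x$variables),
    alpha = x$alpha,
    df = x$df
  )
}
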