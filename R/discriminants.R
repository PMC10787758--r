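#' Fit LDA or QDA in principal-component score space
#'
#' With hundreds of collinear wavelengths and at most a couple of hundred
#' calibration eggs, the raw-spectrum covariance matrix is singular, so the
#' discriminant model is fitted in a reduced PCA score space: a PCA is
#' learned on the calibration rows, spectra are projected onto the
#' components explaining `var_explained` of the variance (capped at
#' `max_dims` and at what the smallest class can support), and a Gaussian
#' class model is fitted on the scores — one pooled covariance for LDA, one
#' covariance per class for QDA. Priors are the empirical class
#' frequencies.
#'
#' @param tbl Calibration spectrum/feature table with a `class` column.
#' @param kind `"lda"` or `"qda"`.
#' @param score_dims Optional fixed number of score dimensions.
#' @param var_explained Variance fraction the retained components must
#'   cover (default 0.99).
#' @param max_dims Cap on the score dimension (default 40).
#' @return An object of class `da_fit`.
#' @export
da_fit <- function(tbl, kind = c("lda", "qda"), score_dims = NULL,
                   var_explained = 0.99, max_dims = 40) {
  kind <- match.arg(kind)
  x <- feature_matrix(tbl)
  classes <- sort(unique(tbl$class))
  if (length(classes) < 2) abort("Discriminant analysis needs at least 2 classes.")
  counts <- table(tbl$class)
  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  rank <- sum(ev > max(ev) * 1e-10)
  if (is.null(score_dims)) {
    score_dims <- min(
      which(cumsum(ev) / sum(ev) >= var_explained)[1],
      max_dims, rank, min(counts) - 2L
    )
  }
  score_dims <- as.integer(score_dims)
  if (score_dims < 1) abort("At least one score dimension is required.")
  if (any(counts <= score_dims + 1) && kind == "qda") {
    abort("Too few rows per class for QDA at this score dimension; reduce `score_dims`.")
  }
  scores <- pca$x[, seq_len(score_dims), drop = FALSE]
  fit <- tryCatch(
    switch(kind,
      lda = MASS::lda(scores, grouping = factor(tbl$class, levels = classes)),
      qda = MASS::qda(scores, grouping = factor(tbl$class, levels = classes))
    ),
    error = function(e) {
      abort(sprintf(
        "Covariance estimation failed (%s); try fewer score dimensions.",
        conditionMessage(e)
      ))
    }
  )
  structure(
    list(
      kind = kind, fit = fit, classes = classes,
      center = pca$center,
      rotation = pca$rotation[, seq_len(score_dims), drop = FALSE],
      score_dims = score_dims,
      variables = colnames(x),
      priors = as.numeric(counts) / sum(counts)
    ),
    class = "da_fit"
  )
}

#' Predict classes and posteriors from a discriminant model
#'
#' Projects new spectra into the fitted score space and assigns each sample
#' to the class with the largest Gaussian posterior. Posterior ties are
#' flagged ambiguous.
#'
#' @param object A `da_fit`.
#' @param new_data Table on the training feature grid.
#' @param ... Unused.
#' @return A tibble: `sample_id`, `.pred_class`, one `posterior_<class>`
#'   column per class, `ambiguous`.
#' @export
predict.da_fit <- function(object, new_data, ...) {
  x <- feature_matrix(new_data)
  if (!identical(colnames(x), object$variables)) {
    abort("Feature grid of `new_data` does not match the fitted model.")
  }
  if (!nrow(x)) {
    out <- tibble::tibble(sample_id = character(), .pred_class = character())
    for (cl in object$classes) out[[paste0("posterior_", cl)]] <- numeric()
    out$ambiguous <- logical()
    return(out)
  }
  scores <- sweep(x, 2, object$center) %*% object$rotation
  pred <- predict(object$fit, scores)
  post <- pred$posterior
  ambiguous <- apply(post, 1, function(r) sum(r == max(r)) > 1)
  out <- tibble::tibble(
    sample_id = new_data$sample_id %||% sprintf("row_%d", seq_len(nrow(x))),
    .pred_class = as.character(pred$class)
  )
  for (cl in object$classes) out[[paste0("posterior_", cl)]] <- unname(post[, cl])
  out$ambiguous <- ambiguous
  out
}

#' @export
print.da_fit <- function(x, ...) {
  cat(sprintf(
    "<da_fit> %s in %d-dimensional PCA score space, classes: %s\n",
    toupper(x$kind), x$score_dims, paste(x$classes, collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.da_fit <- function(x, ...) {
  tibble::tibble(
    class = x$classes,
    prior = x$priors
  )
}

#' @export
glance.da_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    score_dims = x$score_dims,
    n_variables = length(x$variables)
  )
}
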