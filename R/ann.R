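#' Train a single-hidden-layer feed-forward network
#'
#' The network family is the classic one-input-layer / one-hidden-layer /
#' two-output-node feed-forward topology trained by back-propagation
#' (`nnet`), with logistic hidden units and a softmax two-node output
#' trained on cross-entropy. Inputs are standardized with means and
#' standard deviations learned from the calibration rows only; weight decay
#' regularizes training. Given one seed the fitted weights are fully
#' reproducible.
#'
#' @param tbl Calibration spectrum/feature table with a `class` column.
#' @param nhl Number of hidden nodes (NHL), `>= 1`.
#' @param seed Integer seed for the random initial weights.
#' @param maxit Maximum back-propagation epochs (default 500).
#' @param decay Weight decay (default 1e-3).
#' @return An object of class `mlp_fit`.
#' @export
mlp_fit <- function(tbl, nhl, seed = 1, maxit = 500, decay = 1e-3) {
  if (nhl < 1) abort("`nhl` must be at least 1.")
  x <- feature_matrix(tbl)
  classes <- sort(unique(tbl$class))
  if (length(classes) < 2) abort("Network training needs at least 2 classes.")
  mu <- colMeans(x)
  sigma <- apply(x, 2, sd)
  sigma[sigma < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sigma, "/")
  y <- nnet::class.ind(factor(tbl$class, levels = classes))
  set.seed(seed)
  net <- nnet::nnet(
    xs, y,
    size = nhl, softmax = TRUE, maxit = maxit, decay = decay,
    MaxNWts = 1e6, trace = FALSE
  )
  if (!all(is.finite(net$wts))) abort("Training diverged: non-finite weights.")
  structure(
    list(
      net = net, classes = classes, nhl = as.integer(nhl),
      mu = mu, sigma = sigma, variables = colnames(x),
      seed = seed, maxit = maxit, decay = decay,
      topology = sprintf("%d-%d-%d", ncol(x), nhl, length(classes))
    ),
    class = "mlp_fit"
  )
}

#' Predict classes and posteriors from a trained network
#'
#' @param object An `mlp_fit`.
#' @param new_data Table on the training feature grid.
#' @param ... Unused.
#' @return A tibble: `sample_id`, `.pred_class`, one `posterior_<class>`
#'   column per class.
#' @export
predict.mlp_fit <- function(object, new_data, ...) {
  x <- feature_matrix(new_data)
  if (!identical(colnames(x), object$variables)) {
    abort("Feature grid of `new_data` does not match the fitted network.")
  }
  xs <- sweep(sweep(x, 2, object$mu), 2, object$sigma, "/")
  post <- predict(object$net, xs)
  out <- tibble::tibble(
    sample_id = new_data$sample_id %||% sprintf("row_%d", seq_len(nrow(x))),
    .pred_class = object$classes[max.col(post, ties.method = "first")]
  )
  for (i in seq_along(object$classes)) {
    out[[paste0("posterior_", object$classes[i])]] <- unname(post[, i])
  }
  out
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf("<mlp_fit> topology %s, decay %g, seed %d\n",
              x$topology, x$decay, x$seed))
  invisible(x)
}

#' Search the hidden-layer size
#'
#' The trial-and-error topology search: for each candidate number of hidden
#' nodes, `repeats` networks are trained on an internal calibration split
#' (so the external test set stays untouched) with derived seeds
#' `seed * 1000 + repeat`, and their validation accuracies averaged. The
#' best NHL is the argmax of the average accuracy; ties break toward the
#' smaller (cheaper) topology.
#'
#' @param tbl Calibration spectrum/feature table.
#' @param nhl_range Candidate hidden-layer sizes (default `1:30`).
#' @param repeats Networks trained per candidate (default 3).
#' @param seed Master seed; derives the internal split and the per-network
#'   seeds.
#' @param validation_fraction Fraction of calibration rows held out
#'   internally to score each topology (default 0.25).
#' @param maxit,decay Passed to [mlp_fit()].
#' @return A list with `best_nhl` and `results`, an `nhl_search` tibble of
#'   per-candidate mean validation accuracy (%).
#' @export
topology_search <- function(tbl, nhl_range = 1:30, repeats = 3, seed = 1,
                            validation_fraction = 0.25, maxit = 500,
                            decay = 1e-3) {
  if (!length(nhl_range) || any(nhl_range < 1)) abort("`nhl_range` must be positive.")
  if (repeats < 1) abort("`repeats` must be at least 1.")
  inner <- split_calibration_test(tbl, validation_fraction, seed = seed)
  results <- purrr::map_dfr(sort(unique(as.integer(nhl_range))), function(nhl) {
    accs <- vapply(seq_len(repeats), function(r) {
      fit <- mlp_fit(inner$calibration, nhl,
        seed = seed * 1000 + r,
        maxit = maxit, decay = decay
      )
      pred <- predict(fit, inner$test)
      100 * mean(pred$.pred_class == inner$test$class)
    }, numeric(1))
    tibble::tibble(nhl = nhl, mean_accuracy = mean(accs), sd_accuracy = sd(accs))
  })
  class(results) <- c("nhl_search", class(results))
  best <- results$nhl[which.max(results$mean_accuracy)] # ties -> smaller NHL
  list(best_nhl = best, results = results)
}

#' Input sensitivity analysis of a trained network
#'
#' Scores each input's importance as the ratio of the network error after
#' replacing that input (every sample) by its calibration mean to the error
#' on intact data — the mean-substitution convention of classic neural
#' network packages. Ratios near 1 mean the input is unimportant; large
#' ratios mark inputs the fit depends on. The error is the summed squared
#' difference between predicted posteriors and the 0/1 class indicators.
#' `method = "permute"` shuffles the input across samples instead of fixing
#' it at the mean.
#'
#' @param fit An `mlp_fit`.
#' @param tbl Table to evaluate on (typically the calibration set).
#' @param method `"mean"` (default) or `"permute"`.
#' @param seed Seed for the permutation variant.
#' @return A `sensitivity_profile` tibble: `variable`, `wavelength` (NA for
#'   non-spectral features), `ratio`.
#' @export
sensitivity_analysis <- function(fit, tbl, method = c("mean", "permute"), seed = 1) {
  method <- match.arg(method)
  x <- feature_matrix(tbl)
  if (!identical(colnames(x), fit$variables)) {
    abort("Feature grid of `tbl` does not match the fitted network.")
  }
  y <- nnet::class.ind(factor(tbl$class, levels = fit$classes))
  xs <- sweep(sweep(x, 2, fit$mu), 2, fit$sigma, "/")
  err <- function(m) sum((predict(fit$net, m) - y)^2)
  base <- err(xs)
  if (base < 1e-12) {
    warn("Baseline network error is ~0; sensitivity ratios use an error floor of 1e-12.")
    base <- 1e-12
  }
  if (method == "permute") set.seed(seed)
  ratios <- vapply(seq_len(ncol(xs)), function(j) {
    xj <- xs
    xj[, j] <- if (method == "mean") 0 else sample(xs[, j]) # 0 = calibration mean after standardization
    err(xj) / base
  }, numeric(1))
  wl <- suppressWarnings(as.numeric(sub("^nm_", "", fit$variables)))
  out <- tibble::tibble(variable = fit$variables, wavelength = wl, ratio = ratios)
  class(out) <- c("sensitivity_profile", class(out))
  out
}

#' @export
tidy.mlp_fit <- function(x, ...) {
  tibble::tibble(
    topology = x$topology,
    n_inputs = length(x$variables),
    nhl = x$nhl,
    n_outputs = length(x$classes),
    n_weights = length(x$net$wts)
  )
}

#' @export
glance.mlp_fit <- function(x, ...) {
  tibble::tibble(
    nhl = x$nhl,
    final_loss = x$net$value,
    converged = x$net$convergence == 0,
    seed = x$seed
  )
}
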