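test_that("class sub-model residual variances match an independent projection oracle", {
  set.seed(20)
  x <- matrix(rnorm(20 * 8, 5, 2), 20, 8)
  colnames(x) <- paste0("V", 1:8)
  model <- simca_class_model(x, n_pcs = 3)

  # independent oracle: explicit SVD projection and residual arithmetic
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  proj <- sv$v[, 1:3] %*% t(sv$v[, 1:3])
  resid <- xc - xc %*% proj
  expect_equal(unname(model$s2_j), unname(colSums(resid^2) / (20 - 3 - 1)),
               tolerance = 1e-10)
  expect_equal(model$s0_sq, sum(resid^2) / ((20 - 3 - 1) * (8 - 3)),
               tolerance = 1e-10)
})

test_that("degenerate sub-model cases behave as defined", {
  set.seed(21)
  # data lying exactly in a 2-dimensional affine subspace
  basis <- matrix(rnorm(16), 8, 2)
  scores <- matrix(rnorm(24), 12, 2)
  x <- scores %*% t(basis) + matrix(5, 12, 8)
  model <- simca_class_model(x, n_pcs = 2)
  expect_equal(unname(model$s2_j), rep(0, 8), tolerance = 1e-18)

  # zero components: residuals are the centered data themselves
  y <- matrix(rnorm(60), 10, 6)
  m0 <- simca_class_model(y, n_pcs = 0)
  expect_equal(unname(m0$s2_j), unname(apply(y, 2, var)), tolerance = 1e-12)

  expect_error(simca_class_model(y[1:3, ], n_pcs = 3), "more rows")
})

test_that("classification accepts class means and separates planted classes", {
  tbl <- separated_classes(n_per = 30, p = 8, shift = 10, seed = 22)
  sp <- split_calibration_test(tbl, 0.2, seed = 1)
  fit <- simca_fit(sp$calibration, n_pcs = 2)

  # a sample at a class mean has reduced distance ~0 and is accepted
  mean_row <- toy_table(
    matrix(fit$models$fertile$center, 1),
    class = "fertile"
  )
  pred_mean <- predict(fit, mean_row)
  expect_lt(pred_mean$dist_fertile, 0.2)
  expect_true(pred_mean$accepted_fertile)
  expect_equal(pred_mean$.pred_class, "fertile")

  pred <- predict(fit, sp$test)
  expect_gte(mean(pred$.pred_class == sp$test$class), 0.95)
})

test_that("exact distance ties fall to the first class and are flagged", {
  set.seed(23)
  x <- matrix(rnorm(80), 10, 8)
  tbl <- toy_table(rbind(x, x), class = rep(c("fertile", "infertile"), each = 10))
  fit <- simca_fit(tbl, n_pcs = 2)
  probe <- toy_table(matrix(rnorm(8), 1), class = "fertile")
  pred <- predict(fit, probe)
  expect_equal(pred$dist_fertile, pred$dist_infertile)
  expect_true(pred$ambiguous)
  expect_equal(pred$.pred_class, "fertile")
})

test_that("single-class training rows are accepted at close to the nominal rate", {
  set.seed(24)
  tbl <- toy_table(matrix(rnorm(200 * 10), 200, 10))
  x <- spectra_matrix(tbl)
  model <- simca_class_model(x, n_pcs = 3, label = "fertile")
  fit <- structure(
    list(models = list(fertile = model), classes = "fertile", alpha = 0.05,
         df = "corrected", variables = colnames(x)),
    class = "simca_fit"
  )
  pred <- predict(fit, tbl)
  expect_gte(mean(pred$accepted_fertile), 0.90)
})

test_that("discrimination power is ~1 under the null and peaks at a planted band", {
  set.seed(25)
  null_tbl <- toy_table(
    matrix(rnorm(200 * 16), 200, 16),
    class = rep(c("fertile", "infertile"), each = 100)
  )
  fit <- simca_fit(null_tbl, n_pcs = 2)
  dp <- discrimination_power(fit, null_tbl)
  expect_gte(mean(dp$dp), 0.8)
  expect_lte(mean(dp$dp), 1.25)

  # planted mean shift at exactly one band, far above noise
  set.seed(26)
  x <- matrix(rnorm(120 * 16), 120, 16)
  x[1:60, 7] <- x[1:60, 7] + 8
  planted <- toy_table(x, class = rep(c("fertile", "infertile"), each = 60))
  fitp <- simca_fit(planted, n_pcs = 2)
  dpp <- discrimination_power(fitp, planted)
  expect_equal(which.max(dpp$dp), 7)
  expect_gt(max(dpp$dp), 3)
})

test_that("discrimination power is symmetric and exactly 1 on identical inputs", {
  set.seed(27)
  x <- matrix(rnorm(40 * 10), 40, 10)
  same <- toy_table(rbind(x, x), class = rep(c("fertile", "infertile"), each = 40))
  fit <- simca_fit(same, n_pcs = 2)
  dp <- discrimination_power(fit, same)
  expect_equal(dp$dp, rep(1, 10), tolerance = 1e-10)

  # symmetry in class order: relabel and compare
  tbl <- separated_classes(n_per = 25, p = 10, shift = 3, seed = 28)
  fit1 <- simca_fit(tbl, n_pcs = 2)
  dp1 <- discrimination_power(fit1, tbl)
  swapped <- dplyr::mutate(tbl, class = ifelse(class == "fertile", "infertile", "fertile"))
  fit2 <- simca_fit(swapped, n_pcs = 2)
  dp2 <- discrimination_power(fit2, swapped)
  expect_equal(dp1$dp, dp2$dp, tolerance = 1e-10)

  # one-directional variant is exposed and differs in general
  dp_one <- discrimination_power(fit1, tbl, direction = "one_way")
  expect_false(isTRUE(all.equal(dp1$dp, dp_one$dp)))
})
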