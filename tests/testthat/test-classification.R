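test_that("balancing equalizes every specimen-class cell to the minimum count", {
  set.seed(1)
  tbl <- dplyr::bind_rows(
    tibble::tibble(specimen = 1, class = "GM", f1 = rnorm(10)),
    tibble::tibble(specimen = 1, class = "WM", f1 = rnorm(12)),
    tibble::tibble(specimen = 2, class = "GM", f1 = rnorm(8)),
    tibble::tibble(specimen = 2, class = "WM", f1 = rnorm(8))
  )
  bal <- balance_classes(tbl, seed = 5)
  counts <- dplyr::count(bal, specimen, class)
  expect_true(all(counts$n == 8))

  # reproducibility and idempotence
  expect_identical(
    dplyr::arrange(balance_classes(tbl, seed = 5), f1),
    dplyr::arrange(balance_classes(tbl, seed = 5), f1)
  )
  bal2 <- balance_classes(bal, seed = 9)
  expect_setequal(bal2$f1, bal$f1)

  # specimen missing one class is dropped with a warning
  tbl_bad <- dplyr::bind_rows(tbl, tibble::tibble(
    specimen = 3, class = "GM", f1 = rnorm(5)
  ))
  expect_warning(bal3 <- balance_classes(tbl_bad, seed = 2), "lacking")
  expect_false(3 %in% bal3$specimen)
})

test_that("confusion metrics follow the sensitivity/specificity definitions", {
  perfect <- matrix(c(50, 0, 0, 50), 2, 2)
  m <- confusion_metrics(perfect)
  expect_equal(m$accuracy, 100)
  expect_equal(m$true_gm_rate, 100)
  expect_equal(m$true_wm_rate, 100)

  mixed <- matrix(c(40, 10, 10, 40), 2, 2) # rows predicted, cols expected
  m2 <- confusion_metrics(mixed)
  expect_equal(m2$accuracy, 80)
  expect_equal(m2$true_gm_rate, 80)
  expect_equal(m2$true_wm_rate, 80)

  degenerate <- matrix(c(0, 30, 0, 30), 2, 2) # everything predicted WM
  m3 <- confusion_metrics(degenerate)
  expect_equal(m3$true_gm_rate, 0)
  expect_equal(m3$accuracy, 50)
})

test_that("leave-one-specimen-out CV: folds, train fraction, separable case", {
  tbl <- make_separable_table(n_per_cell = 25, n_specimens = 6, gap = 10)
  cv <- losocv_knn(tbl, c("f1", "f2", "f3"), k = 1)
  expect_equal(nrow(cv$folds), 6)
  expect_equal(cv$train_fraction, 5 / 6, tolerance = 1e-12)
  expect_true(all(cv$folds$accuracy_train == 100))
  expect_true(all(cv$folds$accuracy_test == 100))

  expect_error(losocv_knn(tbl, "f1", k = 10000), "exceeds")
  expect_error(
    losocv_knn(dplyr::filter(tbl, specimen == 1), "f1", k = 1),
    ">= 2 specimens"
  )
})

test_that("shuffled labels give chance-level test accuracy", {
  tbl <- make_separable_table(n_per_cell = 60, n_specimens = 4, seed = 3)
  set.seed(10)
  tbl$class <- sample(tbl$class)
  cv <- losocv_knn(tbl, c("f1", "f2", "f3"), k = 15)
  acc <- cv$summary$mean[cv$summary$metric == "accuracy_test"]
  # binomial CI around 50% for n = 120 per fold, 4 folds
  expect_gt(acc, 35)
  expect_lt(acc, 65)
})

test_that("permutation importance isolates the informative feature", {
  tbl <- make_separable_table(n_per_cell = 40, n_specimens = 4, gap = 4)
  imp <- permutation_importance(tbl, c("f1", "f2", "f3"), k = 5, s = 5, seed = 2)
  expect_equal(imp$feature[1], "f1")
  expect_gt(
    imp$importance[imp$feature == "f1"],
    5 * max(abs(imp$importance[imp$feature != "f1"]) + 1e-9)
  )
  # uninformative feature importance is near zero
  expect_lt(max(abs(imp$importance[imp$feature != "f1"])), 5)

  # more repetitions keep the ranking and reduce the spread
  imp10 <- permutation_importance(tbl, c("f1", "f2", "f3"), k = 5, s = 10, seed = 2)
  expect_equal(imp10$feature[1], "f1")
})

test_that("sequential floating selection finds the separating feature first", {
  tbl <- make_separable_table(n_per_cell = 30, n_specimens = 4, gap = 5)
  fw <- sequential_feature_selection(tbl, c("f1", "f2", "f3"),
    n = 1, direction = "forward", k = 5
  )
  expect_true(all(vapply(fw$per_fold, function(s) s == "f1", logical(1))))

  bw <- sequential_feature_selection(tbl, c("f1", "f2", "f3"),
    n = 1, direction = "backward", k = 5
  )
  expect_equal(fw$selected, bw$selected)
  expect_equal(fw$selected, "f1")
})

test_that("rank-sum comparison separates shifted samples and respects symmetry", {
  set.seed(4)
  x <- rnorm(500)
  y <- rnorm(500, 3)
  res <- compare_distributions(x, y)
  expect_lt(res$p_value, 1e-5)

  res_swap <- compare_distributions(y, x)
  expect_equal(res$p_value, res_swap$p_value, tolerance = 1e-12)

  same <- compare_distributions(x, x)
  expect_gt(same$p_value, 0.95)

  tied <- compare_distributions(rep(1, 20), rep(1, 30))
  expect_equal(tied$p_value, 1)

  expect_error(compare_distributions(numeric(0), y), "non-empty")
})

test_that("no class bias on balanced symmetric data", {
  tbl <- make_separable_table(n_per_cell = 50, n_specimens = 4, gap = 2)
  cv <- losocv_knn(tbl, c("f1", "f2", "f3"), k = 9)
  gm <- cv$summary$mean[cv$summary$metric == "true_gm_test"]
  wm <- cv$summary$mean[cv$summary$metric == "true_wm_test"]
  expect_lt(abs(gm - wm), 10)
})
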