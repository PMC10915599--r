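test_that("stratified folds have balanced sizes and class counts", {
  y <- rep(c(1, 0), c(57, 50))
  plan <- stratified_kfold(y, 4, seed = 1)
  sizes <- sort(lengths(plan$test_idx), decreasing = TRUE)
  expect_identical(sizes, c(27L, 27L, 27L, 26L))
  for (f in 1:4) {
    cases <- sum(y[plan$test_idx[[f]]] == 1)
    expect_lte(abs(cases - 57 / 4), 1)
  }
  # partition: union is everything, pairwise disjoint
  all_idx <- sort(unlist(plan$test_idx))
  expect_identical(all_idx, seq_along(y))
  # determinism
  expect_identical(stratified_kfold(y, 4, seed = 1)$test_idx, plan$test_idx)
  expect_false(identical(stratified_kfold(y, 4, seed = 2)$test_idx,
                         plan$test_idx))
  expect_error(stratified_kfold(rep(c(1, 0), c(3, 50)), 4), "at least")
})

test_that("metrics match hand values and the confusion-matrix oracle", {
  # perfect separation
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unname(m), c(1, 1, 1, 1, 1, 1))
  # TP=3 FP=1 TN=2 FN=2
  y <- c(1, 1, 1, 0, 0, 0, 1, 1)
  p <- c(0.9, 0.8, 0.7, 0.6, 0.3, 0.2, 0.4, 0.1)
  m2 <- compute_metrics(y, p)
  expect_equal(unname(m2["ACC"]), 0.625)
  expect_equal(unname(m2["Sn"]), 0.6)
  expect_equal(unname(m2["Sp"]), 2 / 3, tolerance = 1e-4)
  expect_equal(unname(m2["MCC"]), 4 / sqrt(240), tolerance = 1e-4)
  # constant scores: AUROC 0.5 under the tie convention
  expect_equal(unname(compute_metrics(c(1, 0, 1, 0),
                                      rep(0.4, 4))["AUROC"]), 0.5)
  # oracle agreement on random vectors
  set.seed(30)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)      # rounding forces ties
    expect_equal(compute_metrics(y, p), oracle_metrics(y, p))
  }
  # single-class truth: AUROC missing with a warning
  expect_warning(m3 <- compute_metrics(c(1, 1), c(0.6, 0.7)),
                 "single class")
  expect_true(is.na(m3["AUROC"]))
})

test_that("AUROC is invariant to strictly monotone score transforms", {
  set.seed(31)
  y <- rbinom(50, 1, 0.4)
  p <- runif(50)
  a0 <- compute_metrics(y, p)["AUROC"]
  expect_equal(compute_metrics(y, p^3)["AUROC"], a0)
  expect_equal(compute_metrics(y, exp(5 * p))["AUROC"], a0)
  expect_equal(compute_metrics(y, qlogis(p * 0.98 + 0.01))["AUROC"], a0)
})

test_that("MCC degenerates to zero when a margin is empty", {
  # all predictions positive: TN + FN margin is zero
  expect_equal(unname(compute_metrics(c(1, 0, 1), c(0.9, 0.8, 0.7))["MCC"]),
               0)
})

test_that("rank-based AUROC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  for (i in 1:10) {
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(30), 2)
    expect_equal(unname(compute_metrics(y, p)["AUROC"]),
                 as.numeric(pROC::auc(pROC::roc(
                   y, p, quiet = TRUE, direction = "<",
                   levels = c(0, 1)))))
  }
})

test_that("cross_validate reports one row per fold and finds strong signal", {
  coh <- tiny_cohort(seed = 33, species_effect = 3)
  cv <- suppressWarnings(
    cross_validate(coh$species_view, coh$exposome_view, coh$labels,
                   tiny_config(seed = 12)))
  expect_identical(nrow(cv$per_fold), 4L)
  expect_identical(cv$per_fold$fold, 1:4)
  expect_gt(cv$mean["AUROC"], 0.8)
  expect_true(all(cv$per_fold$MCC >= -1 & cv$per_fold$MCC <= 1))
  # partially labeled input is refused: the harness does its own masking
  labs <- hide_labels(coh, 0.2, seed = 1)
  expect_error(cross_validate(coh$species_view, coh$exposome_view, labs,
                              tiny_config()), "fully labeled")
})

test_that("k sweep keeps folds fixed while graphs change", {
  coh <- tiny_cohort(seed = 34)
  ks <- suppressWarnings(
    k_sensitivity(coh$species_view, coh$exposome_view, coh$labels,
                  tiny_config(seed = 13, joint_epochs = 10L,
                              pretrain_epochs = 10L, max_rounds = 6L),
                  k_values = c(2, 5, 8)))
  expect_identical(nrow(ks$summary), 3L)
  expect_identical(ks$summary$k, c(2, 5, 8))
  for (r in ks$reports)
    expect_identical(r$folds$test_idx, ks$folds$test_idx)
  expect_error(
    k_sensitivity(coh$species_view, coh$exposome_view, coh$labels,
                  tiny_config(), k_values = c(2, 1000)),
    "k values")
})

test_that("feature ablation zeroes columns and covers every feature", {
  coh <- tiny_cohort(seed = 35, species_effect = 3)
  # plant an all-zero species column: its importance must be exactly 0
  Xs <- coh$species_view$X
  Xs[, 5] <- 0
  sp <- omics_view(Xs, "species")
  cv <- suppressWarnings(
    cross_validate(sp, coh$exposome_view, coh$labels,
                   tiny_config(seed = 14), keep_fits = TRUE))
  imp <- feature_ablation_importance(cv, coh$labels)
  expect_identical(nrow(imp), ncol(Xs) + ncol(coh$exposome_view$X))
  zero_row <- imp[imp$feature_id == coh$species_view$feature_ids[5], ]
  expect_identical(zero_row$delta_F1, 0)
  # descending order
  expect_true(all(diff(imp$delta_F1) <= 0))
  # needs kept fits
  cv2 <- suppressWarnings(
    cross_validate(sp, coh$exposome_view, coh$labels,
                   tiny_config(seed = 14)))
  expect_error(feature_ablation_importance(cv2, coh$labels), "keep_fits")
})
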