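#' Stratified k-fold plan
#'
#' Partitions the samples into `n_folds` test sets with per-fold class
#' counts within one of proportional stratification, deterministically under
#' `seed`. Per-class remainders are dealt to the folds with the smallest
#' running totals so that overall fold sizes are as even as possible.
#'
#' @param labels a [cohort_labels()] or 0/1 vector.
#' @param n_folds number of folds (default 4).
#' @param seed integer seed for the within-class shuffles.
#' @return An object of class `fold_plan`: list with `n_folds`, `test_idx`
#'   (list of integer index vectors), `seed`.
#' @export
stratified_kfold <- function(labels, n_folds = 4L, seed = 1L) {
  y <- if (inherits(labels, "cohort_labels")) labels$y else as.integer(labels)
  classes <- sort(unique(y))
  tab <- table(factor(y, levels = classes))
  if (any(tab < n_folds))
    stop("every class needs at least n_folds = ", n_folds, " members",
         call. = FALSE)
  # per-class fold counts: base floor + remainders to the lightest folds
  counts <- matrix(0L, length(classes), n_folds)
  totals <- rep(0L, n_folds)
  for (ci in order(tab, decreasing = TRUE)) {
    nc <- as.integer(tab[ci])
    base <- nc %/% n_folds
    counts[ci, ] <- base
    totals <- totals + base
    for (r in seq_len(nc %% n_folds)) {
      f <- which.min(totals)       # ties -> lowest fold index
      counts[ci, f] <- counts[ci, f] + 1L
      totals[f] <- totals[f] + 1L
    }
  }
  test_idx <- with_seed(seed, {
    out <- rep(list(integer()), n_folds)
    for (ci in seq_along(classes)) {
      idx <- sample(which(y == classes[ci]))
      at <- 0L
      for (f in seq_len(n_folds)) {
        take <- counts[ci, f]
        out[[f]] <- c(out[[f]], idx[seq_len(take) + at])
        at <- at + take
      }
    }
    lapply(out, sort)
  })
  structure(list(n_folds = as.integer(n_folds), test_idx = test_idx,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %d folds, test sizes %s (seed %d)\n", x$n_folds,
              paste(lengths(x$test_idx), collapse = "/"), x$seed))
  invisible(x)
}

#' Binary classification metrics
#'
#' Computes accuracy, F1 (positive class = case), rank-based AUROC
#' (mid-ranks, so tied scores contribute 1/2), sensitivity, specificity and
#' the Matthews correlation coefficient at the given probability threshold.
#' MCC is defined as 0 when any confusion-matrix margin is zero. AUROC is
#' `NA` with a warning when `y_true` holds a single class.
#'
#' @param y_true 0/1 vector of true classes.
#' @param class1_prob predicted case-class probabilities.
#' @param threshold classification threshold on `class1_prob` (default 0.5,
#'   with `>= threshold` predicting case).
#' @return Named numeric vector `ACC`, `F1`, `AUROC`, `Sn`, `Sp`, `MCC`.
#' @export
compute_metrics <- function(y_true, class1_prob, threshold = 0.5) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(class1_prob),
            all(y_true %in% c(0L, 1L)))
  pred <- as.integer(class1_prob >= threshold)
  tp <- sum(pred == 1L & y_true == 1L)
  fp <- sum(pred == 1L & y_true == 0L)
  tn <- sum(pred == 0L & y_true == 0L)
  fn <- sum(pred == 0L & y_true == 1L)
  acc <- (tp + tn) / length(y_true)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  sn <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  sp <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  # margins are small integers: form the product exactly before the root,
  # so a perfect confusion matrix gives exactly 1
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den2 == 0) 0 else (tp * tn - fp * fn) / sqrt(den2)
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUROC undefined: y_true holds a single class", call. = FALSE)
    auroc <- NA_real_
  } else {
    r <- rank(class1_prob)               # mid-ranks handle ties
    auroc <- (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  c(ACC = acc, F1 = f1, AUROC = auroc, Sn = sn, Sp = sp, MCC = mcc)
}

#' Stratified cross-validation of MOCO-GCN
#'
#' For each fold the model is fitted transductively: the test fold's
#' samples enter both similarity graphs and the co-training unlabeled pool,
#' but their labels are masked before fitting. Metrics are computed on the
#' test fold from the VCDN case-class probability; the report aggregates
#' the per-fold metrics as mean and standard deviation.
#'
#' @param species,exposome the two views ([omics_view()] or matrices) on a
#'   common sample order.
#' @param labels a fully labeled [cohort_labels()] or 0/1 vector.
#' @param config a [mocogcn_config()].
#' @param n_folds number of folds (default 4).
#' @param fold_seed seed for the fold plan (defaults to `config$seed`).
#' @param folds optional pre-built [stratified_kfold()] plan, overriding
#'   `n_folds`/`fold_seed` (used by [k_sensitivity()] to hold folds fixed).
#' @param threshold classification threshold (default 0.5).
#' @param keep_fits retain the per-fold fitted models (needed by
#'   [feature_ablation_importance()]).
#' @return An object of class `cv_report`: `per_fold` (data frame of the six
#'   metrics per fold), `mean`, `sd`, `folds`, `config`, and `fits` when
#'   requested.
#' @export
cross_validate <- function(species, exposome, labels,
                           config = mocogcn_config(), n_folds = 4L,
                           fold_seed = config$seed, folds = NULL,
                           threshold = 0.5, keep_fits = FALSE) {
  Xs <- as_view_matrix(species)
  if (!inherits(labels, "cohort_labels")) {
    ids <- rownames(Xs) %||% paste0("sample", seq_len(nrow(Xs)))
    labels <- cohort_labels(ids, labels)
  }
  if (!all(labels$labeled_mask))
    stop("cross_validate needs fully labeled data; the harness masks test ",
         "folds itself", call. = FALSE)
  if (is.null(folds))
    folds <- stratified_kfold(labels, n_folds, fold_seed)
  per_fold <- NULL
  fits <- if (keep_fits) vector("list", folds$n_folds) else NULL
  for (f in seq_len(folds$n_folds)) {
    test <- folds$test_idx[[f]]
    mask <- rep(TRUE, length(labels$y))
    mask[test] <- FALSE
    fold_labels <- cohort_labels(labels$sample_ids, labels$y, mask)
    fit <- mocogcn(species, exposome, fold_labels, config)
    p1 <- fit$fitted$final[test, 2]
    m <- compute_metrics(labels$y[test], p1, threshold)
    per_fold <- rbind(per_fold, data.frame(fold = f, t(m)))
    if (keep_fits) fits[[f]] <- fit
  }
  metrics <- c("ACC", "F1", "AUROC", "Sn", "Sp", "MCC")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[metrics], na.rm = TRUE),
                 sd = apply(per_fold[metrics], 2, stats::sd, na.rm = TRUE),
                 folds = folds, config = config, threshold = threshold,
                 fits = fits),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d-fold cross-validation (k = %g)\n",
              x$folds$n_folds, x$config$k))
  for (m in names(x$mean))
    cat(sprintf("  %-6s %.3f +/- %.3f\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Sensitivity of the model to the edge parameter k
#'
#' Re-runs [cross_validate()] for each value of `k` with the fold plan,
#' seed and every other setting held fixed, so only the similarity graphs
#' change between runs.
#'
#' @param species,exposome,labels as in [cross_validate()].
#' @param config a [mocogcn_config()]; its `k` entry is overridden per run.
#' @param k_values edge-parameter values to scan (default 2 to 10).
#' @param n_folds,fold_seed,threshold as in [cross_validate()].
#' @return An object of class `k_sweep`: data frame `summary` with one row
#'   per k (mean and sd of the six metrics), plus `folds` and `reports`.
#' @export
k_sensitivity <- function(species, exposome, labels,
                          config = mocogcn_config(), k_values = 2:10,
                          n_folds = 4L, fold_seed = config$seed,
                          threshold = 0.5) {
  Xs <- as_view_matrix(species)
  if (any(k_values < 1 | k_values > nrow(Xs)))
    stop("k values must lie in [1, n]", call. = FALSE)
  lab <- if (inherits(labels, "cohort_labels")) labels else
    cohort_labels(rownames(Xs) %||% paste0("sample", seq_len(nrow(Xs))),
                  labels)
  folds <- stratified_kfold(lab, n_folds, fold_seed)
  reports <- list()
  summ <- NULL
  for (k in k_values) {
    cfg <- config
    cfg$k <- k
    rep_k <- cross_validate(species, exposome, lab, cfg, folds = folds,
                            threshold = threshold)
    reports[[as.character(k)]] <- rep_k
    row <- data.frame(k = k, t(rep_k$mean), t(stats::setNames(
      rep_k$sd, paste0(names(rep_k$sd), "_sd"))))
    summ <- rbind(summ, row)
  }
  structure(list(summary = summ, folds = folds, reports = reports),
            class = "k_sweep")
}

#' @export
print.k_sweep <- function(x, ...) {
  cat("k_sweep:\n")
  print(x$summary[, c("k", "ACC", "F1", "AUROC", "Sn", "Sp", "MCC")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Feature-ablation importance
#'
#' For every feature of both views, sets that feature's column to zero in
#' the inputs fed to the trained per-fold models (graphs fixed, no
#' retraining), recomputes the test-fold F1, and reports the mean drop
#' relative to the unablated F1 across folds. Features are returned in
#' descending order of importance.
#'
#' @param cv a [cross_validate()] report produced with `keep_fits = TRUE`.
#' @param labels the fully labeled [cohort_labels()] used for the CV.
#' @return An object of class `importance_table`: data frame with columns
#'   `view`, `feature_id`, `delta_F1`, sorted by decreasing `delta_F1`.
#' @export
feature_ablation_importance <- function(cv, labels) {
  stopifnot(inherits(cv, "cv_report"))
  if (is.null(cv$fits))
    stop("run cross_validate() with keep_fits = TRUE first", call. = FALSE)
  if (!inherits(labels, "cohort_labels"))
    labels <- cohort_labels(cv$fits[[1]]$sample_ids, labels)
  thr <- cv$threshold
  f1_of <- function(fit, test, Xs, Xe) {
    p <- predict(fit, species = Xs, exposome = Xe)
    unname(compute_metrics(labels$y[test], p$final[test, 2], thr)["F1"])
  }
  feats <- rbind(
    data.frame(view = "species",
               feature_id = colnames(cv$fits[[1]]$X_species),
               j = seq_len(ncol(cv$fits[[1]]$X_species))),
    data.frame(view = "exposome",
               feature_id = colnames(cv$fits[[1]]$X_exposome),
               j = seq_len(ncol(cv$fits[[1]]$X_exposome))))
  drops <- matrix(0, nrow(feats), cv$folds$n_folds)
  for (f in seq_len(cv$folds$n_folds)) {
    fit <- cv$fits[[f]]
    test <- cv$folds$test_idx[[f]]
    base <- f1_of(fit, test, fit$X_species, fit$X_exposome)
    for (r in seq_len(nrow(feats))) {
      Xs <- fit$X_species
      Xe <- fit$X_exposome
      # zero the whole column fed to the network at test time: under the
      # transductive forward pass the graph mixes rows, so zeroing test
      # rows alone would re-import the feature from training neighbours
      if (feats$view[r] == "species") {
        if (all(Xs[, feats$j[r]] == 0)) { drops[r, f] <- 0; next }
        Xs[, feats$j[r]] <- 0
      } else {
        if (all(Xe[, feats$j[r]] == 0)) { drops[r, f] <- 0; next }
        Xe[, feats$j[r]] <- 0
      }
      drops[r, f] <- base - f1_of(fit, test, Xs, Xe)
    }
  }
  out <- data.frame(view = feats$view, feature_id = feats$feature_id,
                    delta_F1 = rowMeans(drops))
  out <- out[order(-out$delta_F1, out$view, out$feature_id), ]
  rownames(out) <- NULL
  structure(out, class = c("importance_table", "data.frame"))
}

#' @export
print.importance_table <- function(x, n = 10L, ...) {
  cat("importance_table (top", min(n, nrow(x)), "of", nrow(x),
      "features by mean test-fold F1 drop):\n")
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a CV report or importance table as TSV
#'
#' @param x a `cv_report`, `k_sweep` or `importance_table`.
#' @param path output path.
#' @export
write_report <- function(x, path) {
  df <- if (inherits(x, "cv_report")) x$per_fold
  else if (inherits(x, "k_sweep")) x$summary
  else as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
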