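#' Generalized fold change between cases and controls
#'
#' A robust effect size: the mean difference between case and control
#' quantiles over a fixed grid (0.05 to 0.95 in steps of 0.05, linear
#' interpolation). Positive values indicate enrichment in cases, negative
#' values enrichment in controls; the measure is antisymmetric in its
#' arguments.
#'
#' @param case_values,control_values non-empty numeric vectors of a single
#'   feature's values in cases and controls.
#' @param probs quantile grid; the default follows the convention used in
#'   metagenomic differential-abundance work.
#' @return A single numeric value.
#' @examples
#' generalized_fold_change(c(1, 2, 3, 4), c(0, 0, 0, 0))
#' @export
generalized_fold_change <- function(case_values, control_values,
                                    probs = seq(0.05, 0.95, by = 0.05)) {
  if (length(case_values) == 0L || length(control_values) == 0L)
    stop("case and control vectors must be non-empty", call. = FALSE)
  if (anyNA(case_values) || anyNA(control_values))
    stop("missing values in input", call. = FALSE)
  mean(stats::quantile(case_values, probs, names = FALSE, type = 7) -
         stats::quantile(control_values, probs, names = FALSE, type = 7))
}

#' Wilcoxon rank-sum differential-abundance feature selection
#'
#' Tests each feature for a case/control location difference with the
#' two-sided Wilcoxon rank-sum test ([stats::wilcox.test()]) and retains
#' features with raw (unadjusted) p-value strictly below `alpha`. The
#' generalized fold change is reported per feature as the effect direction
#' (positive = case-enriched).
#'
#' @param view an [omics_view()] (or numeric matrix).
#' @param labels a [cohort_labels()]; only samples with `labeled_mask` TRUE
#'   contribute to the test.
#' @param alpha retention threshold on the raw p-value, in (0, 1].
#' @return A list of class `selection_result` with fields
#'   `retained_feature_ids`, `p_value` (named numeric), `gfc` (named
#'   numeric), `alpha`.
#' @export
wilcoxon_select <- function(view, labels, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  X <- as_view_matrix(view)
  ids <- if (inherits(view, "omics_view")) view$feature_ids else
    colnames(X) %||% paste0("feature", seq_len(ncol(X)))
  stopifnot(inherits(labels, "cohort_labels"), nrow(X) == length(labels$y))
  use <- labels$labeled_mask
  y <- labels$y[use]
  X <- X[use, , drop = FALSE]
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stop("both classes must be non-empty", call. = FALSE)
  case <- y == 1L
  pv <- vapply(seq_len(ncol(X)), function(j) {
    xj <- X[, j]
    if (all(xj[case] == xj[case][1]) && all(xj == xj[1])) return(1)
    suppressWarnings(
      stats::wilcox.test(xj[case], xj[!case], alternative = "two.sided")$p.value
    )
  }, numeric(1))
  gfc <- vapply(seq_len(ncol(X)), function(j)
    generalized_fold_change(X[case, j], X[!case, j]), numeric(1))
  names(pv) <- names(gfc) <- ids
  structure(list(retained_feature_ids = ids[pv < alpha],
                 p_value = pv, gfc = gfc, alpha = alpha),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d / %d features retained at p < %g\n",
              length(x$retained_feature_ids), length(x$p_value), x$alpha))
  invisible(x)
}

#' Restrict a view to the features retained by selection
#'
#' @param view an [omics_view()].
#' @param selection a `selection_result` from [wilcoxon_select()].
#' @param renormalize if `TRUE`, species rows are re-closed to sum to 1
#'   after subsetting; off by default (abundances are kept as loaded).
#' @return An [omics_view()] with the retained features only.
#' @export
apply_selection <- function(view, selection, renormalize = FALSE) {
  stopifnot(inherits(view, "omics_view"),
            inherits(selection, "selection_result"))
  keep <- view$feature_ids %in% selection$retained_feature_ids
  X <- view$X[, keep, drop = FALSE]
  if (renormalize && view$view_name == "species") {
    rs <- rowSums(X)
    rs[rs == 0] <- 1
    X <- X / rs
  }
  omics_view(X, view$view_name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
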