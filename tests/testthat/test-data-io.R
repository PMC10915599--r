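test_that("write/load round trip is lossless for both views", {
  set.seed(42)
  Xs <- matrix(runif(12), 4, 3,
               dimnames = list(paste0("s", 1:4), paste0("sp", 1:3)))
  Xs <- Xs / rowSums(Xs)
  vs <- omics_view(Xs, "species")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_view(vs, f)
  expect_identical(load_view(f, "species")$X, vs$X)

  Xe <- matrix(rbinom(8, 1, 0.5), 4, 2,
               dimnames = list(paste0("s", 1:4), c("e1", "e2")))
  ve <- omics_view(Xe, "exposome")
  write_view(ve, f)
  back <- load_view(f, "exposome")
  expect_identical(back$X, ve$X)
  expect_identical(back$sample_ids, ve$sample_ids)
})

test_that("loader enforces the view contracts", {
  m <- matrix(c(0, 1, 0.5, 1), 2, 2,
              dimnames = list(c("a", "b"), c("e1", "e2")))
  expect_error(omics_view(m, "exposome"), "non-binary")
  m2 <- m
  m2[1, 2] <- NA
  expect_error(omics_view(m2, "species"), "missing value.*'a'.*'e2'")
  expect_error(omics_view(matrix(1, 2, 2,
                                 dimnames = list(c("a", "a"), c("x", "y"))),
                          "species"),
               "duplicate sample")
  expect_error(omics_view(matrix(-1, 2, 2), "species"), "negative")
  expect_error(load_view("does-not-exist.tsv", "species"), "not found")
  # a 0/1 table loads as exposome unchanged
  v <- omics_view(matrix(c(0, 1, 1, 0, 1, 1), 3, 2), "exposome")
  expect_identical(dim(v$X), c(3L, 2L))
})

test_that("align_cohort reorders, drops and errors as specified", {
  mk <- function(ids) omics_view(
    matrix(seq_along(ids) * 1.0, length(ids), 1,
           dimnames = list(ids, "f")), "species")
  lab <- cohort_labels(c("a", "b", "c"), c(0, 1, 1))
  # identical sets, shuffled order: reordered, nothing dropped
  out <- align_cohort(mk(c("a", "b", "c")), mk(c("c", "a", "b")), lab)
  expect_identical(out$view_a$sample_ids, out$view_b$sample_ids)
  expect_identical(out$n_dropped, 0L)
  # partial overlap: intersection kept, drops counted
  lab2 <- cohort_labels(c("b", "c", "d"), c(0, 1, 1))
  expect_message(out2 <- align_cohort(mk(c("a", "b", "c")),
                                      mk(c("b", "c", "d")), lab2),
                 "dropped")
  expect_identical(out2$view_a$sample_ids, c("b", "c"))
  expect_identical(out2$labels$y, c(0L, 1L))
  # disjoint: error
  expect_error(align_cohort(mk(c("a", "b")), mk(c("x", "y")),
                            cohort_labels(c("x", "y"), c(0, 1))),
               "no samples shared")
})

test_that("wilcoxon_select retains shifted features and matches a rank-sum oracle", {
  set.seed(7)
  n <- 25
  X <- matrix(rnorm(2 * n * 10), 2 * n, 10,
              dimnames = list(sprintf("s%02d", 1:(2 * n)),
                              sprintf("f%02d", 1:10)))
  X[1:n, 1] <- X[1:n, 1] + 3        # cases shifted 3 SD on feature 1
  X <- X - min(X)                   # keep abundances non-negative
  lab <- cohort_labels(rownames(X), rep(c(1, 0), each = n))
  sel <- wilcoxon_select(omics_view(X, "species"), lab, alpha = 0.05)
  expect_true("f01" %in% sel$retained_feature_ids)
  expect_gt(sel$gfc["f01"], 0)
  # independent normal-approximation oracle agrees away from the boundary
  p_oracle <- vapply(1:10, function(j)
    oracle_ranksum_p(X[1:n, j], X[(n + 1):(2 * n), j]), numeric(1))
  clear <- abs(p_oracle - 0.05) > 0.02
  expect_identical(unname(sel$p_value[clear] < 0.05),
                   p_oracle[clear] < 0.05)
  expect_lt(max(abs(sel$p_value - p_oracle)), 0.02)
})

test_that("wilcoxon_select honours alpha and degenerate features", {
  X <- cbind(const = rep(1, 20), noise = c(rnorm(20)) + 5)
  rownames(X) <- sprintf("s%02d", 1:20)
  lab <- cohort_labels(rownames(X), rep(c(1, 0), 10))
  sel <- wilcoxon_select(omics_view(X, "species"), lab, alpha = 0.05)
  expect_identical(unname(sel$p_value["const"]), 1)
  expect_false("const" %in% sel$retained_feature_ids)
  # alpha = 1 retains exactly the features with p < 1
  sel1 <- wilcoxon_select(omics_view(X, "species"), lab, alpha = 1)
  expect_identical(sel1$retained_feature_ids,
                   names(sel1$p_value)[sel1$p_value < 1])
  # a one-class labeled pool is rejected upstream by the constructor
  expect_error(cohort_labels(rownames(X), rep(c(1, 0), 10),
                             labeled_mask = rep(c(TRUE, FALSE), 10)),
               "both classes")
})

test_that("wilcoxon_select is feature-permutation equivariant and sample-order invariant", {
  set.seed(11)
  X <- matrix(rexp(40 * 8), 40, 8,
              dimnames = list(sprintf("s%02d", 1:40), sprintf("f%d", 1:8)))
  lab <- cohort_labels(rownames(X), rep(c(1, 0), 20))
  sel <- wilcoxon_select(omics_view(X, "species"), lab, 0.1)
  perm <- sample(8)
  sel_p <- wilcoxon_select(omics_view(X[, perm], "species"), lab, 0.1)
  expect_equal(sel_p$p_value, sel$p_value[perm])
  sperm <- sample(40)
  sel_s <- wilcoxon_select(
    omics_view(X[sperm, ], "species"),
    cohort_labels(rownames(X)[sperm], lab$y[sperm]), 0.1)
  expect_equal(sel_s$p_value, sel$p_value)
})

test_that("null data yields a false-positive rate near alpha", {
  set.seed(3)
  d <- 2000
  X <- matrix(rexp(50 * d), 50, d,
              dimnames = list(sprintf("s%02d", 1:50), sprintf("f%04d", 1:d)))
  lab <- cohort_labels(rownames(X), rep(c(1, 0), 25))
  sel <- wilcoxon_select(omics_view(X, "species"), lab, 0.05)
  rate <- length(sel$retained_feature_ids) / d
  half_width <- 2.576 * sqrt(0.05 * 0.95 / d)
  expect_lt(rate, 0.05 + half_width)
  expect_gt(rate, 0.05 - half_width)
})

test_that("generalized fold change follows quantile arithmetic", {
  set.seed(5)
  v <- rexp(30)
  expect_identical(generalized_fold_change(v, v), 0)
  delta <- 1.7
  expect_equal(generalized_fold_change(v + delta, v), delta)
  # brute-force quantile oracle on the stated grid
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_equal(generalized_fold_change(c(1, 2, 3, 4), c(0, 0, 0, 0)),
               mean(stats::quantile(c(1, 2, 3, 4), grid, names = FALSE)))
  # antisymmetry over random draws
  for (i in 1:20) {
    a <- rexp(sample(3:30, 1))
    b <- rexp(sample(3:30, 1))
    expect_equal(generalized_fold_change(a, b),
                 -generalized_fold_change(b, a))
  }
  expect_error(generalized_fold_change(numeric(), v), "non-empty")
})

test_that("apply_selection subsets features and can renormalize", {
  coh <- tiny_cohort(seed = 2)
  sel <- wilcoxon_select(coh$species_view, coh$labels, 0.05)
  sub <- apply_selection(coh$species_view, sel)
  expect_identical(sub$feature_ids, sel$retained_feature_ids)
  sub_rn <- apply_selection(coh$species_view, sel, renormalize = TRUE)
  expect_equal(unname(rowSums(sub_rn$X)), rep(1, nrow(sub_rn$X)))
})

test_that("labels round-trip through their text format", {
  lab <- cohort_labels(c("a", "b", "c"), c(1, 0, 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_labels(lab, f)
  back <- load_labels(f)
  expect_identical(back$y, lab$y)
  expect_identical(back$sample_ids, lab$sample_ids)
})
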