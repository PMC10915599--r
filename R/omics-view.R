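#' Construct a single-view sample-by-feature table
#'
#' An `omics_view` wraps one view's numeric matrix together with ordered
#' sample and feature identifiers. Two views are supported: `"species"`
#' (non-negative relative abundances) and `"exposome"` (binary 0/1 host
#' variables). Validation rejects missing values, duplicate identifiers,
#' negative abundances and non-binary exposome entries.
#'
#' @param X numeric matrix, rows = samples, columns = features. Dimnames are
#'   used as identifiers when `sample_ids`/`feature_ids` are not given.
#' @param view_name `"species"` or `"exposome"`.
#' @param sample_ids,feature_ids optional character identifiers overriding
#'   the dimnames of `X`.
#' @return An object of class `omics_view` with fields `X`, `view_name`,
#'   `sample_ids`, `feature_ids`.
#' @examples
#' v <- omics_view(matrix(c(0, 1, 1, 0, 1, 1), 3, 2,
#'                        dimnames = list(paste0("s", 1:3), c("e1", "e2"))),
#'                 "exposome")
#' dim(v$X)
#' @export
omics_view <- function(X, view_name = c("species", "exposome"),
                       sample_ids = NULL, feature_ids = NULL) {
  view_name <- match.arg(view_name)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(sample_ids)) sample_ids <- rownames(X)
  if (is.null(feature_ids)) feature_ids <- colnames(X)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(X)))
  if (is.null(feature_ids)) feature_ids <- paste0("feature", seq_len(ncol(X)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(X))
    stop("length of sample_ids does not match nrow(X)", call. = FALSE)
  if (length(feature_ids) != ncol(X))
    stop("length of feature_ids does not match ncol(X)", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifiers: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop("missing value at sample '", sample_ids[idx[1]], "', feature '",
         feature_ids[idx[2]], "'; impute metadata upstream before loading ",
         "(imputation is not performed here)", call. = FALSE)
  }
  if (view_name == "species" && any(X < 0)) {
    idx <- which(X < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance at sample '", sample_ids[idx[1]],
         "', feature '", feature_ids[idx[2]], "'", call. = FALSE)
  }
  if (view_name == "exposome" && !all(X %in% c(0, 1))) {
    idx <- which(!(X %in% c(0, 1)))[1]
    rc <- arrayInd(idx, dim(X))
    stop("non-binary exposome entry ", X[idx], " at sample '",
         sample_ids[rc[1]], "', feature '", feature_ids[rc[2]],
         "'; exposome values must be 0/1", call. = FALSE)
  }
  dimnames(X) <- list(sample_ids, feature_ids)
  structure(list(X = X, view_name = view_name, sample_ids = sample_ids,
                 feature_ids = feature_ids),
            class = "omics_view")
}

#' @export
print.omics_view <- function(x, ...) {
  cat(sprintf("omics_view '%s': %d samples x %d features\n",
              x$view_name, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' @export
dim.omics_view <- function(x) dim(x$X)

as_view_matrix <- function(x) {
  if (inherits(x, "omics_view")) x$X else as.matrix(x)
}

#' Construct per-sample class labels with a visibility mask
#'
#' @param sample_ids character identifiers, one per sample.
#' @param y integer class per sample, 0 = control, 1 = case.
#' @param labeled_mask logical; `TRUE` where the label is visible to
#'   training. Defaults to all visible.
#' @return An object of class `cohort_labels`.
#' @export
cohort_labels <- function(sample_ids, y, labeled_mask = NULL) {
  sample_ids <- as.character(sample_ids)
  y <- as.integer(y)
  if (is.null(labeled_mask)) labeled_mask <- rep(TRUE, length(y))
  labeled_mask <- as.logical(labeled_mask)
  if (length(y) != length(sample_ids) ||
      length(labeled_mask) != length(sample_ids))
    stop("sample_ids, y and labeled_mask must have equal length", call. = FALSE)
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("labels must be 0 (control) or 1 (case) for every sample",
         call. = FALSE)
  if (anyNA(labeled_mask))
    stop("labeled_mask must be TRUE/FALSE for every sample", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in labels", call. = FALSE)
  if (any(labeled_mask) && length(unique(y[labeled_mask])) < 2L)
    stop("both classes must be present among labeled samples", call. = FALSE)
  structure(list(sample_ids = sample_ids, y = y, labeled_mask = labeled_mask),
            class = "cohort_labels")
}

#' @export
print.cohort_labels <- function(x, ...) {
  cat(sprintf("cohort_labels: %d samples (%d case / %d control), %d labeled\n",
              length(x$y), sum(x$y == 1L), sum(x$y == 0L),
              sum(x$labeled_mask)))
  invisible(x)
}

#' Read one view from a delimited text file
#'
#' Expects a header row of feature identifiers, a first column named
#' `sample_id` holding sample identifiers, and numeric entries. Exposome
#' tables must contain only 0/1 values.
#'
#' @param path file path.
#' @param view_name `"species"` or `"exposome"`.
#' @param delimiter field separator, tab by default (use `","` for CSV).
#' @return An [omics_view()].
#' @export
load_view <- function(path, view_name = c("species", "exposome"),
                      delimiter = "\t") {
  view_name <- match.arg(view_name)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L)
    stop("expected a sample_id column plus at least one feature column",
         call. = FALSE)
  ids <- df[[1L]]
  M <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(M) <- "double")
  rownames(M) <- ids
  omics_view(M, view_name)
}

#' Write one view as delimited text
#'
#' Emits the same dialect [load_view()] reads; numeric values are printed
#' with 17 significant digits so a write/load round trip is lossless.
#'
#' @param view an [omics_view()].
#' @param path output file path.
#' @param delimiter field separator, tab by default.
#' @export
write_view <- function(view, path, delimiter = "\t") {
  stopifnot(inherits(view, "omics_view"))
  Xc <- matrix(sprintf("%.17g", view$X), nrow(view$X))
  df <- data.frame(sample_id = view$sample_ids, Xc, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("sample_id", view$feature_ids)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample_id/label file
#'
#' @param path file path to a delimited table with columns `sample_id` and
#'   `label` (0/1).
#' @param delimiter field separator, tab by default.
#' @return A [cohort_labels()] with all samples marked labeled.
#' @export
load_labels <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE)
  cohort_labels(df[[1L]], df[[2L]])
}

#' Write labels as delimited text
#'
#' @param labels a [cohort_labels()].
#' @param path output file path.
#' @param delimiter field separator, tab by default.
#' @export
write_labels <- function(labels, path, delimiter = "\t") {
  stopifnot(inherits(labels, "cohort_labels"))
  df <- data.frame(sample_id = labels$sample_ids, label = labels$y)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align two views and labels on their common samples
#'
#' Restricts both views and the labels to the intersection of their sample
#' identifiers, in a single common order (the order of the intersection as
#' it appears in `view_a`). The number of dropped samples is reported via
#' [message()].
#'
#' @param view_a,view_b two [omics_view()] objects (typically species and
#'   exposome).
#' @param labels a [cohort_labels()].
#' @return A list with fields `view_a`, `view_b`, `labels`, `n_dropped`.
#' @export
align_cohort <- function(view_a, view_b, labels) {
  stopifnot(inherits(view_a, "omics_view"), inherits(view_b, "omics_view"),
            inherits(labels, "cohort_labels"))
  common <- intersect(intersect(view_a$sample_ids, view_b$sample_ids),
                      labels$sample_ids)
  if (length(common) == 0L)
    stop("no samples shared between the views and labels", call. = FALSE)
  common <- view_a$sample_ids[view_a$sample_ids %in% common]
  n_drop <- (length(view_a$sample_ids) - length(common)) +
    (length(view_b$sample_ids) - length(common)) +
    (length(labels$sample_ids) - length(common))
  if (n_drop > 0L)
    message(n_drop, " sample entries dropped during alignment")
  ia <- match(common, view_a$sample_ids)
  ib <- match(common, view_b$sample_ids)
  il <- match(common, labels$sample_ids)
  list(
    view_a = omics_view(view_a$X[ia, , drop = FALSE], view_a$view_name),
    view_b = omics_view(view_b$X[ib, , drop = FALSE], view_b$view_name),
    labels = cohort_labels(common, labels$y[il], labels$labeled_mask[il]),
    n_dropped = n_drop
  )
}
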