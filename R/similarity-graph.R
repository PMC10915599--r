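#' Cosine similarity between all sample pairs
#'
#' `S[i, j] = <x_i, x_j> / (||x_i|| ||x_j||)` over the rows of `X`. The
#' diagonal is exactly 1. All-zero rows have undefined similarity and are
#' rejected.
#'
#' @param X sample-by-feature numeric matrix (or [omics_view()]).
#' @return Symmetric n-by-n similarity matrix.
#' @export
cosine_similarity_matrix <- function(X) {
  X <- as_view_matrix(X)
  if (nrow(X) < 2L) stop("need at least two samples", call. = FALSE)
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) {
    bad <- rownames(X)[which(nrm == 0)[1]] %||% which(nrm == 0)[1]
    stop("all-zero feature vector for sample '", bad,
         "': cosine similarity undefined", call. = FALSE)
  }
  S <- tcrossprod(X / nrm)
  S <- (S + t(S)) / 2    # enforce exact symmetry against rounding
  diag(S) <- 1
  S
}

#' Edge-retention threshold from the average-edges-per-node parameter k
#'
#' The threshold `epsilon` is the largest similarity value such that the
#' average number of retained pairs per node is at least `k`, where each
#' node's own self-similarity (always 1) counts as one retained pair. Hence
#' `k = 1` retains no off-diagonal edge at all (the graph degenerates to
#' isolated nodes and the GCN to a plain feed-forward network), and `k = n`
#' keeps the complete graph. Ties at `epsilon` are all retained.
#'
#' @param S symmetric similarity matrix from [cosine_similarity_matrix()].
#' @param k target average retained edges per node (self included), a real
#'   number in `[1, n]`.
#' @return The threshold `epsilon`. For `k = 1` the value returned is
#'   strictly above the largest off-diagonal similarity.
#' @export
threshold_from_k <- function(S, k) {
  n <- nrow(S)
  if (k < 1 || k > n)
    stop("k must lie in [1, n]; got k = ", k, " with n = ", n, call. = FALSE)
  off <- S[row(S) != col(S)]
  # need ceiling((k - 1) * n) off-diagonal entries (both directions) >= epsilon
  need <- ceiling((k - 1) * n - 1e-9)
  if (need <= 0L) return(max(off) + 1)
  sort(off, decreasing = TRUE)[min(need, length(off))]
}

#' Thresholded weighted adjacency
#'
#' Keeps `S[i, j]` as the edge weight wherever `i != j` and
#' `S[i, j] >= epsilon`; all other entries (including the diagonal) are 0.
#'
#' @param S symmetric similarity matrix.
#' @param epsilon retention threshold.
#' @return Weighted adjacency matrix `A` with zero diagonal.
#' @export
build_adjacency <- function(S, epsilon) {
  A <- ifelse(S >= epsilon, S, 0)
  diag(A) <- 0
  A
}

#' Symmetric normalization of the adjacency with self-loops
#'
#' Returns `D^{-1/2} (A + I) D^{-1/2}` where `D` is the diagonal degree
#' matrix of `A + I`. Adding the identity before computing degrees keeps the
#' operator defined for isolated nodes: with no edges at all the operator is
#' exactly the identity, which is what makes the k = 1 degeneracy to a plain
#' feed-forward network possible.
#'
#' @param A symmetric weighted adjacency with zero diagonal and non-negative
#'   weights.
#' @return The normalized propagation operator, symmetric with spectrum in
#'   `[-1, 1]`.
#' @export
normalize_adjacency <- function(A) {
  if (any(A < 0)) stop("negative edge weights are not allowed", call. = FALSE)
  if (any(abs(A - t(A)) > 1e-8)) stop("A must be symmetric", call. = FALSE)
  AI <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(AI))
  AI * tcrossprod(dinv)
}

#' Build a per-view sample-similarity graph
#'
#' Convenience constructor running [cosine_similarity_matrix()],
#' [threshold_from_k()], [build_adjacency()] and [normalize_adjacency()] in
#' sequence.
#'
#' @param X sample-by-feature matrix or [omics_view()].
#' @param k average retained edges per node (self included); see
#'   [threshold_from_k()].
#' @param zscore if `TRUE`, features are standardized (mean 0, sd 1;
#'   constant features left at 0) before the cosine similarity. Off by
#'   default: species abundances and binary exposures are used as loaded.
#' @param zero_rows how to treat samples whose feature vector is all zero
#'   (e.g. a subject with none of the recorded exposures): `"isolate"`
#'   (default) gives them similarity 0 to every other sample, so they become
#'   isolated nodes; `"error"` forwards the [cosine_similarity_matrix()]
#'   error.
#' @return An object of class `similarity_graph` with fields `S`, `epsilon`,
#'   `k`, `A`, `A_hat`, `sample_ids`, `n_edges` (undirected count).
#' @export
similarity_graph <- function(X, k, zscore = FALSE,
                             zero_rows = c("isolate", "error")) {
  zero_rows <- match.arg(zero_rows)
  ids <- if (inherits(X, "omics_view")) X$sample_ids else rownames(as.matrix(X))
  X <- as_view_matrix(X)
  if (zscore) {
    sds <- apply(X, 2, stats::sd)
    sds[sds == 0] <- 1
    X <- scale(X, center = TRUE, scale = sds)
  }
  nrm <- sqrt(rowSums(X^2))
  if (zero_rows == "isolate" && any(nrm == 0)) {
    Xn <- X / ifelse(nrm == 0, 1, nrm)
    S <- tcrossprod(Xn)
    S <- (S + t(S)) / 2
    diag(S) <- 1
  } else {
    S <- cosine_similarity_matrix(X)
  }
  epsilon <- threshold_from_k(S, k)
  A <- build_adjacency(S, epsilon)
  structure(list(S = S, epsilon = epsilon, k = k, A = A,
                 A_hat = normalize_adjacency(A),
                 sample_ids = ids %||% paste0("sample", seq_len(nrow(S))),
                 n_edges = sum(A > 0) / 2),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf(
    "similarity_graph: %d nodes, %d edges (k = %g, epsilon = %.4f)\n",
    nrow(x$S), x$n_edges, x$k, x$epsilon))
  invisible(x)
}

#' Export a graph's edges as a three-column table
#'
#' @param graph a `similarity_graph`.
#' @param path optional TSV output path; when `NULL` the data frame is only
#'   returned.
#' @return Data frame with columns `node_i`, `node_j`, `weight`, one row per
#'   undirected edge.
#' @export
export_edgelist <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "similarity_graph"))
  idx <- which(upper.tri(graph$A) & graph$A > 0, arr.ind = TRUE)
  df <- data.frame(node_i = graph$sample_ids[idx[, 1]],
                   node_j = graph$sample_ids[idx[, 2]],
                   weight = graph$A[idx])
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
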