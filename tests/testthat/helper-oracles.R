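# Independent oracles used to check the implementation. These deliberately
# use naive loops / exhaustive search, not the package's code paths.

# Exhaustive threshold search: every off-diagonal value (plus one value
# above the maximum, for the edgeless case) is a candidate; feasibility
# counts the self-pair, so k = 1 is satisfied by the edgeless threshold.
oracle_threshold <- function(S, k) {
  n <- nrow(S)
  off <- S[row(S) != col(S)]
  cands <- c(max(off) + 1, sort(unique(off), decreasing = TRUE))
  for (eps in cands) {
    cnt <- mean(vapply(seq_len(n), function(i)
      1L + sum(S[i, -i] >= eps), integer(1)))
    if (cnt >= k - 1e-12) return(eps)
  }
  stop("no feasible threshold")
}

oracle_adjacency <- function(S, eps) {
  n <- nrow(S)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && S[i, j] >= eps) A[i, j] <- S[i, j]
  A
}

# Confusion-matrix / all-pairs rank oracle for the six metrics.
oracle_metrics <- function(y, p, thr = 0.5) {
  pred <- ifelse(p >= thr, 1L, 0L)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(y)) {
    if (y[i] == 1L && pred[i] == 1L) tp <- tp + 1L
    if (y[i] == 0L && pred[i] == 1L) fp <- fp + 1L
    if (y[i] == 0L && pred[i] == 0L) tn <- tn + 1L
    if (y[i] == 1L && pred[i] == 0L) fn <- fn + 1L
  }
  acc <- (tp + tn) / length(y)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + (p[i] > p[j]) + 0.5 * (p[i] == p[j])
  c(ACC = acc, F1 = f1, AUROC = s / (length(pos) * length(neg)),
    Sn = sn, Sp = sp, MCC = mcc)
}

# Two-sided rank-sum test, normal approximation with tie correction and
# continuity correction (independent of stats::wilcox.test).
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- (abs(W - mu) - 0.5) / sqrt(sig2)
  2 * stats::pnorm(-z)
}

oracle_outer4 <- function(ye, ys) {
  out <- numeric(4)
  pos <- 1L
  for (a in 1:2) for (b in 1:2) {
    out[pos] <- ye[a] * ys[b]
    pos <- pos + 1L
  }
  out
}

oracle_mean_ce <- function(P, idx, y01) {
  tot <- 0
  for (t in seq_along(idx))
    tot <- tot - log(P[idx[t], y01[t] + 1L])
  tot / length(idx)
}
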