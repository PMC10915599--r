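# Numerical core shared by the per-view GCNs and the VCDN head: activations,
# softmax cross-entropy, manual backpropagation and the Adam update. The
# cohort fits in memory, so everything is full-batch dense matrix algebra.

lrelu <- function(Z, slope) {
  pos <- Z > 0
  Z * (pos + slope * !pos)
}
lrelu_grad <- function(Z, slope) {
  pos <- Z > 0
  pos + slope * !pos
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)      # shift for numerical stability
  E <- exp(Z)
  E / rowSums(E)
}

# d(loss)/d(logits) given d(loss)/d(probs), through the softmax Jacobian
softmax_backprop <- function(P, dP) P * (dP - rowSums(dP * P))

# Mean cross-entropy of probability rows P[idx, ] against labels y01 in {0,1}
cross_entropy <- function(P, idx, y01) {
  p_true <- P[cbind(idx, y01 + 1L)]
  -mean(log(pmax(p_true, 1e-12)))
}

# Gradient of mean cross-entropy w.r.t. logits: (P - onehot)/m on idx rows
ce_logit_grad <- function(P, idx, y01) {
  G <- matrix(0, nrow(P), ncol(P))
  G[idx, ] <- P[idx, , drop = FALSE] / length(idx)
  G[cbind(idx, y01 + 1L)] <- G[cbind(idx, y01 + 1L)] - 1 / length(idx)
  G
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Evaluate a function with a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

glorot <- function(d_in, d_out) {
  lim <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out)
}

#' Initialize a per-view graph convolutional network
#'
#' Creates the stack of layer weight matrices `W(l)` mapping the view's
#' input dimension through the hidden sizes to the 2 class logits. Weights
#' are Glorot-uniform, reproducible from `seed`. The layer map itself has no
#' bias term; each layer computes `sigma(A_hat %*% H %*% W)`.
#'
#' @param d_in number of input features of the view.
#' @param hidden_dims integer vector of hidden layer widths; `c(64, 32)` by
#'   default, and an empty vector gives a single linear layer `d_in -> 2`.
#' @param seed integer seed for the initialization.
#' @param view_name label carried for reporting.
#' @param lrelu_slope negative-side slope of the leaky-rectifier activation.
#' @param dropout dropout probability applied to hidden activations during
#'   training (0 disables).
#' @return An object of class `view_gcn` with fields `W` (list of weight
#'   matrices), `dims`, `view_name`, `lrelu_slope`, `dropout`.
#' @export
init_view_gcn <- function(d_in, hidden_dims = c(64L, 32L), seed = 1L,
                          view_name = "species", lrelu_slope = 0.25,
                          dropout = 0.5) {
  stopifnot(d_in >= 1, all(hidden_dims >= 1))
  dims <- as.integer(c(d_in, hidden_dims, 2L))
  W <- with_seed(seed, lapply(seq_len(length(dims) - 1L), function(l)
    glorot(dims[l], dims[l + 1L])))
  structure(list(W = W, dims = dims, view_name = view_name,
                 lrelu_slope = lrelu_slope, dropout = dropout),
            class = "view_gcn")
}

#' @export
print.view_gcn <- function(x, ...) {
  cat(sprintf("view_gcn '%s': layers %s\n", x$view_name,
              paste(x$dims, collapse = " -> ")))
  invisible(x)
}

#' One graph-convolution layer
#'
#' Computes `sigma(A_hat %*% H %*% W)`.
#'
#' @param H n-by-d_in input activations.
#' @param A_hat normalized propagation operator from
#'   [normalize_adjacency()].
#' @param W d_in-by-d_out weight matrix.
#' @param sigma activation function applied elementwise (default identity).
#' @return n-by-d_out output activations.
#' @export
gcn_layer_forward <- function(H, A_hat, W, sigma = identity) {
  H <- as.matrix(H)
  if (ncol(H) != nrow(W))
    stop("dimension mismatch: H has ", ncol(H), " columns but W has ",
         nrow(W), " rows", call. = FALSE)
  if (nrow(A_hat) != nrow(H))
    stop("dimension mismatch between A_hat and H", call. = FALSE)
  sigma(A_hat %*% H %*% W)
}

# Full forward pass with caches for backprop. Dropout masks are drawn from
# the current RNG stream when training && dropout > 0.
gcn_forward_cache <- function(X, A_hat, model, training = FALSE) {
  L <- length(model$W)
  H <- X
  AH <- vector("list", L)   # A_hat %*% H_{l-1}, needed for dW
  Z <- vector("list", L)    # pre-activations
  M <- vector("list", L)    # dropout masks on hidden outputs
  p <- if (training) model$dropout else 0
  for (l in seq_len(L)) {
    AH[[l]] <- A_hat %*% H
    Z[[l]] <- AH[[l]] %*% model$W[[l]]
    if (l < L) {
      H <- lrelu(Z[[l]], model$lrelu_slope)
      if (p > 0) {
        M[[l]] <- matrix(stats::rbinom(length(H), 1L, 1 - p) / (1 - p),
                         nrow(H), ncol(H))
        H <- H * M[[l]]
      }
    } else H <- Z[[l]]
  }
  logits <- H
  list(logits = logits, probs = softmax_rows(logits), AH = AH, Z = Z, M = M,
       training = training)
}

# Backward pass: given d(loss)/d(logits), returns gradients for each W.
gcn_backward <- function(cache, model, A_hat, dlogits) {
  L <- length(model$W)
  grads <- vector("list", L)
  dZ <- dlogits
  for (l in rev(seq_len(L))) {
    grads[[l]] <- crossprod(cache$AH[[l]], dZ)
    if (l > 1L) {
      dH <- A_hat %*% (dZ %*% t(model$W[[l]]))  # A_hat symmetric
      if (!is.null(cache$M[[l - 1L]])) dH <- dH * cache$M[[l - 1L]]
      dZ <- dH * lrelu_grad(cache$Z[[l - 1L]], model$lrelu_slope)
    }
  }
  grads
}

#' Per-view forward pass to a class distribution
#'
#' Stacks the model's graph-convolution layers over the view's normalized
#' similarity graph (leaky-rectifier activations between layers, linear last
#' layer) and maps the two class scores through a normalized exponential, so
#' every row is a probability pair over control/case.
#'
#' @param view an [omics_view()] or numeric matrix.
#' @param graph a [similarity_graph()] built on the same samples, in the
#'   same order.
#' @param model a [init_view_gcn()] network whose input width matches the
#'   view.
#' @return n-by-2 matrix of class probabilities (columns: control, case).
#' @export
gcn_forward <- function(view, graph, model) {
  X <- as_view_matrix(view)
  stopifnot(inherits(graph, "similarity_graph"), inherits(model, "view_gcn"))
  if (inherits(view, "omics_view") &&
      !identical(view$sample_ids, graph$sample_ids))
    stop("sample order mismatch between view and graph", call. = FALSE)
  if (nrow(X) != nrow(graph$A_hat))
    stop("sample count mismatch between view and graph", call. = FALSE)
  if (ncol(X) != model$dims[1])
    stop("view has ", ncol(X), " features but model expects ",
         model$dims[1], call. = FALSE)
  gcn_forward_cache(X, graph$A_hat, model, training = FALSE)$probs
}

# Plain feed-forward pathway (no graph propagation): the degenerate form the
# GCN reduces to when the graph has no edges.
dense_forward <- function(X, model) {
  L <- length(model$W)
  H <- X
  for (l in seq_len(L)) {
    H <- H %*% model$W[[l]]
    if (l < L) H <- lrelu(H, model$lrelu_slope)
  }
  softmax_rows(H)
}

# One supervised training run of a single view (full-batch Adam on the mean
# cross-entropy over `idx` with labels `y01`). Continues from the passed
# weights and optimizer state. Returns updated model/state and the loss.
fit_view_gcn <- function(X, A_hat, model, idx, y01, epochs, lr,
                         opt_state = NULL, weight_decay = 0) {
  if (is.null(opt_state)) opt_state <- adam_init(model$W)
  loss <- NA_real_
  for (e in seq_len(epochs)) {
    cache <- gcn_forward_cache(X, A_hat, model, training = TRUE)
    loss <- cross_entropy(cache$probs, idx, y01)
    if (!is.finite(loss))
      stop("training diverged: non-finite loss in view '",
           model$view_name, "'", call. = FALSE)
    dlogits <- ce_logit_grad(cache$probs, idx, y01)
    grads <- gcn_backward(cache, model, A_hat, dlogits)
    if (weight_decay > 0)
      grads <- Map(function(g, w) g + weight_decay * w, grads, model$W)
    upd <- adam_step(model$W, grads, opt_state, lr)
    model$W <- upd$params
    opt_state <- upd$state
  }
  list(model = model, opt_state = opt_state, loss = loss)
}
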