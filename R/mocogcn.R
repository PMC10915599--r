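#' Configuration for fitting MOCO-GCN
#'
#' Collects every tunable of the model in one list. Defaults: edge parameter
#' `k = 5`; per-view GCN hidden widths 64 and 32 with a final
#' graph-convolution to the 2 class logits; leaky-rectifier slope 0.25;
#' dropout 0.5 on hidden activations during training; VCDN head with one
#' hidden layer of width 8; pseudo-label confidence threshold `tau = 0.8`
#' and per-round proposal budget `m = max(1, ceiling(m_frac * |unlabeled|))`
#' per view with `m_frac = 0.05`; 50 full-batch Adam epochs per co-training
#' round at learning rate 1e-3 (the optimizer state carries across rounds),
#' at most 30 rounds; 100 joint alternating epochs, with the VCDN head on a
#' ten-fold faster learning rate (1e-2 vs 1e-3) because its 4-input network
#' receives far smaller gradients than the view GCNs and must otherwise
#' start from an arbitrary—possibly anti-correlated—map of the cross-view
#' tensor. Short inner fits matter too: long per-round fits memorize the
#' labeled pool, saturate the confidence scores and export unreliable
#' pseudo-labels to the partner view.
#'
#' @param k average retained edges per node (self included) for both graphs.
#' @param hidden_dims hidden layer widths of each view GCN.
#' @param vcdn_hidden hidden width of the VCDN head (0 = single linear map).
#' @param tau pseudo-label confidence threshold in `[0.5, 1]`.
#' @param m_frac fraction of the unlabeled pool each view may pseudo-label
#'   per round.
#' @param pretrain_epochs Adam epochs per co-training round.
#' @param joint_epochs alternating optimization epochs after co-training.
#' @param max_rounds co-training round cap.
#' @param lr_gcn,lr_vcdn Adam learning rates.
#' @param dropout dropout probability on hidden GCN activations (training
#'   only).
#' @param weight_decay L2 penalty coefficient on the view-GCN weights
#'   (default 5e-4, the customary value for graph-convolutional training);
#'   it curbs memorization of the labeled pool, which would otherwise
#'   saturate pseudo-label confidences.
#' @param lrelu_slope negative-side slope of the leaky rectifier.
#' @param zscore standardize features before the cosine similarity.
#' @param seed integer seed controlling all stochastic elements.
#' @return A named list of class `mocogcn_config`.
#' @export
mocogcn_config <- function(k = 5, hidden_dims = c(64L, 32L), vcdn_hidden = 8L,
                           tau = 0.8, m_frac = 0.05, pretrain_epochs = 50L,
                           joint_epochs = 100L, max_rounds = 30L,
                           lr_gcn = 1e-3, lr_vcdn = 1e-2, dropout = 0.5,
                           weight_decay = 5e-4, lrelu_slope = 0.25,
                           zscore = FALSE, seed = 1L) {
  structure(list(k = k, hidden_dims = as.integer(hidden_dims),
                 vcdn_hidden = as.integer(vcdn_hidden), tau = tau,
                 m_frac = m_frac, pretrain_epochs = as.integer(pretrain_epochs),
                 joint_epochs = as.integer(joint_epochs),
                 max_rounds = as.integer(max_rounds), lr_gcn = lr_gcn,
                 lr_vcdn = lr_vcdn, dropout = dropout,
                 weight_decay = weight_decay,
                 lrelu_slope = lrelu_slope, zscore = zscore,
                 seed = as.integer(seed)),
            class = "mocogcn_config")
}

#' Cross-view label-correlation tensor
#'
#' For each sample the 2-by-2 outer product of the exposome-view and
#' species-view class distributions, flattened row-major to a length-4
#' vector: `(e1*s1, e1*s2, e2*s1, e2*s2)`. When both inputs are probability
#' pairs the entries are non-negative and sum to 1.
#'
#' @param y_exp,y_sp either probability pairs (length-2 vectors) or n-by-2
#'   matrices of per-sample distributions.
#' @return A length-4 vector, or an n-by-4 matrix for matrix input.
#' @export
cross_view_tensor <- function(y_exp, y_sp) {
  ve <- is.null(dim(y_exp))
  if (ve) y_exp <- matrix(y_exp, 1L)
  if (is.null(dim(y_sp))) y_sp <- matrix(y_sp, 1L)
  stopifnot(ncol(y_exp) == 2L, ncol(y_sp) == 2L,
            nrow(y_exp) == nrow(y_sp))
  if (any(y_exp < 0) || any(y_sp < 0))
    stop("inputs to the cross-view tensor must be non-negative",
         call. = FALSE)
  C <- cbind(y_exp[, 1] * y_sp[, 1], y_exp[, 1] * y_sp[, 2],
             y_exp[, 2] * y_sp[, 1], y_exp[, 2] * y_sp[, 2])
  if (ve) C[1, ] else C
}

#' Initialize the VCDN head
#'
#' A fully connected network from the flattened 4-entry cross-view tensor
#' to the 2 class logits, with one hidden layer of width `hidden` (0 gives a
#' single linear map). Weights are Glorot-uniform from `seed`; biases start
#' at zero.
#'
#' @param hidden hidden width (default 8).
#' @param seed integer seed.
#' @param lrelu_slope hidden activation slope.
#' @return An object of class `vcdn_head`.
#' @export
init_vcdn <- function(hidden = 8L, seed = 1L, lrelu_slope = 0.25) {
  params <- with_seed(seed, {
    if (hidden > 0L)
      list(W1 = glorot(4L, hidden), b1 = rep(0, hidden),
           W2 = glorot(hidden, 2L), b2 = rep(0, 2L))
    else
      list(W1 = glorot(4L, 2L), b1 = rep(0, 2L))
  })
  structure(list(params = params, hidden = as.integer(hidden),
                 lrelu_slope = lrelu_slope),
            class = "vcdn_head")
}

vcdn_forward_cache <- function(C, head) {
  p <- head$params
  if (head$hidden > 0L) {
    Z1 <- sweep(C %*% p$W1, 2L, p$b1, `+`)
    H1 <- lrelu(Z1, head$lrelu_slope)
    Z2 <- sweep(H1 %*% p$W2, 2L, p$b2, `+`)
    list(probs = softmax_rows(Z2), Z1 = Z1, H1 = H1)
  } else {
    Z1 <- sweep(C %*% p$W1, 2L, p$b1, `+`)
    list(probs = softmax_rows(Z1))
  }
}

# Gradients of the VCDN loss. Returns parameter gradients and the gradient
# with respect to the input tensor C (needed when the GCNs are being
# updated with the head fixed).
vcdn_backward <- function(C, head, cache, dZout) {
  p <- head$params
  if (head$hidden > 0L) {
    dH1 <- dZout %*% t(p$W2)
    dZ1 <- dH1 * lrelu_grad(cache$Z1, head$lrelu_slope)
    list(grads = list(W1 = crossprod(C, dZ1), b1 = colSums(dZ1),
                      W2 = crossprod(cache$H1, dZout), b2 = colSums(dZout)),
         dC = dZ1 %*% t(p$W1))
  } else {
    list(grads = list(W1 = crossprod(C, dZout), b1 = colSums(dZout)),
         dC = dZout %*% t(p$W1))
  }
}

#' Forward pass of the VCDN head
#'
#' @param c_vec a length-4 flattened cross-view tensor, or an n-by-4 matrix
#'   of them.
#' @param head a [init_vcdn()] network.
#' @return A probability pair (or n-by-2 matrix) over control/case.
#' @export
vcdn_forward <- function(c_vec, head) {
  stopifnot(inherits(head, "vcdn_head"))
  vec <- is.null(dim(c_vec))
  C <- if (vec) matrix(c_vec, 1L) else as.matrix(c_vec)
  if (ncol(C) != 4L)
    stop("cross-view tensor input must have length 4", call. = FALSE)
  P <- vcdn_forward_cache(C, head)$probs
  if (vec) P[1, ] else P
}

#' Composite training loss
#'
#' The model's loss is the sum of three mean cross-entropy terms: one per
#' view GCN and one for the VCDN output, each evaluated on the labeled
#' subset.
#'
#' @param pred_sp,pred_e,pred_vcdn n-by-2 probability matrices for the
#'   species view, exposome view, and VCDN output.
#' @param labels a [cohort_labels()]; only `labeled_mask` samples enter the
#'   loss.
#' @return A list of class `composite_loss` with `loss_species`,
#'   `loss_exposome`, `loss_vcdn` and `total` (their exact sum).
#' @export
composite_loss <- function(pred_sp, pred_e, pred_vcdn, labels) {
  stopifnot(inherits(labels, "cohort_labels"))
  idx <- which(labels$labeled_mask)
  if (length(idx) == 0L) stop("empty labeled set", call. = FALSE)
  y01 <- labels$y[idx]
  ls <- cross_entropy(pred_sp, idx, y01)
  le <- cross_entropy(pred_e, idx, y01)
  lv <- cross_entropy(pred_vcdn, idx, y01)
  structure(list(loss_species = ls, loss_exposome = le, loss_vcdn = lv,
                 total = ls + le + lv),
            class = "composite_loss")
}

#' @export
print.composite_loss <- function(x, ...) {
  cat(sprintf("composite loss: species %.4f + exposome %.4f + vcdn %.4f = %.4f\n",
              x$loss_species, x$loss_exposome, x$loss_vcdn, x$total))
  invisible(x)
}

#' Fit MOCO-GCN on a paired species/exposome cohort
#'
#' Fits the full two-view model: per-view cosine-similarity sample graphs
#' (edge density set by `k`), a graph convolutional network per view,
#' co-training over the unlabeled pool (pseudo-labels exchanged between
#' views), then joint alternating optimization of the two GCNs and the VCDN
#' integration head under the composite cross-entropy loss. The protocol is
#' transductive: unlabeled samples (e.g. a held-out test fold) take part in
#' the graphs and the co-training pool, but their true labels are discarded
#' before training starts and are never read.
#'
#' @param species species relative-abundance [omics_view()] or matrix.
#' @param exposome binary exposome [omics_view()] or matrix, same samples in
#'   the same order.
#' @param labels a [cohort_labels()] (or 0/1 vector, then fully labeled);
#'   `labeled_mask` marks the training pool.
#' @param config a [mocogcn_config()].
#' @param ... convenience overrides of individual `config` entries, e.g.
#'   `mocogcn(s, e, y, k = 4, seed = 7)`.
#' @return An object of class `mocogcn`; see [predict.mocogcn()],
#'   [summary.mocogcn()], [plot.mocogcn()].
#' @examples
#' \donttest{
#' coh <- generate_cohort(n_case = 20, n_control = 20, d_species = 30,
#'                        d_exposome = 8, seed = 1)
#' fit <- mocogcn(coh$species_view, coh$exposome_view, coh$labels,
#'                pretrain_epochs = 50, joint_epochs = 25, seed = 1)
#' head(predict(fit)$final)
#' }
#' @export
mocogcn <- function(species, exposome, labels, config = mocogcn_config(),
                    ...) {
  cl <- match.call()
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(config))
    if (length(bad)) stop("unknown config entries: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    config[names(dots)] <- dots
    config <- do.call(mocogcn_config, unclass(config))
  }
  Xs <- as_view_matrix(species)
  Xe <- as_view_matrix(exposome)
  if (inherits(species, "omics_view") && inherits(exposome, "omics_view") &&
      !identical(species$sample_ids, exposome$sample_ids))
    stop("views must share an identical sample order; see align_cohort()",
         call. = FALSE)
  if (!inherits(labels, "cohort_labels")) {
    ids <- rownames(Xs) %||% paste0("sample", seq_len(nrow(Xs)))
    labels <- cohort_labels(ids, labels)
  }
  stopifnot(nrow(Xs) == nrow(Xe), nrow(Xs) == length(labels$y))

  graphs <- list(species = similarity_graph(Xs, config$k, config$zscore),
                 exposome = similarity_graph(Xe, config$k, config$zscore))

  with_seed(config$seed, {
    ct <- cotrain(Xs, Xe, graphs, labels, config)
    model_s <- ct$model_s
    model_e <- ct$model_e
    head <- init_vcdn(config$vcdn_hidden, seed = config$seed + 2L,
                      lrelu_slope = config$lrelu_slope)

    labeled0 <- which(labels$labeled_mask)
    y0 <- labels$y[labeled0]
    pool_s <- ct$state$pool_species
    pool_e <- ct$state$pool_exposome
    opt_s <- ct$opt_s
    opt_e <- ct$opt_e
    opt_v <- adam_init(head$params)

    trace <- data.frame(epoch = integer(), loss_species = numeric(),
                        loss_exposome = numeric(), loss_vcdn = numeric(),
                        total = numeric())
    for (epoch in seq_len(config$joint_epochs)) {
      ## phase (a): VCDN fixed, update both GCNs against the full loss
      cs <- gcn_forward_cache(Xs, graphs$species$A_hat, model_s,
                              training = TRUE)
      ce <- gcn_forward_cache(Xe, graphs$exposome$A_hat, model_e,
                              training = TRUE)
      C <- cross_view_tensor(ce$probs, cs$probs)
      vc <- vcdn_forward_cache(C, head)
      loss_s <- cross_entropy(cs$probs, pool_s$idx, pool_s$label)
      loss_e <- cross_entropy(ce$probs, pool_e$idx, pool_e$label)
      loss_v <- cross_entropy(vc$probs, labeled0, y0)
      total <- loss_s + loss_e + loss_v
      if (!is.finite(total))
        stop("joint training diverged: non-finite loss at epoch ", epoch,
             call. = FALSE)

      dZv <- ce_logit_grad(vc$probs, labeled0, y0)
      dC <- vcdn_backward(C, head, vc, dZv)$dC
      # unflatten row-major: C columns are (e1 s1, e1 s2, e2 s1, e2 s2)
      dPe <- cbind(dC[, 1] * cs$probs[, 1] + dC[, 2] * cs$probs[, 2],
                   dC[, 3] * cs$probs[, 1] + dC[, 4] * cs$probs[, 2])
      dPs <- cbind(dC[, 1] * ce$probs[, 1] + dC[, 3] * ce$probs[, 2],
                   dC[, 2] * ce$probs[, 1] + dC[, 4] * ce$probs[, 2])
      dlog_s <- ce_logit_grad(cs$probs, pool_s$idx, pool_s$label) +
        softmax_backprop(cs$probs, dPs)
      dlog_e <- ce_logit_grad(ce$probs, pool_e$idx, pool_e$label) +
        softmax_backprop(ce$probs, dPe)
      gs <- gcn_backward(cs, model_s, graphs$species$A_hat, dlog_s)
      ge <- gcn_backward(ce, model_e, graphs$exposome$A_hat, dlog_e)
      if (config$weight_decay > 0) {
        gs <- Map(function(g, w) g + config$weight_decay * w, gs, model_s$W)
        ge <- Map(function(g, w) g + config$weight_decay * w, ge, model_e$W)
      }
      us <- adam_step(model_s$W, gs, opt_s, config$lr_gcn)
      ue <- adam_step(model_e$W, ge, opt_e, config$lr_gcn)
      model_s$W <- us$params; opt_s <- us$state
      model_e$W <- ue$params; opt_e <- ue$state

      ## phase (b): GCNs fixed, update the VCDN head
      ps <- gcn_forward_cache(Xs, graphs$species$A_hat, model_s)$probs
      pe <- gcn_forward_cache(Xe, graphs$exposome$A_hat, model_e)$probs
      Cb <- cross_view_tensor(pe, ps)
      vb <- vcdn_forward_cache(Cb, head)
      dZb <- ce_logit_grad(vb$probs, labeled0, y0)
      gv <- vcdn_backward(Cb, head, vb, dZb)$grads
      uv <- adam_step(head$params, gv, opt_v, config$lr_vcdn)
      head$params <- uv$params; opt_v <- uv$state

      trace <- rbind(trace, data.frame(
        epoch = epoch, loss_species = loss_s, loss_exposome = loss_e,
        loss_vcdn = loss_v, total = total))
    }

    probs_s <- gcn_forward_cache(Xs, graphs$species$A_hat, model_s)$probs
    probs_e <- gcn_forward_cache(Xe, graphs$exposome$A_hat, model_e)$probs
    final <- vcdn_forward_cache(cross_view_tensor(probs_e, probs_s),
                                head)$probs
    rownames(final) <- rownames(probs_s) <- rownames(probs_e) <-
      labels$sample_ids
    colnames(final) <- colnames(probs_s) <- colnames(probs_e) <-
      c("control", "case")

    structure(list(call = cl, config = config, graphs = graphs,
                   model_species = model_s, model_exposome = model_e,
                   vcdn = head, cotrain = ct$state, loss_trace = trace,
                   fitted = list(final = final, species = probs_s,
                                 exposome = probs_e),
                   labels = labels, X_species = Xs, X_exposome = Xe,
                   sample_ids = labels$sample_ids),
              class = "mocogcn")
  })
}

#' Predict with a fitted MOCO-GCN
#'
#' The model is transductive: the similarity graphs are part of the fitted
#' object, so predictions are made for the fitted cohort. Alternative
#' feature matrices for the same samples may be supplied (used by the
#' feature-ablation importance, which zeroes one feature column at a time);
#' the trained graphs are held fixed.
#'
#' @param object a fitted [mocogcn()].
#' @param species,exposome optional replacement feature matrices with the
#'   fitted dimensions.
#' @param ... unused.
#' @return A list with `final` (VCDN output), `species` and `exposome`
#'   (per-view distributions), each an n-by-2 probability matrix, and
#'   `class1_prob`, the case-class probability used for AUROC.
#' @export
predict.mocogcn <- function(object, species = NULL, exposome = NULL, ...) {
  Xs <- if (is.null(species)) object$X_species else as_view_matrix(species)
  Xe <- if (is.null(exposome)) object$X_exposome else as_view_matrix(exposome)
  if (!identical(dim(Xs), dim(object$X_species)) ||
      !identical(dim(Xe), dim(object$X_exposome)))
    stop("replacement matrices must match the fitted dimensions",
         call. = FALSE)
  ps <- gcn_forward_cache(Xs, object$graphs$species$A_hat,
                          object$model_species)$probs
  pe <- gcn_forward_cache(Xe, object$graphs$exposome$A_hat,
                          object$model_exposome)$probs
  final <- vcdn_forward_cache(cross_view_tensor(pe, ps), object$vcdn)$probs
  rownames(final) <- object$sample_ids
  colnames(final) <- c("control", "case")
  list(final = final, species = ps, exposome = pe,
       class1_prob = final[, 2])
}

#' @export
fitted.mocogcn <- function(object, ...) object$fitted$final

#' @export
coef.mocogcn <- function(object, ...) {
  list(species = object$model_species$W, exposome = object$model_exposome$W,
       vcdn = object$vcdn$params)
}

#' @export
print.mocogcn <- function(x, ...) {
  cat("MOCO-GCN fit\n")
  cat(sprintf("  samples: %d (%d labeled), features: %d species + %d exposome\n",
              length(x$sample_ids), sum(x$labels$labeled_mask),
              ncol(x$X_species), ncol(x$X_exposome)))
  cat(sprintf("  k = %g (epsilon %.3f / %.3f), co-training rounds: %d%s\n",
              x$config$k, x$graphs$species$epsilon, x$graphs$exposome$epsilon,
              x$cotrain$rounds,
              if (x$cotrain$converged) "" else " (not converged)"))
  n <- nrow(x$loss_trace)
  if (n > 0)
    cat(sprintf("  final composite loss: %.4f\n", x$loss_trace$total[n]))
  invisible(x)
}

#' Summary of a fitted MOCO-GCN
#'
#' @param object a fitted [mocogcn()].
#' @param ... unused.
#' @return The object, invisibly; prints configuration, co-training
#'   bookkeeping, loss decomposition and training-pool accuracy.
#' @export
summary.mocogcn <- function(object, ...) {
  print(object)
  lab <- which(object$labels$labeled_mask)
  pred <- as.integer(object$fitted$final[lab, 2] >= 0.5)
  cat(sprintf("  labeled-pool accuracy: %.3f\n",
              mean(pred == object$labels$y[lab])))
  cat(sprintf("  pseudo-labels issued: %d (species view %d, exposome view %d)\n",
              nrow(object$cotrain$log),
              sum(object$cotrain$log$view == "species"),
              sum(object$cotrain$log$view == "exposome")))
  n <- nrow(object$loss_trace)
  if (n > 0) {
    cat(sprintf("  loss (epoch %d): species %.4f, exposome %.4f, vcdn %.4f\n",
                n, object$loss_trace$loss_species[n],
                object$loss_trace$loss_exposome[n],
                object$loss_trace$loss_vcdn[n]))
  }
  invisible(object)
}

#' Plot the joint-training loss trace
#'
#' @param x a fitted [mocogcn()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mocogcn <- function(x, ...) {
  tr <- x$loss_trace
  graphics::matplot(tr$epoch,
                    cbind(tr$total, tr$loss_species, tr$loss_exposome,
                          tr$loss_vcdn),
                    type = "l", lty = 1, lwd = c(2, 1, 1, 1),
                    col = c("black", "forestgreen", "steelblue", "firebrick"),
                    xlab = "joint epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright",
                   c("total", "species", "exposome", "vcdn"),
                   col = c("black", "forestgreen", "steelblue", "firebrick"),
                   lty = 1, lwd = c(2, 1, 1, 1), bty = "n")
  invisible(x)
}

#' Save / load a fitted model
#'
#' Serializes the fitted object (weights, graphs, configuration echo) to a
#' single file for later prediction or importance analysis.
#'
#' @param object a fitted [mocogcn()].
#' @param path file path.
#' @return `load_mocogcn` returns the fitted object.
#' @export
save_mocogcn <- function(object, path) {
  stopifnot(inherits(object, "mocogcn"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_mocogcn
#' @export
load_mocogcn <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "mocogcn"))
    stop("file does not contain a mocogcn fit", call. = FALSE)
  object
}
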