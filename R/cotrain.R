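#' Select confident pseudo-labels from a prediction snapshot
#'
#' Among `candidate_idx`, keeps samples whose maximum class probability is
#' at least `tau`, orders them by descending confidence and returns at most
#' `m` of them with the argmax class as pseudo-label. Ties in confidence are
#' broken by candidate order for determinism.
#'
#' @param probs n-by-2 class probability matrix.
#' @param candidate_idx integer indices of the unlabeled candidates.
#' @param m maximum number of pseudo-labels to return (0 allowed).
#' @param tau confidence threshold in `[0.5, 1]`.
#' @return Data frame with columns `idx`, `pseudo_label` (0/1),
#'   `confidence`, possibly empty.
#' @export
confident_pseudolabels <- function(probs, candidate_idx, m, tau = 0.8) {
  stopifnot(m >= 0, tau >= 0.5, tau <= 1)
  if (m == 0L || length(candidate_idx) == 0L)
    return(data.frame(idx = integer(), pseudo_label = integer(),
                      confidence = numeric()))
  p <- probs[candidate_idx, , drop = FALSE]
  conf <- pmax(p[, 1], p[, 2])
  lab <- as.integer(p[, 2] >= p[, 1])
  keep <- conf >= tau
  out <- data.frame(idx = candidate_idx[keep], pseudo_label = lab[keep],
                    confidence = conf[keep])
  out <- out[order(-out$confidence, out$idx), , drop = FALSE]
  out <- utils::head(out, m)
  rownames(out) <- NULL
  out
}

#' Co-train the two per-view GCNs with cross-view pseudo-labeling
#'
#' Each round, both view networks are trained on their current labeled
#' pools (full-batch Adam on the cross-entropy), then each view proposes
#' its most confident unlabeled samples; accepted pseudo-labels are
#' exchanged, i.e. the species view's picks enter the exposome pool and
#' vice versa. If both views propose the same sample in one round with
#' different classes, the higher-confidence proposal wins; an exact tie
#' defers the sample. Training ends when the unlabeled pool is empty and
#' both views' predicted labels are unchanged between consecutive rounds,
#' or at `max_rounds` (with a warning).
#'
#' Ground-truth labels of unlabeled samples are never read: they are
#' removed from the working copy before the first round.
#'
#' @param view_s,view_e species and exposome [omics_view()] objects.
#' @param graphs list with elements `species` and `exposome`, each a
#'   [similarity_graph()] on the same sample order.
#' @param labels a [cohort_labels()]; `labeled_mask` defines the visible
#'   pool.
#' @param config list of co-training settings; see [mocogcn_config()].
#' @param model_s,model_e optional pre-initialized [init_view_gcn()]
#'   networks (created from `config` when `NULL`).
#' @return A list with the two trained networks (`model_s`, `model_e`),
#'   per-view prediction snapshots (`probs_s`, `probs_e`), the per-view
#'   optimizer states, and `state`: the co-training bookkeeping (round
#'   count, per-view pools, event log, convergence flag).
#' @export
cotrain <- function(view_s, view_e, graphs, labels, config = mocogcn_config(),
                    model_s = NULL, model_e = NULL) {
  Xs <- as_view_matrix(view_s)
  Xe <- as_view_matrix(view_e)
  stopifnot(inherits(labels, "cohort_labels"),
            nrow(Xs) == length(labels$y), nrow(Xe) == length(labels$y))
  n <- nrow(Xs)
  # hygiene: drop masked ground truth before anything else runs
  y <- ifelse(labels$labeled_mask, labels$y, NA_integer_)
  labeled0 <- which(labels$labeled_mask)
  if (length(labeled0) == 0L || length(unique(y[labeled0])) < 2L)
    stop("labeled pool must be non-empty and contain both classes",
         call. = FALSE)

  if (is.null(model_s))
    model_s <- init_view_gcn(ncol(Xs), config$hidden_dims, seed = config$seed,
                             view_name = "species",
                             lrelu_slope = config$lrelu_slope,
                             dropout = config$dropout)
  if (is.null(model_e))
    model_e <- init_view_gcn(ncol(Xe), config$hidden_dims,
                             seed = config$seed + 1L,
                             view_name = "exposome",
                             lrelu_slope = config$lrelu_slope,
                             dropout = config$dropout)

  pool_s <- data.frame(idx = labeled0, label = y[labeled0])
  pool_e <- pool_s
  unlabeled <- setdiff(seq_len(n), labeled0)
  log <- data.frame(round = integer(), view = character(),
                    sample_id = character(), pseudo_label = integer(),
                    confidence = numeric())
  opt_s <- opt_e <- NULL
  prev_pred <- NULL
  converged <- FALSE
  round <- 0L

  while (round < config$max_rounds) {
    round <- round + 1L
    fs <- fit_view_gcn(Xs, graphs$species$A_hat, model_s, pool_s$idx,
                       pool_s$label, config$pretrain_epochs, config$lr_gcn,
                       opt_s, config$weight_decay)
    fe <- fit_view_gcn(Xe, graphs$exposome$A_hat, model_e, pool_e$idx,
                       pool_e$label, config$pretrain_epochs, config$lr_gcn,
                       opt_e, config$weight_decay)
    model_s <- fs$model; opt_s <- fs$opt_state
    model_e <- fe$model; opt_e <- fe$opt_state
    probs_s <- gcn_forward_cache(Xs, graphs$species$A_hat, model_s)$probs
    probs_e <- gcn_forward_cache(Xe, graphs$exposome$A_hat, model_e)$probs

    # invariant: original labels never overwritten
    stopifnot(identical(pool_s$label[match(labeled0, pool_s$idx)],
                        y[labeled0]),
              identical(pool_e$label[match(labeled0, pool_e$idx)],
                        y[labeled0]))

    if (length(unlabeled) > 0L) {
      m <- max(1L, ceiling(config$m_frac * length(unlabeled)))
      prop_s <- confident_pseudolabels(probs_s, unlabeled, m, config$tau)
      prop_e <- confident_pseudolabels(probs_e, unlabeled, m, config$tau)
      # cross-view conflicts: same sample, different class, same round
      both <- intersect(prop_s$idx, prop_e$idx)
      defer <- integer()
      for (i in both) {
        ls <- prop_s$pseudo_label[prop_s$idx == i]
        le <- prop_e$pseudo_label[prop_e$idx == i]
        if (ls != le) {
          cs <- prop_s$confidence[prop_s$idx == i]
          ce <- prop_e$confidence[prop_e$idx == i]
          if (cs > ce) prop_e <- prop_e[prop_e$idx != i, ]
          else if (ce > cs) prop_s <- prop_s[prop_s$idx != i, ]
          else { # exact tie: defer to a later round
            prop_s <- prop_s[prop_s$idx != i, ]
            prop_e <- prop_e[prop_e$idx != i, ]
            defer <- c(defer, i)
          }
        }
      }
      # exchange: species proposals train the exposome view and vice versa
      if (nrow(prop_s) > 0L) {
        pool_e <- rbind(pool_e, data.frame(idx = prop_s$idx,
                                           label = prop_s$pseudo_label))
        log <- rbind(log, data.frame(
          round = round, view = "species",
          sample_id = labels$sample_ids[prop_s$idx],
          pseudo_label = prop_s$pseudo_label,
          confidence = prop_s$confidence))
      }
      if (nrow(prop_e) > 0L) {
        pool_s <- rbind(pool_s, data.frame(
          idx = prop_e$idx, label = prop_e$pseudo_label))
        log <- rbind(log, data.frame(
          round = round, view = "exposome",
          sample_id = labels$sample_ids[prop_e$idx],
          pseudo_label = prop_e$pseudo_label,
          confidence = prop_e$confidence))
      }
      newly <- union(prop_s$idx, prop_e$idx)
      unlabeled <- setdiff(unlabeled, newly)
    }

    # stability is judged on the pseudo-label assignments: the predicted
    # classes of the originally-unlabeled samples under both views
    un0 <- setdiff(seq_len(n), labeled0)
    pred <- cbind(max.col(probs_s[un0, , drop = FALSE]),
                  max.col(probs_e[un0, , drop = FALSE]))
    if (length(unlabeled) == 0L &&
        (length(un0) == 0L ||
           (!is.null(prev_pred) && identical(pred, prev_pred)))) {
      converged <- TRUE
      break
    }
    prev_pred <- if (length(unlabeled) == 0L) pred else NULL
  }
  if (!converged)
    warning("co-training reached max_rounds (", config$max_rounds,
            ") before stabilizing; returning current state", call. = FALSE)

  # each pool keeps the first label a sample received
  pool_s <- pool_s[!duplicated(pool_s$idx), ]
  pool_e <- pool_e[!duplicated(pool_e$idx), ]
  list(model_s = model_s, model_e = model_e,
       probs_s = probs_s, probs_e = probs_e,
       opt_s = opt_s, opt_e = opt_e,
       state = list(rounds = round, pool_species = pool_s,
                    pool_exposome = pool_e, unlabeled = unlabeled,
                    log = log, converged = converged))
}
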