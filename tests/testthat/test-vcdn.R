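test_that("cross_view_tensor is the flattened outer product", {
  expect_equal(cross_view_tensor(c(0.6, 0.4), c(0.7, 0.3)),
               c(0.42, 0.18, 0.28, 0.12))
  expect_equal(cross_view_tensor(c(1, 0), c(0, 1)), c(0, 1, 0, 0))
  set.seed(17)
  for (i in 1:50) {
    ye <- random_probs(1)[1, ]
    ys <- random_probs(1)[1, ]
    got <- cross_view_tensor(ye, ys)
    expect_equal(got, oracle_outer4(ye, ys))
    expect_equal(sum(got), 1)
  }
  # matrix form matches row-wise application
  Ye <- random_probs(5)
  Ys <- random_probs(5)
  C <- cross_view_tensor(Ye, Ys)
  for (i in 1:5)
    expect_equal(C[i, ], cross_view_tensor(Ye[i, ], Ys[i, ]))
  expect_error(cross_view_tensor(c(-0.1, 1.1), c(0.5, 0.5)),
               "non-negative")
})

test_that("vcdn_forward yields valid, reproducible distributions", {
  h1 <- init_vcdn(8, seed = 4)
  h2 <- init_vcdn(8, seed = 4)
  h3 <- init_vcdn(8, seed = 5)
  expect_identical(h1$params, h2$params)
  expect_false(identical(h1$params, h3$params))
  set.seed(18)
  C <- cross_view_tensor(random_probs(20), random_probs(20))
  P <- vcdn_forward(C, h1)
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, 20), tolerance = 1e-9)
  expect_identical(vcdn_forward(C, h1), P)
  # distinct seeds give different but valid outputs
  P3 <- vcdn_forward(C, h3)
  expect_false(identical(P, P3))
  expect_equal(unname(rowSums(P3)), rep(1, 20), tolerance = 1e-9)
  expect_error(vcdn_forward(c(0.2, 0.8), h1), "length 4")
  # zero-hidden-layer head is a plain linear-softmax map
  h0 <- init_vcdn(0, seed = 1)
  expect_equal(unname(rowSums(vcdn_forward(C, h0))), rep(1, 20),
               tolerance = 1e-9)
})

test_that("composite loss adds its three cross-entropy terms exactly", {
  n <- 12
  set.seed(19)
  lab <- cohort_labels(sprintf("s%02d", 1:n), rep(c(0, 1), n / 2))
  onehot <- cbind(1 - lab$y, lab$y)
  # perfect one-hot predictions: zero loss
  cl0 <- composite_loss(onehot, onehot, onehot, lab)
  expect_equal(cl0$total, 0)
  # uniform predictions contribute log(2) per term
  U <- matrix(0.5, n, 2)
  clu <- composite_loss(U, U, U, lab)
  expect_equal(clu$loss_species, log(2))
  expect_equal(clu$total, 3 * log(2))
  # random predictions match a naive loop oracle, and the sum is exact
  Ps <- random_probs(n); Pe <- random_probs(n); Pv <- random_probs(n)
  cl <- composite_loss(Ps, Pe, Pv, lab)
  idx <- seq_len(n)
  expect_equal(cl$loss_species, oracle_mean_ce(Ps, idx, lab$y),
               ignore_attr = TRUE)
  expect_equal(cl$loss_exposome, oracle_mean_ce(Pe, idx, lab$y),
               ignore_attr = TRUE)
  expect_equal(cl$loss_vcdn, oracle_mean_ce(Pv, idx, lab$y),
               ignore_attr = TRUE)
  expect_identical(cl$total, cl$loss_species + cl$loss_exposome + cl$loss_vcdn)
  # empty labeled set errors
  lab_none <- cohort_labels(lab$sample_ids, lab$y, rep(FALSE, n))
  expect_error(composite_loss(Ps, Pe, Pv, lab_none), "empty labeled set")
})

test_that("fitting is deterministic under a fixed seed", {
  coh <- tiny_cohort(seed = 20)
  labs <- hide_labels(coh, 0.25, seed = 21)
  cfg <- tiny_config(seed = 6)
  f1 <- suppressWarnings(mocogcn(coh$species_view, coh$exposome_view, labs, cfg))
  f2 <- suppressWarnings(mocogcn(coh$species_view, coh$exposome_view, labs, cfg))
  expect_identical(f1$fitted$final, f2$fitted$final)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loss_trace, f2$loss_trace)
})

test_that("joint training reduces the composite loss on separable data", {
  coh <- tiny_cohort(seed = 22, species_effect = 3)
  fit <- suppressWarnings(
    mocogcn(coh$species_view, coh$exposome_view, coh$labels,
            tiny_config(seed = 7)))
  tr <- fit$loss_trace
  expect_lt(tr$total[nrow(tr)], tr$total[1])
  # additivity on every epoch
  expect_equal(tr$total,
               tr$loss_species + tr$loss_exposome + tr$loss_vcdn)
})

test_that("a pure-noise exposome view still yields valid final distributions", {
  coh <- tiny_cohort(seed = 23, n_inf_exposome = 0L, exposure_effect = 0,
                     coupling = 0)
  fit <- suppressWarnings(
    mocogcn(coh$species_view, coh$exposome_view, coh$labels,
            tiny_config(seed = 8)))
  F <- fit$fitted$final
  expect_true(all(F >= 0))
  expect_equal(unname(rowSums(F)), rep(1, nrow(F)), tolerance = 1e-9)
})

test_that("the fixed component is untouched within each alternation phase", {
  coh <- tiny_cohort(seed = 24)
  # with the VCDN learning rate at zero, phase (a) alone runs: the head
  # must remain bit-identical to its initialization
  cfg <- tiny_config(seed = 9, lr_vcdn = 0)
  fit <- suppressWarnings(
    mocogcn(coh$species_view, coh$exposome_view, coh$labels, cfg))
  ref <- init_vcdn(cfg$vcdn_hidden, seed = cfg$seed + 2L,
                   lrelu_slope = cfg$lrelu_slope)
  expect_identical(fit$vcdn$params, ref$params)
  # while the GCNs did move
  init_s <- init_view_gcn(ncol(coh$species_view$X), cfg$hidden_dims,
                          seed = cfg$seed, view_name = "species",
                          lrelu_slope = cfg$lrelu_slope,
                          dropout = cfg$dropout)
  expect_false(identical(fit$model_species$W, init_s$W))
})

test_that("prediction is permutation-equivariant and exposes class-1 probability", {
  coh <- tiny_cohort(seed = 25)
  cfg <- tiny_config(seed = 10)
  fit <- suppressWarnings(
    mocogcn(coh$species_view, coh$exposome_view, coh$labels, cfg))
  p <- predict(fit)
  expect_equal(unname(p$class1_prob), unname(p$final[, 2]))
  # with fixed weights, the whole prediction pathway commutes with any
  # sample permutation (graphs rebuilt on the permuted order)
  Xs <- coh$species_view$X
  Xe <- coh$exposome_view$X
  ms <- fit$model_species
  me <- fit$model_exposome
  pipeline <- function(Xs, Xe) {
    gs <- similarity_graph(Xs, cfg$k)
    ge <- similarity_graph(Xe, cfg$k)
    vcdn_forward(cross_view_tensor(gcn_forward(Xe, ge, me),
                                   gcn_forward(Xs, gs, ms)), fit$vcdn)
  }
  set.seed(26)
  perm <- sample(nrow(Xs))
  expect_equal(pipeline(Xs[perm, ], Xe[perm, ]), pipeline(Xs, Xe)[perm, ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("model checkpoints round-trip through a file", {
  coh <- tiny_cohort(seed = 27)
  fit <- suppressWarnings(
    mocogcn(coh$species_view, coh$exposome_view, coh$labels,
            tiny_config(seed = 11, joint_epochs = 5L)))
  f <- withr::local_tempfile(fileext = ".rds")
  save_mocogcn(fit, f)
  back <- load_mocogcn(f)
  expect_identical(predict(back)$final, predict(fit)$final)
})
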