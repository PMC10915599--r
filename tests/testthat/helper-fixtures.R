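# Small fixtures built in code. `tiny_config()` shrinks the network and the
# training schedule so that module tests stay fast; acceptance tests use the
# package defaults.

tiny_config <- function(...) {
  args <- list(hidden_dims = c(16L, 8L), pretrain_epochs = 30L,
               joint_epochs = 30L, max_rounds = 15L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(mocogcn_config, args)
}

tiny_cohort <- function(seed = 1L, ...) {
  args <- list(n_case = 24L, n_control = 24L, d_species = 24L,
               d_exposome = 6L, n_inf_species = 4L, n_inf_exposome = 2L,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(generate_cohort, args)
}

random_probs <- function(n) {
  p <- stats::runif(n)
  cbind(1 - p, p)
}
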