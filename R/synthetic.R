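# Synthetic paired-cohort generator. Species abundances follow a log-normal
# compositional model (Gaussian log-abundance, sd 1, closed to the simplex);
# exposures are Bernoulli with a prevalence shift in cases on the informative
# variables. Shapes default to the Spanish PDAC study design: 57 cases / 50
# controls, 125 species, 23 binary exposures.

# Gaussian log-abundance block, before closure; informative columns of case
# rows are shifted by `effect` (log-scale).
sim_log_abundance <- function(n, d, base_mean = 0, sd = 1) {
  matrix(stats::rnorm(n * d, base_mean, sd), n, d)
}

#' Generate a paired species/exposome cohort with planted signal
#'
#' Species: per-sample Gaussian log-abundances (sd 1), with the informative
#' species shifted upward by `species_effect` (log scale) in cases, then
#' exponentiated and closed to the simplex. Exposome: Bernoulli(`p0`) in
#' controls and Bernoulli(`p0 + exposure_effect`) in cases on the
#' informative exposures. A coupling coefficient mixes each informative
#' exposure's 0/1 value into a paired informative species' log-abundance,
#' giving the two views a shared axis beyond the label.
#'
#' @param n_case,n_control class sizes (defaults 57 / 50).
#' @param d_species,d_exposome feature counts (defaults 125 / 23).
#' @param n_inf_species,n_inf_exposome number of informative features per
#'   view (defaults 10 / 3).
#' @param species_effect log-scale shift of informative species in cases
#'   (default 3, i.e. three log-abundance standard deviations).
#' @param exposure_effect prevalence gap of informative exposures in cases
#'   (default 0.3).
#' @param coupling coefficient in `[0, 1]` mixing exposure values into
#'   species log-abundance (default 0.3).
#' @param p0 baseline exposure prevalence (default 0.3).
#' @param seed integer seed; the cohort is bit-reproducible from it.
#' @return A list of class `synthetic_cohort`: `species_view`,
#'   `exposome_view` ([omics_view()]), `labels` ([cohort_labels()], fully
#'   labeled), and `truth` (informative ids, effects, `seed`).
#' @export
generate_cohort <- function(n_case = 57L, n_control = 50L, d_species = 125L,
                            d_exposome = 23L, n_inf_species = 10L,
                            n_inf_exposome = 3L, species_effect = 3,
                            exposure_effect = 0.3, coupling = 0.3, p0 = 0.3,
                            seed = 1L) {
  stopifnot(n_case >= 1, n_control >= 1, d_species >= 1, d_exposome >= 1,
            species_effect >= 0, exposure_effect >= 0,
            coupling >= 0, coupling <= 1)
  if (n_inf_species > d_species || n_inf_exposome > d_exposome)
    stop("informative feature count exceeds feature count", call. = FALSE)
  if (p0 + exposure_effect > 1)
    stop("p0 + exposure_effect must not exceed 1", call. = FALSE)
  n <- n_case + n_control
  with_seed(seed, {
    y <- c(rep(1L, n_case), rep(0L, n_control))
    ids <- sprintf("s%03d", seq_len(n))
    sp_ids <- sprintf("sp%03d", seq_len(d_species))
    ex_ids <- sprintf("exp%02d", seq_len(d_exposome))
    inf_sp <- if (n_inf_species > 0) seq_len(n_inf_species) else integer()
    inf_ex <- if (n_inf_exposome > 0) seq_len(n_inf_exposome) else integer()

    # exposome first so the coupling can read it
    p <- matrix(p0, n, d_exposome)
    if (length(inf_ex)) p[y == 1L, inf_ex] <- p0 + exposure_effect
    E <- matrix(stats::rbinom(n * d_exposome, 1L, as.vector(p)),
                n, d_exposome)

    L <- sim_log_abundance(n, d_species)
    if (length(inf_sp))
      L[y == 1L, inf_sp] <- L[y == 1L, inf_sp] + species_effect
    if (coupling > 0 && length(inf_sp) && length(inf_ex)) {
      # pair informative species with informative exposures cyclically
      for (i in seq_along(inf_sp)) {
        e <- inf_ex[(i - 1L) %% length(inf_ex) + 1L]
        L[, inf_sp[i]] <- L[, inf_sp[i]] + coupling * E[, e]
      }
    }
    Xs <- exp(L)
    Xs <- Xs / rowSums(Xs)
    dimnames(Xs) <- list(ids, sp_ids)
    dimnames(E) <- list(ids, ex_ids)

    structure(list(
      species_view = omics_view(Xs, "species"),
      exposome_view = omics_view(E, "exposome"),
      labels = cohort_labels(ids, y),
      truth = list(informative_species = sp_ids[inf_sp],
                   informative_exposures = ex_ids[inf_ex],
                   species_effect = species_effect,
                   exposure_effect = exposure_effect,
                   coupling = coupling, p0 = p0, seed = seed)),
      class = "synthetic_cohort")
  })
}

#' Generate a null cohort (no signal anywhere)
#'
#' All effects and the coupling are zero and class labels are assigned at
#' random (half the samples, rounded down, become cases), so any
#' classifier's expected AUROC is 0.5.
#'
#' @param n total number of samples.
#' @param d_species,d_exposome feature counts.
#' @param p0 baseline exposure prevalence.
#' @param seed integer seed.
#' @return A `synthetic_cohort` whose `truth` informative sets are empty.
#' @export
generate_null_cohort <- function(n = 107L, d_species = 125L,
                                 d_exposome = 23L, p0 = 0.3, seed = 1L) {
  stopifnot(n >= 2)
  n_case <- n %/% 2L
  coh <- generate_cohort(n_case = n_case, n_control = n - n_case,
                         d_species = d_species, d_exposome = d_exposome,
                         n_inf_species = 0L, n_inf_exposome = 0L,
                         species_effect = 0, exposure_effect = 0,
                         coupling = 0, p0 = p0, seed = seed)
  # shuffle the label assignment so it is random with respect to row order
  y <- with_seed(seed + 1L, sample(coh$labels$y))
  coh$labels <- cohort_labels(coh$labels$sample_ids, y)
  coh
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples (%d case / %d control), %d species + %d exposures\n",
    length(x$labels$y), sum(x$labels$y == 1L), sum(x$labels$y == 0L),
    ncol(x$species_view$X), ncol(x$exposome_view$X)))
  cat(sprintf("  informative: %d species, %d exposures (effects %.2g / %.2g)\n",
              length(x$truth$informative_species),
              length(x$truth$informative_exposures),
              x$truth$species_effect, x$truth$exposure_effect))
  invisible(x)
}

#' Mask a fraction of labels for semi-supervised training
#'
#' Hides a stratified random fraction of the labels (sets `labeled_mask`
#' to `FALSE`); the true values stay in `y` for later scoring but carry a
#' `FALSE` mask, which every training path treats as invisible.
#'
#' @param cohort a `synthetic_cohort` (or a [cohort_labels()]).
#' @param fraction fraction of each class to mask, in `[0, 1)`.
#' @param seed integer seed.
#' @return A [cohort_labels()] with the new mask.
#' @export
hide_labels <- function(cohort, fraction, seed = 1L) {
  labels <- if (inherits(cohort, "synthetic_cohort")) cohort$labels else cohort
  stopifnot(inherits(labels, "cohort_labels"),
            fraction >= 0, fraction < 1)
  y <- labels$y
  mask <- rep(TRUE, length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      n_hide <- floor(fraction * length(idx))
      if (n_hide >= length(idx))
        stop("masking would leave class ", cls, " empty", call. = FALSE)
      if (n_hide > 0) mask[sample(idx, n_hide)] <- FALSE
    }
  })
  cohort_labels(labels$sample_ids, y, mask)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `species.tsv`, `exposome.tsv`, `labels.tsv` in the package's
#' delimited-text dialect plus `truth.json` (ground-truth metadata).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory, created if needed.
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_view(cohort$species_view, file.path(dir, "species.tsv"))
  write_view(cohort$exposome_view, file.path(dir, "exposome.tsv"))
  write_labels(cohort$labels, file.path(dir, "labels.tsv"))
  tr <- cohort$truth
  json <- sprintf(paste0(
    '{"informative_species": [%s], "informative_exposures": [%s], ',
    '"species_effect": %g, "exposure_effect": %g, "coupling": %g, ',
    '"p0": %g, "seed": %d}'),
    paste(sprintf('"%s"', tr$informative_species), collapse = ", "),
    paste(sprintf('"%s"', tr$informative_exposures), collapse = ", "),
    tr$species_effect, tr$exposure_effect, tr$coupling, tr$p0, tr$seed)
  writeLines(json, file.path(dir, "truth.json"))
  invisible(dir)
}
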