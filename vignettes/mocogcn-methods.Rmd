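---
title: "Two-view co-training GCNs with cross-view label integration: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-view co-training GCNs with cross-view label integration: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocogcn)
```

# The problem

Case–control classification of pancreatic ductal adenocarcinoma (PDAC) from
two complementary data layers measured on the same subjects: a species-level
gut-microbiome relative-abundance table (continuous, compositional) and an
exposome table of binary host variables (lifestyle, medication, comorbidity).
Neither layer alone tells the whole story; the model in this package
integrates them while keeping each layer's own structure — its own
sample-similarity graph and its own classifier — rather than concatenating
features.

The package fits the model transductively: all samples, labeled or not,
participate in the similarity graphs and in semi-supervised co-training,
but held-out labels are discarded before training and never read. That is
the standard protocol for graph-convolutional classifiers on a single fixed
cohort, and it is what the cross-validation harness implements fold by fold.

# The model

## Per-view sample-similarity graphs

For each view, cosine similarity between all sample pairs gives
$S_{ij} = \langle x_i, x_j\rangle / (\lVert x_i\rVert\,\lVert x_j\rVert)$.
A weighted adjacency retains $A_{ij} = S_{ij}$ wherever $i \ne j$ and
$S_{ij} \ge \varepsilon$, zero otherwise. The threshold $\varepsilon$ is not
set directly: the user chooses $k$, the average number of retained pairs per
node, and $\varepsilon$ is the largest similarity achieving it,
deterministically, by sorting the off-diagonal values.

A convention matters here. We count each node's self-pair (similarity 1) in
the average, so $k = 1$ retains no off-diagonal edge at all: the graph
degenerates to isolated nodes and the GCN becomes an ordinary feed-forward
network — a degeneracy the model family explicitly admits, and one the test
suite checks bit-for-bit. Under the alternative convention (off-diagonal
edges only, $k \ge 1$) that degeneracy is unreachable, which is why we did
not adopt it. Consequences: valid $k$ runs from 1 (edgeless) to $n$
(complete graph), and the sensitivity sweep over $k = 2,\dots,10$ spans
roughly 1–9 genuine neighbours per sample.

The propagation operator is the renormalized
$\hat{A} = \hat{D}^{-1/2}(A + I)\hat{D}^{-1/2}$ with $\hat{D}$ the degree
matrix **of $A + I$**. Taking degrees of $A$ alone is singular for isolated
nodes, so the renormalization-trick reading is the only one under which the
$k=1$ degeneracy (and indeed any graph with an isolated node) is defined.
With no edges, $\hat{A} = I$ exactly.

Samples whose feature vector is all zero (a subject with none of the
recorded binary exposures — common in small exposome panels) have undefined
cosine similarity. The low-level `cosine_similarity_matrix()` refuses them;
the graph constructor `similarity_graph()` instead isolates them by default
(similarity 0 to every other sample), which composes correctly with the
$A + I$ normalization.

## View GCNs

Each view's classifier stacks graph-convolution layers
$H^{(l+1)} = \sigma(\hat{A} H^{(l)} W^{(l)})$ with a leaky-rectifier
activation (negative slope 0.25) between layers and a linear final map to
two class logits, turned into probabilities by a softmax. Defaults: hidden
widths 64 and 32, dropout 0.5 on hidden activations during training,
no bias terms (the layer map above has none). Layer count and widths are
configurable; nothing in the data dictates them and two hidden layers is
the customary depth for this model family — deeper stacks oversmooth on
graphs this small ($n \approx 100$).

Training is full-batch gradient descent with the Adam update
(learning rate $10^{-3}$) on the mean cross-entropy of the view's labeled
pool, plus L2 weight decay $5 \times 10^{-4}$ on the layer weights. The
weight decay is load-bearing, not cosmetic: without it a view memorizes its
labeled pool within a few hundred epochs, its confidence scores saturate,
and — as described next — it then exports confidently wrong pseudo-labels
to the partner view. Backpropagation and the optimizer are implemented in
plain matrix algebra; the cohort fits comfortably in one dense graph.

## Co-training

The two views train jointly by exchanging pseudo-labels. Each round:

1. each view trains on its current labeled pool (50 Adam epochs,
   optimizer state carried across rounds);
2. each view proposes up to $m = \max(1, \lceil 0.05\,|U|\rceil)$ unlabeled
   samples whose maximum class probability reaches $\tau = 0.8$, ordered by
   confidence;
3. proposals are exchanged: the species view's picks (with their predicted
   labels) join the exposome view's pool and vice versa — the classical
   co-training topology;
4. if both views pick the same sample with different classes in the same
   round, the higher-confidence proposal wins; an exact tie defers the
   sample to a later round.

Originally labeled samples keep their true labels in every round; the
invariant is asserted each round at run time and again by the test suite.
Training ends when the unlabeled pool is empty and the predicted classes of
the originally-unlabeled samples are unchanged between consecutive rounds,
or at `max_rounds` (default 30) with a warning.

Short inner fits (50 epochs, not hundreds) are a deliberate choice: the
proposal rule is only as good as the calibration of the confidence scores,
and an overfit view is confidently wrong on exactly the samples it should
abstain from. In development this single setting moved the weaker view's
held-out AUROC from barely-above-chance to near its Bayes ceiling on
synthetic cohorts.

## Cross-view integration (VCDN)

After co-training, each sample has two class distributions,
$y_i^{\text{exposome}}$ and $y_i^{\text{species}}$. Their outer product
$c_i = y_i^{\text{exposome}} \, (y_i^{\text{species}})^{\mathsf T}$ — a
$2 \times 2$ tensor, flattened row-major to four entries that sum to one —
feeds a small fully connected head (4 → 8 → 2, configurable down to a
single linear map) that emits the final prediction. The head can represent
asymmetric trust: which view to believe, jointly per label combination.

The composite loss is the exact sum of three mean cross-entropy terms, one
per view and one for the head's output, each evaluated on labeled samples.
Optimization alternates every epoch for 100 epochs: (a) with the head
fixed, both GCNs take one Adam step against the full loss, the head's
gradient flowing back through the outer product and each view's softmax;
(b) with the GCNs fixed, the head takes one Adam step. Gradients for every
piece were verified against finite differences during development.

Two numerical choices deserve a note:

* **Head learning rate.** The head's input is four numbers; its gradients
  are an order of magnitude smaller than the GCNs'. At the GCNs' rate
  ($10^{-3}$) the head barely leaves its random initialization within 100
  epochs, and a random linear map of the cross-view tensor is
  anti-correlated with the truth half the time — we observed exactly that
  pathology (final AUROC far below the better view's) before raising the
  head's rate to $10^{-2}$.
* **Per-view losses in the joint phase** use each view's own co-training
  pool (true plus received pseudo-labels); the head's loss uses only the
  originally labeled samples, so pseudo-label noise never reaches the
  final classifier's supervision.

# Feature selection

The differential-abundance stage tests each species with the two-sided
Wilcoxon rank-sum test (`stats::wilcox.test`, the function the analysis
convention comes from) and retains raw $p < \alpha$ (default 0.05, no
multiplicity correction — selection, not inference). Effect direction is
the generalized fold change: the mean difference between case and control
quantiles on the grid $0.05, 0.10, \dots, 0.95$ (linear-interpolation
quantiles), positive meaning case-enriched. The measure is antisymmetric
and shift-equivariant, both property-tested.

One compositional caveat: when a subset of species genuinely expands in
cases, closure (rows summing to 1) *deflates every other species* in cases,
so far more than the planted features can reach nominal significance. On
the default synthetic cohort all 125 species pass $p < 0.05$ even though
only 10 were planted — not a bug but a known property of relative-abundance
data, and one reason the selection stage should be read as dimension
reduction rather than biomarker inference. Under a pure null (no planted
effect) the false-positive rate sits at $\alpha$, which the suite verifies
against binomial bounds.

The loader rejects missing values outright: metadata imputation belongs
upstream of this package, and the error message says so. Exposome
binarization conventions are the caller's responsibility; only the 0/1
domain is enforced. Species abundances are not renormalized after feature
selection by default (`apply_selection(renormalize = FALSE)`), since the
convention is unstated in this analysis lineage; a flag enables it.

# Evaluation harness

`cross_validate()` runs stratified 4-fold cross-validation. Per-class
remainders are dealt to the lightest folds, so 57/50 splits into test folds
of 27/27/27/26 with case counts within one of proportional. Each fold's
model is fitted transductively with the test fold's labels masked; a
sentinel test (flip every masked label, refit, compare parameters
bit-for-bit) guards the no-leakage property.

Metrics at threshold 0.5 on the final case probability: accuracy, F1
(positive class = case), sensitivity, specificity, Matthews correlation
(defined as 0 when a confusion margin is empty; the denominator is formed
as an exact integer product before the square root so a perfect fold gives
exactly 1), and threshold-free AUROC via mid-ranks (tied scores count
one-half). All six are cross-checked against an independent brute-force
oracle, and AUROC additionally against pROC.

`k_sensitivity()` re-runs the cross-validation for each $k$ (default
2–10) with folds, seeds and all other settings held fixed, so only the
graphs change. `feature_ablation_importance()` zeroes one feature column at
a time in the inputs fed to the trained per-fold models — the whole column,
not just the test rows, because the transductive forward pass mixes rows
through $\hat{A}$ and would otherwise re-import the feature from training
neighbours — and reports the mean drop in test-fold F1, without retraining
(a retrain-per-feature variant would cost feature-count × fold refits and
measures a different quantity: the feature's value to training rather than
to the trained predictor).

# The synthetic cohort generator

`generate_cohort()` emulates the real study's shapes: 57 cases / 50
controls, 125 species, 23 binary exposures, 10 informative species and 3
informative exposures by default. Species are log-normal compositional:
Gaussian log-abundances (sd 1), informative species shifted by
`species_effect` (default 3, i.e. three log-scale standard deviations — a
clearly separable planted signal) in cases, then exponentiated and closed
to the simplex. Exposures are Bernoulli with baseline prevalence 0.3 and a
case–control prevalence gap of 0.3 on informative exposures — odds shifts
of the size seen for strong lifestyle/comorbidity risk factors. A coupling
coefficient (default 0.3) adds each informative exposure's value into a
paired informative species' log-abundance, giving the views a shared axis
beyond the label, as exposures that shape the microbiome would.

What the generator does **not** emulate: taxon-specific mean/dispersion
profiles, zero inflation and detection limits, phylogenetic correlation
among species, exposure co-occurrence structure, batch effects. Passing
tests on these cohorts therefore demonstrates that the machinery recovers
planted signal under idealized compositional noise — not that the printed
real-data performance numbers transfer, which would require the
controlled-access cohorts themselves.

`generate_null_cohort()` sets every effect to zero and assigns labels at
random: any classifier's expected AUROC is 0.5, and the harness verifies
the fitted model sits inside [0.35, 0.65] on average. `hide_labels()`
produces stratified semi-supervised masks; the hidden truth stays available
to the *scorer* only.

# Problem sizes and determinism

Everything is keyed to one integer seed per fit (initialization, dropout,
fold shuffles, generators); two runs with the same seed agree
bit-for-bit, and the RNG state of the calling session is restored
afterwards. The test suite runs the full default-sized pipeline (107 × 125
and 107 × 23) for the signal-recovery, null-calibration, importance and
sensitivity checks, and smaller cohorts (about 50 samples, 24–40 species)
with a reduced schedule (hidden widths 16/8, 30-epoch inner fits) for
module-level properties; those sizes keep each property's check to a few
seconds while leaving the assertions comfortably away from their
thresholds.

# Known limitations

* Transductive only: predictions exist for the cohort the graphs were
  built on. Scoring a genuinely new sample means rebuilding graphs with it
  included (and ideally refitting), not applying a frozen model.
* Exactly two views and two classes; the cross-view tensor and its
  gradients are written for the 2 × 2 case.
* Co-training can stall below `max_rounds` if no unlabeled sample ever
  reaches the confidence threshold; the fit then carries a warning and an
  honest partial pool rather than forcing labels.
* The importance score inherits F1's step-function granularity on small
  test folds; features whose removal never flips a prediction tie at zero.
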