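---
title: "Methods: DBN-based subtyping of tumor transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DBN-based subtyping of tumor transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(deepsubtype)
```

This vignette documents the models, assumptions, parameter choices and
known limitations behind `deepsubtype`. It is the package's own account of
its methods; every empirical claim here is one that the test suite or
`scripts/acceptance.R` computes.

## The analysis in one paragraph

Tumor expression is reduced to a binary aberration matrix by comparing
each tumor to Gaussian fits of tissue-matched normal controls and masking
calls explained by copy-number dosage. After removing near-constant and
tissue-confounded genes, a stack of Bernoulli restricted Boltzmann
machines (RBMs) is pre-trained by contrastive divergence, unfolded into a
deep autoencoder, and fine-tuned by cross-entropy backpropagation; the top
hidden layer is each tumor's representation. Subsampled consensus
clustering of these representations, scored by the proportion of ambiguous
clustering (PAC) and pooled across an ensemble of independently trained
models, yields the final subtype assignment, which is read out through
Kaplan–Meier/log-rank survival analysis and per-cluster correlate tables.

## Aberration calling

For each (gene, tissue) pair the control samples of that tissue — and only
those — define a Gaussian N(μ, σ²). The SD uses the unbiased n−1 divisor
(`sd_divisor = "n"` gives the MLE instead). A tumor value is called +1/−1
when beyond μ ± zσ with `z = qnorm(1 - tail)`.

Two interpretive choices deserve note:

* **Tail mass.** "Outside the 0.001 percentile on either side" is read as
  two one-sided tails of mass 0.001 each (z ≈ 3.09), giving a null call
  rate of 0.002 per gene. The alternative reading (0.0005 per side) is
  available by setting `tail = 5e-4`. The calibration check in the
  acceptance suite (null cohort, effect size 0) measures ~0.002.
* **Low-variance branch.** When control σ < `low_sd` (default 0.2
  expression units) the Gaussian tail is numerically meaningless and a
  fold-change rule applies: +1 at ≥ 3-fold the control mean, −1 at ≤ 1/3
  of it — symmetric on the ratio scale, which is the natural symmetry for
  a fold change. σ exactly equal to `low_sd` stays on the Gaussian branch
  (the rule is for SDs *smaller than* the threshold). The fold rule
  requires strictly positive control means; the generator guarantees a
  positive expression scale (means ≥ 5 SD above zero) so it is always well
  defined on synthetic data.

Masking: a +1 call co-occurring with copy-number score ≥ +1, or a −1 call
with ≤ −1, is attributed to dosage and zeroed; ±2 scores, if present, act
like ±1. Masking can only remove calls, never create them, and the full
audit (sample, gene, call, cnv, masked) is attached to the matrix and
written as a TSV.

## Feature filters

`bernoulli_variance_filter(m, p = 0.90)` removes genes whose fraction of
1s (or of 0s) is ≥ p; ties at exactly p are removed. Setting p = 0.95
keeps more genes, p = 0.70 keeps only high-variance genes.
`tissue_correlation_filter(m, tissue, r_max = 0.85)` removes genes whose
Pearson correlation with any tissue's one-hot indicator exceeds r_max *in
absolute value* — an anti-correlated tissue marker identifies tissue just
as well as a correlated one, so signed correlation would leave an obvious
confounder in place. Constant genes, whose correlation is undefined, are
removed with reason `"constant"`. Both filters are idempotent, preserve
gene order, and are monotone in their thresholds (tested properties).

## RBM and autoencoder training

An RBM with visible units v, hidden units h has energy
E(v, h) = −hᵀWv − cᵀv − bᵀh and joint P(v, h) = e^(−E)/Z. Training uses
minibatch CD-1 by default (`cd_steps` is configurable): the positive phase
uses mean-field hidden probabilities for the gradient statistics but
samples binary hidden states to start the Gibbs chain; reconstructions use
visible probabilities rather than samples. Upper RBMs consume the hidden
*probabilities* of the layer below. Weights start at N(0, 0.01²), offsets
at zero; batch order is reshuffled each epoch from the run seed. No
momentum or weight decay by default (both available). All units are
logistic/Bernoulli — the data are binary, so no Gaussian visible units are
needed.

Unfolding copies each RBM's weights into an encoder layer (W, b) and an
independent decoder layer (Wᵀ, c); from that point the copies evolve
separately. Fine-tuning is plain minibatch SGD on the mean binary
cross-entropy between input and reconstruction, with deterministic
probabilities everywhere (no stochastic states). Because the output layer
is logistic with cross-entropy loss, the output delta reduces to
(ŷ − x); hidden deltas carry the usual σ′ factors (the implementation is
verified against finite-difference gradients in development and against
hand-computed reconstruction metrics in the tests). The training log
records per-epoch cross-entropy and MSE (plus held-out MSE when an
evaluation set is supplied). Fine-tuning aborts with a diagnostic if
cross-entropy exceeds 10× its initial value.

**Default training strength.** Deep sigmoid autoencoders trained by plain
SGD suffer vanishing gradients when pre-training is weak: the encoder
barely moves and every sample maps to nearly the same code. At the
package's desk scale (tens to hundreds of samples, 50–200 genes) the
defaults `lr_pretrain = 0.5`, `epochs_pretrain = 50`, `lr_finetune = 0.5`,
`epochs_finetune = 100`, `batch_size = 50` reliably avoid this collapse;
with weak settings (e.g. 10 pre-training epochs at lr 0.05) the encodings
of some seeds degenerate and clustering fails. Users fitting larger
matrices should expect to re-tune via the `modelsel` functions — that is
what they are for.

**Serialization** is a flat JSON container (layer matrices written with 17
significant digits, which round-trips IEEE doubles bit-exactly) holding
the encoder/decoder weights, layer sizes, gene ids and training log. JSON
keeps the artifact plain-text and diffable.

## Model selection

`make_folds(n, k = 8, n_eval = 4)` builds a seeded 8-fold split of which
only the first four folds (in seeded order; which four is arbitrary and
fixed by the seed) are evaluated — halving the cost while still training
on 7/8 of the data each time. `evaluate_config` trains on each evaluated
fold's complement and records held-out MSE after every fine-tuning epoch.
Early stopping is deliberately not used; configurations run their fixed
epoch budget.

**Overfit flag.** A configuration is flagged when, averaged over evaluated
folds, the final held-out error exceeds that fold's own minimum by more
than 5% (relative). The per-fold-then-average form matters: averaging the
curves first lets one fold's rebound be diluted by another's plateau, and
visibly overfit bottleneck architectures (tiny top layer under an
oversized first layer, few samples) then escape the flag.

**Elbow.** `find_elbow` reports the size at the maximum discrete second
difference of the error-vs-size curve. It is reported, not auto-applied —
architecture choice remains an inspection decision, and the elbow
diagnostics table is attached for that purpose. On synthetic cohorts whose
variation is driven by 8 independently activatable transcription factors,
the single-layer error curve flattens at the true latent count: the
acceptance suite checks that the elbow lands in [6, 10] and that the error
drop from 4→8 units dwarfs the drop from 8→16.

The elbow experiment uses effect size 6 (gene calls almost deterministic
given TF state, so the data are essentially rank-8 and extra hidden units
buy nothing once training converges) and 160 tumors. The overfitting
experiment instead uses 16 tumors and effect size 2.5 (noisy calls), so a
[64, 2] network has both the capacity and the incentive to memorize
training noise that does not transfer to held-out folds.

## Consensus clustering and PAC

Each trial draws ⌊0.8·n⌋ samples without replacement and clusters them
hierarchically (Euclidean, average linkage). The consensus entry for a
pair is co-clustered trials / co-sampled trials; pairs never co-sampled
(essentially impossible at 100 trials and 80% sampling, but possible in
pathological settings) are imputed 0 and counted in the object. The final
assignment clusters 1 − consensus as a dissimilarity with the same
linkage, mirroring the trial-level method.

PAC is the fraction of off-diagonal pairs with consensus strictly between
0.2 and 0.8; boundary values count as unambiguous (configurable). k is
chosen by minimum PAC with ties broken toward smaller k. A caution
observed in testing: when planted clusters are unevenly spaced, k smaller
than the truth can also be unambiguous (the same two clusters always
merge), tying PAC at 0 — with equidistant clusters the ambiguity of
under-clustering is visible and the PAC minimum identifies the planted k.

The consensus of consensus pools per-model consensus matrices by
elementwise mean — an equal-vote ensemble; pooling the models' final
co-assignment indicators instead is available via `pool = "assignment"`.
Mean pooling was chosen because it preserves each model's full uncertainty
rather than its hardened labels.

## Survival and correlates

The Kaplan–Meier estimator and the g-sample log-rank test are implemented
directly (product-limit with aggregated tied event times; hypergeometric
variance with the (n−d)/(n−1) ties correction; statistic
(O−E)ᵀV⁻¹(O−E) on g−1 groups). The `survival` package is used in the test
suite as an independent oracle, not in the implementation. Correlates are
Pearson correlations of each binary feature against each cluster's
one-vs-rest indicator — the natural reduction of "correlation with a
cluster" for a multi-class label; top-10 lists rank positive correlations
only, the full signed table is exported alongside, zero-variance features
are excluded with a logged reason, and no multiple-testing correction is
applied (n is exported so users can add one). Word-cloud weights are
scaled within each cluster only (max r → 1.0); they are deliberately not
comparable across clusters.

## The synthetic cohort generator

The generator emulates exactly the structure the analysis assumes:

* **Controls** are Gaussian per (gene, tissue), with means and SDs drawn
  uniformly from configurable ranges. Means are required to sit ≥ 5 SD
  above zero so the expression scale is strictly positive and fold
  changes are defined. Gaussian noise is a modeling assumption shared
  with the aberration caller, not a claim about real RNA profiling noise.
* **Subtypes** activate a fixed, deterministic subset of latent
  *processes* (distinct non-empty subsets ordered by size, so subtypes
  are identifiable); active processes cascade deterministically to
  pathways and transcription factors, and each active TF shifts its
  target genes by ± effect_size control SDs (direction fixed per TF at
  generation, Bernoulli(0.5)). Every gene has exactly one TF, every TF
  one pathway, every pathway one process — a clean tree rather than the
  overlapping regulons of real cells.
* **Copy-number events** occur independently per (tumor, gene) at
  `cnv_rate`, sign ±1 equally likely, and shift expression by
  `cnv_expression_shift` SDs with matching sign — so the masking rule is
  exactly right on synthetic data.
* **Mutations**: each subtype gets `mutations_per_subtype` disjoint driver
  genes mutated at `mutation_enrichment` (default 0.6) against a 0.05
  background. Setting `mutations_per_subtype = 0` disables driver
  planting; this is needed for many-subtype designs (e.g. the 8-TF
  factor cohorts, up to 255 subtypes) where disjoint driver sets cannot
  fit in the panel.
* **Survival** is exponential with subtype hazard ratios (defaults 1, 2,
  4 over baseline 0.1 events/time unit) under independent exponential
  censoring whose default rate (3/7 of the mean hazard) yields ~30%
  censoring. No covariates, no time-varying hazards.

Because the generator satisfies the caller's assumptions *by
construction*, passing tests demonstrate internal correctness and
recoverability of planted structure — not robustness to real-data
violations (counts, batch effects, library size, overlapping pathways,
non-exponential survival), which are explicit non-goals.

**Default scale.** The default cohort (2 tissues × (100 tumors + 30
controls), 200 genes, 3 subtypes, effect size 3) and the default ensemble
(six seeded three-layer models around [60, 25, 10]) run end to end in
about a minute on one CPU; the test and acceptance runs use cohorts from
~16 to 1000 tumors depending on what each check needs (power analyses use
more, overfitting demonstrations use fewer).

## Numerical choices and degenerate inputs

* Reconstruction probabilities are clipped to [1e−12, 1−1e−12] inside the
  cross-entropy only, so the loss is always finite.
* The log-rank variance matrix is inverted with `solve`, falling back to a
  pseudo-inverse via SVD when a group's risk set makes it singular.
* `consensus_cluster` subsample size is max(2, ⌊fraction·n⌋); k = 1 and
  fraction = 1 are valid degenerate settings (single cluster; no
  subsampling randomness).
* Enumeration oracles (`rbm_exact_distribution`, `rbm_exact_loglik`)
  refuse more than 20 total/visible units; they exist for testing, not
  analysis.
* All seeds handed to derived runs are reduced modulo 2³¹ to stay within
  R's integer range.

## Known limitations

* Plain SGD and CD-1 are faithful to the method but slow to converge on
  large matrices; there is no GPU path, momentum/decay are off by
  default, and the wake-sleep ("up-down") fine-tuning variant is not
  implemented.
* PAC-based k selection inherits PAC's known weakness for k = 2 and for
  unevenly spaced clusters (see above).
* The correlate tables report raw correlations; significance and effect
  size interpretation are left to the user.
* The pipeline's resume mechanism trusts stage checkpoint markers; it
  does not hash-verify that upstream artifacts are unchanged since the
  interrupted run.
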