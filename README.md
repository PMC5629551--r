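# deepsubtype

Unsupervised discovery of tumor molecular subtypes from bulk expression
cohorts, using deep-belief-network representation learning and consensus
clustering.

Cancer transcriptomes mix physiological, tissue-specific and pathological
signals. `deepsubtype` implements an analysis strategy that (1) reduces a
tumor's profile to the genes that are *aberrantly* expressed relative to
tissue-matched normal controls, (2) learns a low-dimensional hierarchical
representation of those binary aberration profiles with a stack of
restricted Boltzmann machines unfolded into a deep autoencoder, and
(3) finds robust sample clusters in the learned representation, reading
them out clinically through survival curves and per-cluster gene/mutation
correlates. It is aimed at computational biologists who want a fully
scripted, reproducible version of this workflow, together with a synthetic
cohort generator that makes every stage testable without patient data.

## The model

**Aberration calling.** For each gene *g* and tissue *t*, expression in the
normal controls is fit as Gaussian N(μ, σ²). A tumor's value *x* is called
aberrant when it falls outside the two-sided tails of mass 0.001 per side
(`x > μ + zσ` or `x < μ − zσ`, z = Φ⁻¹(0.999) ≈ 3.09). Genes with control
σ < 0.2 use a symmetric 3-fold-change rule instead. Calls whose direction
matches a discrete copy-number score (up-regulation with amplification,
down-regulation with deletion) are masked, since those changes are driven
by dosage rather than signaling. Near-constant genes (aberrant or silent in
≥ 90% of tumors) and genes correlated |r| > 0.85 with any tissue indicator
are removed.

**Representation learning.** Each restricted Boltzmann machine is a binary
latent-variable model with energy

    E(v, h) = −hᵀWv − cᵀv − bᵀh,   P(v, h) = e^(−E) / Z,

trained by contrastive divergence (CD-1) to maximize the marginal
likelihood of the visible layer. RBMs are pre-trained layer by layer, each
consuming the hidden probabilities of the one below, then unfolded into a
deep autoencoder (encoder = bottom-up weights, decoder = untied top-down
copies) and fine-tuned end to end by stochastic gradient descent on the
binary cross-entropy between the input and its reconstruction. The top
hidden layer is the sample representation.

**Clustering and readout.** Consensus clustering repeats hierarchical
clustering (Euclidean distance, average linkage) on 100 random 80%
subsamples; the consensus matrix entry for a pair is the fraction of
co-sampled trials in which they co-clustered. The proportion of ambiguous
clustering (PAC) — pairs with consensus strictly between 0.2 and 0.8 —
scores candidate cluster numbers. Consensus matrices from independently
trained models are pooled elementwise (a consensus of consensus, one vote
per model) before the final cut. Clusters are compared by Kaplan–Meier
curves with a g-sample log-rank test and characterized by the top-10
positively correlated aberrant genes and mutations (one-vs-rest Pearson).

## Worked example

```r
library(deepsubtype)

cfg    <- cohort_config(seed = 7)          # 2 tissues, 200 tumors, 200 genes
cohort <- generate_cohort(cfg)
#> expression_cohort: 260 samples (200 tumors, 60 controls) x 200 genes, 2 tissues
#> planted subtypes: 1:68 2:66 3:66

ab   <- cohort_aberrations(cohort)         # binarize vs controls, mask CNV
kept <- filter_features(ab, cohort$tissue[cohort$is_tumor == 1])
#> feature_filter_report: 180 genes kept, 20 removed

model <- train_dbn(kept$kept,
                   train_config(c(60, 25, 10), batch_size = 50, seed = 7))
#> dbn_model: 180 visible -> [60-25-10], fine-tuned 100 epochs (final CE 0.2375/unit)

enc <- dbn_encode(model, kept$kept)        # 200 x 10 top-layer encodings
cc  <- consensus_cluster(enc, k = 3, trials = 100, seed = 7)
#> consensus_matrix: 200 x 200, 100 trials at 80% subsampling, PAC 0.000

truth <- cohort$true_subtype[cohort$is_tumor == 1]
adjusted_rand(cc$assignment$labels, truth)
#> [1] 1

tum <- cohort$is_tumor == 1
logrank_test(cohort$survival_time[tum], cohort$survival_event[tum],
             cc$assignment$labels)
#> chi-square 44.52 on 2 df, p = 2.15e-10
```

PAC 0 means every sample pair either always or never co-clusters — a fully
stable partition; the adjusted Rand index of 1 confirms the three planted
subtypes were recovered exactly, and the log-rank test shows they carry
the planted survival differences (hazard ratios 1, 2, 4).

`run_pipeline(pipeline_config(out_dir = "run1", seed = 1))` executes the
whole chain — simulation (or a cohort directory), aberration calling,
filtering, a six-model DBN ensemble, per-model consensus clustering,
PAC-based choice of k, consensus-of-consensus assignment, survival and
correlate tables — writing every artifact plus an MD5 manifest under
`run1/`.

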