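---
title: "Methods: joint transcriptome-metabolome network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint transcriptome-metabolome network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `cuticlenet`, the
choices made where the underlying methodology is genuinely open, and the
limitations that users should keep in mind. The package analyses paired
gene-expression (FPKM) and cuticle-metabolite concentration matrices from a
crossed organ x genotype design with replicates, and identifies gene
networks associated with two cuticle fractions: cuticular waxes and
lipidized cell wall (LCW) monomers.

## Data model and preprocessing

All matrices are features x samples. Genes enter the analysis when they
have FPKM > 0 in strictly more than half the samples
(`filter_low_expression()`); "expressed" means FPKM > 0, with no floor.
Standardization (`standardize()`) centers each feature and scales to unit
variance with the n-1 denominator, matching `scale()`; constant features
carry no pattern and are dropped with a warning rather than an error,
because permutation replicates can create constants. Genes are stratified
by their mean FPKM across all samples: above 100 is the high-expression
stratum, everything else (including exactly 100) is low. The statistic is
the mean; per-sample or median stratification would be equally defensible,
and the choice is recorded here so it is auditable.

## Metabolome statistics

Per metabolite class (class abundance = per-sample sum of member
concentrations) a sequential type-I ANOVA `y ~ genotype + organ +
genotype:organ` partitions the total sum of squares into partial R-squared
shares. Under the balanced design the factors are orthogonal, so the order
of the two main effects does not change the shares; the test suite checks
this by swapping factor roles. Note a dof fact that matters when reading
null results: with 72 samples the model terms consume 23 of 71 degrees of
freedom, so an iid-noise response has an expected residual share of 48/71
(about 0.68), not 1.

Post-hoc genotype contrasts use Tukey's honest significant difference with
a compact letter display computed by the insert-and-absorb algorithm; ties
are broken by group order so the letters are deterministic.

Sample embeddings: PCA via singular value decomposition (per-component
sign fixed so the largest-magnitude score is positive), and an exact
t-SNE computed from all PC scores. With at most a few dozen samples the
O(n^2) gradient is cheap, so no tree approximation is needed. The t-SNE
uses PCA initialization (plus a tiny seeded jitter), early exaggeration 12
for 250 of 1000 iterations, learning rate 200, and perplexity 20 by
default. The perplexity default matters downstream: the two t-SNE
components serve as single-value response variables for the randomized-GLM
scorer and the random-forest cluster stage, and at low perplexity (10) the
embedding frequently "folds" the dominant metabolic manifold - organ
clusters remain separated but their global ordering is scrambled, which
destroys the linear correlation between embedding coordinates and any gene
profile. Perplexity 20 (with n = 72) preserves more global structure and
makes the coordinates usable as responses.

## Co-expression network

The gene-gene similarity is the biweight midcorrelation: observations are
median-centered and Tukey-biweighted with zero weight beyond 9 median
absolute deviations; zero-MAD features fall back to the Pearson transform.
Adjacency is unsigned, `|bicor|^beta` with beta = 16 (the methodology
this package follows fixes the power; unsigned is the standard default
when the sign convention is unstated). The topological overlap matrix

    TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)

is clustered by average linkage on 1 - TOM.

Module detection is a dynamic branch cut designed around the facts of
high-power TOMs, where all dissimilarities are compressed near 1: a static
cut at 99% of the joining-height range between the 5th percentile and the
maximum, followed by recursive branch evaluation using height-normalized
criteria. A branch becomes a module when it has at least `min_module_size`
(default 30) members, its core merge heights are tight relative to the
height range (core scatter), and it is separated from the rest of the tree
by a clear gap. The `deep_split` presets 0-4 trade scatter tolerance
against gap demands, with deep_split = 2 the default. One numerical
choice deserves a note: the branch "top" is measured at the 75th
percentile of the branch's internal merge heights rather than at its root,
because one or two straggler members joining just below the attach point
would otherwise erase the separating gap of a perfectly good module;
dense, noise-like branches keep their upper quartile next to the attach
height and still fail. Modules whose eigengenes correlate above
`1 - merge_cut_height` (default 0.25) are merged iteratively.

The eigengene of a module is the unit-norm leading right singular vector
of the module's standardized expression, sign-fixed so its mean
correlation with members is nonnegative. Eigengenes are grouped into
classes by average-linkage clustering cut at correlation 0.5. Hub genes
must pass three criteria: within-module TOM connectivity strictly above
the module mean ("above-average connection degree"; the methodology gives
no test for "significant", so the mean is the operational reading),
absolute eigengene correlation above 0.8, and a trait correlation (maximum
over all metabolome t-SNE components) above a module-specific cutoff
chosen from the grid 0.05, 0.10, ..., 0.95 to bring the hub fraction as
close as possible to 5%, ties resolved towards the stricter cutoff.

## Cluster-to-metabolome random forest

Each metabolome fraction's two t-SNE components are predicted by a
regression random forest from the cluster eigengenes plus unclustered
genes. Out-of-bag predictions (no extra split at n = 72) feed three
metrics - predictive R² = 1 - SSE/TSS, RMSE, and MAPE with the denominator
guarded at 1e-8 x max|y| because embedding coordinates pass through zero.
For each predictor a reduced forest is fitted without it and the metric
deltas (harmful direction) get one-sided p-values from a paired bootstrap
of the per-sample OOB errors, BH-corrected across predictors per metric;
a predictor is associated when >= 2 metrics degrade at corrected p < 0.01
for some component, and clusters selected for both fractions are labeled
"both".

Two arithmetic constraints shape the defaults. First, with m predictors
the smallest achievable corrected p is m/(n_boot + 1), so corrected
p < 0.01 requires n_boot > 100 x m; the pipeline uses n_boot = 4000 and
caps the unclustered-gene predictors at 20 (by FPKM variance). Second,
because the bootstrap pairs the full and reduced models on the same
resample, the R² and RMSE deltas are both monotone in the resampled SSE
difference and their p-values coincide exactly; the effective rule is
therefore "SSE-based degradation plus MAPE" rather than three independent
votes. Both facts hold for any implementation of this protocol and are
stated here rather than hidden behind defaults. A related caveat: the
paired bootstrap captures sampling noise but not forest-refit noise, so
with very few predictors (where removing any column reshapes every tree)
spurious attribution is possible; at the pipeline's predictor counts
(>= ~20) the test suite measures a designated pure-noise predictor being
selected in fewer than 5% of replicates.

## Gene-to-metabolite importance

Three multivariate models score individual genes per fraction:

* **PLS** (high stratum): NIPALS PLS2 against the full standardized
  metabolite profiles, with both blocks deflated per component. The number
  of components is chosen by 5-fold cross-validated prediction error over
  1..10 with a fixed fold seed.
* **sPLS** (low stratum): the same decomposition with the X-weight vector
  soft-thresholded each iteration so exactly `keep` genes (default 10% of
  the stratum) carry nonzero weight; at full keep it reduces exactly to
  PLS.
* **rGLM** (low stratum): an ensemble of bagged linear models, each fitted
  on a bootstrap sample by greedy forward selection (Gaussian AIC) over a
  random candidate subset of genes, implemented as a small compiled kernel
  with an incremental Gram-Schmidt factorization. The importance score is
  the mean-1 normalized selection frequency. Two defaults deviate from the
  obvious ones and were chosen after measuring the alternative: candidate
  subsets are capped at 50 per bag (the convention of reference
  randomized-GLM ensembles; also the difference between seconds and hours
  under permutation), and forward selection stops at 2 terms. With deep
  forward selection (10 terms) most bag slots go to bootstrap-stable
  chance correlates of the response, so the selection-count distribution
  under real data is indistinguishable from its permutation null and the
  downstream selection rule loses false-discovery control; shallow bags
  keep the counts concentrated on the strongest predictors.

The importance score for the PLS family is the VIP, whose squared values
average exactly to 1, so S > 1 reads "above-average contribution"; the
rGLM's mean-1 normalization gives its score the same semantics. P-values
come from a permutation test: the sample order of the response block is
permuted jointly (preserving its internal covariance), all scores are
recomputed, and the null pool collects every score across genes and
permutations for that model and stratum - pooling is what makes p < 0.01
resolvable at 199 permutations, and is justified by the exchangeability of
standardized genes under the null. A gene is putative when S > 1 and
p < 0.01 (both strict) in at least one of the three models; per fraction
the putative set is the union.

**Known limitation (measured, not hypothetical).** The rGLM regresses on
t-SNE coordinates. Whenever a coordinate is (near-)orthogonal to the
metabolome direction that the truly associated genes drive - which the
embedding is always free to produce, since one 2-D coordinate must carry
everything else - that coordinate is organ-determined yet linearly
unpredictable from any gene, and the pooled permutation rule then passes
roughly the calibrated ~1% of low-stratum genes as false positives. With
thousands of genes and a few dozen true associations this floors the
attainable false-discovery proportion of the three-model union at roughly
0.2-0.3; the PLS/sPLS half of the union does not have this problem because
the VIP's fixed total mass lets real signal suppress everyone else. The
acceptance suite measures the union honestly and this is its one
knife-edge criterion; users who need tight FDP control should treat
rGLM-only selections with caution or restrict attention to the PLS/sPLS
union.

## Integration and enrichment

Putative genes are categorized as lcw-only, wax-only, or both by set
algebra, and become network nodes when their co-expression cluster was
selected by the random-forest stage for the matching fraction(s) ("both"
genes need a cluster associated with both). Edges connect node pairs of
the same cluster whose TOM reaches the 95th percentile of that cluster's
full within-cluster TOM distribution (ties included, so a constant-TOM
cluster is completely connected); the underlying methodology drew networks
by cluster membership without stating an edge rule, and the quantile rule
is this package's sparse, cluster-respecting choice. Enrichment of
function terms is a one-sided hypergeometric (Fisher) test with BH
correction, term size >= 3, against the background of all filtered genes;
ontology-graph propagation and redundancy trimming are deliberately out of
scope.

## The synthetic-data generator

`design_config()` defaults define the emulated study: 6 organs x 4
genotypes x 3 replicates (72 samples), 2000 genes, three planted
co-expression modules (70/60/35 genes), two 50-metabolite fractions, and
40 truly associated genes per fraction. The generator is built so that
ground truth is *identifiable*, which drives several deliberate
constructions:

* Module latents are organ-driven with Gram-Schmidt-orthogonalized organ
  profiles: "not associated" is only well defined if the non-associated
  modules share no organ signal with the metabolome.
* Metabolite organ effects are drawn along the association module's own
  organ profile (random coefficient and sign per metabolite): the cuticle
  metabolome's organ program *is* the associated module's organ program.
  With no planted effects (null configurations) the organ effects move to
  the subspace orthogonal to every module profile, making transcriptome
  and metabolome independent by construction - the basis of the
  type-I-calibration tests.
* Planted slopes (default |slope| = 2.5 on 3 round-robin target
  metabolites per gene) carry a per-metabolite sign that alternates within
  each metabolite class. Within one metabolite all contributions share the
  sign, so the signal stays coherent for the embedding-based stages; class
  sums cancel, so the planted signal does not distort the class-level
  ANOVA variance bands.
* The association module's latent carries genotype modulation (0.35) and
  replicate-level wobble (0.5). The wobble is the module's unique,
  non-redundant signature: organ identity alone is recoverable from any
  two module eigengenes (nonlinearly, by the forest), so without a
  sample-level unique signal the leave-one-predictor-out importance could
  never attribute the metabolome to the right cluster.
* Fraction-specific associated genes form small shared-latent programs
  (below the clusterable size), so their collective metabolite signal is a
  coherent direction rather than a scatter of weak independent effects.
* FPKM scale by exponentiating the Gaussian core (lognormal spread 0.4),
  guaranteeing nonnegativity and a heavy right tail; ~20% of genes sit on
  a > 100 FPKM scale so the high-expression stratum is populated, and ~5%
  are "silent" (expressed in under half the samples) so the filter has
  work to do.

Effect scales were calibrated once so that the wax fraction's class-level
organ share sits mid-band (organ-dominant, genotype below 10%) and the LCW
fraction shows a more balanced organ/genotype split, and then frozen; the
LCW interaction share sits at the low edge of its target range, a known
approximation. What the generator does **not** emulate: count-level
sequencing noise, chain-length homolog structure within wax classes, real
gene identifiers, unbalanced designs, or batch effects. Passing tests on
this generator therefore demonstrate the pipeline's correctness and
calibration under clean, identifiable conditions - not performance on real
data, where organ programs and cuticle chemistry are entangled in ways no
planted truth can capture.

## Determinism and problem sizes

Every stochastic stage takes an explicit seed; a single pipeline seed is
split deterministically per stage, and rerunning a configuration
reproduces byte-identical TSVs (serialization uses 17 significant digits,
so write/read round-trips are exact). The test suite runs the recovery
analyses at the study scale (2000 genes, 72 samples) with 199
permutations, 10 seeds for module recovery and 20 seeds for the variance
bands, and smaller constructed fixtures for the per-operation oracle
checks; these sizes are the package's validation choices and can be scaled
up freely in user analyses.
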