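# cuticlenet

Joint transcriptome–metabolome network analysis of plant cuticle deposition.

The plant cuticle is an extracellular lipid barrier built from two
chemically distinct parts: solvent-extractable **cuticular waxes** (VLCFAs,
fatty alcohols and aldehydes, wax esters, hydrocarbons, terpenes) and the
ester-linked monomers of **lipidized cell wall (LCW) biopolymers** (cutin
and suberin: fatty acids, hydroxy-fatty acids, phenolics). Which genes
support the deposition of which fraction is a systems-level question:
expression and cuticle composition both vary strongly across seedling
organs and more weakly across genotypes, so single-gene correlations are
hopelessly confounded. `cuticlenet` implements a two-pipeline strategy for
paired expression/metabolome profiles from a crossed organ × genotype
design (the package emulates a 6-organ × 4-genotype × 3-replicate maize
seedling study, 72 samples):

1. **WGCNA–RF pipeline** — weighted gene co-expression network analysis:
   biweight midcorrelation, unsigned soft-threshold adjacency
   `a_ij = |bicor(x_i, x_j)|^β` with β = 16, topological overlap
   `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
   average-linkage clustering with a dynamic branch cut, module eigengenes
   (leading right singular vectors), eigengene classes (r > 0.5), and
   three-criterion hub genes (above-average intramodular connectivity,
   eigengene correlation > 0.8, trait correlation above an adaptive cutoff
   targeting a ~5% hub quota). A random-forest regression of the
   metabolome's t-SNE components on cluster eigengenes plus unclustered
   genes then scores each cluster by leave-one-predictor-out degradation of
   predictive R², RMSE and MAPE, with paired-bootstrap p-values and BH
   correction (selected when ≥ 2 metrics degrade at corrected p < 0.01).
2. **Multi-omics integration pipeline** — per-gene importance scores `S`
   from three multivariate models: multi-response PLS (high-expression
   stratum, > 100 FPKM), sparse PLS and a randomized-GLM ensemble
   (low-expression stratum). For the PLS family, `S` is the variable
   importance in projection,
   `VIP_j = sqrt(p · Σ_a SSY_a w_aj² / Σ_a SSY_a)` (so `mean(S²) = 1`);
   for the rGLM, `S` is the mean-1 normalized bag-selection frequency.
   Significance comes from a permutation test with the null pooled over
   genes, and a gene is putatively cuticle-related when `S > 1` and
   `p < 0.01` in at least one model.

The two pipelines intersect into three gene networks (LCW-only, wax-only,
shared), with within-cluster TOM edges and optional Fisher-exact
function-term enrichment.

Everything is exercised on a synthetic data generator
(`generate_dataset()`) with planted co-expression modules, planted
gene→metabolite slopes, and the study's organ-dominant variance structure,
so every stage can be validated against known ground truth.

## Worked example

```r
library(cuticlenet)

res <- run_pipeline(
  pipeline_config(seed = 1, simulate = list(n_assoc_both = 35L)),
  out = "run1")

res$manifest$counts[c("n_genes_filtered", "n_clusters", "n_hub_genes")]
#> $n_genes_filtered   1900
#> $n_clusters            3
#> $n_hub_genes           7

median(res$stats$wax$anova$partial_R2_organ)       # 0.590
median(res$stats$wax$anova$partial_R2_genotype)    # 0.011
lengths(res$putative)                              # lcw 55, wax 49
nrow(res$network$nodes)                            # 35
```

Reading: of 2000 simulated genes, 1900 are expressed in more than half the
samples; the three planted co-expression modules are recovered exactly
(adjusted Rand index 1.0 against the planted labels); organ explains ~59%
of the wax-class variance and genotype ~1%, matching the organ-dominant
design; the multivariate union flags 55 (LCW) and 49 (wax) putative genes,
of which 75 of the 80 planted genes are recovered (sensitivity 94%); and
the integrated "both fractions" network contains all 35 members of the
planted association module. All outputs are also written as TSV (plus a
GraphML network and a JSON run manifest) under `run1/`.

A thin command-line wrapper lives in `inst/cli/cuticlenet.R`
(`simulate` and `run-all` subcommands).

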