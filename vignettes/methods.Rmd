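---
title: "Methods: proteogenomic multi-omics analysis with pgomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteogenomic multi-omics analysis with pgomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgomics)
```

pgomics re-implements, as a tested and reusable pipeline, the statistical
machinery of an integrative proteogenomic study of paired tumor and
non-tumor adjacent tissue (NAT): mutational-signature decomposition,
copy-number cis/trans-effect screening, tumor/NAT differential expression,
single-sample pathway and kinase/TF activity scoring, consensus-clustering
subtype discovery, and survival stratification. Every stage can be exercised
against synthetic cohorts with planted, recorded ground truth, so the whole
stack is verifiable without access to any deposited patient data.

## The synthetic cohort generator

`generate_cohort()` emulates the *statistical structure* of a paired
tumor/NAT multi-omics cohort; it makes no attempt at biological realism at
the level of spectra, peptides or genome coordinates.

* **Paired design.** Each patient contributes one tumor and one NAT sample.
  mRNA and protein abundances live on the log2 scale: a per-gene baseline
  (`N(5, 1.5)`) shared by all samples plus unit-SD sample noise. This shared
  baseline reproduces the strong between-sample correlation real profiling
  data always shows.
* **Tumor/NAT effects.** A configurable fraction of genes (defaults 30% up,
  11% down, matching the proportions reported by deep tumor/normal
  proteome comparisons) receives a log2 fold change drawn from
  `N(2, 0.5)` with the appropriate sign.
* **Cis effects.** Selected genes add `slope x CNA` to both mRNA and
  protein, with CNA log-ratios `N(0, 0.5)` and slopes `N(0.8, 0.1)`.
* **Subtypes.** Disjoint programs of `program_size` genes (default 100, the
  scale of a coherent expression program; capped at
  `floor(n_genes / (2 n_subtypes))` so programs stay disjoint at toy sizes)
  are shifted by `subtype_shift` noise-SDs (default 2) in the tumors of one
  subtype each.
* **Phosphoproteome.** Sites inherit 0.6 of their parent protein's signal
  plus site noise; substrate sets of "active" kinases gain a tumor shift
  (default +1.5) so kinase-activity inference has a recoverable target.
* **Mutations.** Reference signatures are sparse Dirichlet draws over the
  96 canonical trinucleotide channels (concentration 0.1, which yields the
  spiky profiles typical of real single-base-substitution signatures);
  per-tumor exposures are Dirichlet(0.5); counts are Poisson with
  multinomial channel assignment. Using synthetic rather than
  database-derived reference signatures keeps the package self-contained
  while exercising the identical cosine-matching code path.
* **Missingness.** Protein/phospho dropout is intensity dependent
  (probability decreasing with the value's within-gene standing, overall
  rate configurable) to mimic mass-spectrometry dropout; a missing value is
  always distinct from zero.
* **Survival.** Event times are exponential with hazard
  `baseline_rate(subtype) x exp(lp)`, `lp` combining subtype and marker
  protein effects, under independent exponential censoring.
* **Determinism.** Every layer draws from its own RNG stream derived from
  `rng_seed`, so enlarging one layer never perturbs another, and identical
  configs produce bit-identical cohorts.

What passing tests on these cohorts does *not* show: robustness to batch
effects, tumor heterogeneity/subclonality, peptide-level quantification
artifacts, or non-proportional hazards — none of which the generator
emulates.

## Mutational signatures

`build_catalog()` maps every contextful SNV onto one of the 96
pyrimidine-centred channels (6 substitution types x 16 flanking contexts in
alphabetical order; purine-reference records are reverse-complemented on
input). `factorize()` runs multiplicative-update NMF under the Frobenius
objective — the standard, deterministic-under-seeding choice for signature
extraction — with 10 random restarts by default, a 5,000-iteration cap and a
1e-6 relative-error stopping rule. Signature columns are L1-normalized with
the compensating scale folded into the exposures.

**Choosing the number of signatures.** `select_k()` concretizes "the minimal
number of components that explains the variance" as a scree rule: the
per-step improvement in relative reconstruction error, *normalized by the
error at the smallest candidate k*, must stay above an elbow threshold
(default 0.05). Normalizing each step by the previous k's error instead is
scale-unstable: once the true signal is captured, every additional noise
component still trims a few percent of an already-small residual, and k is
systematically over-selected. The chosen k must additionally be stable
across restarts (mean within-k signature cosine >= 0.8), otherwise it is
decreased. `match_to_reference()` reports, for each extracted signature, the
arg-max-cosine reference profile; cosine similarity is scale invariant, so
normalization conventions cannot affect matches.

## Differential expression and biomarker cascades

`compare_groups()` supports Welch t (default; a pooled-variance flag
restores the classic Student form), Wilcoxon rank-sum, one-way ANOVA and
Kruskal-Wallis. Fold changes are computed on the linear scale (log2 input is
exponentiated first) and a feature is called up/down only when both
|FC| > `fc_thresh` (default 2) and BH-adjusted q < `q_thresh` (default
0.05). Features observed in fewer than `min_obs` samples of any group
(default 30% of the group) are skipped and counted. Row z-scores use the
sample-SD (n-1) convention, matching base R's `scale()`; constant rows
become all-missing.

Two screening cascades mirror common biomarker workflows: an
exosome-candidate cascade (quantified in 100% of tumors -> FC > 2 with raw
p < 0.05 versus NAT -> hazard ratio > 1 with cutpoint survival p < 0.05) and
a subtype-marker screen (>= 90% detection -> one-vs-rest ratio > 1.5 with
BH q < 0.05 and a mean above every other subtype -> prognostic). The
exosome cascade uses raw p in its differential stage and the subtype screen
uses BH-adjusted q, following the two workflows' own conventions; both are
flags.

## Single-sample scores

`gsva_score()` estimates, per gene, a cross-sample standing via a
Gaussian-kernel cumulative density (bandwidth sd/4), ranks genes within each
sample by that statistic, and runs a weighted Kolmogorov-Smirnov random walk
down the ranking: in-set steps proportional to the symmetric rank weight
`|(p+1)/2 - rank|^tau` (tau default 1), uniform out-of-set steps, score =
maximum positive plus minimum negative walk deviation ("maxdiff"). The
symmetric midpoint makes mirrored placements score exactly opposite. Sets
with fewer than `min_set_size` members present (default 5; KS walks on tiny
sets are unstable) are dropped with a warning. The same engine serves
pathway scores, kinase-substrate-set activity and TF-regulon activity
(`tf_activity()` is a thin alias); the layer it runs on is always an
explicit argument. `mgps()` is the mean of row-z-scored abundances of the
cell-cycle-regulated set per sample — the standard multi-gene proliferation
score.

## Kinase-substrate enrichment

`ksea_z()` uses the standard KSEA statistic
`z = (mean(substrates) - mean(all sites)) * sqrt(m) / sd(all sites)` with a
two-sided normal p and BH adjustment across kinases. The background is
always the full site vector (restricting it to the substrate set itself
would force z toward zero — a property test guards this), and sites shared
by several kinases count for each with no exclusivity correction. Contrast
mode consumes per-site tumor/NAT mean log2 fold changes;
`ksea_per_sample()` scores each sample's row-z-scored profile.
`kinase_substrate_correlation()` screens mapped substrate sites against a
kinase's protein abundance by pairwise-complete Spearman correlation
(minimum 10 complete pairs).

## Copy-number effects and event associations

`cis_trans_screen()` correlates CNA log-ratios with target abundance
(Spearman, pairwise-complete, minimum 10 shared samples); a pair is *cis*
when the target maps to the CNA gene itself, with phosphosites mapping via
their `GENE_p[STY]pos` prefix. Significance defaults to two-sided p with BH
within the target layer; a one-sided positive mode reproduces
dosage-direction screens. `mutual_exclusivity()` and
`event_feature_association()` are two-sided Fisher exact tests on binary
event tables, reporting the sample odds ratio and the exclusive /
co-occurring direction; unknown clinical categories are excluded with their
count reported.

## Consensus subtyping

`select_features()` keeps the `floor(fraction x m)` highest-SD features
(`floor`, not `ceiling`: half of a 7,055-protein matrix is 3,527 features),
ties broken by feature ID. `consensus_cluster()` subsamples 80% of
samples per repetition without replacement, clusters each subsample
hierarchically with average linkage — the reference consensus-clustering
tool's default — on the 1 - Spearman sample distance, cuts one tree per
repetition at every candidate k, and accumulates co-clustering frequencies
into the consensus matrix M_k. Final assignments cut a tree built on
1 - M_k. Diagnostics are the CDF of upper-triangle consensus values, its
area A(k), the relative delta area (delta(2) = A(2), else
(A(k) - A(k-1)) / A(k-1)), and the mean silhouette of the consensus
clusters computed **on the data distance**. The data distance is used
deliberately: consensus-matrix distances can look crisp even on
structureless data (average linkage stably peels outliers, a documented
pathology of consensus clustering), whereas data-distance silhouettes stay
near zero for noise and peak at the planted k on structured cohorts.
`choose_k()` takes the best-silhouette k among those whose delta area clears
0.025, ties toward the smaller k, and attaches a confidence flag ("no
support" when every silhouette is below 0.25). 500 repetitions are the
package's default scale — consensus frequencies stabilize well before that
on cohorts of one to a few hundred samples — with the repetition count
exposed for heavier runs. `merge_clusters()` applies an explicit relabeling
map (e.g. collapsing five immune clusters to three) and refuses unmapped
labels.

## Survival statistics

Kaplan-Meier estimation, log-rank tests and univariate Cox regression are
delegated to the survival package (`survfit`, `survdiff`, `coxph` with
Efron tie handling — the package's standard and the better approximation
under ties). `maxstat_cutpoint()` implements maximally selected rank
statistics directly: centred Nelson-Aalen log-rank scores, the standardized
partial-sum statistic over every candidate cutpoint (observed values inside
the 10-90% quantile window leaving >= 10 samples per side), and a
selection-adjusted permutation p-value in which the maximal statistic is
recomputed for every permutation of the feature values. Permutation rather
than the asymptotic bound keeps the inference exact at desk scale with no
special functions; the reported cutpoint is the midpoint between the optimal
candidate and the next larger observed value, so it falls between the two
groups' ranges. `survival_screen()` chains cutpoint selection, the log-rank
test on the dichotomy and a Cox hazard ratio per feature, applying BH to
the selection-adjusted p-values (naive post-selection log-rank p-values
would not be calibrated). Ordinal subtype codes can be used as numeric Cox
covariates to reproduce the common "per-subtype-step" hazard-ratio
convention; the output flags this as ordinal-as-numeric.

## Orchestration

`run_pipeline()` executes simulate -> summary -> signatures -> differential
expression -> scoring -> KSEA -> cis/trans -> subtype -> survival from one
nested config with a single seed; every output TSV carries a header comment
naming the stage, parameters and seed, and `provenance.json` indexes all
artifacts. Reruns under the same seed are bit-identical. A stage failure
halts the run naming the stage; earlier outputs are retained.
`summarize_cohort()` reproduces printed-table arithmetic: per-category
percentages over the known-value denominator, one decimal by default.

## Verification scale and limitations

The shipped tests verify, at desk scale: signature-number and
signature-profile recovery on 100-sample cohorts with 2,000 mutations per
sample (50 seeded runs); subtype recovery on 120-sample cohorts with 2-SD,
100-gene programs at 500 consensus repetitions, against a structureless
null; exact equivalence of BH, Fisher (all 2x2 tables with margins <= 12),
KSEA, cutpoint selection and set-score walks with independent oracles;
false-discovery calibration of every screen on null cohorts (100-200
replicates); and Cox/KM parameter recovery at n = 1,000-2,000. These sizes
are the package's chosen verification scale — large enough for the
asymptotics the checks rely on, small enough for routine runs.

Known limitations: no multi-layer joint clustering; no paired-test variants
of the differential stage (the headline contrasts are unpaired); no
moderated (limma-style) statistics; the maxstat asymptotic p-value
approximation is not implemented (permutation only); consensus clustering
inherits the method's optimism on correlated null data — the data-distance
silhouette is the guard, and its "no support" flag should be respected.
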