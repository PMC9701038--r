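# pgomics

Integrative proteogenomic analysis of paired tumor / non-tumor-adjacent
(NAT) multi-omics cohorts, built for analysts who need the statistical
machinery of a modern tumor proteogenomics study — mutational signatures,
copy-number effect screens, differential proteomics, single-sample pathway
and kinase activity scores, consensus subtyping, survival stratification —
as tested, reusable R functions rather than one-off scripts. A built-in
synthetic-cohort generator plants known effects and records them in a truth
ledger, so every stage of the pipeline can be verified end to end without
any external data.

## What it computes

* **Mutational signatures.** Somatic SNVs are tallied into the 96
  pyrimidine-centred trinucleotide channels per sample; the catalog `V`
  (96 x S) is factorized by multiplicative-update NMF, `V ≈ W H` with
  `W >= 0` the signatures (columns sum to 1) and `H >= 0` the exposures.
  The number of signatures comes from a scree rule on reconstruction error
  plus a restart-stability requirement, and each signature is matched to a
  reference catalog by cosine similarity
  `cos(a, b) = <a, b> / (||a|| ||b||)`.
* **Differential expression.** Welch *t* (or Wilcoxon / ANOVA /
  Kruskal-Wallis) per feature with the dual calling rule FC > 2 and
  Benjamini-Hochberg q < 0.05, plus biomarker filter cascades
  (complete-detection -> differential -> prognostic).
* **Single-sample scores.** A rank-based weighted Kolmogorov-Smirnov walk
  (GSVA-style, Gaussian-kernel CDF, maxdiff scoring) for pathway, TF-regulon
  and kinase-substrate-set activity; `mgps()` for the multi-gene
  proliferation score.
* **KSEA.** Kinase activity
  `z = (mean(substrates) - mean(all sites)) * sqrt(m) / sd(all sites)`
  from substrate phosphosite fold changes, contrast-wise or per sample.
* **Copy-number effects.** Spearman screens of CNA dosage against mRNA /
  protein / phosphosite abundance, *cis* when the target maps to the same
  gene; Fisher exact tests for mutual exclusivity and event-clinical
  association.
* **Consensus subtyping.** Subsampled hierarchical clustering (average
  linkage, 1 - Spearman distance, 80% sample resampling), consensus
  matrices with CDF / delta-area / silhouette diagnostics and principled
  k selection, plus explicit cluster merging (e.g. five immune clusters to
  three).
* **Survival.** Kaplan-Meier, log-rank, maximally selected rank-statistic
  cutpoints with selection-adjusted permutation p-values, and univariate
  Cox models (Efron ties).

## Worked example

```r
library(pgomics)

cfg <- cohort_config(n_patients = 60, n_genes = 600, n_mut_per_sample = 1000,
                     k_signatures = 3, rng_seed = 42)
cohort <- generate_cohort(cfg)
tumors <- cohort$clinical$sample_id[cohort$clinical$tissue == "tumor"]

## 1. mutational signatures
catalog <- build_catalog(cohort$mutations, tumors)
k <- select_k(catalog, 1:5, rng_seed = 42)
dec <- factorize(catalog, as.integer(k), rng_seed = 42)
match_to_reference(dec$W, cohort$truth$signatures)
#>    signature reference    cosine
#> 1 Signature1      SYN3 0.9998493
#> 2 Signature2      SYN1 0.9997653
#> 3 Signature3      SYN2 0.9978490
```

All three planted signatures are recovered (cosine > 0.997) and the scree
rule picks k = 3 on its own.

```r
## 2. tumor vs NAT differential expression
groups <- factor(ifelse(grepl("_T$", colnames(cohort$protein$values)),
                        "tumor", "nat"), levels = c("tumor", "nat"))
de <- compare_groups(cohort$protein, groups)
table(de$call)
#> down   ns   up
#>   50  275  275
```

Calls require both |FC| > 2 and BH q < 0.05; the up/down counts reflect the
planted 30%/11% effect fractions plus the subtype programs.

```r
## 3. consensus subtypes and survival
tm <- cohort$protein$values[, tumors]
keep <- select_features(tm, 0.5)            # top-variance half
cc <- consensus_cluster(tm[keep, ], 2:5, n_reps = 200, rng_seed = 42)
k_sub <- choose_k(cc)                        # -> 3, the planted number
adjusted_rand_index(cc$assignments[["3"]], cohort$truth$subtype[tumors])
#> [1] 1

cl <- cohort$clinical[match(tumors, cohort$clinical$sample_id), ]
cox_univariate(as.numeric(cc$assignments[["3"]]), cl$os_time, cl$os_event)[
  c("hr", "ci_low", "ci_high", "p")]
#> $hr        [1] 0.5988223
#> $ci_low    [1] 0.3850194
#> $ci_high   [1] 0.9313508
#> $p         [1] 0.02287215
```

Subtype recovery is exact (adjusted Rand index 1), and the ordinal-subtype
Cox fit shows the planted hazard gradient across subtypes (hazard ratio
0.60 per subtype step, p = 0.023 — the recovered label order happens to run
from highest to lowest baseline hazard here).

`run_pipeline(list(rng_seed = 1), "out/")` runs every stage on one config
and writes provenance-stamped TSVs plus `provenance.json`; reruns under the
same seed are bit-identical. A thin command-line front end over the same
functions ships in `inst/cli/pgomics.R` (subcommands `simulate`, `run-all`,
`summary`, `signatures`, `diffexp`).

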