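Package: pgomics
Title: Proteogenomic Multi-Omics Analysis of Paired Tumor/Normal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative proteogenomic analysis toolkit for paired
    tumor/normal multi-omics cohorts (mRNA, protein, phosphoproteome,
    copy number, mutations and cell-type scores). Provides readers and
    writers for the standard tabular formats, a synthetic-cohort
    generator with a recorded ground-truth ledger, 96-channel
    trinucleotide mutational-signature extraction by non-negative
    matrix factorization with cosine matching against a reference
    catalog, tumor-versus-normal and multi-group differential
    expression with fold-change and false-discovery thresholds,
    single-sample pathway and transcription-factor activity scoring by
    a rank-based Kolmogorov-Smirnov random walk, kinase-substrate
    enrichment analysis, cis/trans copy-number-effect screening,
    consensus-clustering subtype discovery with CDF/delta-area and
    silhouette diagnostics, and survival stratification with
    maximally-selected rank-statistic cutpoints, log-rank tests and
    univariate Cox models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
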