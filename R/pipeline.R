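# End-to-end orchestration: cohort summary arithmetic and the staged
# pipeline runner with provenance.

#' Cohort summary table
#'
#' Per-category counts and percentages for the clinical variables. The
#' denominator of each variable is the number of samples with a known value
#' (missing and `"unknown"` excluded). Alternatively an explicit printed
#' count table can be summarized: a data.frame with columns `variable`,
#' `category`, `n` and optionally `denom` (defaults to the per-variable sum
#' of `n`).
#'
#' @param clinical a `clinical_table` (tumor rows are summarized), or NULL.
#' @param counts an explicit count table (see above), or NULL.
#' @param digits decimal places for percentages (default 1).
#' @return data.frame: `variable`, `category`, `n`, `denom`, `pct`.
#' @export
summarize_cohort <- function(clinical = NULL, counts = NULL, digits = 1) {
  if (is.null(clinical) && is.null(counts))
    stop("provide a clinical table or a count table")
  if (!is.null(counts)) {
    if (nrow(counts) == 0) stop("empty count table")
    if (!"denom" %in% names(counts)) {
      denoms <- tapply(counts$n, counts$variable, sum)
      counts$denom <- as.numeric(denoms[counts$variable])
    }
    counts$pct <- round(100 * counts$n / counts$denom, digits)
    return(counts[, c("variable", "category", "n", "denom", "pct")])
  }
  df <- clinical[clinical$tissue == "tumor", , drop = FALSE]
  if (nrow(df) == 0) stop("empty clinical table")
  vars <- c("sex", "tnm_stage", "location", "diabetes", "metastasis")
  rows <- list()
  for (v in vars) {
    lab <- as.character(df[[v]])
    known <- !is.na(lab) & lab != "unknown"
    if (!any(known)) {
      message("variable '", v, "' is entirely missing; omitted")
      next
    }
    tab <- table(lab[known])
    denom <- sum(tab)
    rows[[v]] <- data.frame(variable = v, category = names(tab),
                            n = as.integer(tab), denom = denom,
                            pct = round(100 * as.integer(tab) / denom, digits),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

default_pipeline_config <- function() {
  list(
    rng_seed = 1L,
    cohort = list(n_patients = 60, n_genes = 400, n_phosphosites = 150,
                  n_mut_per_sample = 500, k_signatures = 3),
    stages = c("simulate", "summary", "signatures", "diffexp", "score",
               "ksea", "cistrans", "subtype", "survival"),
    signatures = list(k_range = 1:5, n_restarts = 3),
    diffexp = list(test = "t", fc_thresh = 2, q_thresh = 0.05),
    score = list(tau = 1, min_set_size = 5),
    ksea = list(min_substrates = 3),
    cistrans = list(mode = "cis_only", min_pairs = 10),
    subtype = list(k_range = 2:5, n_reps = 200, p_item = 0.8,
                   top_fraction = 0.5),
    survival = list(endpoint = "os", n_perm = 100)
  )
}

write_stage_tsv <- function(df, path, stage, params, seed) {
  hdr <- sprintf("# stage=%s params=%s seed=%s pgomics=%s", stage,
                 paste(names(params), unlist(params), sep = "=", collapse = ","),
                 seed, as.character(utils::packageVersion("pgomics")))
  con <- file(path, "w")
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, na = "NA"))
  close(con)
  path
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Runs the stages in dependency order on a generated cohort: simulate ->
#' cohort summary -> mutational signatures -> tumor/NAT differential
#' expression -> pathway/TF scoring -> KSEA -> cis/trans CNA screen ->
#' consensus subtyping -> survival stratification. Every output TSV carries
#' a header comment with the stage, parameters and seed, and a JSON
#' provenance file indexes all artifacts. Deterministic given the config
#' seed. A stage failure halts the run naming the failing stage; earlier
#' outputs are retained.
#'
#' @param config nested list of stage parameters; see
#'   `pgomics:::default_pipeline_config()` for the shape. Missing entries
#'   take the defaults.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) the provenance list.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(seed = cfg$rng_seed, stages = list(),
               version = as.character(utils::packageVersion("pgomics")))
  artifacts <- list()
  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    prov$stages[[name]] <<- list(completed = TRUE)
    res
  }
  env <- new.env()

  run_stage("simulate", function() {
    ccfg <- do.call(cohort_config, c(cfg$cohort, list(rng_seed = cfg$rng_seed)))
    env$cohort <- generate_cohort(ccfg)
    write_clinical(env$cohort$clinical, file.path(out_dir, "clinical.tsv"))
    write_matrix(env$cohort$protein, file.path(out_dir, "protein.tsv"))
    write_matrix(env$cohort$cna, file.path(out_dir, "cna.tsv"))
    write_maf(env$cohort$mutations, file.path(out_dir, "mutations.maf.tsv"))
    artifacts$cohort <<- c("clinical.tsv", "protein.tsv", "cna.tsv",
                           "mutations.maf.tsv")
  })
  co <- env$cohort
  if (is.null(co) && length(setdiff(cfg$stages, "simulate")) > 0)
    stop("the 'simulate' stage is required: downstream stages consume its cohort")
  tumors <- co$clinical$sample_id[co$clinical$tissue == "tumor"]

  run_stage("summary", function() {
    s <- summarize_cohort(clinical = co$clinical)
    write_stage_tsv(s, file.path(out_dir, "cohort_summary.tsv"), "summary",
                    list(), cfg$rng_seed)
    artifacts$summary <<- "cohort_summary.tsv"
  })

  run_stage("signatures", function() {
    cat_ <- suppressMessages(build_catalog(
      co$mutations[!is.na(co$mutations$trinucleotide_context), ], tumors))
    k <- select_k(cat_, cfg$signatures$k_range, rng_seed = cfg$rng_seed,
                  n_restarts = cfg$signatures$n_restarts)
    dec <- factorize(cat_, as.integer(k),
                     n_restarts = cfg$signatures$n_restarts,
                     rng_seed = cfg$rng_seed)
    mt <- match_to_reference(dec$W, co$truth$signatures)
    write_stage_tsv(as.data.frame(dec$W), file.path(out_dir, "signatures_W.tsv"),
                    "signatures", list(k = as.integer(k)), cfg$rng_seed)
    write_stage_tsv(as.data.frame(dec$exposures),
                    file.path(out_dir, "signatures_exposures.tsv"),
                    "signatures", list(k = as.integer(k)), cfg$rng_seed)
    write_stage_tsv(mt, file.path(out_dir, "signature_matches.tsv"),
                    "signatures", list(k = as.integer(k)), cfg$rng_seed)
    env$signatures <- list(k = as.integer(k), matches = mt)
    artifacts$signatures <<- c("signatures_W.tsv", "signatures_exposures.tsv",
                               "signature_matches.tsv")
  })

  run_stage("diffexp", function() {
    grp <- factor(ifelse(co$clinical$tissue[match(colnames(co$protein$values),
                                                  co$clinical$sample_id)] == "tumor",
                         "tumor", "nat"), levels = c("tumor", "nat"))
    de <- suppressMessages(compare_groups(co$protein, grp,
                                          test = cfg$diffexp$test,
                                          fc_thresh = cfg$diffexp$fc_thresh,
                                          q_thresh = cfg$diffexp$q_thresh))
    write_stage_tsv(de, file.path(out_dir, "diffexp_protein.tsv"), "diffexp",
                    cfg$diffexp, cfg$rng_seed)
    env$diffexp <- de
    artifacts$diffexp <<- "diffexp_protein.tsv"
  })

  run_stage("score", function() {
    sc <- suppressWarnings(gsva_score(subset_matrix(co$protein, NULL, tumors),
                                      co$gene_sets, tau = cfg$score$tau,
                                      min_set_size = cfg$score$min_set_size))
    mg <- mgps(subset_matrix(co$protein, NULL, tumors),
               co$truth$programs[[1]])
    write_stage_tsv(as.data.frame(unclass(sc)), file.path(out_dir, "scores_gsva.tsv"),
                    "score", cfg$score, cfg$rng_seed)
    write_stage_tsv(data.frame(sample = names(mg), mgps = mg),
                    file.path(out_dir, "scores_mgps.tsv"), "score",
                    cfg$score, cfg$rng_seed)
    artifacts$score <<- c("scores_gsva.tsv", "scores_mgps.tsv")
  })

  run_stage("ksea", function() {
    pv <- as_values(co$phospho)
    nats <- sub("_T$", "_N", tumors)
    fc <- rowMeans(pv[, tumors, drop = FALSE], na.rm = TRUE) -
      rowMeans(pv[, nats, drop = FALSE], na.rm = TRUE)
    ks <- suppressMessages(ksea_z(fc, co$ks_map,
                                  min_substrates = cfg$ksea$min_substrates))
    write_stage_tsv(ks, file.path(out_dir, "ksea_contrast.tsv"), "ksea",
                    cfg$ksea, cfg$rng_seed)
    env$ksea <- ks
    artifacts$ksea <<- "ksea_contrast.tsv"
  })

  run_stage("cistrans", function() {
    ct <- cis_trans_screen(co$cna, subset_matrix(co$protein, NULL, tumors),
                           mode = cfg$cistrans$mode,
                           min_pairs = cfg$cistrans$min_pairs)
    write_stage_tsv(ct, file.path(out_dir, "cistrans_protein.tsv"), "cistrans",
                    cfg$cistrans, cfg$rng_seed)
    env$cistrans <- ct
    artifacts$cistrans <<- "cistrans_protein.tsv"
  })

  run_stage("subtype", function() {
    tm <- subset_matrix(co$protein, NULL, tumors)
    feats <- select_features(tm, cfg$subtype$top_fraction)
    cc <- consensus_cluster(subset_matrix(tm, feats),
                            k_range = cfg$subtype$k_range,
                            n_reps = cfg$subtype$n_reps,
                            p_item = cfg$subtype$p_item,
                            rng_seed = cfg$rng_seed)
    k <- choose_k(cc)
    asn <- cc$assignments[[as.character(k)]]
    write_stage_tsv(data.frame(sample = names(asn), subtype = asn),
                    file.path(out_dir, "subtype_assignments.tsv"), "subtype",
                    list(k = as.integer(k)), cfg$rng_seed)
    diag_ <- data.frame(k = cc$k_range, A = cc$A, delta = cc$delta,
                        silhouette = cc$silhouette)
    write_stage_tsv(diag_, file.path(out_dir, "subtype_diagnostics.tsv"),
                    "subtype", list(), cfg$rng_seed)
    env$subtype <- list(k = as.integer(k), assignments = asn, result = cc)
    artifacts$subtype <<- c("subtype_assignments.tsv", "subtype_diagnostics.tsv")
  })

  run_stage("survival", function() {
    cl <- co$clinical[match(tumors, co$clinical$sample_id), ]
    ep <- cfg$survival$endpoint
    rows <- list()
    if (!is.null(env$subtype)) {
      asn <- env$subtype$assignments[tumors]
      lr <- logrank(cl[[paste0(ep, "_time")]], cl[[paste0(ep, "_event")]], asn)
      cx <- cox_univariate(as.numeric(asn), cl[[paste0(ep, "_time")]],
                           cl[[paste0(ep, "_event")]])
      rows$subtype <- data.frame(variable = "subtype_ordinal", hr = cx$hr,
                                 ci_low = cx$ci_low, ci_high = cx$ci_high,
                                 cox_p = cx$p, logrank_p = lr$p,
                                 note = "ordinal subtype code as numeric covariate",
                                 stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    write_stage_tsv(tab, file.path(out_dir, "survival_subtype.tsv"),
                    "survival", cfg$survival, cfg$rng_seed)
    env$survival <- tab
    artifacts$survival <<- "survival_subtype.tsv"
  })

  prov$artifacts <- artifacts
  prov$config <- cfg[setdiff(names(cfg), "stages")]
  prov$stages_run <- cfg$stages
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prov)
}
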