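# Synthetic paired tumor/NAT cohorts with a recorded ground-truth ledger.
# Every downstream stage of the pipeline can be tested against the planted
# effects without any external download.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a desk-scale paired tumor/NAT cohort: tumor/NAT
#' differential programs at the proportions seen in deep proteomic
#' tumor/normal comparisons (~30% up, ~11% down at |log2FC| around 2),
#' cis-regulated genes whose copy-number log-ratio propagates into mRNA and
#' protein, trinucleotide mutation spectra mixed from sparse reference
#' signatures, three proteomic subtypes carried by disjoint 100-gene
#' programs, five immune clusters over 64 cell-type scores, and
#' proportional-hazards survival driven by subtype and marker proteins.
#'
#' @param n_patients number of patients (each contributes a tumor and a
#'   paired NAT sample).
#' @param n_genes number of genes (mRNA/protein/CNA features).
#' @param n_phosphosites number of phosphosites.
#' @param n_mut_per_sample mean somatic SNV count per tumor (Poisson).
#' @param k_signatures number of planted mutational signatures.
#' @param signature_sparsity Dirichlet concentration of reference signatures
#'   over the 96 channels (small = spiky, signature-like).
#' @param frac_tumor_up,frac_tumor_down fractions of genes shifted up/down in
#'   tumors.
#' @param effect_mean,effect_sd log2 fold-change distribution of planted
#'   tumor/NAT effects.
#' @param n_cis_genes number of genes with a planted CNA cis-effect.
#' @param cis_slope_mean,cis_slope_sd distribution of cis slopes (log2
#'   abundance per CNA log-ratio unit).
#' @param n_subtypes number of proteomic subtypes.
#' @param program_size genes per subtype program (disjoint).
#' @param subtype_shift shift (in noise SDs) of a subtype's program in its
#'   tumors.
#' @param n_immune_clusters,n_celltypes immune clustering structure of the
#'   cell-type score layer.
#' @param immune_marker_size,immune_shift cell types per immune-cluster
#'   signature and their shift.
#' @param n_kinases,substrates_per_kinase,n_active_kinases,kinase_shift the
#'   kinase-substrate map and the tumor-activated kinases (substrate sites
#'   shifted by `kinase_shift` in tumors).
#' @param baseline_rates per-subtype exponential baseline hazards (events per
#'   day); recycled to `n_subtypes`.
#' @param n_surv_markers,surv_coef number of hazardous marker proteins and
#'   their log-hazard per z-score unit.
#' @param censor_rate exponential censoring rate (per day).
#' @param missing_protein,missing_phospho overall missingness rates of the
#'   protein and phospho layers (intensity-dependent, higher at low
#'   abundance).
#' @param rng_seed integer seed; the generator is deterministic given the
#'   config.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100,
                          n_genes = 1000,
                          n_phosphosites = 400,
                          n_mut_per_sample = 2000,
                          k_signatures = 3,
                          signature_sparsity = 0.1,
                          frac_tumor_up = 0.30,
                          frac_tumor_down = 0.11,
                          effect_mean = 2,
                          effect_sd = 0.5,
                          n_cis_genes = 20,
                          cis_slope_mean = 0.8,
                          cis_slope_sd = 0.1,
                          n_subtypes = 3,
                          program_size = 100,
                          subtype_shift = 2,
                          n_immune_clusters = 5,
                          n_celltypes = 64,
                          immune_marker_size = 8,
                          immune_shift = 2,
                          n_kinases = 20,
                          substrates_per_kinase = 10,
                          n_active_kinases = 3,
                          kinase_shift = 1.5,
                          baseline_rates = c(8e-4, 1.2e-3, 2e-3),
                          n_surv_markers = 5,
                          surv_coef = log(1.5),
                          censor_rate = 5e-4,
                          missing_protein = 0.10,
                          missing_phospho = 0.20,
                          rng_seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_patients", "n_genes", "n_phosphosites", "k_signatures",
              "n_subtypes", "n_immune_clusters", "n_celltypes", "n_kinases")
  for (nm in counts)
    if (cfg[[nm]] <= 0) stop("'", nm, "' must be > 0")
  for (nm in c("frac_tumor_up", "frac_tumor_down", "missing_protein",
               "missing_phospho"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop("'", nm, "' must lie in [0, 1]")
  if (cfg$frac_tumor_up + cfg$frac_tumor_down > 1)
    stop("planted up/down fractions exceed 1")
  if (any(cfg$baseline_rates <= 0) || cfg$censor_rate < 0)
    stop("hazard rates must be > 0 (censor_rate >= 0)")
  if (cfg$n_subtypes > cfg$n_patients)
    stop("n_subtypes may not exceed n_patients")
  cfg$baseline_rates <- rep_len(cfg$baseline_rates, cfg$n_subtypes)
  # subtype programs must stay disjoint and leave background genes; cap the
  # per-subtype program size at half the gene space split across subtypes
  cfg$program_size <- min(cfg$program_size,
                          max(2, floor(cfg$n_genes / (2 * cfg$n_subtypes))))
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate proportional-hazards survival data
#'
#' Event times are exponential with hazard `baseline_rate * exp(lp)`;
#' censoring is an independent exponential with rate `censor_rate`
#' (`censor_rate = 0` means no censoring). Uses the caller's RNG stream.
#'
#' @param linear_predictors finite numeric vector of log-hazard offsets.
#' @param baseline_rate scalar baseline hazard (> 0).
#' @param censor_rate scalar censoring hazard (>= 0).
#' @return list with `time` (observed) and `event` (1 = event, 0 = censored).
#' @export
simulate_survival <- function(linear_predictors, baseline_rate, censor_rate) {
  if (any(!is.finite(linear_predictors)))
    stop("linear predictors must be finite")
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  n <- length(linear_predictors)
  t_event <- stats::rexp(n, rate = baseline_rate * exp(linear_predictors))
  t_cens <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate)
            else rep(Inf, n)
  list(time = pmin(t_event, t_cens),
       event = as.integer(t_event <= t_cens))
}

# Balanced shuffled labels 1..k over n items.
balanced_labels <- function(n, k) sample(rep_len(seq_len(k), n))

# Intensity-dependent missingness: dropout probability decreases with the
# feature's within-row standing, mean dropout equals `rate`.
apply_dropout <- function(m, rate) {
  if (rate <= 0) return(m)
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    p <- pmin(1, 2 * rate * (1 - stats::pnorm(x, mean = mean(x), sd = max(stats::sd(x), 1e-9))))
    m[i, stats::runif(length(x)) < p] <- NA
  }
  m
}

#' Generate a paired tumor/NAT multi-omics cohort with known ground truth
#'
#' Produces a clinical table, mRNA/protein/phospho/CNA/cell-score layers, a
#' mutation table, supporting gene sets and a kinase-substrate map, plus a
#' `truth` ledger recording every planted quantity (tumor/NAT log2 effects,
#' cis genes and slopes, subtype and immune-cluster labels, signature
#' exposures, true linear predictors of hazard, activated kinases). Output is
#' deterministic given the config: each layer draws from its own RNG stream
#' derived from `rng_seed`, so adding a layer does not perturb the others.
#'
#' @param config a [cohort_config].
#' @return list with elements `clinical`, `mrna`, `protein`, `phospho`,
#'   `cna`, `cellscore`, `mutations`, `gene_sets`, `ks_map`, `truth`,
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop("'config' must be a cohort_config")
  cfg <- config
  P <- cfg$n_patients
  G <- cfg$n_genes
  genes <- sprintf("GENE%04d", seq_len(G))
  patients <- sprintf("P%03d", seq_len(P))
  tum <- paste0(patients, "_T")
  nat <- paste0(patients, "_N")
  stream <- function(i) set.seed((cfg$rng_seed * 1000L + i) %% .Machine$integer.max)

  ## --- design: labels, planted effects ------------------------------------
  stream(1L)
  subtype <- balanced_labels(P, cfg$n_subtypes)
  immune <- balanced_labels(P, cfg$n_immune_clusters)
  n_up <- round(cfg$frac_tumor_up * G)
  n_dn <- round(cfg$frac_tumor_down * G)
  de_genes <- sample(genes, n_up + n_dn)
  log2fc <- stats::setNames(numeric(G), genes)
  if (n_up > 0)
    log2fc[de_genes[seq_len(n_up)]] <- abs(stats::rnorm(n_up, cfg$effect_mean, cfg$effect_sd))
  if (n_dn > 0)
    log2fc[de_genes[n_up + seq_len(n_dn)]] <- -abs(stats::rnorm(n_dn, cfg$effect_mean, cfg$effect_sd))
  need <- cfg$n_subtypes * cfg$program_size
  if (need > G) stop("subtype programs need more genes than available")
  prog_genes <- sample(genes, need)
  programs <- split(prog_genes, rep(seq_len(cfg$n_subtypes), each = cfg$program_size))
  names(programs) <- paste0("subtype_program_", seq_len(cfg$n_subtypes))
  cis_genes <- if (cfg$n_cis_genes > 0) sample(genes, cfg$n_cis_genes) else character(0)
  cis_slope <- stats::setNames(stats::rnorm(length(cis_genes), cfg$cis_slope_mean,
                                            cfg$cis_slope_sd), cis_genes)
  marker_pool <- setdiff(genes, prog_genes)
  if (length(marker_pool) < cfg$n_surv_markers) marker_pool <- genes
  surv_markers <- if (cfg$n_surv_markers > 0)
    sample(marker_pool, cfg$n_surv_markers) else character(0)
  baseline <- stats::rnorm(G, 5, 1.5)
  names(baseline) <- genes

  ## --- CNA layer (tumors) -------------------------------------------------
  stream(5L)
  cna_vals <- matrix(stats::rnorm(G * P, 0, 0.5), G, P,
                     dimnames = list(genes, tum))
  cna <- omics_matrix(cna_vals, "cna", "logratio")

  ## --- expression layers ---------------------------------------------------
  make_layer <- function(noise_sd) {
    m <- matrix(stats::rnorm(G * 2 * P, 0, noise_sd), G, 2 * P,
                dimnames = list(genes, c(tum, nat)))
    m <- m + baseline
    m[, tum] <- m[, tum] + log2fc
    for (s in seq_len(cfg$n_subtypes)) {
      idx <- which(subtype == s)
      m[programs[[s]], tum[idx]] <- m[programs[[s]], tum[idx]] +
        cfg$subtype_shift * noise_sd
    }
    if (length(cis_genes))
      m[cis_genes, tum] <- m[cis_genes, tum] +
        cna_vals[cis_genes, tum] * cis_slope
    m
  }
  stream(2L)
  mrna_vals <- make_layer(1)
  stream(3L)
  prot_vals <- make_layer(1)
  prot_vals <- apply_dropout(prot_vals, cfg$missing_protein)
  mrna <- omics_matrix(mrna_vals, "mrna", "log2")
  protein <- omics_matrix(prot_vals, "protein", "log2")

  ## --- phosphoproteome + kinase-substrate map ------------------------------
  stream(4L)
  S <- cfg$n_phosphosites
  site_gene <- sample(genes, S, replace = TRUE)
  site_pos <- sample(50:2000, S, replace = TRUE)
  site_res <- sample(c("S", "T", "Y"), S, replace = TRUE, prob = c(.73, .24, .03))
  sites <- paste0(site_gene, "_p", site_res, site_pos)
  dup <- duplicated(sites)
  while (any(dup)) {  # site IDs must be unique
    site_pos[dup] <- site_pos[dup] + sample(1:37, sum(dup), replace = TRUE)
    sites <- paste0(site_gene, "_p", site_res, site_pos)
    dup <- duplicated(sites)
  }
  n_kin <- cfg$n_kinases
  kinases <- sprintf("KIN%02d", seq_len(n_kin))
  ks_map <- lapply(seq_len(n_kin), function(i)
    sample(sites, min(cfg$substrates_per_kinase, S)))
  names(ks_map) <- kinases
  class(ks_map) <- "kinase_substrate_map"
  active_kin <- kinases[seq_len(min(cfg$n_active_kinases, n_kin))]
  phospho_vals <- 0.6 * (if (is.null(dim(prot_vals))) prot_vals else
                         matrix(ifelse(is.na(prot_vals[site_gene, ]), 0,
                                       prot_vals[site_gene, ]), S, 2 * P)) +
    matrix(stats::rnorm(S * 2 * P, 2, 1), S, 2 * P)
  dimnames(phospho_vals) <- list(sites, c(tum, nat))
  for (k in active_kin) {
    sub_sites <- ks_map[[k]]
    phospho_vals[sub_sites, tum] <- phospho_vals[sub_sites, tum] + cfg$kinase_shift
  }
  phospho_vals <- apply_dropout(phospho_vals, cfg$missing_phospho)
  phospho <- omics_matrix(phospho_vals, "phospho", "log2")

  ## --- mutations -----------------------------------------------------------
  stream(6L)
  channels <- sbs_channels()
  K <- cfg$k_signatures
  W <- matrix(stats::rgamma(96 * K, shape = cfg$signature_sparsity), 96, K,
              dimnames = list(channels, paste0("SYN", seq_len(K))))
  W <- sweep(W, 2, colSums(W), "/")
  expo <- matrix(stats::rgamma(K * P, shape = 0.5), K, P,
                 dimnames = list(colnames(W), tum))
  expo <- sweep(expo, 2, colSums(expo), "/")
  mut_list <- vector("list", P)
  for (j in seq_len(P)) {
    n_mut <- stats::rpois(1, cfg$n_mut_per_sample)
    if (n_mut == 0) { mut_list[[j]] <- NULL; next }
    probs <- as.vector(W %*% expo[, j])
    cnt <- as.vector(stats::rmultinom(1, n_mut, probs))
    ch <- rep(channels, cnt)
    ref <- substr(ch, 3, 3)
    alt <- substr(ch, 5, 5)
    ctx <- paste0(substr(ch, 1, 1), ref, substr(ch, 7, 7))
    mut_list[[j]] <- data.frame(
      sample_id = tum[j], gene = sample(genes, length(ch), replace = TRUE),
      variant_class = sample(c("missense", "nonsense", "inframe", "other"),
                             length(ch), replace = TRUE,
                             prob = c(.78, .05, .12, .05)),
      ref_allele = ref, alt_allele = alt, trinucleotide_context = ctx,
      protein_change = NA_character_, stringsAsFactors = FALSE)
  }
  n_fs <- max(1L, round(0.02 * cfg$n_mut_per_sample))
  fs <- data.frame(sample_id = sample(tum, n_fs, replace = TRUE),
                   gene = sample(genes, n_fs, replace = TRUE),
                   variant_class = "frameshift", ref_allele = NA_character_,
                   alt_allele = NA_character_,
                   trinucleotide_context = NA_character_,
                   protein_change = NA_character_, stringsAsFactors = FALSE)
  mutations <- do.call(rbind, c(mut_list, list(fs)))
  class(mutations) <- c("mutation_table", "data.frame")

  ## --- cell-type scores (tumors) -------------------------------------------
  stream(7L)
  celltypes <- sprintf("CELL%02d", seq_len(cfg$n_celltypes))
  cell_vals <- matrix(stats::rnorm(cfg$n_celltypes * P), cfg$n_celltypes, P,
                      dimnames = list(celltypes, tum))
  need_ct <- cfg$n_immune_clusters * cfg$immune_marker_size
  marker_ct <- split(sample(celltypes, min(need_ct, cfg$n_celltypes)),
                     rep_len(seq_len(cfg$n_immune_clusters),
                             min(need_ct, cfg$n_celltypes)))
  for (cl in seq_len(cfg$n_immune_clusters)) {
    idx <- which(immune == cl)
    cell_vals[marker_ct[[cl]], idx] <- cell_vals[marker_ct[[cl]], idx] +
      cfg$immune_shift
  }
  cellscore <- omics_matrix(cell_vals, "cellscore", "zscore")

  ## --- survival + clinical --------------------------------------------------
  stream(8L)
  marker_z <- matrix(0, length(surv_markers), P)
  if (length(surv_markers)) {
    mz <- prot_vals[surv_markers, tum, drop = FALSE]
    mz[is.na(mz)] <- mean(mz, na.rm = TRUE)
    marker_z <- t(scale(t(mz)))
  }
  lp <- log(cfg$baseline_rates[subtype] / cfg$baseline_rates[1]) +
    if (length(surv_markers)) colSums(cfg$surv_coef * marker_z) else 0
  os <- simulate_survival(lp, cfg$baseline_rates[1], cfg$censor_rate)
  dfs_frac <- stats::runif(P, 0.5, 1)
  age <- pmin(90, pmax(30, round(stats::rnorm(P, 64, 10))))
  sex <- sample(c("male", "female"), P, replace = TRUE, prob = c(.58, .42))
  stage <- sample(c("IA", "IB", "IIA", "IIB", "III"), P, replace = TRUE,
                  prob = c(.12, .34, .07, .39, .08))
  location <- sample(c("head", "body_tail"), P, replace = TRUE, prob = c(.63, .37))
  diabetes <- sample(c("yes", "no", "unknown"), P, replace = TRUE,
                     prob = c(.19, .79, .02))
  metastasis <- sample(c("yes", "no", "unknown"), P, replace = TRUE,
                       prob = c(.40, .30, .30))
  glucose <- stats::rnorm(P, 5.5, 1) + 2 * (diabetes == "yes")
  purity <- stats::runif(P, 0.1, 0.8)
  clin_one <- function(sid, tissue) data.frame(
    sample_id = sid, patient_id = patients, tissue = tissue, age = age,
    sex = sex, tnm_stage = stage, location = location, diabetes = diabetes,
    metastasis = metastasis,
    blood_glucose = if (tissue == "tumor") round(glucose, 2) else NA_real_,
    purity = if (tissue == "tumor") round(purity, 3) else NA_real_,
    os_time = round(os$time, 1), os_event = os$event,
    dfs_time = round(os$time * dfs_frac, 1), dfs_event = os$event,
    stringsAsFactors = FALSE)
  clinical <- validate_clinical(rbind(clin_one(tum, "tumor"), clin_one(nat, "nat")))

  gene_sets <- c(programs, list(cis_gene_set = if (length(cis_genes)) cis_genes
                                else genes[1:5]))
  class(gene_sets) <- "gene_set_collection"

  truth <- structure(list(
    log2fc = log2fc,
    cis_genes = data.frame(gene = cis_genes, slope = as.numeric(cis_slope),
                           stringsAsFactors = FALSE),
    subtype = stats::setNames(subtype, tum),
    immune_cluster = stats::setNames(immune, tum),
    exposures = expo,
    signatures = W,
    linear_predictor = stats::setNames(lp, tum),
    active_kinases = data.frame(kinase = active_kin,
                                shift = cfg$kinase_shift,
                                stringsAsFactors = FALSE),
    surv_markers = data.frame(gene = surv_markers, coef = cfg$surv_coef,
                              stringsAsFactors = FALSE),
    programs = programs,
    immune_markers = marker_ct), class = "cohort_truth")

  list(clinical = clinical, mrna = mrna, protein = protein, phospho = phospho,
       cna = cna, cellscore = cellscore, mutations = mutations,
       gene_sets = gene_sets, ks_map = ks_map, truth = truth, config = cfg)
}
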