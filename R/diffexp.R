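# Tumor-vs-NAT, group-vs-group and multi-group differential tests with the
# dual fold-change + FDR calling rule, plus the biomarker filter cascades.

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around the standard step-up procedure
#' (`stats::p.adjust(method = "BH")`): q_i = min over j >= i of p_(j) * m / j,
#' with enforced monotonicity and values clamped to [0, 1].
#'
#' @param p numeric vector of p-values in [0, 1] (NA passed through).
#' @return adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Row-wise z-score transformation
#'
#' Each feature is centred and scaled across all samples (sample SD, n-1
#' convention, missing-aware). Constant rows (SD 0 or fewer than two observed
#' values) become all-missing; their count is attached as attribute
#' `n_constant` and reported in a message.
#'
#' @param x an [omics_matrix] or bare numeric matrix.
#' @return object of the same kind on the z-score scale.
#' @export
zscore_rows <- function(x) {
  v <- as_values(x)
  ctr <- rowMeans(v, na.rm = TRUE)
  n_obs <- rowSums(!is.na(v))
  sds <- apply(v, 1, stats::sd, na.rm = TRUE)
  bad <- n_obs < 2 | is.na(sds) | sds == 0
  z <- (v - ctr) / sds
  z[bad, ] <- NA_real_
  if (any(bad))
    message(sum(bad), " constant row(s) set to missing in z-score transform")
  out <- if (inherits(x, "omics_matrix"))
    omics_matrix(z, x$layer, "zscore") else z
  attr(out, "n_constant") <- sum(bad)
  out
}

# Linear-scale view of a matrix for fold-change computation.
linearize <- function(x) {
  v <- as_values(x)
  if (inherits(x, "omics_matrix") && x$scale == "log2") 2^v else v
}

welch_rows <- function(v, g1, g2, pooled = FALSE) {
  n1 <- rowSums(!is.na(v[, g1, drop = FALSE]))
  n2 <- rowSums(!is.na(v[, g2, drop = FALSE]))
  m1 <- rowMeans(v[, g1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(v[, g2, drop = FALSE], na.rm = TRUE)
  s1 <- apply(v[, g1, drop = FALSE], 1, stats::var, na.rm = TRUE)
  s2 <- apply(v[, g2, drop = FALSE], 1, stats::var, na.rm = TRUE)
  if (pooled) {
    sp <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(s1 / n1 + s2 / n2)
    df <- (s1 / n1 + s2 / n2)^2 /
      ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  }
  stat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(stat), df)
  list(stat = stat, p = p)
}

#' Differential test between sample groups
#'
#' Two-group (`t`, `wilcoxon`) or multi-group (`anova`, `kruskal`) tests per
#' feature, with fold change computed on the linear scale (log2-scale input
#' is exponentiated first) and the dual calling rule: a feature is called
#' `up`/`down` only if both |FC| exceeds `fc_thresh` and the BH-adjusted q is
#' below `q_thresh`. Features observed fewer than `min_obs` times in any
#' group are skipped (count attached as attribute `n_skipped`).
#'
#' The fold change and the `up` call refer to the first level of `groups`
#' relative to the second (e.g. tumor/NAT with levels c("tumor","nat")).
#'
#' @param x an [omics_matrix] or matrix (features x samples).
#' @param groups factor (or coercible) of length ncol(x); its first level is
#'   the fold-change numerator.
#' @param test one of `"t"`, `"wilcoxon"`, `"anova"`, `"kruskal"`.
#' @param fc_thresh linear fold-change threshold (default 2).
#' @param q_thresh BH q threshold (default 0.05).
#' @param min_obs minimum observed values per group (default 30% of the
#'   group's size).
#' @param pooled_var use the pooled-variance (classic Student) t instead of
#'   the Welch default.
#' @return data.frame of class `differential_result`: feature, per-group
#'   means (linear), `log2fc`, `stat`, `p`, `q`, `call`, `test`.
#' @export
compare_groups <- function(x, groups, test = c("t", "wilcoxon", "anova", "kruskal"),
                           fc_thresh = 2, q_thresh = 0.05, min_obs = NULL,
                           pooled_var = FALSE) {
  test <- match.arg(test)
  v <- as_values(x)
  groups <- factor(groups)
  if (length(groups) != ncol(v)) stop("'groups' must match the sample columns")
  if (nlevels(groups) < 2) stop(">= 2 groups required")
  if (any(table(groups) == 0)) stop("empty group(s): ",
                                    paste(levels(groups)[table(groups) == 0], collapse = ", "))
  if (test %in% c("t", "wilcoxon") && nlevels(groups) != 2)
    stop("test '", test, "' requires exactly 2 groups")
  lev <- levels(groups)
  if (is.null(min_obs)) min_obs <- ceiling(0.3 * min(table(groups)))
  obs_ok <- Reduce(`&`, lapply(lev, function(l)
    rowSums(!is.na(v[, groups == l, drop = FALSE])) >= min_obs))
  n_skipped <- sum(!obs_ok)
  if (n_skipped > 0)
    message(n_skipped, " feature(s) below the min_obs threshold were skipped")
  vv <- v[obs_ok, , drop = FALSE]
  lin <- linearize(x)[obs_ok, , drop = FALSE]
  means <- sapply(lev, function(l)
    rowMeans(lin[, groups == l, drop = FALSE], na.rm = TRUE))
  if (!is.matrix(means)) means <- matrix(means, nrow = sum(obs_ok),
                                         dimnames = list(rownames(vv), lev))
  colnames(means) <- paste0("mean_", lev)
  if (nlevels(groups) == 2) {
    log2fc <- log2(means[, 1] / means[, 2])
  } else {
    log2fc <- rep(NA_real_, nrow(vv))
  }
  stat <- p <- rep(NA_real_, nrow(vv))
  if (nrow(vv) > 0) {
    if (test == "t") {
      res <- welch_rows(vv, groups == lev[1], groups == lev[2], pooled = pooled_var)
      stat <- res$stat; p <- res$p
      zero_se <- !is.finite(stat)
      stat[zero_se] <- 0; p[zero_se] <- 1
    } else if (test == "wilcoxon") {
      for (i in seq_len(nrow(vv))) {
        a <- vv[i, groups == lev[1]]; b <- vv[i, groups == lev[2]]
        wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
        stat[i] <- wt$statistic; p[i] <- wt$p.value
      }
    } else {
      for (i in seq_len(nrow(vv))) {
        y <- vv[i, ]; ok <- !is.na(y)
        if (test == "anova") {
          ft <- stats::oneway.test(y[ok] ~ groups[ok], var.equal = TRUE)
        } else {
          ft <- stats::kruskal.test(y[ok], groups[ok])
        }
        stat[i] <- unname(ft$statistic); p[i] <- ft$p.value
      }
    }
  }
  p[is.nan(p)] <- 1
  q <- bh_adjust(p)
  call <- rep("ns", nrow(vv))
  if (nlevels(groups) == 2) {
    call[log2fc >= log2(fc_thresh) & q < q_thresh] <- "up"
    call[log2fc <= -log2(fc_thresh) & q < q_thresh] <- "down"
  }  # multi-group tests carry no direction; q is the criterion
  out <- data.frame(feature = rownames(vv), means, log2fc = log2fc,
                    stat = stat, p = p, q = q, call = call, test = test,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Biomarker cascade: complete detection, differential, prognostic
#'
#' Ordered filters for circulating-biomarker candidates: (1) proteins
#' quantified in 100% of tumor samples; (2) overexpressed in tumors versus
#' NATs (FC > `fc_thresh`, p < `p_thresh`; raw p by default, BH behind
#' `use_adjusted`); (3) hazardous (HR > 1 with cutpoint-based survival p <
#' `surv_p_thresh` at the maximally-selected cutpoint). Per-stage survivor
#' counts are reported.
#'
#' @param protein an [omics_matrix] (protein layer, tumors and NATs).
#' @param clinical a `clinical_table` covering the matrix samples.
#' @param fc_thresh,p_thresh stage-2 thresholds.
#' @param use_adjusted use BH-adjusted q instead of raw p in stage 2.
#' @param surv_p_thresh stage-3 threshold on the selection-adjusted cutpoint
#'   p-value.
#' @param endpoint `"os"` or `"dfs"`.
#' @param n_perm permutations for the cutpoint p-value.
#' @param rng_seed seed for the permutation p-values.
#' @return list with `stage_counts` and the surviving feature IDs per stage
#'   (`stage1`, `stage2`, `stage3`) plus the stage-3 survival table.
#' @export
biomarker_cascade_exosome <- function(protein, clinical, fc_thresh = 2,
                                      p_thresh = 0.05, use_adjusted = FALSE,
                                      surv_p_thresh = 0.05, endpoint = "os",
                                      n_perm = 200, rng_seed = 1) {
  v <- as_values(protein)
  cl <- clinical[match(colnames(v), clinical$sample_id), ]
  if (any(is.na(cl$tissue))) stop("clinical table does not cover all samples")
  tum <- cl$tissue == "tumor"
  if (!any(tum) || !any(!tum)) stop("need both tumor and NAT samples")
  stage1 <- rownames(v)[rowSums(is.na(v[, tum, drop = FALSE])) == 0]
  stage2 <- character(0); stage3 <- character(0); surv_tab <- NULL
  if (length(stage1) > 0) {
    de <- compare_groups(subset_matrix(protein, stage1),
                         factor(ifelse(tum, "tumor", "nat"),
                                levels = c("tumor", "nat")),
                         test = "t", fc_thresh = fc_thresh, q_thresh = 1,
                         min_obs = 1)
    crit <- if (use_adjusted) de$q else de$p
    stage2 <- de$feature[de$log2fc > log2(fc_thresh) & crit < p_thresh]
  }
  if (length(stage2) > 0) {
    tum_m <- subset_matrix(protein, stage2, colnames(v)[tum])
    surv_tab <- survival_screen(tum_m, clinical, endpoint = endpoint,
                                n_perm = n_perm, rng_seed = rng_seed)
    stage3 <- surv_tab$feature[!is.na(surv_tab$hr) & surv_tab$hr > 1 &
                                 surv_tab$perm_p < surv_p_thresh]
  }
  list(stage_counts = c(complete = length(stage1), differential = length(stage2),
                        prognostic = length(stage3)),
       stage1 = stage1, stage2 = stage2, stage3 = stage3,
       survival = surv_tab)
}

subset_matrix <- function(x, features = NULL, samples = NULL) {
  v <- as_values(x)
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  if (inherits(x, "omics_matrix")) omics_matrix(v, x$layer, x$scale) else v
}

#' Subtype discriminative-marker screen
#'
#' Screens for proteins that mark one subtype: (1) quantified in at least
#' `min_frac` of samples; (2) higher in one subtype than the rest
#' (one-vs-rest linear-mean ratio > `ratio_thresh`, BH q < `q_thresh`, and
#' subtype mean above every other subtype's mean); (3) prognostic (cutpoint
#' survival p < `surv_p_thresh`).
#'
#' @param protein an [omics_matrix] of tumor samples.
#' @param subtype_labels named vector (sample -> subtype) or vector aligned
#'   with the matrix columns; every subtype needs >= 3 samples.
#' @param clinical `clinical_table` for the survival stage (NULL skips
#'   stage 3).
#' @param min_frac detection fraction threshold (default 0.9).
#' @param ratio_thresh one-vs-rest linear ratio threshold (default 1.5).
#' @param q_thresh BH threshold (default 0.05).
#' @param surv_p_thresh survival p threshold (default 0.05).
#' @param n_perm,rng_seed cutpoint permutation settings.
#' @return data.frame: `feature`, `subtype`, `ratio`, `q`, and (with
#'   clinical) `surv_p`, `hr`; one row per marker.
#' @export
subtype_marker_screen <- function(protein, subtype_labels, clinical = NULL,
                                  min_frac = 0.9, ratio_thresh = 1.5,
                                  q_thresh = 0.05, surv_p_thresh = 0.05,
                                  n_perm = 200, rng_seed = 1) {
  v <- as_values(protein)
  if (!is.null(names(subtype_labels)))
    subtype_labels <- subtype_labels[colnames(v)]
  labs <- factor(subtype_labels)
  if (nlevels(labs) < 2) stop(">= 2 subtypes required")
  if (any(table(labs) < 3))
    stop("subtype(s) with < 3 samples: ",
         paste(levels(labs)[table(labs) < 3], collapse = ", "))
  present <- rowMeans(!is.na(v)) >= min_frac
  keep <- rownames(v)[present]
  rows <- list()
  for (s in levels(labs)) {
    grp <- factor(ifelse(labs == s, s, "rest"), levels = c(s, "rest"))
    de <- compare_groups(subset_matrix(protein, keep), grp, test = "t",
                         fc_thresh = ratio_thresh, q_thresh = q_thresh,
                         min_obs = 2)
    lin <- linearize(subset_matrix(protein, keep))
    other_means <- sapply(setdiff(levels(labs), s), function(o)
      rowMeans(lin[, labs == o, drop = FALSE], na.rm = TRUE))
    if (!is.matrix(other_means))
      other_means <- matrix(other_means, ncol = 1)
    dominates <- de[[paste0("mean_", s)]] > apply(other_means[match(de$feature, keep), , drop = FALSE], 1, max)
    hit <- de$call == "up" & dominates
    if (any(hit))
      rows[[s]] <- data.frame(feature = de$feature[hit], subtype = s,
                              ratio = 2^de$log2fc[hit], q = de$q[hit],
                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(0), subtype = character(0),
               ratio = numeric(0), q = numeric(0))
  rownames(out) <- NULL
  if (!is.null(clinical) && nrow(out) > 0) {
    sv <- survival_screen(subset_matrix(protein, unique(out$feature)),
                          clinical, n_perm = n_perm, rng_seed = rng_seed)
    idx <- match(out$feature, sv$feature)
    out$surv_p <- sv$perm_p[idx]
    out$hr <- sv$hr[idx]
    out <- out[!is.na(out$surv_p) & out$surv_p < surv_p_thresh, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
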