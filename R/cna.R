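# Copy-number cis/trans effect screening and binary-event association tests.

# A target feature maps to its gene: phosphosites via their gene prefix,
# everything else by identity.
target_gene_of <- function(features) {
  sub("_p[STY][0-9]+$", "", features)
}

#' Screen copy-number effects on a molecular layer (cis and trans)
#'
#' Correlates each CNA gene's log-ratio with target-feature abundance over
#' shared samples (Spearman, pairwise-complete). A pair is a *cis* effect
#' when the target feature maps to the CNA gene itself (phosphosites map via
#' their gene prefix); all other pairs are *trans*. BH adjustment is applied
#' within the target layer.
#'
#' @param cna an [omics_matrix] of layer `cna` (genes x samples).
#' @param targets an [omics_matrix] of the target layer.
#' @param mode `"cis_only"` (default) tests only same-gene pairs; `"all"`
#'   tests every CNA-gene x target pair.
#' @param min_pairs minimum complete sample pairs per test (default 10).
#' @param alternative `"two.sided"` (default) or `"greater"` (positive
#'   correlations, the direction expected of a dosage effect).
#' @return data.frame of class `cis_trans_result`: `cna_gene`,
#'   `target_feature`, `target_layer`, `relation`, `rho`, `p`, `q`,
#'   `n_pairs`.
#' @export
cis_trans_screen <- function(cna, targets, mode = c("cis_only", "all"),
                             min_pairs = 10,
                             alternative = c("two.sided", "greater")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  cv <- as_values(cna); tv <- as_values(targets)
  shared <- intersect(colnames(cv), colnames(tv))
  if (length(shared) < min_pairs)
    stop("fewer than min_pairs shared samples between the layers")
  tg <- target_gene_of(rownames(tv))
  pairs <- if (mode == "cis_only") {
    idx <- which(tg %in% rownames(cv))
    data.frame(cna_gene = tg[idx], target = rownames(tv)[idx],
               stringsAsFactors = FALSE)
  } else {
    expand.grid(cna_gene = rownames(cv), target = rownames(tv),
                stringsAsFactors = FALSE)
  }
  layer <- if (inherits(targets, "omics_matrix")) targets$layer else "unknown"
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs$cna_gene[i]; f <- pairs$target[i]
    xs <- cv[g, shared]; ys <- tv[f, shared]
    ok <- !is.na(xs) & !is.na(ys)
    if (sum(ok) < min_pairs) return(NULL)
    ct <- suppressWarnings(stats::cor.test(xs[ok], ys[ok], method = "spearman",
                                           exact = FALSE,
                                           alternative = alternative))
    data.frame(cna_gene = g, target_feature = f, target_layer = layer,
               relation = if (target_gene_of(f) == g) "cis" else "trans",
               rho = unname(ct$estimate), p = ct$p.value, n_pairs = sum(ok),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    stop("no testable CNA-target pair with >= min_pairs complete samples")
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[, c("cna_gene", "target_feature", "target_layer", "relation",
                 "rho", "p", "q", "n_pairs")]
  class(out) <- c("cis_trans_result", "data.frame")
  out
}

#' Mutual exclusivity / co-occurrence of two binary genomic events
#'
#' Two-sided Fisher's exact test on the 2x2 co-occurrence table of two rows
#' of a binary event matrix. The direction is `exclusive` when the sample
#' odds ratio is below one and `co-occurring` when above.
#'
#' @param events binary events x samples matrix (0/1) with rownames.
#' @param a,b event row names.
#' @return list with `odds_ratio` (sample OR, n11*n00/(n10*n01)), `p`,
#'   `direction`, `table`.
#' @export
mutual_exclusivity <- function(events, a, b) {
  ea <- events[a, ]; eb <- events[b, ]
  if (!all(c(ea, eb) %in% c(0, 1))) stop("event matrix must be binary")
  for (nm in c(a, b)) {
    e <- events[nm, ]
    if (all(e == 0) || all(e == 1))
      stop("event '", nm, "' has a degenerate margin (present in all or no samples)")
  }
  tab <- matrix(c(sum(ea == 1 & eb == 1), sum(ea == 1 & eb == 0),
                  sum(ea == 0 & eb == 1), sum(ea == 0 & eb == 0)),
                2, 2, byrow = TRUE,
                dimnames = list(c("a1", "a0"), c("b1", "b0")))
  ft <- stats::fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p = ft$p.value,
       direction = if (!is.nan(or) && or < 1) "exclusive" else
         if (!is.nan(or) && or > 1) "co-occurring" else "none",
       table = tab)
}

#' Associate binary events with categorical clinical variables
#'
#' Batched Fisher's exact tests of each event against each categorical
#' clinical column; `"unknown"` and missing categories are excluded (their
#' count is reported). BH adjustment across all tested pairs.
#'
#' @param events binary events x samples matrix with sample colnames.
#' @param feature_table data.frame of categorical columns, rownames (or a
#'   `sample_id` column) matching the event samples.
#' @return data.frame: `event`, `variable`, `p`, `q`, `n_used`.
#' @export
event_feature_association <- function(events, feature_table) {
  if ("sample_id" %in% names(feature_table)) {
    rownames(feature_table) <- feature_table$sample_id
    feature_table$sample_id <- NULL
  }
  shared <- intersect(colnames(events), rownames(feature_table))
  if (length(shared) == 0) stop("no shared samples")
  rows <- list()
  for (ev in rownames(events)) {
    for (var in names(feature_table)) {
      lab <- as.character(feature_table[shared, var])
      use <- !is.na(lab) & lab != "unknown"
      e <- factor(events[ev, shared][use], levels = c(0, 1))
      l <- factor(lab[use])
      if (nlevels(droplevels(l)) < 2 || length(unique(e)) < 1) next
      tab <- table(e, droplevels(l))
      if (any(dim(tab) < 2)) next
      p <- stats::fisher.test(tab)$p.value
      rows[[paste(ev, var)]] <- data.frame(event = ev, variable = var, p = p,
                                           n_used = sum(use),
                                           stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(event = character(0), variable = character(0),
                      p = numeric(0), q = numeric(0), n_used = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out[, c("event", "variable", "p", "q", "n_used")]
}
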