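# Single-sample enrichment scores: a rank-based weighted Kolmogorov-Smirnov
# random walk (GSVA-style), the multi-gene proliferation score, and
# transcription-factor activity over target-gene sets.

#' Single-sample gene-set scores by a weighted KS random walk
#'
#' For each gene, a cross-sample standing is estimated with a Gaussian-kernel
#' cumulative density (bandwidth sd/4). Within each sample, genes are ranked
#' by that statistic; a weighted Kolmogorov-Smirnov random walk over the
#' ranking uses in-set increments proportional to the symmetric rank weight
#' `|(p+1)/2 - rank|^tau` (so tail genes at either end weigh most, and
#' mirrored placements score exactly opposite) and uniform out-of-set
#' decrements. The score is the
#' maximum positive deviation plus the minimum negative deviation of the walk
#' ("maxdiff"), so sets concentrated at the top of a sample's ranking score
#' positive and mirrored sets score negative.
#'
#' @param x an [omics_matrix] or matrix (features x samples, >= 3 samples).
#' @param sets a `gene_set_collection` (named list of feature IDs).
#' @param tau rank-weight exponent (default 1).
#' @param min_set_size sets with fewer members present in the matrix are
#'   dropped with a warning (default 5).
#' @return sets x samples score matrix of class `score_matrix` with
#'   attributes `method` and `tau`.
#' @export
gsva_score <- function(x, sets, tau = 1, min_set_size = 5) {
  v <- as_values(x)
  if (ncol(v) < 3) stop(">= 3 samples required for the cross-sample density step")
  sets <- lapply(sets, intersect, rownames(v))
  small <- lengths(sets) < min_set_size
  if (any(small)) {
    warning("dropping set(s) below min_set_size: ",
            paste(names(sets)[small], collapse = ", "))
    sets <- sets[!small]
  }
  if (length(sets) == 0) stop("no scorable sets after intersection")
  kcdf <- t(apply(v, 1, function(row) {
    obs <- !is.na(row)
    if (sum(obs) < 2) return(rep(NA_real_, length(row)))
    bw <- max(stats::sd(row[obs]) / 4, 1e-9)
    z <- rep(NA_real_, length(row))
    z[obs] <- vapply(row[obs], function(xi)
      mean(stats::pnorm((xi - row[obs]) / bw)), numeric(1))
    z
  }))
  dimnames(kcdf) <- dimnames(v)
  scores <- matrix(NA_real_, length(sets), ncol(v),
                   dimnames = list(names(sets), colnames(v)))
  for (j in seq_len(ncol(v))) {
    zc <- kcdf[, j]
    usable <- !is.na(zc)
    p <- sum(usable)
    if (p < 2) next
    ord <- order(zc[usable], decreasing = TRUE)
    ranked_genes <- rownames(v)[usable][ord]
    w <- abs((p + 1) / 2 - seq_len(p))^tau
    for (s in seq_along(sets)) {
      members <- ranked_genes %in% sets[[s]]
      if (!any(members) || all(members)) { scores[s, j] <- 0; next }
      step <- ifelse(members, w / sum(w[members]), -1 / sum(!members))
      walk <- cumsum(step)
      scores[s, j] <- max(c(0, walk)) + min(c(0, walk))
    }
  }
  structure(scores, method = "gsva_ks", tau = tau, class = c("score_matrix", "matrix", "array"))
}

#' Multi-gene proliferation score
#'
#' Mean of the row-z-scored abundances of the cell-cycle-regulated gene set
#' in each sample (missing-aware): the standard summary of proliferative
#' activity from normalized expression/proteomic data.
#'
#' @param x an [omics_matrix] or matrix.
#' @param cellcycle_set character vector of cell-cycle-regulated features.
#' @param min_set_size minimum set members present (default 5).
#' @return named per-sample score vector.
#' @export
mgps <- function(x, cellcycle_set, min_set_size = 5) {
  v <- as_values(x)
  members <- intersect(cellcycle_set, rownames(v))
  if (length(members) == 0) stop("cell-cycle set has no overlap with the matrix")
  if (length(members) < min_set_size)
    stop("cell-cycle set overlap (", length(members), ") below min_set_size")
  z <- as_values(suppressMessages(zscore_rows(subset_matrix(x, members))))
  colMeans(z, na.rm = TRUE)
}

#' Transcription-factor activity from target-gene sets
#'
#' Thin semantic alias for [gsva_score] over TF target regulons: a TF's
#' activity in a sample is the enrichment of its targets in that sample's
#' expression ranking.
#'
#' @param x an [omics_matrix] or matrix.
#' @param tf_target_sets named list: TF -> target feature IDs.
#' @inheritParams gsva_score
#' @return TFs x samples `score_matrix`.
#' @export
tf_activity <- function(x, tf_target_sets, tau = 1, min_set_size = 5) {
  gsva_score(x, tf_target_sets, tau = tau, min_set_size = min_set_size)
}
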