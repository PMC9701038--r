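# Kinase-substrate enrichment analysis: kinase activity from the aggregate
# abundance change of substrate phosphosites, plus kinase-substrate
# correlation screens.

#' KSEA z-statistic over a per-site contrast vector
#'
#' For a kinase with m matched substrate sites, the activity statistic is
#' `z = (mean(substrates) - mean(all sites)) * sqrt(m) / sd(all sites)` with
#' a two-sided normal p-value and BH adjustment across kinases. The
#' background is always the full site vector; sites shared by several
#' kinases count for each of them (no exclusivity correction).
#'
#' @param site_values named numeric vector per phosphosite (typically
#'   tumor/NAT mean log2 fold changes, or one sample's site z-scores).
#' @param ks_map a `kinase_substrate_map` (kinase -> site IDs).
#' @param min_substrates kinases with fewer matched substrates are skipped
#'   (logged; default 3).
#' @return data.frame of class `kinase_activity_result`: `kinase`, `m`, `z`,
#'   `p`, `q`, `substrates` (semicolon-joined IDs used).
#' @export
ksea_z <- function(site_values, ks_map, min_substrates = 3) {
  site_values <- site_values[!is.na(site_values)]
  if (length(site_values) < 2) stop("need >= 2 non-missing site values")
  if (any(!is.finite(site_values))) stop("site values must be finite")
  mu <- mean(site_values)
  sigma <- stats::sd(site_values)
  if (sigma == 0) stop("all site values identical: background SD is zero")
  rows <- lapply(names(ks_map), function(k) {
    s <- intersect(ks_map[[k]], names(site_values))
    m <- length(s)
    if (m < min_substrates) return(NULL)
    z <- (mean(site_values[s]) - mu) * sqrt(m) / sigma
    data.frame(kinase = k, m = m, z = z, p = 2 * stats::pnorm(-abs(z)),
               substrates = paste(s, collapse = ";"), stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0)
    message(skipped, " kinase(s) below min_substrates were skipped")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no kinase has >= min_substrates matched sites")
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[, c("kinase", "m", "z", "p", "q", "substrates")]
  class(out) <- c("kinase_activity_result", "data.frame")
  out
}

#' Per-sample kinase activity scores
#'
#' Applies [ksea_z] to each sample's row-z-scored phosphosite profile,
#' producing a kinase x sample activity matrix.
#'
#' @param phospho an [omics_matrix] (phospho layer) or matrix.
#' @inheritParams ksea_z
#' @return kinases x samples numeric matrix of z-statistics.
#' @export
ksea_per_sample <- function(phospho, ks_map, min_substrates = 3) {
  z <- as_values(suppressMessages(zscore_rows(phospho)))
  res <- lapply(seq_len(ncol(z)), function(j) {
    col <- z[, j]
    tab <- suppressMessages(ksea_z(col, ks_map, min_substrates))
    stats::setNames(tab$z, tab$kinase)
  })
  kin <- sort(unique(unlist(lapply(res, names))))
  out <- sapply(res, function(r) r[kin])
  rownames(out) <- kin
  colnames(out) <- colnames(z)
  out
}

#' Correlation between a kinase's protein abundance and candidate substrate
#' sites
#'
#' Spearman correlation (tie-corrected ranks, pairwise-complete) between the
#' kinase's protein expression and the abundance of each mapped substrate
#' phosphosite, with BH adjustment across tested sites. Pairs with fewer
#' than `min_pairs` complete observations are skipped (logged).
#'
#' @param kinase_abundance named numeric vector (sample -> protein value).
#' @param site_matrix an [omics_matrix] (phospho) or matrix.
#' @param ks_map `kinase_substrate_map`.
#' @param kinase kinase name to screen (must be in the map).
#' @param min_pairs minimum complete pairs (default 10).
#' @return data.frame: `site`, `rho`, `p`, `q`, `n_pairs`.
#' @export
kinase_substrate_correlation <- function(kinase_abundance, site_matrix, ks_map,
                                         kinase, min_pairs = 10) {
  if (!kinase %in% names(ks_map)) stop("kinase '", kinase, "' not in the map")
  v <- as_values(site_matrix)
  shared <- intersect(names(kinase_abundance), colnames(v))
  sites <- intersect(ks_map[[kinase]], rownames(v))
  rows <- lapply(sites, function(s) {
    xs <- kinase_abundance[shared]
    ys <- v[s, shared]
    ok <- !is.na(xs) & !is.na(ys)
    if (sum(ok) < min_pairs) return(NULL)
    ct <- suppressWarnings(stats::cor.test(xs[ok], ys[ok], method = "spearman",
                                           exact = FALSE))
    data.frame(site = s, rho = unname(ct$estimate), p = ct$p.value,
               n_pairs = sum(ok), stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0)
    message(skipped, " site(s) with < min_pairs complete observations skipped")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(site = character(0), rho = numeric(0), p = numeric(0),
                      q = numeric(0), n_pairs = integer(0)))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[, c("site", "rho", "p", "q", "n_pairs")]
}
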