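# Consensus-clustering subtype discovery with CDF / delta-area / silhouette
# model selection, cluster merging, and PCA projection.

#' Select the top-variance feature subset
#'
#' Keeps the `floor(top_fraction * m)` features with the largest standard
#' deviation (missing-aware); ties at the boundary are broken by feature ID
#' order (lexicographically smaller kept).
#'
#' @param x an [omics_matrix] or matrix.
#' @param top_fraction fraction of features to keep (default 0.5).
#' @return character vector of kept feature IDs.
#' @export
select_features <- function(x, top_fraction = 0.5) {
  v <- as_values(x)
  sds <- apply(v, 1, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0
  if (all(sds == 0)) stop("all features are constant")
  n_keep <- max(1L, floor(top_fraction * nrow(v)))
  ord <- order(-sds, rownames(v))
  rownames(v)[ord][seq_len(n_keep)]
}

spearman_distance <- function(v) {
  rho <- suppressWarnings(stats::cor(v, method = "spearman",
                                     use = "pairwise.complete.obs"))
  rho[is.na(rho)] <- 0
  1 - rho
}

#' Consensus clustering by subsampled hierarchical clustering
#'
#' Repeatedly subsamples `floor(p_item * n)` samples without replacement,
#' clusters them hierarchically (average linkage on 1 - Spearman correlation
#' between sample profiles) and cuts the tree at every k in `k_range`. The
#' consensus matrix entry M_k(i, j) is the fraction of co-subsampled
#' repetitions in which i and j co-clustered. Final assignments come from
#' hierarchical clustering of 1 - M_k. Diagnostics: the empirical CDF of
#' upper-triangle consensus values, its area A(k), the relative delta area
#' (delta(2) = A(2); delta(k) = (A(k) - A(k-1)) / A(k-1)), and the mean
#' silhouette width of the consensus clusters on the 1 - Spearman data
#' distance (structureless data then earns silhouettes near zero, whereas
#' consensus-matrix distances can look crisp even for noise).
#'
#' @param x an [omics_matrix] or matrix (features x samples).
#' @param k_range candidate cluster numbers, within [2, n-1].
#' @param n_reps subsampling repetitions (>= 50; default 500).
#' @param p_item sample subsampling fraction (default 0.8).
#' @param rng_seed integer seed (deterministic given seed).
#' @param linkage hclust linkage for both the inner and final clustering
#'   (default "average").
#' @param min_coverage samples observed on fewer than this fraction of the
#'   features are excluded with a warning (default 0.5).
#' @return list of class `consensus_result`: `k_range`, `consensus` (list of
#'   M_k), `assignments` (list of named integer vectors), `A`, `delta`,
#'   `silhouette`, `samples`.
#' @export
consensus_cluster <- function(x, k_range, n_reps = 500, p_item = 0.8,
                              rng_seed = 1, linkage = "average",
                              min_coverage = 0.5) {
  v <- as_values(x)
  cover <- colMeans(!is.na(v))
  if (any(cover < min_coverage)) {
    warning(sum(cover < min_coverage),
            " sample(s) below the feature-coverage threshold excluded")
    v <- v[, cover >= min_coverage, drop = FALSE]
  }
  n <- ncol(v)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2 | k_range > n - 1))
    stop("k_range must lie within [2, n_samples - 1]")
  if (n_reps < 50) stop("n_reps must be >= 50")
  D <- spearman_distance(v)
  n_sub <- floor(p_item * n)
  if (n_sub < max(k_range) + 1) stop("subsample too small for the largest k")
  set.seed(rng_seed %% .Machine$integer.max)
  co_sampled <- matrix(0, n, n)
  co_clustered <- stats::setNames(
    lapply(k_range, function(k) matrix(0, n, n)), k_range)
  for (r in seq_len(n_reps)) {
    idx <- sort(sample.int(n, n_sub))
    hc <- stats::hclust(stats::as.dist(D[idx, idx]), method = linkage)
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    for (k in k_range) {
      cl <- stats::cutree(hc, k)
      same <- outer(cl, cl, "==") * 1
      kk <- as.character(k)
      co_clustered[[kk]][idx, idx] <- co_clustered[[kk]][idx, idx] + same
    }
  }
  isolated <- which(rowSums(co_sampled > 0) <= 1)
  if (length(isolated))
    stop("sample(s) never co-subsampled with any other; increase n_reps")
  consensus <- lapply(co_clustered, function(cc) {
    M <- ifelse(co_sampled > 0, cc / pmax(co_sampled, 1), 0)
    diag(M) <- 1
    dimnames(M) <- list(colnames(v), colnames(v))
    M
  })
  assignments <- stats::setNames(vector("list", length(k_range)), k_range)
  A <- numeric(length(k_range)); sil <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    M <- consensus[[as.character(k)]]
    hc_final <- stats::hclust(stats::as.dist(1 - M), method = linkage)
    cl <- stats::cutree(hc_final, k)
    assignments[[as.character(k)]] <- cl
    ut <- M[upper.tri(M)]
    xs <- sort(unique(c(0, ut, 1)))
    cdf <- stats::ecdf(ut)
    A[i] <- sum(diff(xs) * cdf(utils::head(xs, -1)))
    # silhouette on the data distance: measures whether the consensus
    # clusters are supported by the sample geometry itself (resampling
    # self-consistency alone can look crisp even on structureless data)
    sw <- cluster::silhouette(cl, dmatrix = D)
    sil[i] <- if (is.matrix(sw)) mean(sw[, "sil_width"]) else NA_real_
  }
  delta <- c(A[1], diff(A) / utils::head(A, -1))
  structure(list(k_range = k_range, consensus = consensus,
                 assignments = assignments,
                 A = stats::setNames(A, k_range),
                 delta = stats::setNames(delta, k_range),
                 silhouette = stats::setNames(sil, k_range),
                 samples = colnames(v)),
            class = "consensus_result")
}

#' Choose the number of clusters from consensus diagnostics
#'
#' Among k whose relative delta-area meets the `elbow` threshold, picks the
#' k with the largest mean silhouette (ties broken toward the smaller k).
#' Always returns a k; the attached `confidence` attribute is
#' `"no support"` when every silhouette is below 0.25 (structureless data)
#' and `"low"` when no k passed the elbow rule.
#'
#' @param result a [consensus_cluster] result.
#' @param elbow relative delta-area threshold (default 0.025).
#' @return chosen k (integer) with attribute `confidence`.
#' @export
choose_k <- function(result, elbow = 0.025) {
  stopifnot(inherits(result, "consensus_result"))
  k_range <- result$k_range
  eligible <- result$delta >= elbow
  conf <- "ok"
  if (!any(eligible)) { eligible <- rep(TRUE, length(k_range)); conf <- "low" }
  sil <- result$silhouette
  cand <- k_range[eligible]
  smax <- max(sil[eligible])
  best <- min(cand[sil[eligible] >= smax - 1e-12])  # ties -> smaller k
  if (max(sil, na.rm = TRUE) < 0.25) conf <- "no support"
  structure(as.integer(best), confidence = conf)
}

#' Merge cluster labels according to an explicit map
#'
#' @param assignments vector of cluster labels (named by sample or not).
#' @param merge_map named vector/list: old label -> new label; must cover
#'   every label present.
#' @return relabeled assignments (same length/names); counts are conserved.
#' @export
merge_clusters <- function(assignments, merge_map) {
  merge_map <- unlist(merge_map)
  labs <- as.character(assignments)
  missing_lab <- setdiff(unique(labs), names(merge_map))
  if (length(missing_lab))
    stop("merge map does not cover label(s): ",
         paste(missing_lab, collapse = ", "))
  out <- unname(merge_map[labs])
  names(out) <- names(assignments)
  out
}

#' Centred-SVD PCA projection of samples
#'
#' Features are mean-imputed where missing, samples are projected onto the
#' first `n_components` principal components; each component's sign is fixed
#' so its largest-magnitude loading is positive.
#'
#' @param x an [omics_matrix] or matrix (features x samples).
#' @param n_components number of components (default 2).
#' @return list with `scores` (samples x components),
#'   `explained_variance_ratio`, `loadings`.
#' @export
project_pca <- function(x, n_components = 2) {
  v <- as_values(x)
  imp <- t(apply(v, 1, function(r) {
    r[is.na(r)] <- mean(r, na.rm = TRUE)
    r
  }))
  imp <- imp[apply(imp, 1, function(r) all(is.finite(r))), , drop = FALSE]
  pc <- stats::prcomp(t(imp), center = TRUE, scale. = FALSE)
  rank_ <- sum(pc$sdev > 1e-10)
  if (n_components > rank_)
    stop("n_components (", n_components, ") exceeds the data rank (", rank_, ")")
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores,
       explained_variance_ratio = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)],
       loadings = load)
}

#' Adjusted Rand index between two clusterings
#'
#' Chance-corrected agreement between two label vectors (1 = identical
#' partitions up to label names, ~0 = random agreement).
#'
#' @param a,b label vectors of equal length.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}
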