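# 96-channel mutation catalogs and signature extraction by NMF.

#' Build a 96-channel trinucleotide mutation catalog
#'
#' Each qualifying SNV (pyrimidine-centred context present, alleles valid)
#' increments exactly one channel of its sample. Non-SNVs and missing
#' contexts are skipped; their count is reported as an attribute and a
#' message. Samples are the columns, in the order given.
#'
#' @param muts a `mutation_table` (see [read_maf]).
#' @param samples character vector of sample IDs defining the catalog
#'   columns; every mutation's sample must be among them.
#' @return 96 x length(samples) integer matrix of class `mutation_catalog`
#'   with rows in the canonical [sbs_channels] order.
#' @export
build_catalog <- function(muts, samples) {
  if (anyDuplicated(samples)) stop("duplicate sample IDs")
  unknown <- setdiff(unique(muts$sample_id), samples)
  if (length(unknown))
    stop("mutation sample(s) absent from the clinical sample list: ",
         paste(utils::head(unknown), collapse = ", "))
  ch <- sbs_channel_of(muts$trinucleotide_context, muts$ref_allele,
                       muts$alt_allele)
  skipped <- sum(is.na(ch))
  keep <- !is.na(ch)
  cat_mat <- matrix(0L, 96, length(samples),
                    dimnames = list(sbs_channels(), samples))
  if (any(keep)) {
    tab <- table(factor(ch[keep], levels = sbs_channels()),
                 factor(muts$sample_id[keep], levels = samples))
    cat_mat[] <- as.integer(tab)
  } else {
    warning("no contextful SNVs: the catalog is all zero")
  }
  if (skipped > 0)
    message(skipped, " mutation(s) without a usable trinucleotide channel were skipped")
  structure(cat_mat, skipped = skipped, class = c("mutation_catalog", "matrix", "array"))
}

frobenius_rel_error <- function(V, W, H) {
  sqrt(sum((V - W %*% H)^2)) / max(sqrt(sum(V^2)), .Machine$double.eps)
}

# One multiplicative-update NMF run (Frobenius objective).
nmf_run <- function(V, K, max_iter, tol) {
  eps <- 1e-12
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * K, 0.1, 1), n, K)
  H <- matrix(stats::runif(K * m, 0.1, 1), K, m)
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
    W <- W * (tcrossprod(V, H) / (W %*% tcrossprod(H) + eps))
    if (it %% 10 == 0 || it == max_iter) {
      err <- frobenius_rel_error(V, W, H)
      if (is.finite(err_prev) && (err_prev - err) < tol * max(err_prev, eps)) break
      err_prev <- err
    }
  }
  list(W = W, H = H, err = frobenius_rel_error(V, W, H))
}

#' Factorize a mutation catalog into K signatures by NMF
#'
#' Multiplicative-update non-negative matrix factorization of the 96 x S
#' catalog minimizing Frobenius reconstruction error; the best of
#' `n_restarts` random initializations is kept. Signature columns of `W` are
#' L1-normalized (the compensating scale is folded into `H`); `exposures`
#' are `H` with columns normalized to sum to one.
#'
#' @param catalog a [build_catalog] matrix (96 x samples).
#' @param K number of signatures (1 <= K <= min(96, n samples)).
#' @param n_restarts random restarts (best kept).
#' @param rng_seed integer seed making the run deterministic.
#' @param max_iter,tol multiplicative-update iteration cap and relative
#'   error-change stopping tolerance.
#' @return list of class `signature_decomposition` with `W` (96 x K, columns
#'   sum to 1), `H` (K x S), `exposures` (K x S, columns sum to 1), `K`,
#'   `rel_error`, `restart_errors`, and per-restart signature matrices in
#'   `restart_W` (for stability diagnostics).
#' @export
factorize <- function(catalog, K, n_restarts = 10, rng_seed = 1,
                      max_iter = 5000, tol = 1e-6) {
  V <- unclass(catalog)
  if (any(V < 0)) stop("catalog must be non-negative")
  if (all(V == 0)) stop("catalog is all zero; nothing to factorize")
  if (K < 1 || K > min(nrow(V), ncol(V)))
    stop("K must lie in [1, min(96, n_samples)]")
  set.seed(rng_seed %% .Machine$integer.max)
  runs <- lapply(seq_len(n_restarts), function(i) nmf_run(V, K, max_iter, tol))
  errs <- vapply(runs, `[[`, numeric(1), "err")
  best <- runs[[which.min(errs)]]
  norm_sig <- function(run) {
    s <- colSums(run$W)
    s[s == 0] <- 1
    W <- sweep(run$W, 2, s, "/")
    rownames(W) <- rownames(V)
    colnames(W) <- paste0("Signature", seq_len(ncol(W)))
    W
  }
  W <- norm_sig(best)
  H <- best$H * colSums(best$W)
  rownames(H) <- colnames(W); colnames(H) <- colnames(V)
  hs <- colSums(H); hs[hs == 0] <- 1
  exposures <- sweep(H, 2, hs, "/")
  structure(list(W = W, H = H, exposures = exposures, K = K,
                 rel_error = min(errs), restart_errors = errs,
                 restart_W = lapply(runs, norm_sig)),
            class = "signature_decomposition")
}

#' Cosine similarity between two non-negative vectors
#' @param a,b numeric vectors of equal length.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine undefined for a zero-norm vector")
  sum(a * b) / (na * nb)
}

# Mean best-match cosine of each restart's signatures against the reference
# signature set (greedy column matching).
signature_stability <- function(restart_W, ref_W) {
  mean(vapply(restart_W, function(W) {
    cs <- crossprod(W / rep(sqrt(colSums(W^2)), each = nrow(W)),
                    ref_W / rep(sqrt(colSums(ref_W^2)), each = nrow(ref_W)))
    used <- rep(FALSE, ncol(ref_W))
    tot <- 0
    for (i in order(-apply(cs, 1, max))) {
      j <- order(-cs[i, ])
      j <- j[!used[j]][1]
      used[j] <- TRUE
      tot <- tot + cs[i, j]
    }
    tot / ncol(W)
  }, numeric(1)))
}

#' Choose the number of signatures by an elbow-plus-stability rule
#'
#' Fits each k in `k_range` and selects the smallest k after which the
#' reconstruction-error improvement drops below `elbow`. The improvement at
#' k is the per-step error reduction as a fraction of the error at the
#' smallest candidate k, `(err[k-1] - err[k]) / err[k_min]` — a scree-style
#' criterion that stays stable once the residual error is small. The
#' selected k must also be stable across restarts (mean within-k signature
#' cosine >= `stability_min`), otherwise it is decreased until stable.
#'
#' @inheritParams factorize
#' @param k_range candidate k values (ascending).
#' @param elbow relative-improvement threshold (default 0.05).
#' @param stability_min minimum mean within-k cosine across restarts.
#' @param n_restarts restarts per k.
#' @return the chosen k (integer) with diagnostics in attributes
#'   `rel_error`, `improvement`, `stability`.
#' @export
select_k <- function(catalog, k_range, rng_seed = 1, elbow = 0.05,
                     stability_min = 0.8, n_restarts = 5, max_iter = 2000,
                     tol = 1e-5) {
  if (length(k_range) == 0) stop("empty k_range")
  k_range <- sort(unique(as.integer(k_range)))
  fits <- lapply(k_range, function(k)
    factorize(catalog, k, n_restarts = n_restarts,
              rng_seed = rng_seed + k, max_iter = max_iter, tol = tol))
  errs <- vapply(fits, `[[`, numeric(1), "rel_error")
  stab <- vapply(fits, function(f)
    signature_stability(f$restart_W, f$W), numeric(1))
  # per-step improvement as a fraction of the initial (smallest-k) error:
  # a scree-style criterion, stable when the residual error is already small
  imp <- c(NA, -diff(errs) / max(errs[1], 1e-8))
  chosen <- k_range[length(k_range)]
  for (i in seq_along(k_range)[-1]) {
    if (imp[i] < elbow) { chosen <- k_range[i - 1]; break }
  }
  while (chosen > k_range[1] && stab[match(chosen, k_range)] < stability_min)
    chosen <- k_range[match(chosen, k_range) - 1]
  structure(chosen, rel_error = stats::setNames(errs, k_range),
            improvement = stats::setNames(imp, k_range),
            stability = stats::setNames(stab, k_range))
}

#' Match extracted signatures to a reference catalog by cosine similarity
#'
#' For each extracted signature (column of `W`), reports the reference
#' signature with maximal cosine similarity. Both matrices must be on the
#' canonical 96-channel ordering. Cosine ranges from 0 (maximal
#' dissimilarity) to 1 (maximal similarity) for non-negative profiles.
#'
#' @param W 96 x K matrix of extracted signatures (columns).
#' @param reference 96 x R matrix of reference signatures with colnames.
#' @return data.frame with `signature`, `reference`, `cosine`.
#' @export
match_to_reference <- function(W, reference) {
  W <- as.matrix(W); reference <- as.matrix(reference)
  if (nrow(W) != nrow(reference))
    stop("signature and reference matrices must share the channel ordering")
  res <- lapply(seq_len(ncol(W)), function(i) {
    cs <- vapply(seq_len(ncol(reference)), function(j)
      cosine_similarity(W[, i], reference[, j]), numeric(1))
    best <- which.max(cs)
    data.frame(signature = colnames(W)[i] %||% paste0("Signature", i),
               reference = colnames(reference)[best] %||% paste0("Ref", best),
               cosine = cs[best], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
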