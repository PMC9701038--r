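make_catalog <- function(m) {
  stopifnot(nrow(m) == 96)
  dimnames(m) <- list(sbs_channels(), paste0("S", seq_len(ncol(m))))
  structure(m, class = c("mutation_catalog", "matrix", "array"))
}

test_that("catalog building counts each qualifying SNV exactly once", {
  mut <- data.frame(sample_id = "S1", gene = "KRAS",
                    variant_class = "missense", ref_allele = "C",
                    alt_allele = "T", trinucleotide_context = "ACA",
                    protein_change = NA, stringsAsFactors = FALSE)
  cat_ <- build_catalog(mut, c("S1", "S2"))
  expect_equal(sum(cat_), 1)
  expect_equal(cat_["A[C>T]A", "S1"], 1)

  fs <- transform(mut, variant_class = "frameshift",
                  trinucleotide_context = NA, ref_allele = NA, alt_allele = NA)
  expect_warning(suppressMessages(build_catalog(fs, "S1")), "all zero")
  expect_error(build_catalog(mut, "OTHER"), "absent")
})

test_that("catalog columns follow the sampled channel distribution", {
  set.seed(21)
  probs <- as.numeric(stats::rgamma(96, 0.2)); probs <- probs / sum(probs)
  ch <- sample(sbs_channels(), 1000, replace = TRUE, prob = probs)
  mut <- data.frame(sample_id = "S1", gene = "G",
                    variant_class = "missense",
                    ref_allele = substr(ch, 3, 3),
                    alt_allele = substr(ch, 5, 5),
                    trinucleotide_context = paste0(substr(ch, 1, 1),
                                                   substr(ch, 3, 3),
                                                   substr(ch, 7, 7)),
                    protein_change = NA, stringsAsFactors = FALSE)
  cat_ <- build_catalog(mut, "S1")
  keep <- probs > 1e-4
  gof <- suppressWarnings(stats::chisq.test(cat_[keep, 1], p = probs[keep],
                                            rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("NMF recovers a planted exact factorization", {
  set.seed(31)
  W0 <- matrix(stats::rgamma(96 * 2, 0.3), 96, 2)
  W0 <- sweep(W0, 2, colSums(W0), "/")
  H0 <- matrix(stats::rgamma(2 * 12, 1), 2, 12) * 500
  cat_ <- make_catalog(W0 %*% H0)
  dec <- factorize(cat_, 2, n_restarts = 5, rng_seed = 1)
  expect_lt(dec$rel_error, 1e-4)
  cos_best <- apply(crossprod(dec$W, W0) /
                      outer(sqrt(colSums(dec$W^2)), sqrt(colSums(W0^2))),
                    2, max)
  expect_true(all(cos_best >= 0.99))
  # normalizations hold
  expect_equal(colSums(dec$W), rep(1, 2), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(colSums(dec$exposures), rep(1, 12), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a rank-1 catalog is fit exactly at K = 1 and selected as K = 1", {
  set.seed(32)
  w <- stats::rgamma(96, 0.5)
  cat_ <- make_catalog(outer(w, c(100, 220, 350)))
  dec <- factorize(cat_, 1, n_restarts = 2, rng_seed = 1)
  expect_lt(dec$rel_error, 1e-6)
  expect_equal(as.integer(select_k(cat_, 1:3, rng_seed = 1, n_restarts = 3)), 1)
})

test_that("pure-noise catalogs select K = 1 under the elbow rule", {
  set.seed(33)
  cat_ <- make_catalog(matrix(stats::rpois(96 * 40, 20), 96, 40))
  expect_equal(as.integer(select_k(cat_, 1:4, rng_seed = 2, n_restarts = 3)), 1)
})

test_that("reconstruction error is non-increasing in K", {
  set.seed(34)
  co <- generate_cohort(cohort_config(n_patients = 20, n_genes = 100,
                                      n_phosphosites = 20,
                                      n_mut_per_sample = 500, rng_seed = 8))
  tum <- co$clinical$sample_id[co$clinical$tissue == "tumor"]
  cat_ <- suppressMessages(build_catalog(co$mutations, tum))
  errs <- vapply(1:4, function(k)
    factorize(cat_, k, n_restarts = 3, rng_seed = 10)$rel_error, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))
})

test_that("permuting catalog samples permutes exposures identically", {
  set.seed(35)
  co <- generate_cohort(cohort_config(n_patients = 12, n_genes = 100,
                                      n_phosphosites = 20,
                                      n_mut_per_sample = 800, rng_seed = 4))
  tum <- co$clinical$sample_id[co$clinical$tissue == "tumor"]
  cat_ <- suppressMessages(build_catalog(co$mutations, tum))
  perm <- sample(ncol(cat_))
  cat_p <- make_catalog(unclass(cat_)[, perm])
  d1 <- factorize(cat_, 2, n_restarts = 2, rng_seed = 6)
  d2 <- factorize(cat_p, 2, n_restarts = 2, rng_seed = 6)
  # same initialization schedule, permuted data: signatures agree up to
  # component order, exposures follow the sample permutation
  m <- match_to_reference(d2$W, d1$W)
  expect_true(all(m$cosine > 0.99))
  reorder <- match(m$reference, colnames(d1$W))
  expect_equal(unname(d2$exposures[order(reorder), ]),
               unname(d1$exposures[, perm]), tolerance = 0.05)
})

test_that("cosine matching equals the direct dot-product computation", {
  set.seed(36)
  ref <- matrix(stats::rgamma(96 * 3, 0.3), 96,
                dimnames = list(sbs_channels(), c("R1", "R2", "R3")))
  ref <- sweep(ref, 2, colSums(ref), "/")
  # identity match
  m <- match_to_reference(ref[, 1, drop = FALSE], ref)
  expect_equal(m$reference, "R1")
  expect_equal(m$cosine, 1, tolerance = 1e-12)
  # dominant-mixture match against the hand-computed cosine
  mix <- 0.9 * ref[, 1] + 0.1 * ref[, 2]
  m2 <- match_to_reference(matrix(mix, 96), ref)
  expect_equal(m2$reference, "R1")
  expect_equal(m2$cosine,
               sum(mix * ref[, 1]) / sqrt(sum(mix^2) * sum(ref[, 1]^2)),
               tolerance = 1e-12)
  # scale invariance
  m3 <- match_to_reference(matrix(7 * mix, 96), ref)
  expect_equal(m2$cosine, m3$cosine, tolerance = 1e-12)
  # orthogonal one-hot vectors
  a <- c(1, rep(0, 95)); b <- c(0, 1, rep(0, 94))
  expect_equal(cosine_similarity(a, b), 0)
  expect_error(cosine_similarity(a, rep(0, 96)), "zero-norm")
})
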