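test_that("top-variance feature selection keeps the right count and ties", {
  m <- matrix(0, 10, 6, dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  sds <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  for (i in 1:10) m[i, ] <- sds[i] * scale(seq_len(6))[, 1]
  keep <- select_features(m, 0.5)
  expect_length(keep, 5)
  expect_setequal(keep, paste0("f", 1:5))
  # equal-SD boundary tie: lexicographically smaller ID kept
  m2 <- m[1:4, ]
  rownames(m2) <- c("a1", "a2", "zz", "ba")
  m2["ba", ] <- m2["zz", ]  # tie exactly at the keep boundary
  keep2 <- select_features(m2, 0.75)  # keeps floor(3) of 4
  expect_length(keep2, 3)
  expect_true("ba" %in% keep2 && !"zz" %in% keep2)
  # a deep proteome: half of 7055 quantified proteins
  expect_equal(max(1, floor(0.5 * 7055)), 3527)
  expect_error(select_features(matrix(1, 3, 3,
                                      dimnames = list(letters[1:3], LETTERS[1:3]))),
               "constant")
})

test_that("two well-separated blobs give a crisp consensus and exact labels", {
  set.seed(81)
  n_half <- 20
  m <- matrix(stats::rnorm(60 * 2 * n_half), 60, 2 * n_half)
  m[1:30, seq_len(n_half)] <- m[1:30, seq_len(n_half)] + 6          # blob 1
  m[31:60, (n_half + 1):(2 * n_half)] <-
    m[31:60, (n_half + 1):(2 * n_half)] + 6                          # blob 2
  dimnames(m) <- list(paste0("g", 1:60), paste0("s", 1:(2 * n_half)))
  truth <- rep(1:2, each = n_half)
  cc <- consensus_cluster(m, 2:3, n_reps = 100, rng_seed = 3)
  M2 <- cc$consensus[["2"]]
  within <- c(M2[1:n_half, 1:n_half][upper.tri(M2[1:n_half, 1:n_half])],
              M2[-(1:n_half), -(1:n_half)][upper.tri(M2[-(1:n_half), -(1:n_half)])])
  between <- M2[1:n_half, (n_half + 1):(2 * n_half)]
  expect_true(all(within >= 0.99))
  expect_true(all(between <= 0.01))
  expect_equal(adjusted_rand_index(cc$assignments[["2"]], truth), 1)
})

test_that("consensus matrices satisfy their structural invariants", {
  set.seed(82)
  m <- matrix(stats::rnorm(50 * 24), 50, 24,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:24)))
  cc <- consensus_cluster(m, 2:4, n_reps = 60, rng_seed = 5)
  for (k in as.character(2:4)) {
    M <- cc$consensus[[k]]
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_true(all(diag(M) == 1))
    expect_true(all(M >= 0 & M <= 1))
    expect_length(cc$assignments[[k]], 24)
  }
  expect_equal(cc$delta[["2"]], cc$A[["2"]])
  expect_error(consensus_cluster(m, 1:3, n_reps = 60), "k_range")
  expect_error(consensus_cluster(m, 2:3, n_reps = 10), "n_reps")
})

test_that("planted subtypes are recovered with the right k and high ARI", {
  co <- generate_cohort(cohort_config(n_patients = 60, n_genes = 500,
                                      n_phosphosites = 30,
                                      n_mut_per_sample = 20,
                                      subtype_shift = 2, rng_seed = 19))
  tum <- co$clinical$sample_id[co$clinical$tissue == "tumor"]
  tm <- co$protein$values[, tum]
  keep <- select_features(tm, 0.5)
  cc <- consensus_cluster(tm[keep, ], 2:5, n_reps = 200, rng_seed = 7)
  k <- choose_k(cc)
  expect_equal(as.integer(k), 3)
  ari <- adjusted_rand_index(cc$assignments[["3"]], co$truth$subtype[tum])
  expect_gte(ari, 0.9)
  # in-package ARI agrees with the independent implementation
  skip_if_not_installed("mclust")
  expect_equal(ari, mclust::adjustedRandIndex(cc$assignments[["3"]],
                                              co$truth$subtype[tum]),
               tolerance = 1e-12)
})

test_that("k selection breaks silhouette ties toward the smaller k", {
  fake <- structure(list(k_range = c(2L, 3L, 4L),
                         delta = c(`2` = 0.5, `3` = 0.3, `4` = 0.2),
                         silhouette = c(`2` = 0.7, `3` = 0.7, `4` = 0.5)),
                    class = "consensus_result")
  expect_equal(as.integer(choose_k(fake)), 2)
  fake$silhouette <- c(`2` = 0.1, `3` = 0.2, `4` = 0.15)
  k <- choose_k(fake)
  expect_equal(attr(k, "confidence"), "no support")
})

test_that("cluster merging relabels while conserving counts", {
  asn <- stats::setNames(c(1, 2, 3, 4, 5, 2, 4), paste0("s", 1:7))
  map <- c(`1` = "Im1", `2` = "Im2", `3` = "Im2", `4` = "Im3", `5` = "Im3")
  merged <- merge_clusters(asn, map)
  expect_equal(as.integer(table(merged)[c("Im1", "Im2", "Im3")]), c(1, 3, 3))
  expect_equal(sum(table(merged)), length(asn))
  expect_identical(merge_clusters(asn, stats::setNames(as.character(1:5), 1:5)),
                   stats::setNames(as.character(asn), names(asn)))
  expect_error(merge_clusters(asn, map[-2]), "2")
})

test_that("the immune-style 5-to-3 merge sums the right groups", {
  asn <- rep(c("Im-S-I", "Im-S-II", "Im-S-III", "Im-S-IV", "Im-S-V"),
             c(9, 15, 9, 8, 13))
  map <- c("Im-S-I" = "Im-1", "Im-S-II" = "Im-2", "Im-S-III" = "Im-2",
           "Im-S-IV" = "Im-3", "Im-S-V" = "Im-3")
  merged <- merge_clusters(asn, map)
  expect_equal(as.integer(table(merged)[c("Im-1", "Im-2", "Im-3")]),
               c(9, 24, 21))
})

test_that("PCA projection is deterministic in sign and rotation-invariant", {
  set.seed(83)
  m <- matrix(stats::rnorm(30 * 20), 30, 20,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
  m[, 11:20] <- m[, 11:20] + 3
  pc <- project_pca(m)
  # two-cluster data: PC1 separates clusters
  sep <- abs(mean(pc$scores[11:20, 1]) - mean(pc$scores[1:10, 1]))
  expect_gt(sep, 2 * stats::sd(c(pc$scores[1:10, 1] - mean(pc$scores[1:10, 1]),
                                 pc$scores[11:20, 1] - mean(pc$scores[11:20, 1]))))
  # duplicated sample projects identically
  m2 <- cbind(m, dup = m[, 1])
  pc2 <- project_pca(m2)
  expect_equal(unname(pc2$scores["dup", ]), unname(pc2$scores["s1", ]),
               tolerance = 1e-9)
  # orthogonal rotation of the feature space preserves explained variance
  Q <- qr.Q(qr(matrix(stats::rnorm(30 * 30), 30)))
  m3 <- Q %*% m
  dimnames(m3) <- dimnames(m)
  pc3 <- project_pca(m3)
  expect_equal(pc$explained_variance_ratio, pc3$explained_variance_ratio,
               tolerance = 1e-9)
  expect_error(project_pca(m, n_components = 25), "rank")
})
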