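test_that("BH adjustment matches the hand step-up enumeration", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(41)
  for (i in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("row z-scores use the sample-SD convention and are idempotent", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:3)))
  z <- suppressMessages(zscore_rows(m))
  expect_equal(z["a", ], c(s1 = -1, s2 = 0, s3 = 1))
  expect_true(all(is.na(z["b", ])))  # constant row -> all missing
  z2 <- suppressMessages(zscore_rows(z[1, , drop = FALSE]))
  expect_equal(z2[1, ], z["a", ], tolerance = 1e-12)
  expect_equal(mean(z["a", ]), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z["a", ]), 1, tolerance = 1e-9)
})

test_that("identical groups produce FC = 1 and no calls", {
  set.seed(42)
  half <- matrix(stats::rnorm(30 * 10, 8), 30, 10)
  m <- cbind(half, half)
  dimnames(m) <- list(paste0("g", 1:30), paste0("s", 1:20))
  de <- compare_groups(m, rep(c("A", "B"), each = 10))
  expect_equal(de$log2fc, rep(0, 30), tolerance = 1e-12)
  expect_true(all(de$call == "ns"))
})

test_that("the Welch t statistic matches the textbook formula", {
  set.seed(43)
  a <- stats::rnorm(20, 10, 1); b <- stats::rnorm(20, 2, 1)
  m <- matrix(c(a, b), 1, dimnames = list("g1", paste0("s", 1:40)))
  de <- compare_groups(m, rep(c("A", "B"), each = 20), min_obs = 1)
  # from-scratch Welch oracle
  se <- sqrt(stats::var(a) / 20 + stats::var(b) / 20)
  tstat <- (mean(a) - mean(b)) / se
  df <- se^4 / ((stats::var(a) / 20)^2 / 19 + (stats::var(b) / 20)^2 / 19)
  expect_equal(de$stat, tstat, tolerance = 1e-10)
  expect_equal(de$p, 2 * stats::pt(-abs(tstat), df), tolerance = 1e-10)
  expect_equal(de$call, "up")
  expect_lt(de$q, 1e-6)
  # base-R cross-check of the full p-value path
  expect_equal(de$p, stats::t.test(a, b)$p.value, tolerance = 1e-12)
})

test_that("group swap inverts the fold change and the call", {
  set.seed(44)
  m <- matrix(stats::rnorm(40 * 20, 5), 40, 20,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:20)))
  m[1:5, 1:10] <- m[1:5, 1:10] + 3
  g <- factor(rep(c("A", "B"), each = 10), levels = c("A", "B"))
  de_ab <- compare_groups(m, g)
  de_ba <- compare_groups(m, stats::relevel(g, "B"))
  expect_equal(de_ab$log2fc, -de_ba$log2fc, tolerance = 1e-10)
  swapped <- c(up = "down", down = "up", ns = "ns")
  expect_equal(unname(swapped[de_ab$call]), de_ba$call)
  # sample-order invariance
  perm <- sample(20)
  de_perm <- compare_groups(m[, perm], g[perm])
  expect_equal(de_perm$log2fc, de_ab$log2fc, tolerance = 1e-12)
})

test_that("multi-group tests agree with the base-R references", {
  set.seed(45)
  m <- matrix(stats::rnorm(5 * 30), 5, 30,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
  g <- rep(c("A", "B", "C"), each = 10)
  de_a <- compare_groups(m, g, test = "anova", min_obs = 1)
  de_k <- compare_groups(m, g, test = "kruskal", min_obs = 1)
  for (i in 1:5) {
    expect_equal(de_a$p[i],
                 stats::oneway.test(m[i, ] ~ g, var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
    expect_equal(de_k$p[i], stats::kruskal.test(m[i, ], factor(g))$p.value,
                 tolerance = 1e-10)
  }
  expect_error(compare_groups(m, g, test = "t"), "exactly 2")
})

test_that("planted biomarkers survive the whole exosome cascade", {
  set.seed(46)
  co <- generate_cohort(null_cohort_config(n_patients = 50, n_genes = 120,
                                           rng_seed = 13))
  v <- co$protein$values
  tum <- co$clinical$sample_id[co$clinical$tissue == "tumor"]
  markers <- paste0("GENE", sprintf("%04d", 1:10))
  # engineer 10 biomarkers: complete in tumors, 4-fold up, and all tracking
  # one hazardous latent factor
  common <- stats::rnorm(length(tum))
  v[markers, ] <- matrix(stats::rnorm(10 * ncol(v), 6, 0.3), 10)
  v[markers, tum] <- sweep(v[markers, tum], 2, common + 2, "+")
  cl <- co$clinical
  set.seed(47)
  sv <- simulate_survival(1.5 * common, 1e-3, 2e-4)
  cl$os_time[match(tum, cl$sample_id)] <- sv$time
  cl$os_event[match(tum, cl$sample_id)] <- sv$event
  pm <- omics_matrix(v, "protein", "log2")
  res <- suppressMessages(
    biomarker_cascade_exosome(pm, cl, n_perm = 100, rng_seed = 5))
  expect_true(all(markers %in% res$stage2))
  expect_true(all(markers %in% res$stage3))

  # ubiquitous missingness empties stage 1 without crashing
  v_na <- v; v_na[, tum[1]] <- NA
  res2 <- suppressMessages(
    biomarker_cascade_exosome(omics_matrix(v_na, "protein", "log2"), cl,
                              n_perm = 50))
  expect_equal(unname(res2$stage_counts), c(0, 0, 0))
})

test_that("subtype marker screen enforces its three criteria", {
  set.seed(48)
  n <- 45
  m <- matrix(stats::rnorm(30 * n, 8), 30, n,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:n)))
  labs <- stats::setNames(rep(c("S1", "S2", "S3"), each = 15), colnames(m))
  m["g1", labs == "S1"] <- m["g1", labs == "S1"] + 3   # clean S1 marker
  m["g2", labs == "S2"] <- m["g2", labs == "S2"] + 3   # S2 marker but sparse
  m["g2", sample(n, round(0.2 * n))] <- NA             # present in only ~80%
  res <- suppressMessages(
    subtype_marker_screen(omics_matrix(m, "protein", "log2"), labs))
  expect_true("g1" %in% res$feature[res$subtype == "S1"])
  expect_false("g2" %in% res$feature)  # fails the 90%-presence criterion
  expect_error(subtype_marker_screen(m, stats::setNames(c("A", rep("B", n - 1)),
                                                        colnames(m))),
               "< 3 samples")
})

test_that("tumor/NAT discovery proportions track the planted fractions", {
  # scaled re-enactment of a deep tumor/normal proteome contrast where ~30%
  # of proteins are called up and ~11% down at |log2FC| ~ 2
  cfg <- cohort_config(n_patients = 100, n_genes = 1000, n_phosphosites = 30,
                       n_mut_per_sample = 20, subtype_shift = 0,
                       n_cis_genes = 0, rng_seed = 17)
  co <- generate_cohort(cfg)
  grp <- factor(ifelse(grepl("_T$", colnames(co$protein$values)),
                       "tumor", "nat"), levels = c("tumor", "nat"))
  de <- suppressMessages(compare_groups(co$protein, grp))
  expect_lt(abs(mean(de$call == "up") - 0.30), 0.03)
  expect_lt(abs(mean(de$call == "down") - 0.11), 0.03)
})
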