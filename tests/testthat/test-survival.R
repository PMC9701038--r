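test_that("KM matches the hand product-limit on a no-censoring toy", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  # all censored -> survival identically 1
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$survival == 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), ">= 0")
})

test_that("the log-rank test matches a from-scratch O-E/V computation", {
  # 5-subject toy, no tied event times
  times <- c(1, 2, 3, 4, 5)
  events <- c(1, 0, 1, 1, 1)
  group <- c(1, 1, 1, 0, 0)
  res <- logrank(times, events, group)
  expect_equal(res$chi2, logrank_oracle(times, events, group),
               tolerance = 1e-10)
  expect_equal(res$df, 1)
  # identical groups: duplicated data -> chi2 ~ 0
  res0 <- logrank(rep(times, 2), rep(events, 2), rep(c(1, 2), each = 5))
  expect_lt(res0$chi2, 1e-10)
  expect_gt(res0$p, 0.999)
})

test_that("log-rank has power against a 3-fold rate difference", {
  set.seed(91)
  hits <- replicate(20, {
    t1 <- stats::rexp(200, 0.03); t2 <- stats::rexp(200, 0.01)
    logrank(c(t1, t2), rep(1, 400), rep(1:2, each = 200))$p < 1e-6
  })
  expect_gte(mean(hits), 0.99)
})

test_that("KM and log-rank are invariant to increasing time transforms", {
  set.seed(92)
  times <- stats::rexp(100, 0.02)
  events <- stats::rbinom(100, 1, 0.7)
  group <- rep(1:2, 50)
  r1 <- logrank(times, events, group)
  r2 <- logrank(log1p(times), events, group)
  expect_equal(r1$chi2, r2$chi2, tolerance = 1e-10)
  k1 <- km_estimate(times, events)
  k2 <- km_estimate(log1p(times), events)
  expect_equal(k1$survival, k2$survival, tolerance = 1e-12)
})

test_that("the maxstat cutpoint equals the exhaustive per-candidate scan", {
  set.seed(93)
  for (rep_ in 1:5) {
    n <- 60
    x <- stats::rnorm(n)
    tt <- stats::rexp(n, 0.01 * exp(0.8 * (x > stats::median(x))))
    ev <- stats::rbinom(n, 1, 0.8)
    if (sum(ev) == 0) next
    ms <- maxstat_cutpoint(x, tt, ev, n_perm = 50, rng_seed = rep_)
    oracle <- maxstat_oracle(x, tt, ev)
    expect_equal(ms$cutpoint, oracle$cutpoint, tolerance = 1e-12)
    expect_equal(ms$statistic, oracle$statistic, tolerance = 1e-10)
    expect_equal(ms$n_candidates, length(oracle$candidates))
  }
})

test_that("a clean high-hazard group is split at the separating value", {
  set.seed(94)
  x <- c(stats::runif(30, 0, 1), stats::runif(30, 2, 3))
  # perfect separation: the high-x group fails an order of magnitude faster
  lp <- ifelse(x > 1.5, 3.5, 0)
  tt <- stats::rexp(60, 0.01 * exp(lp))
  ms <- maxstat_cutpoint(x, tt, rep(1, 60), n_perm = 200, rng_seed = 2)
  # the chosen cut reproduces the true two-group split (the standardized
  # statistic may peak within one rank of the knife-edge boundary)
  expect_gte(sum((x > ms$cutpoint) == (x > 1.5)), 59)
  expect_lt(ms$p, 0.05)
  # and it is exactly the brute-force scan optimum
  oracle <- maxstat_oracle(x, tt, rep(1, 60))
  expect_equal(ms$cutpoint, oracle$cutpoint, tolerance = 1e-12)
  expect_error(maxstat_cutpoint(rep(1, 60), tt, rep(1, 60)), "constant")
})

test_that("the selection-adjusted permutation p is valid under the null", {
  set.seed(95)
  ps <- replicate(200, {
    n <- 50
    x <- stats::rnorm(n)
    tt <- stats::rexp(n, 0.02)
    ev <- stats::rbinom(n, 1, 0.8)
    maxstat_cutpoint(x, tt, ev, n_perm = 99)$p
  })
  for (alpha in c(0.05, 0.1, 0.25))
    expect_lte(mean(ps <= alpha), alpha + 2 * sqrt(alpha * (1 - alpha) / 200))
  # and not wildly conservative either: the p-values spread over (0, 1]
  expect_gt(stats::sd(ps), 0.2)
})

test_that("Cox recovery: binary covariate with true HR 2", {
  set.seed(96)
  hrs <- replicate(30, {
    g <- rep(0:1, each = 500)
    tt <- stats::rexp(1000, 0.01 * exp(log(2) * g))
    cox_univariate(g, tt, rep(1, 1000))$hr
  })
  expect_gt(stats::median(hrs), 1.7)
  expect_lt(stats::median(hrs), 2.35)
})

test_that("the Cox fit maximizes the Efron partial likelihood (grid oracle)", {
  x <- c(0, 1, 1, 0, 1, 0)
  times <- c(2, 1, 4, 6, 3, 5)
  events <- c(1, 1, 1, 0, 1, 1)
  fit <- cox_univariate(x, times, events)
  ll <- function(b) cox_loglik_oracle(b, x, times, events)
  expect_gte(ll(fit$coef), ll(fit$coef + 0.01))
  expect_gte(ll(fit$coef), ll(fit$coef - 0.01))
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
  expect_error(cox_univariate(rep(1, 6), times, events), "constant")
  expect_error(cox_univariate(x, times, rep(0, 6)), "events")
})

test_that("Cox and log-rank agree on direction and scale for two groups", {
  set.seed(97)
  g <- rep(0:1, each = 300)
  tt <- stats::rexp(600, 0.01 * exp(0.5 * g))
  cx <- cox_univariate(g, tt, rep(1, 600))
  lr <- logrank(tt, rep(1, 600), g)
  expect_gt(cx$hr, 1)
  ratio <- cx$p / lr$p
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("the survival screen flags a planted hazardous marker", {
  set.seed(98)
  co <- generate_cohort(null_cohort_config(n_patients = 60, rng_seed = 31))
  tum <- co$clinical$sample_id[co$clinical$tissue == "tumor"]
  v <- co$protein$values[1:10, tum]
  v[] <- stats::rnorm(length(v))
  cl <- co$clinical
  sv <- simulate_survival(1.2 * v["GENE0001", ], 1e-3, 2e-4)
  cl$os_time[match(tum, cl$sample_id)] <- sv$time
  cl$os_event[match(tum, cl$sample_id)] <- sv$event
  res <- suppressMessages(survival_screen(omics_matrix(v, "protein", "log2"),
                                          cl, n_perm = 200, rng_seed = 4))
  hit <- res[res$feature == "GENE0001", ]
  expect_gt(hit$hr, 1)
  expect_lt(hit$q, 0.05)
  # a constant feature is skipped, not fatal
  v2 <- v; v2["GENE0002", ] <- 1
  expect_message(survival_screen(omics_matrix(v2, "protein", "log2"), cl,
                                 n_perm = 50), "skipped")
})
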