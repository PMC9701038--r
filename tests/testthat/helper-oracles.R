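# Independent oracles and small fixture builders shared by the unit and
# acceptance tests. Each oracle re-derives its quantity from first
# principles, independently of the package's computational path.

# Null cohort: every planted effect switched off.
null_cohort_config <- function(n_patients = 20, n_genes = 150,
                               n_phosphosites = 30, rng_seed = 1, ...) {
  cohort_config(n_patients = n_patients, n_genes = n_genes,
                n_phosphosites = n_phosphosites, n_mut_per_sample = 50,
                frac_tumor_up = 0, frac_tumor_down = 0, n_cis_genes = 0,
                subtype_shift = 0, kinase_shift = 0, surv_coef = 0,
                immune_shift = 0, baseline_rates = 1e-3,
                n_celltypes = 16, rng_seed = rng_seed, ...)
}

# BH step-up by direct enumeration: q_i = min over j >= i of p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / (i:m))),
               numeric(1))
  q <- numeric(m)
  q[o] <- qs
  q
}

# Two-sided Fisher exact p by hypergeometric tail enumeration.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- exp(lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Direct weighted-KS walk score for a gene ranking and an in-set indicator,
# per the scoring definition (symmetric rank weights, maxdiff).
ks_walk_oracle <- function(in_set, tau = 1) {
  p <- length(in_set)
  w <- abs((p + 1) / 2 - seq_len(p))^tau
  step <- ifelse(in_set, w / sum(w[in_set]), -1 / sum(!in_set))
  walk <- cumsum(step)
  max(c(0, walk)) + min(c(0, walk))
}

# Log-rank chi-square by the textbook observed-minus-expected computation
# over pooled distinct event times (two groups, no tied event times needed).
logrank_oracle <- function(times, events, group) {
  ts <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Per-candidate maximally-selected statistic by direct subset sums (no
# cumulative-sum shortcut): centred Nelson-Aalen log-rank scores, partial sum
# over {x <= c}, permutation variance.
maxstat_oracle <- function(x, times, events, q_low = 0.1, q_high = 0.9,
                           min_group = 10) {
  n <- length(x)
  evt <- sort(unique(times[events == 1]))
  haz <- vapply(evt, function(s)
    sum(times == s & events == 1) / sum(times >= s), numeric(1))
  H <- vapply(times, function(t) sum(haz[evt <= t]), numeric(1))
  a <- events - H
  a <- a - mean(a)
  ss <- sum(a^2)
  qs <- stats::quantile(x, c(q_low, q_high), names = FALSE)
  cands <- sort(unique(x))
  cands <- cands[cands >= qs[1] & cands <= qs[2]]
  cands <- cands[vapply(cands, function(cut)
    sum(x <= cut) >= min_group && sum(x > cut) >= min_group, logical(1))]
  zs <- vapply(cands, function(cut) {
    grp <- x <= cut
    n1 <- sum(grp)
    v <- n1 * (n - n1) / (n * (n - 1)) * ss
    sum(a[grp]) / sqrt(v)
  }, numeric(1))
  best_c <- cands[which.max(abs(zs))]
  next_x <- min(x[x > best_c])
  list(cutpoint = (best_c + next_x) / 2, statistic = max(abs(zs)),
       candidates = cands, z = zs)
}

# Efron-tie log partial likelihood for a single covariate (used as a grid
# oracle for the Cox fit; reduces to Breslow when event times are unique).
cox_loglik_oracle <- function(beta, x, times, events) {
  ll <- 0
  for (t in unique(times[events == 1])) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    d <- length(D)
    sum_r <- sum(exp(beta * x[R]))
    sum_d <- sum(exp(beta * x[D]))
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum_r - l / d * sum_d)
    ll <- ll + beta * sum(x[D])
  }
  ll
}
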