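# Kaplan-Meier estimation, log-rank tests, maximally-selected-rank-statistic
# cutpoints with selection-adjusted permutation inference, and univariate Cox
# regression.

#' Kaplan-Meier product-limit estimate
#'
#' @param times non-negative observed times.
#' @param events 0/1 event indicators.
#' @return data.frame of class `km_estimate` (`time`, `n_risk`, `n_event`,
#'   `survival`) with an evaluator attribute `surv_fun` (right-continuous
#'   step function S(t)).
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1) stop("need >= 1 observation")
  if (any(times < 0)) stop("times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  attr(out, "surv_fun") <- sf
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected statistic over the pooled event times,
#' df = number of groups - 1.
#'
#' @param times,events survival data.
#' @param groups group labels (>= 2 groups, >= 1 event overall).
#' @return list: `chi2`, `df`, `p`.
#' @export
logrank <- function(times, events, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop(">= 2 groups required")
  if (sum(events) == 0) stop("no events: the log-rank test is undefined")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd_$n) - 1
  list(chi2 = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

# Centred log-rank scores (Nelson-Aalen form): a_i = delta_i - H(t_i), then
# centred. The maximally selected statistic for the split {x <= c} is the
# standardized partial sum of these scores under the permutation variance.
logrank_scores <- function(times, events) {
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]
  n <- length(t_s)
  at_risk <- n - seq_len(n) + 1
  # Nelson-Aalen increments at each ordered observation (ties handled by
  # the counting order; adequate for continuous times).
  H <- cumsum(e_s / at_risk)
  a <- numeric(n)
  a[ord] <- e_s - H
  a - mean(a)
}

maxstat_scan <- function(a_centred, x_sorted_idx, cand_pos, ss) {
  n <- length(a_centred)
  cs <- cumsum(a_centred[x_sorted_idx])
  i <- cand_pos
  v <- i * (n - i) / (n * (n - 1)) * ss
  z <- cs[i] / sqrt(v)
  z
}

#' Maximally selected rank-statistic cutpoint for survival
#'
#' Scans candidate cutpoints (observed values between the `q_low` and
#' `q_high` quantiles leaving at least `min_group` samples on each side) and
#' selects the one maximizing the absolute standardized log-rank statistic
#' of the induced two-group split. The p-value is selection-adjusted by
#' permutation: the feature values are permuted against the survival data
#' and the maximal statistic is recomputed for each permutation.
#'
#' @param x numeric feature values (one per subject).
#' @param times,events survival data.
#' @param q_low,q_high candidate-cutpoint quantile window (defaults 0.1,
#'   0.9).
#' @param n_perm permutations for the adjusted p (default 1000).
#' @param rng_seed optional seed for the permutation draw.
#' @param min_group minimum group size on each side of a candidate cut
#'   (default 10).
#' @return list: `cutpoint`, `statistic` (max |standardized statistic|),
#'   `p` (permutation), `n_candidates`.
#' @export
maxstat_cutpoint <- function(x, times, events, q_low = 0.1, q_high = 0.9,
                             n_perm = 1000, rng_seed = NULL, min_group = 10) {
  ok <- !is.na(x) & !is.na(times) & !is.na(events)
  x <- x[ok]; times <- times[ok]; events <- events[ok]
  n <- length(x)
  if (length(unique(x)) < 2) stop("feature is constant; no cutpoint exists")
  if (sum(events) == 0) stop("no events")
  a <- logrank_scores(times, events)
  ss <- sum(a^2)
  if (ss == 0) stop("degenerate log-rank scores")
  ord <- order(x)
  xs <- x[ord]
  qs <- stats::quantile(x, c(q_low, q_high), names = FALSE)
  cand_pos <- which(xs >= qs[1] & xs <= qs[2] &
                      seq_len(n) >= min_group & seq_len(n) <= n - min_group &
                      xs != c(xs[-1], Inf))
  if (length(cand_pos) == 0)
    stop("no candidate cutpoint leaves both sides populated")
  z <- maxstat_scan(a, ord, cand_pos, ss)
  best <- which.max(abs(z))
  stat <- abs(z[best])
  if (!is.null(rng_seed)) set.seed(rng_seed %% .Machine$integer.max)
  perm_max <- vapply(seq_len(n_perm), function(i) {
    max(abs(maxstat_scan(sample(a), seq_len(n), cand_pos, ss)))
  }, numeric(1))
  p <- (1 + sum(perm_max >= stat)) / (n_perm + 1)
  # report the midpoint between the optimal candidate and the next larger
  # observed value, so the cut falls between the two groups' ranges
  pos <- cand_pos[best]
  list(cutpoint = (xs[pos] + xs[pos + 1]) / 2, statistic = stat, p = p,
       n_candidates = length(cand_pos))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; Wald confidence interval
#' and p-value. Non-convergence or a monotone likelihood (infinite
#' coefficient) is flagged rather than silently returned.
#'
#' @param covariate numeric or two-level covariate.
#' @param times,events survival data.
#' @param min_events minimum number of events (default 5).
#' @return list: `hr`, `ci_low`, `ci_high`, `p`, `coef`, `flag`
#'   (`"ok"`/`"unstable"`).
#' @export
cox_univariate <- function(covariate, times, events, min_events = 5) {
  ok <- !is.na(covariate) & !is.na(times) & !is.na(events)
  covariate <- covariate[ok]; times <- times[ok]; events <- events[ok]
  if (length(unique(covariate)) < 2) stop("covariate is constant")
  if (sum(events) < min_events)
    stop("fewer than ", min_events, " events")
  if (is.character(covariate)) covariate <- factor(covariate)
  flag <- "ok"
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ covariate,
                    ties = "efron"),
    warning = function(w) {
      flag <<- "unstable"
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  beta <- unname(stats::coef(fit)[1])
  if (!is.finite(beta) || abs(beta) > 15) flag <- "unstable"
  list(hr = unname(sm$conf.int[1, "exp(coef)"]),
       ci_low = unname(sm$conf.int[1, "lower .95"]),
       ci_high = unname(sm$conf.int[1, "upper .95"]),
       p = unname(sm$coefficients[1, "Pr(>|z|)"]),
       coef = beta, flag = flag)
}

#' Cutpoint-based survival screen over a feature matrix
#'
#' For each feature: maximally selected cutpoint, then the hazard ratio of
#' the high (> cutpoint) versus low group from a univariate Cox fit and a
#' log-rank test on the dichotomy. BH adjustment is applied to the
#' selection-adjusted permutation p-values. Features failing preconditions
#' (constant, too few events/candidates) are skipped and counted.
#'
#' @param x an [omics_matrix] or matrix (features x samples).
#' @param clinical a `clinical_table` covering the matrix samples.
#' @param endpoint `"os"` or `"dfs"`.
#' @param n_perm permutations per feature (default 200).
#' @param rng_seed seed.
#' @param q_low,q_high,min_group cutpoint settings (see
#'   [maxstat_cutpoint]).
#' @return data.frame of class `survival_screen`: `feature`, `cutpoint`,
#'   `statistic`, `perm_p`, `logrank_p`, `hr`, `q`, `n`, `events`; skipped
#'   feature count in attribute `n_skipped`.
#' @export
survival_screen <- function(x, clinical, endpoint = c("os", "dfs"),
                            n_perm = 200, rng_seed = 1, q_low = 0.1,
                            q_high = 0.9, min_group = 10) {
  endpoint <- match.arg(endpoint)
  v <- as_values(x)
  cl <- clinical[match(colnames(v), clinical$sample_id), ]
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  times <- cl[[tcol]]; events <- cl[[ecol]]
  set.seed(rng_seed %% .Machine$integer.max)
  seeds <- sample.int(1e8, nrow(v))
  rows <- lapply(seq_len(nrow(v)), function(i) {
    xi <- v[i, ]
    res <- tryCatch({
      ms <- maxstat_cutpoint(xi, times, events, q_low = q_low,
                             q_high = q_high, n_perm = n_perm,
                             rng_seed = seeds[i], min_group = min_group)
      ok <- !is.na(xi) & !is.na(times) & !is.na(events)
      grp <- xi[ok] > ms$cutpoint
      lr <- logrank(times[ok], events[ok], grp)
      cx <- tryCatch(cox_univariate(as.numeric(grp), times[ok], events[ok]),
                     error = function(e) list(hr = NA_real_))
      data.frame(feature = rownames(v)[i], cutpoint = ms$cutpoint,
                 statistic = ms$statistic, perm_p = ms$p,
                 logrank_p = lr$p, hr = cx$hr, n = sum(ok),
                 events = sum(events[ok]), stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    res
  })
  n_skipped <- sum(vapply(rows, is.null, logical(1)))
  if (n_skipped > 0)
    message(n_skipped, " feature(s) skipped in the survival screen")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(structure(data.frame(feature = character(0)),
                     n_skipped = n_skipped))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$perm_p)
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("survival_screen", "data.frame")
  out
}
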