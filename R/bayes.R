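#' JZS Bayes factor for a paired (one-sample) design
#'
#' Default-prior Bayes factor for the mean of paired differences: under H1
#' the standardized effect \eqn{\delta} has a Cauchy(0, r) prior (Jeffreys
#' prior on the variance), under H0 \eqn{\delta = 0}.  With the data reduced
#' to the t statistic, the marginal likelihood under a fixed \eqn{\delta} is
#' the noncentral-t density with noncentrality \eqn{\sqrt{n}\,\delta}, so
#'
#' \deqn{BF_{10} = \frac{\int t_\nu(t;\sqrt{n}\delta)\,\pi(\delta)\,
#'   d\delta}{t_\nu(t; 0)}}
#'
#' evaluated by adaptive quadrature.  Directed hypotheses use the truncated
#' (half-Cauchy) prior, i.e. twice the prior mass on the selected half-line,
#' so `bf10(greater) + bf10(less) = 2 * bf10(two_sided)` identically.
#'
#' @param differences per-participant paired differences (finite, n >= 2,
#'   nonzero spread).
#' @param r Cauchy prior scale (default 1, the study's setting).
#' @param direction `"two_sided"`, `"greater"` or `"less"` (for the mean of
#'   `differences`).
#' @return list: `bf10`, `t_stat`, `n`, `df`.
#' @export
jzs_bf_paired <- function(differences, r = 1,
                          direction = c("two_sided", "greater", "less")) {
  direction <- match.arg(direction)
  x <- as.numeric(differences)
  n <- length(x)
  if (n < 2L) abort("need at least 2 paired differences",
                    class = "pupilload_data")
  if (any(!is.finite(x))) abort("differences must be finite",
                                class = "pupilload_data")
  s <- sd(x)
  if (s == 0) abort("degenerate t: zero variance in differences",
                    class = "pupilload_degenerate")
  t_stat <- mean(x) / (s / sqrt(n))
  bf <- jzs_bf_from_t(t_stat, n, r, direction)
  list(bf10 = bf, t_stat = t_stat, n = n, df = n - 1L)
}

# likelihood of the observed t as a function of delta (vectorized);
# the noncentral-t series routinely emits per-element precision warnings,
# which are irrelevant at the quadrature tolerances used here and costly to
# trap individually, so warnings are switched off for the call
t_likelihood <- function(t_stat, df, n) {
  force(t_stat); force(df); force(n)
  function(delta) {
    old <- options(warn = -1)
    on.exit(options(old))
    dt(t_stat, df = df, ncp = sqrt(n) * delta)
  }
}

jzs_bf_from_t <- function(t_stat, n, r = 1,
                          direction = c("two_sided", "greater", "less")) {
  direction <- match.arg(direction)
  df <- n - 1
  lik <- t_likelihood(t_stat, df, n)
  dens0 <- dt(t_stat, df = df)
  # substitute delta = r * tan(theta): Cauchy(0, r) maps to Uniform on
  # (-pi/2, pi/2), so the integrand is bounded for every prior scale
  integrand <- function(theta) lik(r * tan(theta)) / pi
  lims <- switch(direction,
                 two_sided = c(-pi / 2, pi / 2),
                 greater = c(0, pi / 2),
                 less = c(-pi / 2, 0))
  mult <- if (direction == "two_sided") 1 else 2
  num <- integrate(integrand, lims[1], lims[2],
                   rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L)$value
  mult * num / dens0
}

#' Posterior mean and central 95% credible interval of the effect size
#'
#' Posterior of the standardized effect \eqn{\delta} under the same JZS
#' model: density proportional to noncentral-t likelihood times the
#' (possibly truncated) Cauchy prior, normalized on a fine grid that is
#' refined until the posterior mean is stable to 1e-6.
#'
#' @inheritParams jzs_bf_paired
#' @return list: `es_mean`, `es_ci` (length-2 central 95% interval).
#' @export
posterior_effect_size <- function(differences, r = 1,
                                  direction = c("two_sided", "greater",
                                                "less")) {
  direction <- match.arg(direction)
  x <- as.numeric(differences)
  n <- length(x)
  if (n < 2L) abort("need at least 2 paired differences",
                    class = "pupilload_data")
  s <- sd(x)
  if (s == 0) abort("degenerate t: zero variance in differences",
                    class = "pupilload_degenerate")
  t_stat <- mean(x) / (s / sqrt(n))
  posterior_es_from_t(t_stat, n, r, direction)
}

posterior_es_from_t <- function(t_stat, n, r = 1,
                                direction = c("two_sided", "greater",
                                              "less")) {
  direction <- match.arg(direction)
  df <- n - 1
  lik <- t_likelihood(t_stat, df, n)
  logpost <- function(delta) {
    log(pmax(lik(delta), .Machine$double.xmin)) + dcauchy(delta, 0, r,
                                                          log = TRUE)
  }
  # bounded reparameterization delta = center + s * tan(theta): the whole
  # real line (or the truncation half-line) maps to a finite theta interval,
  # so no tail is ever cut off and the grid needs no widening
  center <- t_stat / sqrt(n)
  s <- sqrt((1 + center^2 / 2) / n) + 0.05
  th_lo <- if (direction == "greater") atan((0 - center) / s) else -pi / 2
  th_hi <- if (direction == "less") atan((0 - center) / s) else pi / 2
  prev_mean <- Inf
  npts <- 801L
  for (iter in 1:6) {
    theta <- seq(th_lo, th_hi, length.out = npts + 2L)
    theta <- theta[-c(1L, npts + 2L)]          # drop the infinite endpoints
    delta <- center + s * tan(theta)
    # posterior density in theta: f(delta(theta)) * s * sec^2(theta)
    lp <- logpost(delta) + log(s) - 2 * log(cos(theta))
    w <- exp(lp - max(lp))
    h <- theta[2] - theta[1]
    m <- length(theta)
    simp <- rep(c(2, 4), length.out = m) / 3 * h   # composite Simpson
    simp[c(1L, m)] <- h / 3
    Z <- sum(w * simp)
    dens <- w / Z
    es_mean <- sum(delta * dens * simp)
    if (is.finite(prev_mean) && abs(es_mean - prev_mean) < 1e-6) break
    prev_mean <- es_mean
    npts <- npts * 2L + 1L
  }
  cdf <- cumsum(c(0, (dens[-1] + dens[-m]) / 2) * h)
  cdf <- cdf / cdf[m]
  qfun <- function(p) {
    i <- findInterval(p, cdf, all.inside = TRUE)
    frac <- (p - cdf[i]) / (cdf[i + 1] - cdf[i])
    center + s * tan(theta[i] + frac * h)
  }
  list(es_mean = es_mean, es_ci = c(qfun(0.025), qfun(0.975)))
}

#' Classify Bayes-factor evidence
#'
#' Standard evidence bands: anecdotal (1 < BF <= 3, or 1/3 <= BF < 1),
#' moderate (3 < BF <= 10 or 1/10 <= BF < 1/3), strong (10 < BF <= 30 or
#' 1/30 <= BF < 1/10), very strong (30 < BF <= 100 or 1/100 <= BF < 1/30),
#' extreme (BF > 100 or BF < 1/100).  `BF = 1` falls in neither printed
#' bracket and is assigned to the H0 side (anecdotal) by convention.
#'
#' @param bf10 Bayes factor, > 0.
#' @return category string, e.g. `"strong_H1"`, `"moderate_H0"`.
#' @export
classify_evidence <- function(bf10) {
  if (!is.finite(bf10) && is.na(bf10)) abort("bf10 must be a number",
                                             class = "pupilload_data")
  if (bf10 <= 0) abort("bf10 must be > 0", class = "pupilload_data")
  if (bf10 > 1) {
    if (bf10 > 100) "extreme_H1"
    else if (bf10 > 30) "very_strong_H1"
    else if (bf10 > 10) "strong_H1"
    else if (bf10 > 3) "moderate_H1"
    else "anecdotal_H1"
  } else {
    if (bf10 < 1 / 100) "extreme_H0"
    else if (bf10 < 1 / 30) "very_strong_H0"
    else if (bf10 < 1 / 10) "strong_H0"
    else if (bf10 < 1 / 3) "moderate_H0"
    else "anecdotal_H0"
  }
}

#' Printable evidence marker
#'
#' Table-legend style: `*`/`'` moderate, `**`/`''` strong, `***`/`'''` very
#' strong, `****`/`''''` extreme, for H1 respectively H0; anecdotal evidence
#' carries no marker.
#'
#' @param evidence a category from [classify_evidence()].
#' @return marker string (possibly empty).
#' @export
evidence_marker <- function(evidence) {
  switch(evidence,
         moderate_H1 = "*", strong_H1 = "**", very_strong_H1 = "***",
         extreme_H1 = "****",
         moderate_H0 = "'", strong_H0 = "''", very_strong_H0 = "'''",
         extreme_H0 = "''''",
         "")
}

#' The study's default comparison plan
#'
#' Eight ordered pair contrasts: fixation task 2 minus fixation task 1
#' (undirected, the fatigue check), then Level a against both fixation
#' tasks and each level against its easier neighbour (directed).  For the
#' mean (and single-eye) channels the directed hypothesis is "more demanding
#' > less demanding"; for the between-eye diff channel it points the other
#' way ("more demanding < less demanding": lower between-eye variability
#' under load).
#'
#' @param channel indicator channel the plan is for.
#' @param pooled_extra append the post-hoc one- vs two-transformation-step
#'   contrast (levels a+b vs c-f) as a ninth, undirected entry.
#' @return tibble `pair_a, pair_b, direction`.
#' @export
default_comparison_plan <- function(channel = c("mean", "diff", "left",
                                                "right"),
                                    pooled_extra = FALSE) {
  channel <- match.arg(channel)
  dir_h1 <- if (channel == "diff") "less" else "greater"
  plan <- tibble(
    pair_a = c("fix2", "a", "a", "b", "c", "d", "e", "f"),
    pair_b = c("fix1", "fix1", "fix2", "a", "b", "c", "d", "e"),
    direction = c("two_sided", rep(dir_h1, 7)))
  if (pooled_extra) {
    plan <- bind_rows(plan, tibble(pair_a = "ab", pair_b = "cdef",
                                   direction = "two_sided"))
  }
  plan
}

#' Run a comparison plan over per-condition aggregates
#'
#' One paired JZS analysis per plan entry: participants contribute when they
#' have aggregates for both labels (others are dropped from that pair only);
#' differences are `value(pair_a) - value(pair_b)`.
#'
#' @param aggregates output of [aggregate_by_label()].
#' @param plan tibble `pair_a, pair_b, direction` (default:
#'   [default_comparison_plan()] for the channel).
#' @param channel indicator channel to analyse.
#' @param standardized analyse standardized (`TRUE`) or raw values.
#' @param r Cauchy prior scale.
#' @return tibble `pair_a, pair_b, channel, standardized, direction, n,
#'   t_stat, bf10, es_mean, es_lo, es_hi, evidence`; pairs with fewer than 2
#'   complete participants or zero spread are flagged `not_computable`.
#' @export
run_pairwise_comparisons <- function(aggregates, plan = NULL,
                                     channel = "mean", standardized = FALSE,
                                     r = 1) {
  if (is.null(plan)) plan <- default_comparison_plan(channel)
  agg <- aggregates[aggregates$channel == channel &
                      aggregates$standardized == standardized, ,
                    drop = FALSE]
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    a <- agg[agg$label == plan$pair_a[i], c("participant_id", "value")]
    b <- agg[agg$label == plan$pair_b[i], c("participant_id", "value")]
    m <- dplyr::inner_join(a, b, by = "participant_id",
                           suffix = c("_a", "_b"))
    x <- m$value_a - m$value_b
    base <- tibble(pair_a = plan$pair_a[i], pair_b = plan$pair_b[i],
                   channel = channel, standardized = standardized,
                   direction = plan$direction[i], n = length(x))
    res <- tryCatch({
      bf <- jzs_bf_paired(x, r = r, direction = plan$direction[i])
      es <- posterior_es_from_t(bf$t_stat, bf$n, r = r,
                                direction = plan$direction[i])
      mutate(base, t_stat = bf$t_stat, bf10 = bf$bf10,
             es_mean = es$es_mean, es_lo = es$es_ci[1], es_hi = es$es_ci[2],
             evidence = classify_evidence(bf$bf10))
    }, error = function(e) {
      mutate(base, t_stat = NA_real_, bf10 = NA_real_, es_mean = NA_real_,
             es_lo = NA_real_, es_hi = NA_real_, evidence = "not_computable")
    })
    rows[[i]] <- res
  }
  bind_rows(rows)
}
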