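test_that("JZS Bayes factor behaves at its analytic anchor points", {
  # exactly null-centered data favour H0
  x <- c(-2, -1, 0, 1, 2)
  expect_lt(jzs_bf_paired(x)$bf10, 1)
  # prior symmetry: bf(greater; x) == bf(less; -x)
  set.seed(70)
  y <- rnorm(20, 0.4)
  expect_equal(jzs_bf_paired(y, direction = "greater")$bf10,
               jzs_bf_paired(-y, direction = "less")$bf10,
               tolerance = 1e-12)
  # degenerate inputs
  expect_error(jzs_bf_paired(rep(1, 5)), class = "pupilload_degenerate")
  expect_error(jzs_bf_paired(1), class = "pupilload_data")
})

test_that("directed Bayes factors partition the two-sided one", {
  set.seed(71)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1), runif(1, -1, 1))
    b2 <- jzs_bf_paired(x)$bf10
    bg <- jzs_bf_paired(x, direction = "greater")$bf10
    bl <- jzs_bf_paired(x, direction = "less")$bf10
    expect_equal(bg + bl, 2 * b2, tolerance = 1e-6 * 2 * b2)
  }
})

test_that("the Bayes factor collapses to 1 as the prior scale vanishes", {
  set.seed(72)
  x <- rnorm(25, 0.5)
  bfs <- sapply(c(1, 0.1, 0.01, 1e-6), function(r)
    jzs_bf_paired(x, r = r)$bf10)
  expect_equal(bfs[4], 1, tolerance = 1e-4)
  expect_true(all(abs(bfs[-1] - 1) < abs(bfs[1] - 1)))
})

test_that("the two-sided Bayes factor increases with |t| at fixed n", {
  ts <- c(0, 0.5, 1, 2, 3, 5, 8)
  bfs <- sapply(ts, function(tt) pupilload:::jzs_bf_from_t(tt, 30, 1))
  expect_true(all(diff(bfs) > 0))
  bfs_neg <- sapply(-ts, function(tt) pupilload:::jzs_bf_from_t(tt, 30, 1))
  expect_equal(bfs, bfs_neg, tolerance = 1e-10)
})

test_that("quadrature matches the Monte-Carlo marginal-likelihood oracle", {
  set.seed(73)
  for (i in 1:10) {
    n <- 55
    x <- rnorm(n, runif(1, -0.5, 0.5), runif(1, 0.5, 2))
    bf <- jzs_bf_paired(x, r = 1)$bf10
    mc <- oracle_bf_mc(x, r = 1, n_draws = 1e6)
    expect_lt(abs(bf - mc) / bf, 0.02)
  }
})

test_that("posterior effect size matches the sampling oracle", {
  set.seed(74)
  cases <- list(c(t = 2.5, n = 30), c(t = 0.3, n = 55), c(t = -1.8, n = 20))
  for (cs in cases) {
    est <- pupilload:::posterior_es_from_t(cs[["t"]], cs[["n"]], 1)
    orc <- oracle_posterior_is(cs[["t"]], cs[["n"]], 1, n_draws = 1e6)
    expect_lt(abs(est$es_mean - orc$es_mean), 0.005 * orc$es_sd)
    expect_lt(max(abs(est$es_ci - orc$es_ci)), 0.05 * orc$es_sd)
  }
})

test_that("posterior is symmetric at t = 0 and truncated when directed", {
  es0 <- pupilload:::posterior_es_from_t(0, 30, 1)
  expect_lt(abs(es0$es_mean), 1e-6)
  expect_equal(es0$es_ci[1], -es0$es_ci[2], tolerance = 1e-4)
  esg <- pupilload:::posterior_es_from_t(1.5, 30, 1, "greater")
  expect_gte(esg$es_ci[1], 0)
  expect_true(esg$es_ci[1] <= esg$es_mean && esg$es_mean <= esg$es_ci[2])
})

test_that("two-sided posterior means shrink the sample effect toward zero", {
  set.seed(75)
  for (tt in c(0.8, 1.6, 3.1)) {
    n <- 30
    est <- pupilload:::posterior_es_from_t(tt, n, 1)
    expect_gte(est$es_mean, 0)
    expect_lte(est$es_mean, tt / sqrt(n))
  }
})

test_that("evidence bands reproduce the published classification", {
  expect_identical(classify_evidence(17.36), "strong_H1")
  expect_identical(classify_evidence(398.98), "extreme_H1")
  expect_identical(classify_evidence(0.16), "moderate_H0")
  expect_identical(classify_evidence(0.03), "very_strong_H0")
  # band edges: > is strict on the H1 side, mirrored on the H0 side
  expect_identical(classify_evidence(3), "anecdotal_H1")
  expect_identical(classify_evidence(3.0001), "moderate_H1")
  expect_identical(classify_evidence(1 / 3), "anecdotal_H0")
  expect_identical(classify_evidence(0.3332), "moderate_H0")
  expect_identical(classify_evidence(1), "anecdotal_H0")
  expect_identical(classify_evidence(150), "extreme_H1")
  expect_error(classify_evidence(0), class = "pupilload_data")
  expect_identical(evidence_marker("extreme_H1"), "****")
  expect_identical(evidence_marker("very_strong_H0"), "'''")
  expect_identical(evidence_marker("anecdotal_H1"), "")
})

test_that("the default comparison plan has the study's eight contrasts", {
  plan_mean <- default_comparison_plan("mean")
  expect_identical(nrow(plan_mean), 8L)
  expect_identical(plan_mean$direction[1], "two_sided")
  expect_true(all(plan_mean$direction[-1] == "greater"))
  plan_diff <- default_comparison_plan("diff")
  expect_true(all(plan_diff$direction[-1] == "less"))
  expect_identical(plan_mean$pair_a,
                   c("fix2", "a", "a", "b", "c", "d", "e", "f"))
  expect_identical(plan_mean$pair_b,
                   c("fix1", "fix1", "fix2", "a", "b", "c", "d", "e"))
  expect_identical(nrow(default_comparison_plan("mean", pooled_extra = TRUE)),
                   9L)
})

test_that("null aggregates yield H0-side evidence for most pairs", {
  labels <- condition_labels()
  h0 <- logical(0)
  for (rep_i in 1:20) {
    set.seed(500 + rep_i)
    agg <- tidyr::expand_grid(participant_id = sprintf("p%02d", 1:30),
                              label = labels)
    agg <- dplyr::mutate(agg, channel = "mean", standardized = FALSE,
                         value = rnorm(nrow(agg), 2, 0.5), n_segments = 1L)
    res <- run_pairwise_comparisons(agg, channel = "mean")
    h0 <- c(h0, grepl("_H0$", res$evidence))
  }
  expect_gte(mean(h0), 0.9)
})

test_that("a designed large effect is detected in most replications", {
  hits <- vapply(1:20, function(rep_i) {
    set.seed(540 + rep_i)
    x <- rnorm(30, 0.8, 1)   # standardized effect 0.8
    jzs_bf_paired(x, direction = "greater")$bf10 > 10
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("pairwise comparisons pair participants and flag degenerate pairs", {
  set.seed(76)
  agg <- tidyr::expand_grid(participant_id = sprintf("p%02d", 1:10),
                            label = c("fix1", "a"))
  agg <- dplyr::mutate(agg, channel = "mean", standardized = FALSE,
                       value = rnorm(20, ifelse(label == "a", 2, 1), 0.3),
                       n_segments = 1L)
  # participant p10 misses the fix1 aggregate -> dropped from the pair
  agg <- agg[!(agg$participant_id == "p10" & agg$label == "fix1"), ]
  plan <- tibble::tibble(pair_a = "a", pair_b = "fix1",
                         direction = "greater")
  res <- run_pairwise_comparisons(agg, plan, "mean", FALSE)
  expect_identical(res$n, 9L)
  expect_gt(res$bf10, 1)
  expect_identical(res$evidence, classify_evidence(res$bf10))
  # constant differences cannot be analysed
  agg2 <- agg
  agg2$value <- ifelse(agg2$label == "a", 2, 1)
  res2 <- run_pairwise_comparisons(agg2, plan, "mean", FALSE)
  expect_identical(res2$evidence, "not_computable")
  expect_true(is.na(res2$bf10))
})
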