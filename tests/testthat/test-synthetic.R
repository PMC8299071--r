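test_that("switching every stochastic component off leaves the baseline", {
  p <- signal_params(event_rate_hz = 0, hippus_amp_mm = 0, noise_sd_mm = 0,
                     drift_mm_per_min = 0, blink_rate_hz = 0)
  g <- generate_pupil_segment(2, 300, p, seed = 80)
  expect_true(all(g$left == p$baseline_mm))
  expect_true(all(g$right == p$baseline_mm))
  expect_identical(length(g$t), 600L)
})

test_that("full coupling with zero noise makes the eyes identical", {
  p <- signal_params(coupling = 1, noise_sd_mm = 0, blink_rate_hz = 0)
  g <- generate_pupil_segment(5, 300, p, seed = 81)
  expect_identical(g$left, g$right)
  expect_identical(length(g$events$left), 0L)
  expect_identical(length(g$events$right), 0L)
  # shared noise is also fully coupled at rho = 1 even when noise_sd > 0
  g2 <- generate_pupil_segment(5, 300, signal_params(coupling = 1,
                                                     blink_rate_hz = 0),
                               seed = 82)
  expect_identical(g2$left, g2$right)
})

test_that("event counts follow the Poisson design rate", {
  counts <- vapply(1:100, function(i) {
    g <- generate_pupil_segment(10, 300, signal_params(event_rate_hz = 2,
                                                       blink_rate_hz = 0),
                                seed = 8200 + i)
    length(g$events$shared) + length(g$events$left)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20) / sqrt(100))
})

test_that("parameter validation names the offending field", {
  expect_error(signal_params(coupling = 1.2), "coupling",
               class = "pupilload_param")
  expect_error(signal_params(noise_sd_mm = -1), "noise_sd_mm",
               class = "pupilload_param")
  expect_error(cohort_design(accuracy_probs = c(a = 2, b = .5, c = .5,
                                                d = .5, e = .5, f = .5)),
               class = "pupilload_param")
})

test_that("cohorts are reproducible from the master seed", {
  c1 <- generate_cohort(mini_design(2, master_seed = 83))
  c2 <- generate_cohort(mini_design(2, master_seed = 83))
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$segments, c2$segments)
  expect_identical(c1$truth$segments, c2$truth$segments)
  c3 <- generate_cohort(mini_design(2, master_seed = 84))
  expect_false(identical(c1$samples$pupil_left, c3$samples$pupil_left))
})

test_that("the session layout matches the declarative design", {
  coh <- generate_cohort(cohort_design(1, master_seed = 85), signals = FALSE)
  segs <- coh$segments
  expect_identical(nrow(segs), 62L)
  # fixation tasks: 9 crosses x (3 s square + 3 s cross)
  fix <- segs[segs$label %in% c("fix1", "fix2"), ]
  expect_equal(fix$t_end - fix$t_start, c(54, 54))
  # item segments never exceed the one-minute response limit
  items <- segs[!segs$label %in% c("fix1", "fix2"), ]
  expect_true(all(items$t_end - items$t_start <= 60))
  # five possible and five impossible items per level
  tab <- table(items$label, items$item_type)
  expect_true(all(tab == 5))
  # blocks in order of increasing difficulty
  first_item <- tapply(items$t_start, items$label, min)
  expect_true(all(diff(first_item[c("a", "c", "e")]) > 0))
  # 9 cross windows per fixation task with on-grid targets
  expect_identical(nrow(coh$targets), 18L)
  expect_identical(sort(unique(coh$targets$cross_index)), 1:9)
  # segments validate against the reader's rules
  expect_silent(pupilload:::validate_segments(segs))
})

test_that("designed per-level accuracies are recovered by simulation", {
  coh <- generate_cohort(cohort_design(55, master_seed = 101),
                         signals = FALSE)
  acc <- accuracy_score(coh$segments)
  probs <- c(a = .95, b = .93, c = .86, d = .80, e = .73, f = .43)
  for (lev in names(probs)) {
    p_hat <- mean(acc$accuracy[acc$label == lev])
    se <- sqrt(probs[[lev]] * (1 - probs[[lev]]) / (55 * 5))
    expect_lt(abs(p_hat - probs[[lev]]), 3.5 * se)
  }
  # levels are ordered easy to hard on average
  means <- tapply(acc$accuracy, acc$label, mean)[letters[1:6]]
  expect_true(all(diff(means) < 0.05))
})

test_that("the ground-truth manifest accounts for every designed quantity", {
  coh <- generate_cohort(mini_design(2, master_seed = 86))
  tr <- coh$truth$segments
  expect_identical(nrow(tr), nrow(coh$segments))
  expect_identical(tr$segment_id, coh$segments$segment_id)
  # designed coupling propagates from the preset
  expect_true(all(tr$coupling[tr$label %in% c("fix1", "fix2")] == 0.25))
  expect_true(all(tr$coupling[tr$label %in% c("c", "d", "e", "f")] == 0.75))
  # per-participant workload effect shifts every level rate equally
  wl <- coh$truth$participants$workload_effect
  for (i in 1:2) {
    pid <- coh$truth$participants$participant_id[i]
    lev_rates <- tr$event_rate[tr$participant_id == pid &
                                 !tr$label %in% c("fix1", "fix2")]
    expect_true(all(abs(lev_rates - pmax(0.05, 2.0 + wl[i])) < 1e-12))
  }
})

test_that("higher coupling shrinks the between-eye indicator difference", {
  mean_diff <- function(rho) {
    mean(vapply(1:20, function(i) {
      g <- generate_pupil_segment(10, 300,
                                  signal_params(coupling = rho,
                                                blink_rate_hz = 0),
                                  seed = 8700 + i)
      abs(compute_ipa(g$left, fs = 300)$ipa -
            compute_ipa(g$right, fs = 300)$ipa)
    }, numeric(1)))
  }
  d0 <- mean_diff(0)
  d5 <- mean_diff(0.5)
  d1 <- mean_diff(1)
  expect_gt(d0, d5)
  expect_gt(d5, d1)
  expect_identical(d1, 0)
})
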