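test_that("channel derivation follows the mean/absolute-difference rules", {
  ch <- channels_from_eyes(2.0, 1.0)
  expect_equal(ch$mean, 1.5)
  expect_equal(ch$diff, 1.0)
  eq <- channels_from_eyes(3.2, 3.2)
  expect_equal(eq$diff, 0)
  expect_equal(eq$mean, 3.2)
  expect_null(channels_from_eyes(NA_real_, 1))
  # brute-force recomputation on random pairs; swapping eyes changes nothing
  set.seed(60)
  for (i in 1:1000) {
    l <- runif(1, 0, 5)
    r <- runif(1, 0, 5)
    ch <- channels_from_eyes(l, r)
    sw <- channels_from_eyes(r, l)
    expect_identical(ch$mean, (l + r) / 2)
    expect_identical(ch$diff, abs(l - r))
    expect_identical(sw$mean, ch$mean)
    expect_identical(sw$diff, ch$diff)
  }
})

test_that("z-standardization yields mean 0, sd 1, and affine invariance", {
  expect_equal(z_standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(61)
  x <- rnorm(62, 3, 2)
  z <- z_standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  # direct-formula oracle
  expect_equal(z, (x - mean(x)) / sd(x))
  # idempotent on standardized input
  expect_equal(z_standardize(z), z, tolerance = 1e-12)
  # affine invariance
  expect_equal(z_standardize(2.5 * x + 7), z, tolerance = 1e-12)
  # degenerate inputs
  const <- z_standardize(rep(4, 5))
  expect_true(all(is.na(const)))
  expect_identical(attr(const, "reason"), "constant indicator")
  expect_true(all(is.na(z_standardize(c(1, NA, NA)))))
})

test_that("aggregation is an unweighted mean over usable segments", {
  ind <- tibble::tibble(
    participant_id = "p1", label = c("a", "a", "b"),
    segment_id = c("s1", "s2", "s3"), channel = "mean",
    standardized = FALSE, value = c(1, 3, NA))
  agg <- aggregate_by_label(ind)
  expect_identical(nrow(agg), 1L)     # label b has no usable segment
  expect_equal(agg$value, 2)
  expect_identical(agg$n_segments, 2L)
  # group-by oracle on a full synthetic table
  set.seed(62)
  ind2 <- tibble::tibble(
    participant_id = rep(c("p1", "p2"), each = 40),
    label = rep(rep(c("a", "b"), each = 20), 2),
    segment_id = paste0("s", 1:80), channel = "mean",
    standardized = FALSE, value = rnorm(80))
  agg2 <- aggregate_by_label(ind2)
  oracle <- tapply(ind2$value, paste(ind2$participant_id, ind2$label), mean)
  expect_equal(agg2$value,
               as.numeric(oracle[paste(agg2$participant_id, agg2$label)]))
})

test_that("accuracy counts possible items only, with timeouts as zero", {
  segs <- rbind(
    make_segment(sid = paste0("p", 1:5), item_type = "possible",
                 correct = c(1L, 1L, 1L, 0L, 0L)),
    make_segment(sid = paste0("i", 1:5), item_type = "impossible",
                 correct = 0L))
  acc <- accuracy_score(segs)
  expect_equal(acc$accuracy, 0.6)
  expect_identical(acc$n_items, 5L)
  all_right <- make_segment(sid = paste0("p", 1:5), item_type = "possible",
                            correct = 1L)
  expect_equal(accuracy_score(all_right)$accuracy, 1)
  # unanswered possible item scores 0
  with_na <- make_segment(sid = paste0("p", 1:4), item_type = "possible",
                          correct = c(1L, 1L, NA, NA))
  expect_equal(accuracy_score(with_na)$accuracy, 0.5)
  # no possible items -> no row
  none <- make_segment(item_type = "impossible")
  expect_identical(nrow(accuracy_score(none)), 0L)
})

test_that("fixation precision is the n-1 sd of target residuals", {
  exact <- fixation_precision(rep(960, 10), rep(540, 10),
                              rep(960, 10), rep(540, 10))
  expect_equal(exact$sd_x, 0)
  expect_equal(exact$sd_y, 0)
  two <- fixation_precision(c(100, 102), c(200, 200),
                            c(100, 100), c(200, 200))
  expect_equal(two$sd_x, sqrt(2), tolerance = 1e-12)
  expect_equal(two$sd_y, 0)
  expect_null(fixation_precision(1, 1, 1, 1))
  # Monte Carlo recovery of a 15 px scatter
  set.seed(63)
  n <- 8100
  mc <- fixation_precision(rnorm(n, 500, 15), rnorm(n, 300, 15),
                           rep(500, n), rep(300, n))
  expect_equal(mc$sd_x, 15, tolerance = 0.02 * 15)
  expect_equal(mc$sd_y, 15, tolerance = 0.02 * 15)
})

test_that("cohort fixation precision recovers the designed gaze scatter", {
  coh <- generate_cohort(mini_design(n_participants = 2, master_seed = 64,
                                     gaze_sd_px = 15))
  prec <- precision_by_task(coh$samples, coh$targets)
  expect_identical(nrow(prec), 4L)    # 2 participants x 2 fixation tasks
  expect_true(all(abs(prec$sd_x - 15) < 1))
  expect_true(all(abs(prec$sd_y - 15) < 1))
})

test_that("standardized diff variants both standardize within participant", {
  set.seed(65)
  ind <- compute_indicators(
    generate_cohort(mini_design(1, 66))$samples,
    generate_cohort(mini_design(1, 66))$segments)
  for (mode in c("z_of_diff", "diff_of_z")) {
    std <- standardize_indicators(ind, mode = mode)
    z <- std[std$standardized & std$channel == "mean", ]
    expect_lt(abs(mean(z$value, na.rm = TRUE)), 1e-10)
    expect_lt(abs(sd(z$value, na.rm = TRUE) - 1), 1e-10)
  }
  # diff_of_z really is |z(L) - z(R)|
  std <- standardize_indicators(ind, mode = "diff_of_z")
  zl <- std[std$standardized & std$channel == "left", ]
  zr <- std[std$standardized & std$channel == "right", ]
  zd <- std[std$standardized & std$channel == "diff", ]
  expect_equal(zd$value, abs(zl$value - zr$value))
})
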