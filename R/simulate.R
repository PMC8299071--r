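#' Parameters of the synthetic binocular pupil signal
#'
#' The generated signal per eye is
#' `baseline + drift*t + hippus + shared events + eye-specific events +
#' noise`: a slow linear drift (fatigue proxy), a low-frequency hippus
#' sinusoid (shared phase between eyes), workload-dependent transient
#' dilation events (smooth Gaussian bumps, Poisson-timed), and white
#' measurement noise.  `coupling` is the fraction of event rate and noise
#' variance shared between the eyes: at `coupling = 1` with zero independent
#' noise both eyes are sample-for-sample identical.
#'
#' @param baseline_mm resting pupil diameter (mm).
#' @param drift_mm_per_min linear baseline drift (mm/min, negative =
#'   fatigue-like shrinkage).
#' @param hippus_amp_mm,hippus_freq_hz amplitude (mm) and frequency (Hz) of
#'   the resting pupillary oscillation.
#' @param event_rate_hz Poisson rate of transient dilation events (1/s).
#' @param event_amp_mm nominal bump amplitude (mm; each event is jittered
#'   +/-20%).
#' @param event_width_s effective bump width (s); the Gaussian profile uses
#'   `sigma = event_width_s / 8`, so the default 0.033 bump spans about
#'   10 samples at 300 Hz and lands in the level-2 detail band.
#' @param coupling rho in `[0, 1]`, shared fraction of events and noise.
#' @param noise_sd_mm white-noise standard deviation (mm).
#' @param blink_rate_hz,blink_dur_s Poisson blink rate (1/s) and blink
#'   duration (s); blinks invalidate both eyes.
#' @return validated list of class `signal_params`.
#' @export
signal_params <- function(baseline_mm = 4.2, drift_mm_per_min = -0.05,
                          hippus_amp_mm = 0.1, hippus_freq_hz = 0.2,
                          event_rate_hz = 1.5, event_amp_mm = 0.15,
                          event_width_s = 0.033, coupling = 0.4,
                          noise_sd_mm = 0.015, blink_rate_hz = 0.15,
                          blink_dur_s = 0.15) {
  p <- list(baseline_mm = baseline_mm, drift_mm_per_min = drift_mm_per_min,
            hippus_amp_mm = hippus_amp_mm, hippus_freq_hz = hippus_freq_hz,
            event_rate_hz = event_rate_hz, event_amp_mm = event_amp_mm,
            event_width_s = event_width_s, coupling = coupling,
            noise_sd_mm = noise_sd_mm, blink_rate_hz = blink_rate_hz,
            blink_dur_s = blink_dur_s)
  nonneg <- c("hippus_amp_mm", "hippus_freq_hz", "event_rate_hz",
              "event_amp_mm", "event_width_s", "noise_sd_mm",
              "blink_rate_hz", "blink_dur_s")
  for (nm in nonneg) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0) {
      abort(paste0("invalid signal parameter: ", nm),
            class = "pupilload_param")
    }
  }
  if (p$baseline_mm <= 0) abort("invalid signal parameter: baseline_mm",
                                class = "pupilload_param")
  if (p$coupling < 0 || p$coupling > 1) {
    abort("invalid signal parameter: coupling", class = "pupilload_param")
  }
  structure(p, class = "signal_params")
}

add_bumps <- function(d, t, times, amps, sigma) {
  n <- length(t)
  if (n < 2L) return(d)
  dt_samp <- t[2] - t[1]
  for (k in seq_along(times)) {
    i0 <- max(1L, ceiling((times[k] - 5 * sigma - t[1]) / dt_samp) + 1L)
    i1 <- min(n, floor((times[k] + 5 * sigma - t[1]) / dt_samp) + 1L)
    if (i0 > i1) next
    win <- i0:i1
    d[win] <- d[win] + amps[k] * exp(-(t[win] - times[k])^2 / (2 * sigma^2))
  }
  d
}

#' Generate one binocular pupil segment with ground truth
#'
#' Draw order (fixed for reproducibility): hippus phase, shared events,
#' left events, right events, event amplitude jitters, shared noise, left
#' noise, right noise, blinks.
#'
#' @param duration segment length (s).
#' @param fs sampling rate (Hz).
#' @param params a [signal_params()] list.
#' @param t0 absolute start time (s); baseline drift and hippus phase are
#'   evaluated in absolute time so consecutive segments line up.
#' @param phase hippus phase (rad); random if `NULL`.
#' @param seed optional integer seed (otherwise the current RNG state is
#'   used).
#' @return list: `t`, `left`, `right`, `valid_left`, `valid_right`, `events`
#'   (lists `shared`, `left`, `right` of event times) and `blinks`
#'   (tibble `start`, `end`).
#' @export
generate_pupil_segment <- function(duration, fs = 300,
                                   params = signal_params(), t0 = 0,
                                   phase = NULL, seed = NULL) {
  stopifnot(inherits(params, "signal_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  if (n < 2L) abort("segment duration too short", class = "pupilload_param")
  t <- t0 + (seq_len(n) - 1L) / fs
  if (is.null(phase)) phase <- runif(1, 0, 2 * pi)
  rho <- params$coupling
  base <- params$baseline_mm +
    params$drift_mm_per_min / 60 * t +
    params$hippus_amp_mm * sin(2 * pi * params$hippus_freq_hz * t + phase)
  ev_shared <- sort(runif(rpois(1, rho * params$event_rate_hz * duration),
                          t0, t0 + duration))
  ev_left <- sort(runif(rpois(1, (1 - rho) * params$event_rate_hz * duration),
                        t0, t0 + duration))
  ev_right <- sort(runif(rpois(1, (1 - rho) * params$event_rate_hz * duration),
                         t0, t0 + duration))
  amp <- function(k) params$event_amp_mm * runif(k, 0.8, 1.2)
  a_shared <- amp(length(ev_shared))
  a_left <- amp(length(ev_left))
  a_right <- amp(length(ev_right))
  sigma <- params$event_width_s / 8
  left <- add_bumps(base, t, c(ev_shared, ev_left), c(a_shared, a_left),
                    sigma)
  right <- add_bumps(base, t, c(ev_shared, ev_right), c(a_shared, a_right),
                     sigma)
  z_sh <- rnorm(n)
  left <- left + params$noise_sd_mm *
    (sqrt(rho) * z_sh + sqrt(1 - rho) * rnorm(n))
  right <- right + params$noise_sd_mm *
    (sqrt(rho) * z_sh + sqrt(1 - rho) * rnorm(n))
  n_blink <- rpois(1, params$blink_rate_hz * duration)
  blink_start <- sort(runif(n_blink, t0, t0 + duration - params$blink_dur_s))
  # physiological refractoriness: successive blinks at least 1 s apart
  if (length(blink_start) > 1L) {
    keep <- rep(TRUE, length(blink_start))
    last <- blink_start[1]
    for (i in seq_along(blink_start)[-1]) {
      if (blink_start[i] - last < 1) keep[i] <- FALSE else last <- blink_start[i]
    }
    blink_start <- blink_start[keep]
  }
  valid <- rep(TRUE, n)
  for (b in blink_start) {
    valid[t >= b & t < b + params$blink_dur_s] <- FALSE
  }
  left[!valid] <- 0
  right[!valid] <- 0
  list(t = t, left = left, right = right,
       valid_left = valid, valid_right = valid,
       events = list(shared = ev_shared, left = ev_left, right = ev_right),
       blinks = tibble(start = blink_start,
                       end = blink_start + params$blink_dur_s))
}

#' Session structure of the study design
#'
#' Two fixation tasks (nine crosses on a 3x3 grid, each preceded by a 3 s
#' square and shown for 3 s) flanking three blocks of 20 test items (two
#' difficulty levels per block, five possible and five impossible items per
#' level, 1 s pre-item cross, response-limited at 60 s).
#'
#' @param fixation_cross_count,fixation_cross_duration,fixation_square_duration
#'   fixation-task layout.
#' @param blocks,items_per_block,levels test layout.
#' @param pre_item_cross_duration seconds of pre-item cross.
#' @param sampling_rate recording rate (Hz).
#' @param screen_px screen resolution `c(width, height)`.
#' @return list of class `study_design`.
#' @export
study_design <- function(fixation_cross_count = 9L,
                         fixation_cross_duration = 3,
                         fixation_square_duration = 3,
                         blocks = 3L, items_per_block = 20L,
                         levels = c("a", "b", "c", "d", "e", "f"),
                         pre_item_cross_duration = 1,
                         sampling_rate = 300,
                         screen_px = c(1920L, 1080L)) {
  stopifnot(fixation_cross_count >= 1L, blocks >= 1L, items_per_block >= 2L,
            !anyDuplicated(levels), length(levels) == 2L * blocks)
  structure(list(fixation_cross_count = as.integer(fixation_cross_count),
                 fixation_cross_duration = fixation_cross_duration,
                 fixation_square_duration = fixation_square_duration,
                 blocks = as.integer(blocks),
                 items_per_block = as.integer(items_per_block),
                 levels = levels,
                 pre_item_cross_duration = pre_item_cross_duration,
                 sampling_rate = sampling_rate,
                 screen_px = screen_px),
            class = "study_design")
}

#' Declarative design of a synthetic cohort
#'
#' The `"study"` preset encodes the study conditions this generator
#' emulates: equal fixation-task event rates before and after the test (no
#' built-in IPA fatigue effect), a workload step from fixation (1.2
#' events/s) to the test levels (2.0 events/s) with a per-participant
#' workload effect `e_p ~ N(0, participant_rate_sd)` added to every level's
#' rate — a designed standardized level-vs-fixation effect of
#' `(2.0 - 1.2) / participant_rate_sd`, i.e. delta = 0.8 at the default sd
#' of 1.0 — and between-eye coupling rising from .25 (fixation) over .45 (one
#' transformation step: levels a, b) to .75 (two steps: c-f), which makes
#' the diff channel fall with difficulty.  Per-level accuracy probabilities
#' are the published level means (.95, .93, .86, .80, .73, .43).  The
#' `"null"` preset removes every designed difference (identical parameters
#' for all conditions, no participant workload effect).
#'
#' @param n_participants cohort size.
#' @param preset `"study"` or `"null"`.
#' @param master_seed integer; every random draw in [generate_cohort()]
#'   derives from it.
#' @param participant_rate_sd sd of the per-participant additive workload
#'   effect on level event rates (1/s).
#' @param baseline_sd_mm between-participant baseline diameter sd.
#' @param gaze_sd_px gaze scatter around fixation targets (px).
#' @param item_duration_median_s named per-level median item duration (s).
#' @param item_duration_sdlog lognormal sdlog of item durations.
#' @param label_params optional named list of [signal_params()] per label,
#'   overriding the preset.
#' @param accuracy_probs optional named per-level accuracy probabilities.
#' @param design a [study_design()].
#' @return list of class `cohort_design`.
#' @export
cohort_design <- function(n_participants = 30L,
                          preset = c("study", "null"),
                          master_seed = 1L,
                          participant_rate_sd = NULL,
                          baseline_sd_mm = 0.4,
                          gaze_sd_px = 15,
                          item_duration_median_s = NULL,
                          item_duration_sdlog = NULL,
                          label_params = NULL,
                          accuracy_probs = NULL,
                          design = study_design()) {
  preset <- match.arg(preset)
  if (is.null(accuracy_probs)) {
    accuracy_probs <- c(a = .95, b = .93, c = .86, d = .80, e = .73, f = .43)
  }
  if (any(accuracy_probs < 0 | accuracy_probs > 1)) {
    abort("accuracy probabilities must be in [0, 1]",
          class = "pupilload_param")
  }
  if (is.null(participant_rate_sd)) {
    participant_rate_sd <- if (preset == "null") 0 else 1.0
  }
  if (is.null(item_duration_median_s)) {
    # the null preset removes the segment-duration confound entirely: the
    # universal threshold grows with series length, so unequal durations
    # alone bias the IPA; a true null equalizes every segment at 6 s
    item_duration_median_s <- if (preset == "null") {
      c(a = 6, b = 6, c = 6, d = 6, e = 6, f = 6)
    } else {
      c(a = 4, b = 4.5, c = 5.5, d = 6, e = 7, f = 8)
    }
  }
  if (is.null(item_duration_sdlog)) {
    item_duration_sdlog <- if (preset == "null") 0 else 0.4
  }
  if (preset == "null" && missing(design)) {
    # one 6 s square+cross window per fixation task: fixation segments get
    # the same length as the items, for the same reason
    design <- study_design(fixation_cross_count = 1L)
  }
  if (is.null(label_params)) {
    label_params <- if (preset == "study") {
      lp <- list(fix1 = signal_params(event_rate_hz = 1.2, coupling = 0.25),
                 fix2 = signal_params(event_rate_hz = 1.2, coupling = 0.25))
      for (lev in design$levels) {
        lp[[lev]] <- signal_params(
          event_rate_hz = 2.0,
          coupling = if (lev %in% c("a", "b")) 0.45 else 0.75)
      }
      lp
    } else {
      lp <- lapply(condition_labels(), function(l) signal_params())
      names(lp) <- condition_labels()
      lp
    }
  }
  missing_lab <- setdiff(condition_labels(), names(label_params))
  if (length(missing_lab)) {
    abort(paste0("label_params missing: ", paste(missing_lab, collapse = ", ")),
          class = "pupilload_param")
  }
  structure(list(n_participants = as.integer(n_participants),
                 preset = preset,
                 master_seed = as.integer(master_seed),
                 participant_rate_sd = participant_rate_sd,
                 baseline_sd_mm = baseline_sd_mm,
                 gaze_sd_px = gaze_sd_px,
                 item_duration_median_s = item_duration_median_s,
                 item_duration_sdlog = item_duration_sdlog,
                 label_params = label_params,
                 accuracy_probs = accuracy_probs,
                 design = design),
            class = "cohort_design")
}

cross_positions <- function(design) {
  w <- design$screen_px[1]
  h <- design$screen_px[2]
  gx <- w / 2 + c(-1, 0, 1) * w / 8
  gy <- h / 2 + c(-1, 0, 1) * h / 5
  expand.grid(target_x = gx, target_y = gy)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Per participant (with a seed derived from the master seed): fixation
#' task 1 (nine 6 s square+cross windows, one continuous 54 s pupil
#' segment), three blocks of 20 items in random within-block order with 1 s
#' pre-item crosses and lognormal response-limited durations, fixation
#' task 2.  Correctness of possible items is Bernoulli with the level's
#' accuracy probability.  Seed-splitting rule: `set.seed(master_seed)` then
#' one `sample.int(2^31 - 1)` draw per participant, in participant order.
#'
#' @param design a [cohort_design()].
#' @param signals synthesize pupil/gaze samples (default).  `FALSE` skips
#'   signal synthesis and returns only the session layout, item metadata and
#'   ground truth — enough for item-level analyses (accuracy calibration)
#'   at large cohort sizes.  The random draws then differ from a
#'   `signals = TRUE` run of the same seed.
#' @return list: `samples`, `segments`, `targets` (fixation-cross windows),
#'   `truth` (list of `participants` and `segments` ground-truth tibbles),
#'   `design`.
#' @export
generate_cohort <- function(design = cohort_design(), signals = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  sd_ <- design$design
  fs <- sd_$sampling_rate
  set.seed(design$master_seed)
  pseeds <- sample.int(.Machine$integer.max, design$n_participants)
  grid <- cross_positions(sd_)
  block_levels <- split(sd_$levels, rep(seq_len(sd_$blocks), each = 2L))
  per_part <- vector("list", design$n_participants)
  for (p in seq_len(design$n_participants)) {
    pid <- sprintf("p%03d", p)
    set.seed(pseeds[p])
    e_p <- rnorm(1, 0, design$participant_rate_sd)
    base_p <- rnorm(1, 0, design$baseline_sd_mm)
    phase_p <- runif(1, 0, 2 * pi)
    acc <- new.env(parent = emptyenv())
    acc$chunks <- list()        # per-chunk list(t, pl, pr, gx, gy, valid)
    acc$seg <- list()           # per-segment metadata rows (plain lists)
    acc$tgt <- list()
    acc$truth <- list()
    acc$cur_t <- 0
    add_chunk <- function(gen, gx, gy) {
      acc$chunks[[length(acc$chunks) + 1L]] <-
        list(t = gen$t, pl = gen$left, pr = gen$right, gx = gx, gy = gy,
             valid = gen$valid_left)
    }
    add_segment <- function(label, item_type, correct, dur, rate_shift) {
      params <- design$label_params[[label]]
      params$baseline_mm <- params$baseline_mm + base_p
      if (label %in% sd_$levels) {
        params$event_rate_hz <- max(0.05, params$event_rate_hz + rate_shift)
      }
      gen <- if (signals) {
        generate_pupil_segment(dur, fs, params, t0 = acc$cur_t,
                               phase = phase_p)
      }
      acc$seg[[length(acc$seg) + 1L]] <- list(
        label = label, item_type = item_type, correct = correct,
        t_start = acc$cur_t, t_end = acc$cur_t + dur)
      acc$truth[[length(acc$truth) + 1L]] <- list(
        label = label, event_rate = params$event_rate_hz,
        coupling = params$coupling,
        n_events_shared = if (signals) length(gen$events$shared) else NA_integer_,
        n_events_left = if (signals) length(gen$events$left) else NA_integer_,
        n_events_right = if (signals) length(gen$events$right) else NA_integer_,
        n_blinks = if (signals) nrow(gen$blinks) else NA_integer_,
        duration = dur)
      acc$cur_t <- acc$cur_t + dur
      gen
    }
    fixation_task <- function(label) {
      win <- sd_$fixation_square_duration + sd_$fixation_cross_duration
      dur <- sd_$fixation_cross_count * win
      t_start <- acc$cur_t
      order_idx <- sample.int(nrow(grid), sd_$fixation_cross_count,
                              replace = sd_$fixation_cross_count > nrow(grid))
      gen <- add_segment(label, "none", NA_integer_, dur, 0)
      if (signals) gx <- gy <- numeric(length(gen$t))
      for (k in seq_len(sd_$fixation_cross_count)) {
        w0 <- t_start + (k - 1) * win
        if (signals) {
          sel <- gen$t >= w0 & gen$t < w0 + win
          gx[sel] <- grid$target_x[order_idx[k]] +
            rnorm(sum(sel), 0, design$gaze_sd_px)
          gy[sel] <- grid$target_y[order_idx[k]] +
            rnorm(sum(sel), 0, design$gaze_sd_px)
        }
        acc$tgt[[length(acc$tgt) + 1L]] <- list(
          label = label, cross_index = k, t_start = w0, t_end = w0 + win,
          target_x = grid$target_x[order_idx[k]],
          target_y = grid$target_y[order_idx[k]])
      }
      if (signals) add_chunk(gen, gx, gy)
    }
    item_gap <- function() {
      if (signals) {
        gen0 <- generate_pupil_segment(sd_$pre_item_cross_duration, fs,
                                       design$label_params$fix1,
                                       t0 = acc$cur_t, phase = phase_p)
        n0 <- length(gen0$t)
        add_chunk(gen0,
                  sd_$screen_px[1] / 2 + rnorm(n0, 0, design$gaze_sd_px),
                  sd_$screen_px[2] / 2 + rnorm(n0, 0, design$gaze_sd_px))
      }
      acc$cur_t <- acc$cur_t + sd_$pre_item_cross_duration
    }
    fixation_task("fix1")
    for (b in seq_len(sd_$blocks)) {
      levs <- block_levels[[b]]
      item_label <- rep(levs, each = sd_$items_per_block / 2L)
      item_kind <- rep(rep(c("possible", "impossible"),
                           each = sd_$items_per_block / 4L), 2L)
      ord <- sample.int(length(item_label))
      item_label <- item_label[ord]
      item_kind <- item_kind[ord]
      for (it in seq_along(item_label)) {
        item_gap()
        lab <- item_label[it]
        dur <- rlnorm(1, log(design$item_duration_median_s[[lab]]),
                      design$item_duration_sdlog)
        dur <- round(min(max(dur, 1.5), 60) * fs) / fs
        correct <- rbinom(1, 1, design$accuracy_probs[[lab]])
        gen <- add_segment(lab, item_kind[it], as.integer(correct), dur, e_p)
        if (signals) {
          n0 <- length(gen$t)
          add_chunk(gen,
                    sd_$screen_px[1] / 2 + rnorm(n0, 0, 8 * design$gaze_sd_px),
                    sd_$screen_px[2] / 2 + rnorm(n0, 0, 8 * design$gaze_sd_px))
        }
      }
    }
    fixation_task("fix2")
    pull <- function(rows, field) unlist(lapply(rows, `[[`, field),
                                         use.names = FALSE)
    nseg <- length(acc$seg)
    samples_p <- if (!signals) NULL else tibble(
      participant_id = pid,
      t = pull(acc$chunks, "t"),
      pupil_left = pull(acc$chunks, "pl"),
      pupil_right = pull(acc$chunks, "pr"),
      gaze_x = pull(acc$chunks, "gx"),
      gaze_y = pull(acc$chunks, "gy"),
      valid_left = pull(acc$chunks, "valid"),
      valid_right = pull(acc$chunks, "valid"))
    segments_p <- tibble(
      participant_id = pid,
      segment_id = sprintf("%s_s%02d", pid, seq_len(nseg)),
      label = pull(acc$seg, "label"),
      item_type = pull(acc$seg, "item_type"),
      response_correct = pull(acc$seg, "correct"),
      t_start = pull(acc$seg, "t_start"),
      t_end = pull(acc$seg, "t_end"))
    targets_p <- tibble(
      participant_id = pid,
      label = pull(acc$tgt, "label"),
      cross_index = pull(acc$tgt, "cross_index"),
      t_start = pull(acc$tgt, "t_start"),
      t_end = pull(acc$tgt, "t_end"),
      target_x = pull(acc$tgt, "target_x"),
      target_y = pull(acc$tgt, "target_y"))
    truth_p <- tibble(
      participant_id = pid,
      segment_id = segments_p$segment_id,
      label = pull(acc$truth, "label"),
      event_rate = pull(acc$truth, "event_rate"),
      coupling = pull(acc$truth, "coupling"),
      n_events_shared = pull(acc$truth, "n_events_shared"),
      n_events_left = pull(acc$truth, "n_events_left"),
      n_events_right = pull(acc$truth, "n_events_right"),
      n_blinks = pull(acc$truth, "n_blinks"),
      duration = pull(acc$truth, "duration"))
    per_part[[p]] <- list(
      samples = samples_p, segments = segments_p, targets = targets_p,
      truth = truth_p,
      part = tibble(participant_id = pid, seed = pseeds[p],
                    workload_effect = e_p, baseline_shift = base_p))
  }
  list(samples = bind_rows(lapply(per_part, `[[`, "samples")),
       segments = bind_rows(lapply(per_part, `[[`, "segments")),
       targets = bind_rows(lapply(per_part, `[[`, "targets")),
       truth = list(
         participants = bind_rows(lapply(per_part, `[[`, "part")),
         segments = bind_rows(lapply(per_part, `[[`, "truth"))),
       design = design)
}

#' Write a generated session to delimited text files
#'
#' Fixed numeric formatting (timestamps and segment boundaries 7 decimals,
#' diameters 4, gaze 2) so equal cohorts produce byte-identical files;
#' re-readable with [read_samples()] / [read_segments()].  Timestamps and
#' boundaries share one precision: the wavelet chain is decimation-phase
#' sensitive, so a boundary that rounds across a sample tick would shift
#' every detail coefficient of that segment.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_session <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(samples = file.path(dir, "samples.csv"),
             segments = file.path(dir, "segments.csv"),
             targets = file.path(dir, "targets.csv"),
             truth_participants = file.path(dir, "truth_participants.csv"),
             truth_segments = file.path(dir, "truth_segments.csv"))
  write_formatted(cohort$samples, paths["samples"],
                  list(t = 7L, pupil_left = 4L, pupil_right = 4L,
                       gaze_x = 2L, gaze_y = 2L))
  write_formatted(cohort$segments, paths["segments"],
                  list(t_start = 7L, t_end = 7L))
  write_formatted(cohort$targets, paths["targets"],
                  list(t_start = 7L, t_end = 7L, target_x = 2L,
                       target_y = 2L))
  write_formatted(cohort$truth$participants, paths["truth_participants"],
                  list(workload_effect = 6L, baseline_shift = 6L))
  write_formatted(cohort$truth$segments, paths["truth_segments"],
                  list(event_rate = 6L, coupling = 6L, duration = 6L))
  invisible(paths)
}
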