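#' The four indicator channels from a pair of per-eye values
#'
#' `mean = (left + right)/2`; `diff = |left - right|` — the between-eye
#' variability channel, expected to *shrink* under higher cognitive load
#' (reduced autonomic variability).  If either eye is missing the whole set
#' is missing.
#'
#' @param ipa_left,ipa_right per-eye indicator values (events/s).
#' @return named list `left, right, mean, diff`, or `NULL` when an eye is
#'   missing.
#' @export
channels_from_eyes <- function(ipa_left, ipa_right) {
  if (is.null(ipa_left) || is.null(ipa_right) ||
      is.na(ipa_left) || is.na(ipa_right)) {
    return(NULL)
  }
  list(left = ipa_left, right = ipa_right,
       mean = (ipa_left + ipa_right) / 2,
       diff = abs(ipa_left - ipa_right))
}

#' Within-participant z-standardization
#'
#' `(x - mean(x)) / sd(x)` with the n-1 denominator, computed over all
#' non-missing values of one participant's one channel across every segment
#' (both fixation tasks and all test items).  Controls inter-individual
#' differences in indicator range: affinely transformed inputs
#' (`a*x + b`, `a > 0`) standardize to the same values.
#'
#' @param x numeric vector (one participant, one channel).
#' @return standardized vector; all-`NA` (with a `reason` attribute) when
#'   fewer than 2 values are available or the spread is zero.
#' @export
z_standardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) {
    out <- rep(NA_real_, length(x))
    attr(out, "reason") <- "fewer than 2 values"
    return(out)
  }
  m <- mean(x[ok])
  s <- sd(x[ok])
  if (s == 0) {
    out <- rep(NA_real_, length(x))
    attr(out, "reason") <- "constant indicator"
    return(out)
  }
  (x - m) / s
}

#' Per-segment indicator table for a cohort
#'
#' Runs the full per-segment chain for every participant x segment: prepare
#' both eyes' series, compute the IPA, derive the four channels.  Segments
#' where either eye is unusable yield missing values (never zeros).
#'
#' @param samples sample tibble.
#' @param segments segment tibble.
#' @param params [ipa_params()].
#' @param fs sampling rate (Hz).
#' @param max_gap,reject_fraction blink-repair settings (see
#'   [repair_gaps()]).
#' @param drop_degraded treat series with over-long interpolated gaps as
#'   missing (default TRUE).
#' @return tibble `participant_id, label, segment_id, channel, standardized
#'   (FALSE), value` with four rows per usable segment.
#' @export
compute_indicators <- function(samples, segments, params = ipa_params(),
                               fs = 300, max_gap = 0.2,
                               reject_fraction = 0.5,
                               drop_degraded = TRUE) {
  by_pid <- split(seq_len(nrow(samples)), samples$participant_id)
  out_pid <- character(0); out_label <- character(0)
  out_sid <- character(0); out_left <- numeric(0); out_right <- numeric(0)
  rows <- list()
  for (pid in unique(segments$participant_id)) {
    idx <- by_pid[[pid]]
    if (is.null(idx)) next
    segs <- segments[segments$participant_id == pid, , drop = FALSE]
    segs <- segs[order(segs$t_start), , drop = FALSE]
    tt <- samples$t[idx]
    # one pass: samples -> enclosing segment via the sorted segment starts
    si <- findInterval(tt, segs$t_start)
    inside <- si >= 1L & tt < segs$t_end[pmax(si, 1L)]
    groups <- split(idx[inside], si[inside])
    seg_label <- segs$label
    seg_sid <- segs$segment_id
    t_col <- samples$t
    d_col <- list(left = samples$pupil_left, right = samples$pupil_right)
    v_col <- list(left = samples$valid_left, right = samples$valid_right)
    min_n <- ipa_min_length(params)
    for (j in seq_len(nrow(segs))) {
      rows_j <- groups[[as.character(j)]]
      if (is.null(rows_j)) next
      vals <- lapply(c("left", "right"), function(eye) {
        d <- d_col[[eye]][rows_j]
        d[!v_col[[eye]][rows_j]] <- NA_real_
        ser <- new_pupil_series(eye, t_col[rows_j], d, fs, seg_sid[j])
        ser <- tryCatch(
          repair_gaps(ser, max_gap = max_gap,
                      reject_fraction = reject_fraction),
          pupilload_rejected = function(e) NULL)
        if (is.null(ser) || ser$n < min_n) {
          return(NA_real_)
        }
        res <- compute_ipa(ser, params)
        if (drop_degraded && res$degraded) return(NA_real_)
        res$ipa
      })
      ch <- channels_from_eyes(vals[[1]], vals[[2]])
      if (is.null(ch)) next
      out_pid <- c(out_pid, pid)
      out_label <- c(out_label, seg_label[j])
      out_sid <- c(out_sid, seg_sid[j])
      out_left <- c(out_left, ch$left)
      out_right <- c(out_right, ch$right)
    }
  }
  nseg <- length(out_sid)
  tibble(
    participant_id = rep(out_pid, each = 4L),
    label = rep(out_label, each = 4L),
    segment_id = rep(out_sid, each = 4L),
    channel = rep(c("left", "right", "mean", "diff"), nseg),
    standardized = FALSE,
    value = as.numeric(rbind(out_left, out_right,
                             (out_left + out_right) / 2,
                             abs(out_left - out_right))))
}

#' Add within-participant z-standardized rows to an indicator table
#'
#' Each channel is standardized separately within participant across all of
#' that participant's segments (the common reference distribution that puts
#' all eight condition groups on one scale).  The default standardizes the
#' raw diff channel, i.e. `z(|L - R|)`; `mode = "diff_of_z"` instead derives
#' the standardized diff as `|z(L) - z(R)|`.
#'
#' @param indicators raw indicator tibble from [compute_indicators()].
#' @param mode `"z_of_diff"` (default) or `"diff_of_z"`.
#' @return the input with standardized rows appended (`standardized = TRUE`).
#' @export
standardize_indicators <- function(indicators,
                                   mode = c("z_of_diff", "diff_of_z")) {
  mode <- match.arg(mode)
  raw <- indicators[!indicators$standardized, , drop = FALSE]
  z <- raw %>%
    group_by(.data$participant_id, .data$channel) %>%
    mutate(value = as.numeric(z_standardize(.data$value))) %>%
    ungroup() %>%
    mutate(standardized = TRUE)
  if (mode == "diff_of_z") {
    zl <- z[z$channel == "left", c("participant_id", "segment_id", "value")]
    zr <- z[z$channel == "right", c("participant_id", "segment_id", "value")]
    names(zl)[3] <- "zl"
    names(zr)[3] <- "zr"
    dd <- left_join(zl, zr, by = c("participant_id", "segment_id"))
    z$value[z$channel == "diff"] <-
      abs(dd$zl - dd$zr)[match(paste(z$participant_id, z$segment_id)[z$channel == "diff"],
                               paste(dd$participant_id, dd$segment_id))]
  }
  bind_rows(indicators, z)
}

#' Aggregate indicator values per participant x condition label
#'
#' Unweighted arithmetic mean over a label's usable segments; missing
#' segment values are excluded, never zero-filled, and a label with no
#' usable segment yields no aggregate row.
#'
#' @param indicators indicator tibble (raw and/or standardized rows).
#' @return tibble `participant_id, label, channel, standardized, value,
#'   n_segments`.
#' @export
aggregate_by_label <- function(indicators) {
  indicators %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$participant_id, .data$label, .data$channel,
             .data$standardized) %>%
    summarise(n_segments = dplyr::n(), value = mean(.data$value),
              .groups = "drop") %>%
    dplyr::select(dplyr::all_of(c("participant_id", "label", "channel",
                                  "standardized", "value", "n_segments")))
}

#' Accuracy per participant and difficulty level
#'
#' The test's accuracy rule: only *possible* items count; a correctly solved
#' possible item scores 1, an incorrect or unanswered one 0.  Impossible
#' items never enter numerator or denominator.
#'
#' @param segments segment tibble of one cohort.
#' @return tibble `participant_id, label, accuracy, n_items` (levels only).
#' @export
accuracy_score <- function(segments) {
  poss <- segments[segments$item_type == "possible", , drop = FALSE]
  if (nrow(poss) == 0L) {
    return(tibble(participant_id = character(), label = character(),
                  accuracy = double(), n_items = integer()))
  }
  poss$score <- ifelse(is.na(poss$response_correct), 0L,
                       poss$response_correct)
  poss %>%
    group_by(.data$participant_id, .data$label) %>%
    summarise(accuracy = mean(.data$score), n_items = dplyr::n(),
              .groups = "drop")
}

#' Fixation precision from gaze residuals
#'
#' Standard deviation (n-1 denominator) of gaze-point residuals around the
#' fixation targets, per screen coordinate, pooled over all cross
#' presentations of one fixation task.
#'
#' @param gaze_x,gaze_y gaze samples (px).
#' @param target_x,target_y per-sample target positions (px).
#' @return named list `sd_x`, `sd_y`, or `NULL` with fewer than 2 valid
#'   samples.
#' @export
fixation_precision <- function(gaze_x, gaze_y, target_x, target_y) {
  ok <- !is.na(gaze_x) & !is.na(gaze_y)
  if (sum(ok) < 2L) return(NULL)
  list(sd_x = sd(gaze_x[ok] - target_x[ok]),
       sd_y = sd(gaze_y[ok] - target_y[ok]))
}

#' Fixation precision for every participant and fixation task
#'
#' Joins gaze samples to fixation-cross presentation windows (half-open) and
#' computes [fixation_precision()] per participant x task.
#'
#' @param samples sample tibble.
#' @param targets cross-window tibble `participant_id, label, t_start,
#'   t_end, target_x, target_y` (one row per cross presentation).
#' @return tibble `participant_id, label, sd_x, sd_y, n_samples`.
#' @export
precision_by_task <- function(samples, targets) {
  rows <- list()
  for (pid in unique(targets$participant_id)) {
    s <- samples[samples$participant_id == pid, , drop = FALSE]
    tg <- targets[targets$participant_id == pid, , drop = FALSE]
    for (lab in unique(tg$label)) {
      tw <- tg[tg$label == lab, , drop = FALSE]
      rx <- ry <- numeric(0)
      for (j in seq_len(nrow(tw))) {
        sel <- s$t >= tw$t_start[j] & s$t < tw$t_end[j]
        rx <- c(rx, s$gaze_x[sel] - tw$target_x[j])
        ry <- c(ry, s$gaze_y[sel] - tw$target_y[j])
      }
      if (length(rx) >= 2L) {
        rows[[length(rows) + 1L]] <- tibble(
          participant_id = pid, label = lab,
          sd_x = sd(rx), sd_y = sd(ry), n_samples = length(rx))
      }
    }
  }
  bind_rows(rows)
}
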