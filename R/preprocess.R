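#' Extract one eye's pupil series for one segment
#'
#' Half-open window: samples with `t_start <= t < t_end`.  Samples flagged
#' invalid for the requested eye become `NA` in the series (to be repaired or
#' rejected by [repair_gaps()]).
#'
#' @param samples sample tibble (see [read_samples()]).
#' @param segment one-row segment tibble or list with `participant_id`,
#'   `segment_id`, `t_start`, `t_end`.
#' @param eye `"left"` or `"right"`.
#' @param fs nominal sampling rate in Hz.
#' @return list of class `pupil_series`: `eye`, `t`, `d` (mm, `NA` where
#'   invalid), `fs`, `n`, `duration` (s, `n / fs`), `segment_id`, `degraded`.
#' @export
extract_segment_series <- function(samples, segment, eye = c("left", "right"),
                                   fs = 300) {
  eye <- match.arg(eye)
  sel <- samples$participant_id == segment$participant_id &
    samples$t >= segment$t_start & samples$t < segment$t_end
  if (!any(sel)) {
    abort(paste0("segment too short / empty span: ", segment$segment_id),
          class = "pupilload_too_short")
  }
  s <- samples[sel, , drop = FALSE]
  d <- s[[paste0("pupil_", eye)]]
  d[!s[[paste0("valid_", eye)]]] <- NA_real_
  new_pupil_series(eye, s$t, d, fs, segment$segment_id)
}

new_pupil_series <- function(eye, t, d, fs, segment_id = NA_character_,
                             degraded = FALSE) {
  structure(list(eye = eye, t = t, d = d, fs = fs, n = length(d),
                 duration = length(d) / fs, segment_id = segment_id,
                 degraded = degraded),
            class = "pupil_series")
}

invalid_runs <- function(bad) {
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Repair blink gaps in a pupil series
#'
#' Leading/trailing invalid samples are trimmed.  Interior invalid runs no
#' longer than `max_gap` seconds are linearly interpolated from the flanking
#' valid samples (so interpolated values never leave their range); longer
#' runs are bridged linearly as well but mark the series as degraded, so
#' downstream code can decide via the `degraded` flag whether to keep the
#' value.  A series with more than `reject_fraction` invalid samples is
#' rejected outright.
#'
#' Idempotent: repairing a repaired series returns it unchanged.
#'
#' @param series a `pupil_series`.
#' @param max_gap longest interior gap (s) that is silently interpolated.
#' @param reject_fraction reject when the invalid share exceeds this.
#' @return repaired `pupil_series` with attribute `n_interpolated`.
#' @export
repair_gaps <- function(series, max_gap = 0.2, reject_fraction = 0.5) {
  stopifnot(inherits(series, "pupil_series"))
  d <- series$d
  t <- series$t
  bad <- is.na(d)
  if (!any(bad)) {
    attr(series, "n_interpolated") <- 0L
    return(series)
  }
  if (mean(bad) > reject_fraction) {
    abort(sprintf("segment %s rejected: %.0f%% invalid samples",
                  series$segment_id, 100 * mean(bad)),
          class = "pupilload_rejected")
  }
  # trim leading/trailing invalid samples
  keep <- range(which(!bad))
  d <- d[keep[1]:keep[2]]
  t <- t[keep[1]:keep[2]]
  bad <- is.na(d)
  degraded <- isTRUE(series$degraded)
  n_interp <- 0L
  if (any(bad)) {
    runs <- invalid_runs(bad)
    gap_len <- (runs[, "end"] - runs[, "start"] + 1L) / series$fs
    degraded <- degraded || any(gap_len > max_gap)
    for (i in seq_len(nrow(runs))) {
      a <- runs[i, "start"] - 1L
      b <- runs[i, "end"] + 1L
      idx <- runs[i, "start"]:runs[i, "end"]
      w <- (idx - a) / (b - a)
      d[idx] <- (1 - w) * d[a] + w * d[b]
      n_interp <- n_interp + length(idx)
    }
  }
  out <- new_pupil_series(series$eye, t, d, series$fs, series$segment_id,
                          degraded = degraded)
  attr(out, "n_interpolated") <- n_interp
  out
}

#' Extract and repair in one call
#'
#' Convenience wrapper; returns `NULL` (a missing series) instead of
#' signalling when the segment is empty, rejected, or too short for the
#' wavelet decomposition, so cohort-level loops can simply drop it.
#'
#' @inheritParams extract_segment_series
#' @inheritParams repair_gaps
#' @param params [ipa_params()] used only for the minimum-length check.
#' @return a `pupil_series` or `NULL`.
#' @export
prepare_series <- function(samples, segment, eye, fs = 300, max_gap = 0.2,
                           reject_fraction = 0.5, params = ipa_params()) {
  res <- tryCatch(
    repair_gaps(extract_segment_series(samples, segment, eye, fs),
                max_gap = max_gap, reject_fraction = reject_fraction),
    pupilload_too_short = function(e) NULL,
    pupilload_rejected = function(e) NULL)
  if (!is.null(res) && res$n < ipa_min_length(params)) return(NULL)
  res
}
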