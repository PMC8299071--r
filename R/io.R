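#' Condition labels of a session
#'
#' Two fixation tasks flanking six test difficulty levels.
#' @return character vector in presentation order.
#' @export
condition_labels <- function() c("fix1", "a", "b", "c", "d", "e", "f", "fix2")

level_labels <- function() c("a", "b", "c", "d", "e", "f")

#' Column-name dialect for delimited eye-tracking exports
#'
#' Maps the canonical column names used internally to the names found in a
#' vendor export.  Unknown extra columns in a file are ignored (with a
#' message); missing required columns raise a format error naming the
#' column.
#'
#' @param ... named overrides, e.g. `pupil_left = "PupilLeft"`.
#' @param unit time unit of the `t` column: `"seconds"`, `"milliseconds"` or
#'   `"microseconds"`; timestamps are normalized to seconds internally.
#' @return named list of class `io_dialect`.
#' @export
io_dialect <- function(..., unit = c("seconds", "milliseconds", "microseconds")) {
  unit <- match.arg(unit)
  map <- list(participant_id = "participant_id", t = "t",
              pupil_left = "pupil_left", pupil_right = "pupil_right",
              gaze_x = "gaze_x", gaze_y = "gaze_y",
              valid_left = "valid_left", valid_right = "valid_right")
  over <- list(...)
  bad <- setdiff(names(over), names(map))
  if (length(bad)) {
    abort(paste0("unknown dialect field(s): ", paste(bad, collapse = ", ")),
          class = "pupilload_format")
  }
  map[names(over)] <- over
  structure(c(map, list(unit = unit)), class = "io_dialect")
}

time_scale <- function(unit) {
  switch(unit, seconds = 1, milliseconds = 1e-3, microseconds = 1e-6)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_quiet <- function(path) {
  readr::read_delim(path, delim = detect_delim(path),
                    show_col_types = FALSE, progress = FALSE)
}

#' Read binocular pupil samples from a delimited text export
#'
#' Comma- or tab-delimited (auto-detected from the header line).  Timestamps
#' are converted to seconds per the dialect's unit and must be non-decreasing
#' within each participant.  A sample is usable for an eye iff its validity
#' flag is true *and* its diameter lies in `(pupil_min, pupil_max)` mm;
#' invalid samples are flagged, never dropped.
#'
#' @param path file path.
#' @param dialect an [io_dialect()].
#' @param pupil_min,pupil_max physiological plausibility bounds in mm.
#' @return tibble with columns `participant_id, t, pupil_left, pupil_right,
#'   gaze_x, gaze_y, valid_left, valid_right`, sorted by participant then `t`
#'   (stable).
#' @export
read_samples <- function(path, dialect = io_dialect(),
                         pupil_min = 0.5, pupil_max = 10) {
  if (!file.exists(path)) {
    abort(paste0("samples file not found: ", path), class = "pupilload_format")
  }
  raw <- read_delim_quiet(path)
  canonical <- setdiff(names(unclass(dialect)), "unit")
  wanted <- unlist(dialect[canonical])
  missing_cols <- wanted[!wanted %in% names(raw)]
  if (length(missing_cols)) {
    abort(paste0("samples file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pupilload_format")
  }
  extra <- setdiff(names(raw), wanted)
  if (length(extra)) {
    message("read_samples: ignoring extra column(s): ",
            paste(extra, collapse = ", "))
  }
  out <- tibble(
    participant_id = as.character(raw[[dialect$participant_id]]),
    t = as.numeric(raw[[dialect$t]]) * time_scale(dialect$unit),
    pupil_left = as.numeric(raw[[dialect$pupil_left]]),
    pupil_right = as.numeric(raw[[dialect$pupil_right]]),
    gaze_x = as.numeric(raw[[dialect$gaze_x]]),
    gaze_y = as.numeric(raw[[dialect$gaze_y]]),
    valid_left = as.logical(raw[[dialect$valid_left]]),
    valid_right = as.logical(raw[[dialect$valid_right]])
  )
  # timestamps must be non-decreasing within participant (file order)
  for (pid in unique(out$participant_id)) {
    tt <- out$t[out$participant_id == pid]
    bad <- which(diff(tt) < 0)
    if (length(bad)) {
      abort(sprintf(
        "non-monotone timestamps for participant %s: first offending row %d",
        pid, bad[1] + 1L), class = "pupilload_data")
    }
  }
  out$valid_left <- validity_mask(out$valid_left, out$pupil_left,
                                  pupil_min, pupil_max)
  out$valid_right <- validity_mask(out$valid_right, out$pupil_right,
                                   pupil_min, pupil_max)
  out[order(out$participant_id, method = "radix"), , drop = FALSE]
}

validity_mask <- function(flag, d, pupil_min, pupil_max) {
  flag & !is.na(d) & is.finite(d) & d > pupil_min & d < pupil_max
}

#' Read segment annotations
#'
#' Segments assign half-open sample spans `[t_start, t_end)` to condition
#' labels.  Labels must come from [condition_labels()]; spans must not
#' overlap within a participant; item segments must not exceed 60 s (the
#' per-item response limit).
#'
#' @param path file path (delimited text, auto-detected comma/tab).
#' @return tibble `participant_id, segment_id, label, item_type,
#'   response_correct, t_start, t_end`, stably sorted by participant and
#'   `t_start`.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("segments file not found: ", path), class = "pupilload_format")
  }
  raw <- read_delim_quiet(path)
  need <- c("participant_id", "segment_id", "label", "item_type",
            "response_correct", "t_start", "t_end")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(paste0("segments file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pupilload_format")
  }
  seg <- tibble(
    participant_id = as.character(raw$participant_id),
    segment_id = as.character(raw$segment_id),
    label = as.character(raw$label),
    item_type = as.character(raw$item_type),
    response_correct = as.integer(raw$response_correct),
    t_start = as.numeric(raw$t_start),
    t_end = as.numeric(raw$t_end)
  )
  validate_segments(seg)
}

validate_segments <- function(seg) {
  bad_label <- setdiff(unique(seg$label), condition_labels())
  if (length(bad_label)) {
    abort(paste0("unknown segment label(s): ", paste(bad_label, collapse = ", ")),
          class = "pupilload_format")
  }
  if (any(seg$t_start >= seg$t_end)) {
    abort("segments with t_start >= t_end", class = "pupilload_data")
  }
  is_fix <- seg$label %in% c("fix1", "fix2")
  if (any(is_fix & seg$item_type != "none") ||
      any(!is_fix & seg$item_type == "none")) {
    abort("item_type must be 'none' exactly for fixation segments",
          class = "pupilload_data")
  }
  too_long <- !is_fix & (seg$t_end - seg$t_start) > 60 + 1e-9
  if (any(too_long)) {
    abort(paste0("item segment(s) longer than 60 s: ",
                 paste(seg$segment_id[too_long], collapse = ", ")),
          class = "pupilload_data")
  }
  seg <- seg[order(seg$participant_id, seg$t_start, method = "radix"), ,
             drop = FALSE]
  for (pid in unique(seg$participant_id)) {
    s <- seg[seg$participant_id == pid, ]
    if (nrow(s) > 1L) {
      overlap <- which(s$t_start[-1L] < s$t_end[-nrow(s)] - 1e-12)
      if (length(overlap)) {
        i <- overlap[1]
        abort(sprintf("overlapping segments for participant %s: %s and %s",
                      pid, s$segment_id[i], s$segment_id[i + 1L]),
              class = "pupilload_data")
      }
    }
  }
  seg
}

fmt_num <- function(x, digits = 6L) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}

write_formatted <- function(df, path, digits) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      out[[nm]] <- fmt_num(out[[nm]], digits[[nm]] %||% 6L)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an indicator table to delimited text
#'
#' Fixed column order (`participant_id, label, segment_id, channel,
#' standardized, value`) and fixed 6-decimal formatting, so identical inputs
#' produce byte-identical files.
#'
#' @param records indicator tibble.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_indicators <- function(records, path) {
  cols <- c("participant_id", "label", "segment_id", "channel",
            "standardized", "value")
  if (nrow(records) == 0L) {
    warn("write_indicators: no records; writing header only")
    records <- tibble(participant_id = character(), label = character(),
                      segment_id = character(), channel = character(),
                      standardized = logical(), value = double())
  }
  write_formatted(records[, cols], path, list(value = 6L))
}

#' Write a comparison-result table to delimited text
#'
#' @param results comparison tibble (see [run_pairwise_comparisons()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_comparisons <- function(results, path) {
  cols <- c("pair_a", "pair_b", "channel", "standardized", "direction", "n",
            "t_stat", "bf10", "es_mean", "es_lo", "es_hi", "evidence")
  if (nrow(results) == 0L) {
    warn("write_comparisons: no results; writing header only")
    results <- tibble(pair_a = character(), pair_b = character(),
                      channel = character(), standardized = logical(),
                      direction = character(), n = integer(),
                      t_stat = double(), bf10 = double(), es_mean = double(),
                      es_lo = double(), es_hi = double(),
                      evidence = character())
  }
  out <- results[, cols]
  out$bf10 <- ifelse(is.na(out$bf10), "NA", sprintf("%.6g", out$bf10))
  write_formatted(out, path, list(t_stat = 6L, es_mean = 6L,
                                  es_lo = 6L, es_hi = 6L))
  invisible(path)
}
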