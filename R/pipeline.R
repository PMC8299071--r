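#' Resolved configuration of an analysis run
#'
#' Flat nested list mirroring the stages: IO dialect, preprocessing, IPA
#' parameters, standardization, Bayesian comparisons.  Validated up front;
#' serialized as YAML into every output directory.
#'
#' @param io [io_dialect()].
#' @param preprocess list: `max_gap_s`, `reject_invalid_fraction`,
#'   `pupil_min_mm`, `pupil_max_mm`.
#' @param ipa [ipa_params()].
#' @param standardize list: `mode` (see [standardize_indicators()]).
#' @param bayes list: `prior_scale`, optional `plan` (tibble), `channels`,
#'   `standardized` (logical vector of variants to analyse).
#' @param sampling_rate recording rate (Hz).
#' @param seed integer seed for any stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(io = io_dialect(),
                       preprocess = list(max_gap_s = 0.2,
                                         reject_invalid_fraction = 0.5,
                                         pupil_min_mm = 0.5,
                                         pupil_max_mm = 10),
                       ipa = ipa_params(),
                       standardize = list(mode = "z_of_diff"),
                       bayes = list(prior_scale = 1, plan = NULL,
                                    channels = c("mean", "diff"),
                                    standardized = c(FALSE, TRUE)),
                       sampling_rate = 300,
                       seed = 1L) {
  stopifnot(inherits(io, "io_dialect"), inherits(ipa, "ipa_params"))
  if (!is.numeric(bayes$prior_scale) || bayes$prior_scale <= 0) {
    abort("bayes$prior_scale must be > 0", class = "pupilload_param")
  }
  structure(list(io = io, preprocess = preprocess, ipa = ipa,
                 standardize = standardize, bayes = bayes,
                 sampling_rate = sampling_rate, seed = as.integer(seed)),
            class = "run_config")
}

config_as_yaml <- function(config) {
  yaml::as.yaml(rapply(unclass(config), unclass, how = "replace"))
}

#' Run the full analysis pipeline
#'
#' samples + segments -> per-segment per-eye IPA -> four indicator channels
#' -> within-participant z-standardization -> per-condition aggregates ->
#' JZS pairwise comparison battery (one row per plan entry x channel x
#' standardization), plus accuracy scoring and (when fixation-cross targets
#' are supplied) fixation precision with its undirected fix2-vs-fix1
#' equality checks.
#'
#' @param samples sample tibble or path to a samples file.
#' @param segments segment tibble or path to a segments file.
#' @param config a [run_config()].
#' @param targets optional fixation-cross window tibble (see
#'   [precision_by_task()]).
#' @param out_dir optional directory; when given, all tables, the resolved
#'   config and a run log are written there.
#' @return list of class `run_result`: `indicators`, `aggregates`,
#'   `comparisons`, `accuracy`, `precision`, `precision_comparisons`,
#'   `config`, `log` (character vector of dropped-segment reasons).
#' @export
run_analysis <- function(samples, segments, config = run_config(),
                         targets = NULL, out_dir = NULL) {
  if (is.character(samples)) {
    samples <- read_samples(samples, config$io,
                            pupil_min = config$preprocess$pupil_min_mm,
                            pupil_max = config$preprocess$pupil_max_mm)
  }
  if (is.character(segments)) segments <- read_segments(segments)
  log_lines <- character(0)
  indicators <- compute_indicators(
    samples, segments, params = config$ipa, fs = config$sampling_rate,
    max_gap = config$preprocess$max_gap_s,
    reject_fraction = config$preprocess$reject_invalid_fraction)
  done <- unique(indicators$segment_id)
  dropped <- setdiff(segments$segment_id, done)
  if (length(dropped)) {
    log_lines <- c(log_lines,
                   sprintf("segment %s dropped: unusable series", dropped))
  }
  indicators <- standardize_indicators(indicators,
                                       mode = config$standardize$mode)
  aggregates <- aggregate_by_label(indicators)
  comb <- expand.grid(channel = config$bayes$channels,
                      standardized = config$bayes$standardized,
                      stringsAsFactors = FALSE)
  comparisons <- bind_rows(lapply(seq_len(nrow(comb)), function(i) {
    ch <- comb$channel[i]
    plan <- config$bayes$plan %||% default_comparison_plan(ch)
    run_pairwise_comparisons(aggregates, plan = plan, channel = ch,
                             standardized = comb$standardized[i],
                             r = config$bayes$prior_scale)
  }))
  if (nrow(comparisons) > 0L &&
      all(comparisons$evidence == "not_computable")) {
    warn("all comparisons are degenerate (constant indicators?); results flagged not_computable")
  }
  accuracy <- accuracy_score(segments)
  precision <- NULL
  precision_comparisons <- NULL
  if (!is.null(targets)) {
    precision <- precision_by_task(samples, targets)
    precision_comparisons <- compare_fixation_precision(
      precision, r = config$bayes$prior_scale)
  }
  result <- structure(list(indicators = indicators, aggregates = aggregates,
                           comparisons = comparisons, accuracy = accuracy,
                           precision = precision,
                           precision_comparisons = precision_comparisons,
                           config = config, log = log_lines),
                      class = "run_result")
  if (!is.null(out_dir)) write_run_result(result, out_dir)
  result
}

#' Undirected equality check of fixation precision before vs after the test
#'
#' Paired JZS t-tests (two-sided) of the per-participant precision (gaze sd
#' per coordinate) of fixation task 2 against fixation task 1 — the
#' task-engagement precondition for interpreting fatigue contrasts.
#'
#' @param precision output of [precision_by_task()].
#' @param r Cauchy prior scale.
#' @return comparison tibble with channels `precision_x`, `precision_y`.
#' @export
compare_fixation_precision <- function(precision, r = 1) {
  agg <- bind_rows(
    mutate(precision, channel = "precision_x", value = .data$sd_x),
    mutate(precision, channel = "precision_y", value = .data$sd_y)) %>%
    mutate(standardized = FALSE) %>%
    dplyr::select(dplyr::all_of(c("participant_id", "label", "channel",
                                  "standardized", "value")))
  plan <- tibble(pair_a = "fix2", pair_b = "fix1", direction = "two_sided")
  bind_rows(
    run_pairwise_comparisons(agg, plan, channel = "precision_x", r = r),
    run_pairwise_comparisons(agg, plan, channel = "precision_y", r = r))
}

write_run_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_indicators(result$indicators, file.path(out_dir, "indicators.csv"))
  write_formatted(result$aggregates, file.path(out_dir, "aggregates.csv"),
                  list(value = 6L))
  write_comparisons(result$comparisons, file.path(out_dir,
                                                  "comparisons.csv"))
  if (nrow(result$accuracy)) {
    write_formatted(result$accuracy, file.path(out_dir, "accuracy.csv"),
                    list(accuracy = 6L))
  }
  if (!is.null(result$precision)) {
    write_formatted(result$precision, file.path(out_dir, "precision.csv"),
                    list(sd_x = 6L, sd_y = 6L))
    write_comparisons(result$precision_comparisons,
                      file.path(out_dir, "precision_comparisons.csv"))
  }
  writeLines(config_as_yaml(result$config),
             file.path(out_dir, "config.yaml"))
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Human-readable summary of a completed run
#'
#' Reads artifacts only (no recomputation): per-condition indicator
#' profiles and the comparison table with evidence markers in the
#' table-legend style (`*`/`'` moderate ... `****`/`''''` extreme).
#'
#' @param x a `run_result` or an output directory written by
#'   [run_analysis()].
#' @return character vector of report lines, invisibly; also written to
#'   `report.txt` when `x` is a directory.
#' @export
make_report <- function(x) {
  from_dir <- is.character(x)
  if (from_dir) {
    dir <- x
    need <- file.path(dir, c("aggregates.csv", "comparisons.csv"))
    missing_f <- need[!file.exists(need)]
    if (length(missing_f)) {
      abort(paste0("missing artifact: ", paste(missing_f, collapse = ", ")),
            class = "pupilload_format")
    }
    aggregates <- readr::read_csv(need[1], show_col_types = FALSE)
    comparisons <- readr::read_csv(need[2], show_col_types = FALSE)
  } else {
    aggregates <- x$aggregates
    comparisons <- x$comparisons
  }
  lines <- c("Pupillary workload indicators: run report",
             "=========================================", "")
  prof <- aggregates %>%
    group_by(.data$label, .data$channel, .data$standardized) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  lines <- c(lines, "Condition profiles (grand mean over participants):")
  for (std in unique(prof$standardized)) {
    lines <- c(lines, sprintf("  %s values:",
                              if (std) "z-standardized" else "conventional"))
    for (ch in unique(prof$channel)) {
      sub <- prof[prof$channel == ch & prof$standardized == std, ]
      if (!nrow(sub)) next
      ord <- match(condition_labels(), sub$label)
      ord <- ord[!is.na(ord)]
      lines <- c(lines, sprintf(
        "    %-5s %s", ch,
        paste(sprintf("%s=%.3f", sub$label[ord], sub$value[ord]),
              collapse = "  ")))
    }
  }
  lines <- c(lines, "", "Pairwise comparisons (JZS paired t, r = prior scale):")
  comp_ok <- comparisons[comparisons$evidence != "not_computable", ,
                         drop = FALSE]
  if (nrow(comp_ok) == 0L) {
    lines <- c(lines, "  no computable pairs")
  } else {
    for (i in seq_len(nrow(comp_ok))) {
      r <- comp_ok[i, ]
      lines <- c(lines, sprintf(
        "  %-4s - %-4s  %-5s %-13s n=%2d  ES=% .2f [% .2f; % .2f]  BF10=%.6g%s",
        r$pair_a, r$pair_b, r$channel,
        ifelse(r$standardized, "z-standardized", "conventional"), r$n,
        r$es_mean, r$es_lo, r$es_hi, r$bf10,
        evidence_marker(r$evidence)))
    }
  }
  nc <- nrow(comparisons) - nrow(comp_ok)
  if (nc > 0) lines <- c(lines, sprintf("  (%d pair(s) not computable)", nc))
  if (from_dir) writeLines(lines, file.path(dir, "report.txt"))
  invisible(lines)
}
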