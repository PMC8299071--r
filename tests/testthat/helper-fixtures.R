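# small in-code fixtures shared across test files

# a regular well-formed sample tibble for one participant
make_samples <- function(n = 900, fs = 300, pid = "p001",
                         left = rep(4, n), right = rep(4, n)) {
  tibble::tibble(
    participant_id = pid,
    t = (seq_len(n) - 1) / fs,
    pupil_left = left, pupil_right = right,
    gaze_x = 960, gaze_y = 540,
    valid_left = TRUE, valid_right = TRUE)
}

make_segment <- function(pid = "p001", sid = "s01", label = "a",
                         item_type = "possible", correct = 1L,
                         t_start = 0, t_end = 3) {
  tibble::tibble(participant_id = pid, segment_id = sid, label = label,
                 item_type = item_type, response_correct = correct,
                 t_start = t_start, t_end = t_end)
}

# a small session layout for fast pipeline tests: 3 crosses per fixation
# task, 4 items per block (one possible and one impossible per level)
mini_design <- function(n_participants = 3, master_seed = 1, ...) {
  cohort_design(
    n_participants = n_participants, master_seed = master_seed,
    item_duration_median_s = c(a = 2, b = 2, c = 2, d = 2, e = 2, f = 2),
    design = study_design(fixation_cross_count = 3, items_per_block = 4),
    ...)
}

write_temp_csv <- function(df, digits = list()) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  pupilload:::write_formatted(df, path, digits)
  path
}
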