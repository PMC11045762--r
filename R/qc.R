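#' Motion and scan-time quality-control filtering
#'
#' Applies the study's run- and subject-level exclusions in order:
#' (1) runs with mean framewise displacement at or above `fd_threshold` are
#' dropped ("motion"); (2) when a subject has multiple sessions, only the
#' session with the most surviving runs is kept, ties going to the earliest
#' session ("session"); (3) subjects whose retained concatenated duration
#' falls below `min_minutes` are dropped entirely ("scan_time").
#'
#' @param runs_table Tibble with one row per run: `subject_id`, `mean_fd`
#'   (mm), `duration_min` (minutes), optionally `session_id` and any further
#'   columns (carried through).
#' @param fd_threshold Mean-FD exclusion threshold in mm (default 0.3; runs
#'   with `mean_fd >= fd_threshold` are excluded).
#' @param min_minutes Minimum retained concatenated scan time per subject in
#'   minutes (default 7).
#' @return List with `retained` (the surviving runs) and `exclusions`
#'   (tibble: `subject_id`, `run_id`/`session_id` where applicable, `reason`
#'   in `"motion"`, `"session"`, `"scan_time"`).
#' @export
qc_filter <- function(runs_table, fd_threshold = 0.3, min_minutes = 7) {
  if (fd_threshold <= 0 || min_minutes <= 0)
    abort("thresholds must be positive.")
  req <- c("subject_id", "mean_fd", "duration_min")
  missing <- setdiff(req, names(runs_table))
  if (length(missing))
    abort(paste0("runs table lacks columns: ", paste(missing, collapse = ", ")))
  runs_table <- as_tibble(runs_table)
  if (!"run_id" %in% names(runs_table))
    runs_table$run_id <- as.character(seq_len(nrow(runs_table)))

  excl <- list()

  motion_bad <- runs_table$mean_fd >= fd_threshold
  if (any(motion_bad))
    excl$motion <- tibble(subject_id = runs_table$subject_id[motion_bad],
                          run_id = runs_table$run_id[motion_bad],
                          reason = "motion")
  kept <- runs_table[!motion_bad, , drop = FALSE]

  if ("session_id" %in% names(kept) && nrow(kept)) {
    best <- kept %>%
      group_by(.data$subject_id, .data$session_id) %>%
      summarise(n_runs = dplyr::n(), .groups = "drop") %>%
      arrange(.data$subject_id, dplyr::desc(.data$n_runs), .data$session_id) %>%
      group_by(.data$subject_id) %>%
      dplyr::slice(1) %>%
      ungroup()
    drop <- kept %>%
      dplyr::anti_join(best, by = c("subject_id", "session_id"))
    if (nrow(drop))
      excl$session <- tibble(subject_id = drop$subject_id,
                             run_id = drop$run_id, reason = "session")
    kept <- kept %>% dplyr::semi_join(best, by = c("subject_id", "session_id"))
  }

  if (nrow(kept)) {
    dur <- kept %>%
      group_by(.data$subject_id) %>%
      summarise(total_min = sum(.data$duration_min), .groups = "drop")
    short <- dur$subject_id[dur$total_min < min_minutes]
  } else {
    short <- character(0)
  }
  # subjects who lost every run to motion are scan-time exclusions too
  all_subjects <- unique(runs_table$subject_id)
  no_runs <- setdiff(all_subjects, kept$subject_id)
  short <- union(short, no_runs)
  if (length(short))
    excl$scan_time <- tibble(subject_id = short, run_id = NA_character_,
                             reason = "scan_time")
  kept <- kept[!(kept$subject_id %in% short), , drop = FALSE]

  list(retained = kept,
       exclusions = if (length(excl)) bind_rows(excl) else
         tibble(subject_id = character(), run_id = character(),
                reason = character()))
}
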