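trial_schema <- c("subject_id", "timepoint", "block", "trial", "choice1",
                  "transition", "state2", "choice2", "reward", "rt1_s",
                  "rt2_s")

#' Read a two-stage task trial table
#'
#' Reads a comma-delimited trial table with the exact header
#' `subject_id,timepoint,block,trial,choice1,transition,state2,choice2,reward,rt1_s,rt2_s`
#' (empty fields = missing RTs for choice-only data) and validates codes and
#' the consistency of the transition label with `(choice1, state2)`.
#'
#' @param path file path.
#' @return Trial table data frame.
#' @export
read_trials <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (!identical(header, trial_schema))
    stop("malformed header in ", path, ": expected ",
         paste(trial_schema, collapse = ","))
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject_id = "character",
                                timepoint = "character",
                                transition = "character"),
                 na.strings = "")
  validate_trials(df, origin = path)
  df
}

validate_trials <- function(df, origin = "trial table") {
  bad <- function(ok, what) {
    if (any(!ok)) {
      lines <- which(!ok)[seq_len(min(5, sum(!ok)))] + 1L # +1 for header
      stop(origin, ": ", what, " (line ", paste(lines, collapse = ", "),
           if (sum(!ok) > 5) ", ..." else "", ")")
    }
  }
  bad(df$choice1 %in% c(1, 2), "choice1 must be 1 or 2")
  bad(df$choice2 %in% c(1, 2), "choice2 must be 1 or 2")
  bad(df$state2 %in% c(2, 3), "state2 must be 2 or 3")
  bad(df$reward %in% c(0, 1), "reward must be 0 or 1")
  bad(df$transition %in% c("common", "rare"), "unknown transition label")
  expected <- ifelse((df$choice1 == 1) == (df$state2 == 2), "common", "rare")
  bad(df$transition == expected,
      "transition label inconsistent with (choice1, state2)")
  bad(is.na(df$rt1_s) | df$rt1_s > 0, "rt1_s must be > 0 when present")
  bad(is.na(df$rt2_s) | df$rt2_s > 0, "rt2_s must be > 0 when present")
  ord <- unlist(lapply(split_sessions(df), function(s)
    all(diff(s$trial) > 0)), use.names = FALSE)
  if (!all(ord)) stop(origin, ": trial indices must be strictly increasing ",
                      "within a session")
  invisible(df)
}

#' Write a two-stage task trial table
#'
#' Writes the schema of [read_trials()]; RTs keep full double precision so
#' that a write/read round trip is exact. Missing RTs become empty fields.
#'
#' @param data trial table.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path) {
  stopifnot(all(trial_schema %in% names(data)))
  out <- data[trial_schema]
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  out$rt1_s <- fmt(out$rt1_s)
  out$rt2_s <- fmt(out$rt2_s)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Apply participant- and trial-level exclusions
#'
#' Participant rules: exclude a subject who pressed the same first-stage key
#' on more than `same_key_max` of trials, or whose fraction of implausibly
#' fast trials (any stage RT below `rt_min`) exceeds `fast_rt_max`. For
#' retained subjects, the first trial of each block and any trial with an RT
#' below `rt_min` are dropped. RT-based rules are skipped (and noted) for
#' choice-only data.
#'
#' @param data multi-subject trial table.
#' @param same_key_max maximum tolerated same-key fraction (exclusive).
#' @param fast_rt_max maximum tolerated fast-trial fraction (exclusive).
#' @param rt_min implausible-RT threshold in seconds.
#' @return List with `data` (filtered trial table) and `report` (class
#'   `exclusion_report`): per-subject fractions and flags, and trial-drop
#'   counts.
#' @export
apply_exclusions <- function(data, same_key_max = 0.95, fast_rt_max = 0.10,
                             rt_min = 0.150) {
  has_rt <- !all(is.na(data$rt1_s)) || !all(is.na(data$rt2_s))
  subjects <- split(data, data$subject_id)
  sub_report <- do.call(rbind, lapply(subjects, function(d) {
    same_key <- max(mean(d$choice1 == 1), mean(d$choice1 == 2))
    fast <- if (has_rt)
      mean((!is.na(d$rt1_s) & d$rt1_s < rt_min) |
             (!is.na(d$rt2_s) & d$rt2_s < rt_min)) else NA_real_
    excluded <- same_key > same_key_max || (has_rt && fast > fast_rt_max)
    reason <- if (!excluded) "" else if (same_key > same_key_max)
      "same key" else "fast RTs"
    data.frame(subject_id = d$subject_id[1], same_key_fraction = same_key,
               fast_rt_fraction = fast, excluded = excluded, reason = reason,
               stringsAsFactors = FALSE)
  }))
  rownames(sub_report) <- NULL
  keep <- data$subject_id %in% sub_report$subject_id[!sub_report$excluded]
  df <- data[keep, ]
  first_of_block <- unlist(lapply(split_sessions(df), function(s)
    s$trial %in% vapply(split(s$trial, s$block), min, numeric(1))),
    use.names = FALSE)
  fast_trial <- if (has_rt)
    (!is.na(df$rt1_s) & df$rt1_s < rt_min) |
      (!is.na(df$rt2_s) & df$rt2_s < rt_min)
  else rep(FALSE, nrow(df))
  report <- structure(list(subjects = sub_report,
                           n_subjects_excluded = sum(sub_report$excluded),
                           n_first_trials = sum(first_of_block),
                           n_fast_trials = sum(fast_trial & !first_of_block),
                           rt_rules_applied = has_rt),
                      class = "exclusion_report")
  list(data = df[!(first_of_block | fast_trial), ], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusions: %d of %d subject(s) removed",
              x$n_subjects_excluded, nrow(x$subjects)))
  if (x$n_subjects_excluded)
    cat(" (", paste(x$subjects$subject_id[x$subjects$excluded],
                    collapse = ", "), ")", sep = "")
  cat(sprintf("\nTrials dropped: %d block-initial, %d fast-RT%s\n",
              x$n_first_trials, x$n_fast_trials,
              if (x$rt_rules_applied) "" else " (RT rules skipped: no RTs)"))
  invisible(x)
}

#' Generate the bundled synthetic example cohort
#'
#' Deterministically regenerates the small synthetic cohort shipped in
#' `inst/extdata/`: three DDM-RL and three RL agents, two timepoints of 40
#' trials each, parameters spread over plausible ranges. Used by tests and
#' examples; the committed files are byte-identical to this function's
#' output.
#'
#' @param dir optional directory to write `synthetic_cohort.csv` and
#'   `synthetic_cohort_scores.csv` into.
#' @return The cohort trial table, invisibly if `dir` is given.
#' @export
make_fixtures <- function(dir = NULL) {
  set.seed(20260901)
  cfg <- task_config(n_trials = 40, n_blocks = 2)
  ddm <- t(vapply(c(0.2, 0.5, 0.9), function(w)
    ddmrl_params(alpha1 = 0.4 + 0.2 * w, lambda = 0.5, w = w, p = 0.1,
                 b1 = 5, a1 = 1.8, tau1 = 0.3), numeric(11)))
  rl <- t(vapply(c(0.1, 0.5, 0.8), function(w)
    rl_params(alpha1 = 0.5, beta1 = 5, lambda = 0.5, w = w, p = 0.1),
    numeric(7)))
  cohort <- do.call(rbind, lapply(c("baseline", "followup"), function(tp) {
    rbind(simulate_twostep(ddm, cfg, timepoint = tp,
                           subject_ids = paste0("ddm_", 1:3)),
          simulate_twostep(rl, cfg, timepoint = tp,
                           subject_ids = paste0("rl_", 1:3)))
  }))
  if (!is.null(dir)) {
    write_trials(cohort, file.path(dir, "synthetic_cohort.csv"))
    sc <- twostep_scores(cohort)
    num <- vapply(sc, is.numeric, logical(1))
    sc[num] <- lapply(sc[num], function(x) round(x, 10))
    write.csv(sc, file.path(dir, "synthetic_cohort_scores.csv"),
              row.names = FALSE, quote = FALSE, na = "")
    return(invisible(cohort))
  }
  cohort
}
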