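#' Filter temporal-order trials by response time
#'
#' Discards trials with response times shorter than `min_s` (default 0.5 s)
#' or longer than `max_s` (default 15 s), reading the rule strictly: trials
#' at exactly the bounds are retained. Discard counts per participant and the
#' overall discard proportion are attached as the `discards` attribute and
#' reported via a message.
#'
#' @param trials Tibble of memory trials (needs `participant_id`, `rt_s`).
#' @param min_s,max_s Retention bounds in seconds (defaults 0.5 and 15).
#' @return The retained trials, with a `discards` attribute: a list with
#'   `n_total`, `n_discarded`, `prop` and a per-participant tibble `by_id`.
#' @export
filter_rt <- function(trials, min_s = 0.5, max_s = 15) {
  if (any(trials$rt_s < 0)) abort("filter_rt: negative response times")
  keep <- trials$rt_s >= min_s & trials$rt_s <= max_s
  by_id <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(trials, .keep_flag = keep), .data$participant_id),
    n_total = dplyr::n(),
    n_discarded = sum(!.data$.keep_flag),
    .groups = "drop"
  )
  report <- list(n_total = nrow(trials), n_discarded = sum(!keep),
                 prop = if (nrow(trials) > 0) mean(!keep) else NA_real_,
                 by_id = by_id)
  message(sprintf("filter_rt: discarded %d of %d trials (%.2f%%) outside [%g, %g] s",
                  report$n_discarded, report$n_total, 100 * report$prop,
                  min_s, max_s))
  out <- trials[keep, , drop = FALSE]
  attr(out, "discards") <- report
  out
}

#' Score the temporal-order memory task
#'
#' Computes each participant's hit rate (proportion of correct order
#' judgments among retained trials) separately for the within-scene and
#' across-scenes conditions, plus their difference. A condition with zero
#' retained trials gets an `NA` accuracy (excluded from paired tests) with a
#' warning. Pass the output of [filter_rt()] so the per-participant discard
#' counts are carried through.
#'
#' @param trials RT-filtered trials (columns `participant_id`, `condition`,
#'   `correct`; or `response`/`earlier_side` from which `correct` is derived).
#' @return A tibble with columns `participant_id`, `acc_within`,
#'   `acc_across`, `diff`, `n_retained`, `n_discarded`.
#' @export
score_memory <- function(trials) {
  if (!"correct" %in% names(trials)) {
    trials$correct <- trials$response == trials$earlier_side
  }
  per_cond <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id, .data$condition),
    acc = mean(.data$correct), n = dplyr::n(), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(per_cond, id_cols = "participant_id",
                             names_from = "condition",
                             values_from = c("acc", "n"))
  for (nm in c("acc_within", "acc_across", "n_within", "n_across")) {
    if (!nm %in% names(wide)) wide[[nm]] <- if (grepl("^n_", nm)) 0L else NA_real_
  }
  wide$n_within <- tidyr::replace_na(wide$n_within, 0L)
  wide$n_across <- tidyr::replace_na(wide$n_across, 0L)
  if (any(is.na(wide$acc_within)) || any(is.na(wide$acc_across))) {
    warn(sprintf("score_memory: %d participant-condition cell(s) have no retained trials; accuracy set to NA",
                 sum(is.na(wide$acc_within)) + sum(is.na(wide$acc_across))))
  }
  discards <- attr(trials, "discards")
  n_disc <- if (!is.null(discards)) {
    setNames(discards$by_id$n_discarded, discards$by_id$participant_id)
  } else {
    setNames(integer(0), character(0))
  }
  out <- tibble::tibble(
    participant_id = wide$participant_id,
    acc_within = wide$acc_within,
    acc_across = wide$acc_across,
    diff = wide$acc_within - wide$acc_across,
    n_retained = wide$n_within + wide$n_across,
    n_discarded = as.integer(tidyr::replace_na(
      n_disc[wide$participant_id], 0L))
  )
  dplyr::arrange(out, .data$participant_id)
}

#' Cohort summary of memory accuracy by condition
#'
#' @param scores Output of [score_memory()].
#' @return A tibble with one row per condition: mean, SD, SE and n over
#'   participants with a defined accuracy.
#' @export
memory_condition_summary <- function(scores) {
  long <- tidyr::pivot_longer(scores[, c("participant_id", "acc_within", "acc_across")],
                              cols = c("acc_within", "acc_across"),
                              names_to = "condition", values_to = "acc",
                              names_prefix = "acc_")
  dplyr::summarise(
    dplyr::group_by(long, .data$condition),
    mean = mean(.data$acc, na.rm = TRUE),
    sd = sd(.data$acc, na.rm = TRUE),
    se = sd(.data$acc, na.rm = TRUE) / sqrt(sum(!is.na(.data$acc))),
    n = sum(!is.na(.data$acc)),
    .groups = "drop"
  )
}

#' Score the semantic-knowledge quiz
#'
#' Proportion correct out of the attempted three-option items (chance level
#' 1/3 = 0.33).
#'
#' @param records Tibble with columns `participant_id`, `n_correct`,
#'   `n_trials`.
#' @return A tibble with `participant_id` and `prop_correct`.
#' @export
score_semantic <- function(records) {
  if (any(records$n_trials <= 0)) abort("score_semantic: n_trials must be positive")
  if (any(records$n_correct < 0 | records$n_correct > records$n_trials)) {
    abort("score_semantic: n_correct must lie in 0..n_trials")
  }
  tibble::tibble(participant_id = as.character(records$participant_id),
                 prop_correct = records$n_correct / records$n_trials)
}
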