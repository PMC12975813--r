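#' Read a boundary press log
#'
#' Reads a long-format CSV of button-press timestamps (one row per press,
#' columns `participant_id` and `time_s`) recorded while participants
#' segmented a continuous stimulus. Presses are sorted within participant and
#' presses falling outside `[0, duration_s]` are dropped with a warning.
#'
#' @param path Path to a CSV file with columns `participant_id`, `time_s`.
#' @param duration_s Stimulus duration in seconds (default 1320, i.e. the
#'   22-minute episode the default analysis assumes).
#' @return A tibble with columns `participant_id` (character) and `time_s`
#'   (double), sorted by participant and time, carrying `duration_s` and
#'   `n_dropped` attributes.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("participant_id,time_s", "p1,3.0", "p1,1.0"), f)
#' read_press_log(f, duration_s = 100)
#' @export
read_press_log <- function(path, duration_s = 1320) {
  stopifnot(is.numeric(duration_s), duration_s > 0)
  df <- read_validated_csv(path, c("participant_id", "time_s"))
  df$time_s <- parse_num(df$time_s, "time_s", path)
  df$participant_id <- as.character(df$participant_id)
  bad <- df$time_s < 0 | df$time_s > duration_s
  if (any(bad)) {
    warn(sprintf("read_press_log: dropped %d press(es) outside [0, %g] s in '%s'",
                 sum(bad), duration_s, path))
    df <- df[!bad, , drop = FALSE]
  }
  out <- dplyr::arrange(tibble::as_tibble(df), .data$participant_id, .data$time_s)
  attr(out, "duration_s") <- duration_s
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Read ASRS questionnaire responses
#'
#' Reads a wide CSV of 18-item Adult ADHD Self-Report Scale responses
#' (`participant_id`, `item_01` ... `item_18`, each item scored 0--4).
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per participant and the 18 item columns.
#' @export
read_asrs <- function(path) {
  cols <- c("participant_id", asrs_item_names())
  df <- read_validated_csv(path, cols)
  df$participant_id <- as.character(df$participant_id)
  for (nm in asrs_item_names()) {
    df[[nm]] <- parse_num(df[[nm]], nm, path)
    chk <- df[[nm]]
    if (any(chk %% 1 != 0 | chk < 0 | chk > 4)) {
      abort(sprintf("read_asrs: column '%s' in '%s' has values outside the 0..4 item scale (first bad row %d)",
                    nm, path, which(chk %% 1 != 0 | chk < 0 | chk > 4)[1]))
    }
  }
  tibble::as_tibble(df[, cols])
}

asrs_item_names <- function() sprintf("item_%02d", 1:18)

#' Score the 18-item ASRS
#'
#' Sums the 18 item scores (0--4 each, total 0--72) and flags likely ADHD
#' when the total exceeds 24 (strictly: a total of exactly 24 is not flagged).
#' No item is reverse-scored; the published v1.1 checklist is summed directly.
#'
#' @param x Either a numeric vector of exactly 18 item scores, or a data frame
#'   with columns `participant_id` and `item_01` ... `item_18`.
#' @param ... Unused.
#' @return A tibble with columns `participant_id`, `total`, `likely_adhd`
#'   (one row per participant).
#' @examples
#' score_asrs(rep(2, 18))
#' @export
score_asrs <- function(x, ...) UseMethod("score_asrs")

#' @rdname score_asrs
#' @param participant_id Identifier used for the single-record method.
#' @export
score_asrs.numeric <- function(x, participant_id = NA_character_, ...) {
  validate_asrs_items(x)
  total <- sum(x)
  tibble::tibble(participant_id = participant_id,
                 total = as.integer(total),
                 likely_adhd = total > 24L)
}

#' @rdname score_asrs
#' @export
score_asrs.data.frame <- function(x, ...) {
  items <- asrs_item_names()
  missing <- setdiff(c("participant_id", items), names(x))
  if (length(missing) > 0) {
    abort(paste0("score_asrs: missing columns: ", paste(missing, collapse = ", ")))
  }
  mat <- as.matrix(x[, items])
  apply(mat, 1, validate_asrs_items)
  tibble::tibble(participant_id = as.character(x$participant_id),
                 total = as.integer(rowSums(mat)),
                 likely_adhd = rowSums(mat) > 24)
}

validate_asrs_items <- function(items) {
  if (length(items) != 18) {
    abort(sprintf("ASRS requires exactly 18 items, got %d", length(items)))
  }
  if (any(!is.finite(items) | items %% 1 != 0 | items < 0 | items > 4)) {
    abort("ASRS item scores must be integers in 0..4")
  }
  invisible(items)
}

#' Read temporal-order memory trials
#'
#' Reads a CSV of two-alternative forced-choice temporal-order trials with
#' columns `participant_id`, `trial_id`, `condition` (`within`/`across`),
#' `earlier_side` (`left`/`right`), `response` (`left`/`right`) and `rt_s`.
#' Enum tokens are matched case-insensitively. A derived logical `correct`
#' column (`response == earlier_side`) is added.
#'
#' @param path Path to the CSV file.
#' @return A tibble of typed trials with a `correct` column.
#' @export
read_memory_trials <- function(path) {
  cols <- c("participant_id", "trial_id", "condition", "earlier_side",
            "response", "rt_s")
  df <- read_validated_csv(path, cols)
  df$participant_id <- as.character(df$participant_id)
  df$trial_id <- as.character(df$trial_id)
  df$condition <- parse_enum(df$condition, c("within", "across"), "condition", path)
  df$earlier_side <- parse_enum(df$earlier_side, c("left", "right"), "earlier_side", path)
  df$response <- parse_enum(df$response, c("left", "right"), "response", path)
  df$rt_s <- parse_num(df$rt_s, "rt_s", path)
  if (any(df$rt_s < 0)) {
    abort(sprintf("read_memory_trials: negative rt_s at row %d of '%s'",
                  which(df$rt_s < 0)[1], path))
  }
  out <- tibble::as_tibble(df[, cols])
  out$correct <- out$response == out$earlier_side
  out
}

#' Read semantic-quiz summaries
#'
#' Reads a CSV with columns `participant_id`, `n_correct` and `n_trials`
#' (three-option multiple choice items; 14 trials by default in the design).
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated records.
#' @export
read_semantic <- function(path) {
  df <- read_validated_csv(path, c("participant_id", "n_correct", "n_trials"))
  df$participant_id <- as.character(df$participant_id)
  df$n_correct <- parse_num(df$n_correct, "n_correct", path)
  df$n_trials <- parse_num(df$n_trials, "n_trials", path)
  bad <- df$n_correct < 0 | df$n_correct > df$n_trials | df$n_trials <= 0
  if (any(bad)) {
    abort(sprintf("read_semantic: invalid counts at row %d of '%s'", which(bad)[1], path))
  }
  tibble::as_tibble(df)
}

#' Read a prototypical boundary set
#'
#' Reads a CSV with columns `time_s` and `agreement` (the number of norming
#' participants contributing to each consensus boundary).
#'
#' @param path Path to the CSV file.
#' @return A tibble sorted by `time_s`.
#' @export
read_proto_boundaries <- function(path) {
  df <- read_validated_csv(path, c("time_s", "agreement"))
  df$time_s <- parse_num(df$time_s, "time_s", path)
  df$agreement <- parse_num(df$agreement, "agreement", path)
  dplyr::arrange(tibble::as_tibble(df), .data$time_s)
}

#' Write a per-participant metrics table
#'
#' Writes a flat CSV with a stable column order: `participant_id` first (when
#' present), then any of the documented metric columns in their canonical
#' order, then everything else in input order.
#'
#' @param path Output CSV path.
#' @param table A data frame of per-participant metrics.
#' @return The path, invisibly.
#' @export
write_metrics <- function(path, table) {
  canonical <- c("participant_id", "n_presses", "jaccard", "agreement",
                 "peak_latency_s", "acc_within", "acc_across", "diff",
                 "n_retained", "n_discarded", "prop_correct", "total",
                 "likely_adhd")
  first <- intersect(canonical, names(table))
  rest <- setdiff(names(table), first)
  readr::write_csv(table[, c(first, rest)], path, progress = FALSE)
  invisible(path)
}

# -- shared CSV plumbing ------------------------------------------------------

read_validated_csv <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("'%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  as.data.frame(df, stringsAsFactors = FALSE)
}

parse_num <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  if (any(is.na(out))) {
    abort(sprintf("non-numeric value '%s' in column '%s' at row %d of '%s'",
                  x[which(is.na(out))[1]], col, which(is.na(out))[1], path))
  }
  out
}

parse_enum <- function(x, levels, col, path) {
  lowered <- tolower(trimws(x))
  bad <- !lowered %in% levels
  if (any(bad)) {
    abort(sprintf("unknown %s token '%s' at row %d of '%s' (expected one of: %s)",
                  col, x[which(bad)[1]], which(bad)[1], path,
                  paste(levels, collapse = ", ")))
  }
  lowered
}
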