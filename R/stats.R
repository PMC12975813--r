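#' Cronbach's alpha
#'
#' Internal-consistency coefficient for a participants-by-items score matrix:
#' `alpha = k/(k-1) * (1 - sum(var_item) / var(total))` with sample variances
#' (n - 1 denominators).
#'
#' @param items A numeric matrix or data frame, one column per item.
#' @return Alpha as a single number; `NA` (with a warning) when the total
#'   score is constant across participants.
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 3, 2, 5, 4), c = c(2, 2, 4, 4, 5))
#' cronbach_alpha(m)
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (!is.numeric(m)) abort("cronbach_alpha: items must be numeric")
  k <- ncol(m)
  if (k < 2) abort("cronbach_alpha: at least 2 items required")
  if (nrow(m) < 3) abort("cronbach_alpha: at least 3 participants required")
  vt <- var(rowSums(m))
  if (vt == 0) {
    warn("cronbach_alpha: constant total score; alpha undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / vt)
}

# one-row StatResult tibble shared by all tests in the battery
stat_result <- function(test, estimate, statistic, df, p, effect_size = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, n = NA_integer_) {
  out <- tibble::tibble(test = test, estimate = estimate, statistic = statistic,
                        df = df, p = p, effect_size = effect_size,
                        ci_low = ci_low, ci_high = ci_high,
                        n = as.integer(n))
  class(out) <- c("stat_result", class(out))
  out
}

#' Pearson correlation test
#'
#' Two-tailed Pearson correlation with `t = r * sqrt((n - 2) / (1 - r^2))`,
#' `df = n - 2`, and a Fisher-z 95% confidence interval. Pairs with a missing
#' value in either series are removed pairwise before the test.
#'
#' @param x,y Equal-length numeric vectors.
#' @param test Label for the result row.
#' @return A one-row `stat_result` tibble (`estimate` is r); all-`NA`
#'   statistics (with a warning) when fewer than 3 complete pairs remain or
#'   either series is constant.
#' @export
pearson_test <- function(x, y, test = "pearson") {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0) {
    warn(sprintf("pearson_test [%s]: undefined (n = %d or constant input)", test, n))
    return(stat_result(test, NA_real_, NA_real_, NA_integer_, NA_real_, n = n))
  }
  ct <- cor.test(x, y, method = "pearson", conf.level = 0.95)
  ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA_real_, NA_real_)
  stat_result(test, unname(ct$estimate), unname(ct$statistic),
              unname(ct$parameter), ct$p.value,
              ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Paired-samples t test
#'
#' Two-tailed paired t test on complete pairs, with Cohen's d computed from
#' the standard deviation of the pair differences (`d = mean(d) / sd(d)`,
#' hence `d = t / sqrt(n)`), and the 95% CI of the mean difference.
#'
#' @param x,y Paired numeric vectors.
#' @param test Label for the result row.
#' @return A one-row `stat_result` tibble (`estimate` is the mean
#'   difference x - y).
#' @export
paired_t_test <- function(x, y, test = "paired_t") {
  ok <- !is.na(x) & !is.na(y)
  one_sample_t_test(x[ok] - y[ok], mu = 0, test = test)
}

#' One-sample t test
#'
#' Two-tailed one-sample t test against `mu`, with Cohen's d
#' (`(mean - mu) / sd`) and the 95% CI of the mean.
#'
#' @param x Numeric vector (`NA`s removed).
#' @param mu Null value (default 0).
#' @param test Label for the result row.
#' @return A one-row `stat_result` tibble (`estimate` is the sample mean).
#' @export
one_sample_t_test <- function(x, mu = 0, test = "one_sample_t") {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2 || sd(x) == 0) {
    warn(sprintf("t test [%s]: undefined (n = %d or zero variance)", test, n))
    return(stat_result(test, if (n > 0) mean(x) else NA_real_,
                       NA_real_, NA_integer_, NA_real_, n = n))
  }
  tt <- t.test(x, mu = mu, conf.level = 0.95)
  stat_result(test, unname(tt$estimate), unname(tt$statistic),
              unname(tt$parameter), tt$p.value,
              effect_size = (mean(x) - mu) / sd(x),
              ci_low = tt$conf.int[1], ci_high = tt$conf.int[2], n = n)
}

#' Run the full correlational battery
#'
#' Joins the per-participant tables on `participant_id` and computes every
#' test in the study's analysis: Cronbach's alpha over the 18 ASRS items;
#' Pearson correlations of the ASRS total with the segmentation metrics
#' (press count, Jaccard, agreement) and the memory scores (within, across,
#' their mean, within - across difference, semantic proportion); the 3 x 3
#' table of correlations between temporal-order accuracy (all/within/across)
#' and the segmentation metrics; the paired within-vs-across t test; and the
#' one-sample t test of peak latency against zero. Undefined values are
#' removed pairwise per test, so each row reports its own df.
#'
#' @param seg Per-participant segmentation metrics ([seg_metrics()]).
#' @param memory Per-participant memory scores ([score_memory()]).
#' @param semantic Per-participant semantic scores ([score_semantic()]).
#' @param asrs_items ASRS item responses ([read_asrs()] layout).
#' @param alpha_level Two-tailed significance threshold (default 0.05,
#'   uncorrected, fixed a priori).
#' @return An object of class `seg_battery`: a list with `results` (all
#'   StatResult rows), `table1` (the accuracy-by-segmentation correlation
#'   grid), `cronbach_alpha`, `data` (the joined table), `n`, and
#'   `alpha_level`. Supports [tidy()], [glance()], `print()` and
#'   [ggplot2::autoplot()].
#' @export
run_battery <- function(seg, memory, semantic, asrs_items, alpha_level = 0.05) {
  stopifnot(alpha_level > 0, alpha_level < 1)
  asrs <- score_asrs(asrs_items)
  joined <- dplyr::inner_join(seg, asrs, by = "participant_id")
  joined <- dplyr::inner_join(joined, memory, by = "participant_id")
  joined <- dplyr::inner_join(joined, score_semantic(semantic), by = "participant_id")
  n_tables <- c(nrow(seg), nrow(asrs), nrow(memory), nrow(semantic))
  if (nrow(joined) == 0) abort("run_battery: no participants shared across tables")
  if (any(n_tables != nrow(joined))) {
    warn(sprintf("run_battery: %d participant(s) dropped by the join (table sizes %s -> %d)",
                 max(n_tables) - nrow(joined),
                 paste(n_tables, collapse = "/"), nrow(joined)))
  }
  joined$acc_mean <- (joined$acc_within + joined$acc_across) / 2
  joined$acc_diff <- joined$diff

  asrs_targets <- c(n_presses = "n_presses", jaccard = "jaccard",
                    agreement = "agreement", acc_within = "acc_within",
                    acc_across = "acc_across", acc_mean = "acc_mean",
                    acc_diff = "acc_diff", semantic = "prop_correct")
  asrs_rows <- purrr::imap(asrs_targets, function(colnm, label) {
    pearson_test(joined$total, joined[[colnm]],
                 test = paste0("asrs_x_", label))
  })

  acc_rows <- c(all = "acc_mean", within = "acc_within", across = "acc_across")
  seg_cols <- c(n_presses = "n_presses", jaccard = "jaccard", agreement = "agreement")
  table1_rows <- purrr::imap(acc_rows, function(acc_col, acc_lab) {
    purrr::imap(seg_cols, function(seg_col, seg_lab) {
      res <- pearson_test(joined[[acc_col]], joined[[seg_col]],
                          test = paste0("acc_", acc_lab, "_x_", seg_lab))
      res
    })
  })
  table1 <- purrr::map_dfr(names(acc_rows), function(acc_lab) {
    row <- purrr::map_dbl(names(seg_cols), function(seg_lab) {
      table1_rows[[acc_lab]][[seg_lab]]$estimate
    })
    tibble::tibble(condition = acc_lab,
                   n_presses = row[1], jaccard = row[2], agreement = row[3])
  })

  extra <- list(
    paired_t_test(joined$acc_within, joined$acc_across,
                  test = "within_vs_across_paired_t"),
    one_sample_t_test(joined$peak_latency_s, mu = 0,
                      test = "peak_latency_vs_zero_t")
  )

  results <- dplyr::bind_rows(c(asrs_rows,
                                purrr::flatten(table1_rows),
                                extra))
  results$significant <- !is.na(results$p) & results$p < alpha_level

  alpha_val <- cronbach_alpha(asrs_items[, asrs_item_names()])

  structure(list(results = results, table1 = table1,
                 cronbach_alpha = alpha_val, data = joined,
                 n = nrow(joined), alpha_level = alpha_level),
            class = "seg_battery")
}

#' @export
print.seg_battery <- function(x, ...) {
  cat(sprintf("Segmentation/memory battery: n = %d, Cronbach's alpha = %.3f, alpha level = %g\n\n",
              x$n, x$cronbach_alpha, x$alpha_level))
  print(x$results, n = nrow(x$results))
  cat("\nTemporal-order accuracy x segmentation correlations:\n")
  print(x$table1)
  invisible(x)
}

#' Tidy the battery results
#'
#' @param x A `seg_battery` object.
#' @param ... Unused.
#' @return The StatResult rows as a tibble (one row per test).
#' @export
tidy.seg_battery <- function(x, ...) x$results

#' One-row battery summary
#'
#' @param x A `seg_battery` object.
#' @param ... Unused.
#' @return A one-row tibble: participants, Cronbach's alpha, number of tests
#'   and number significant at the battery's alpha level.
#' @export
glance.seg_battery <- function(x, ...) {
  tibble::tibble(n = x$n, cronbach_alpha = x$cronbach_alpha,
                 n_tests = nrow(x$results),
                 n_significant = sum(x$results$significant),
                 alpha_level = x$alpha_level)
}
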