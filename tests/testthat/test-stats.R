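test_that("cronbach alpha matches the hand-computed 5x3 value", {
  m <- cbind(a = c(1, 2, 3, 4, 5),
             b = c(2, 2, 3, 5, 4),
             c = c(1, 3, 3, 4, 5))
  # item variances 2.5, 1.7, 2.2; total variance 17.3;
  # alpha = 1.5 * (1 - 6.4 / 17.3)
  expect_equal(cronbach_alpha(m), 1.5 * (1 - 6.4 / 17.3), tolerance = 1e-12)
  expect_equal(cronbach_alpha(m), oracle_alpha(m), tolerance = 1e-12)
})

test_that("duplicated items give alpha 1 and independent items give about 0", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(cronbach_alpha(cbind(x, x)), 1, tolerance = 1e-12)
  set.seed(51)
  big <- cbind(rnorm(3000), rnorm(3000))
  expect_lt(abs(cronbach_alpha(big)), 0.12)
})

test_that("alpha degenerate inputs are rejected or marked undefined", {
  expect_error(cronbach_alpha(matrix(1, 5, 1)), "2 items")
  expect_error(cronbach_alpha(matrix(1, 2, 3)), "3 participants")
  const <- cbind(c(1, 2, 3, 4), c(4, 3, 2, 1))  # total constant at 5
  expect_warning(out <- cronbach_alpha(const), "constant")
  expect_true(is.na(out))
})

test_that("pearson_test matches the direct-formula oracle on 6 points", {
  x <- c(1.2, 2.8, 3.1, 4.5, 5.2, 6.9)
  y <- c(2.0, 2.5, 4.1, 3.9, 6.0, 6.2)
  res <- pearson_test(x, y)
  r_hand <- oracle_pearson_r(x, y)
  expect_equal(res$estimate, r_hand, tolerance = 1e-10)
  expect_equal(res$statistic, r_hand * sqrt(4 / (1 - r_hand^2)), tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p, oracle_pearson_p(r_hand, 6), tolerance = 1e-10)
  expect_equal(res$n, 6L)
})

test_that("perfect linear relations give r = +/- 1", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_test(x, x)$estimate, 1)
  expect_equal(pearson_test(x, -x)$estimate, -1)
  # r = sign(b) for any affine y = a + b x
  set.seed(52)
  for (i in 1:10) {
    a <- rnorm(1); b <- rnorm(1)
    if (abs(b) < 1e-6) next
    expect_equal(pearson_test(x, a + b * x)$estimate, sign(b), tolerance = 1e-10)
  }
})

test_that("pearson_test removes undefined pairs pairwise and guards tiny n", {
  x <- c(1, 2, NA, 4, 5, 6)
  y <- c(2, NA, 3, 5, 4, 7)
  res <- pearson_test(x, y)
  expect_equal(res$n, 4L)
  expect_equal(res$df, 2)
  expect_warning(out <- pearson_test(c(1, 2), c(3, 4)), "undefined")
  expect_true(is.na(out$p))
  expect_warning(out2 <- pearson_test(rep(1, 5), c(1, 2, 3, 4, 5)), "undefined")
  expect_true(is.na(out2$estimate))
})

test_that("paired t test matches the direct-formula oracle on 5 pairs", {
  x <- c(0.9, 0.8, 0.85, 0.95, 0.7)
  y <- c(0.7, 0.75, 0.6, 0.9, 0.65)
  d <- x - y
  res <- paired_t_test(x, y)
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$estimate, mean(d), tolerance = 1e-12)
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-10)
  expect_equal(res$effect_size, mean(d) / sd(d), tolerance = 1e-12)
  se <- sd(d) / sqrt(5)
  expect_equal(res$ci_low, mean(d) - qt(0.975, 4) * se, tolerance = 1e-10)
  expect_equal(res$ci_high, mean(d) + qt(0.975, 4) * se, tolerance = 1e-10)
})

test_that("paired t equals one-sample t on the differences, and d = t / sqrt(n)", {
  set.seed(53)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    x <- rnorm(n, 0.8, 0.1)
    y <- rnorm(n, 0.7, 0.1)
    p1 <- paired_t_test(x, y)
    p2 <- one_sample_t_test(x - y)
    expect_equal(p1$statistic, p2$statistic)
    expect_equal(p1$p, p2$p)
    expect_equal(p1$effect_size, p1$statistic / sqrt(n), tolerance = 1e-12)
  }
})

test_that("identical paired samples give t = 0, p = 1, d = 0 when noise is added", {
  x <- c(1, 2, 3, 4, 5)
  expect_warning(res0 <- paired_t_test(x, x), "zero variance")
  expect_equal(res0$estimate, 0)
  # symmetric differences: exact zero mean with nonzero variance
  y <- x + c(-0.1, 0.1, -0.1, 0.1, 0)
  res <- paired_t_test(x, y)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(res$effect_size, 0)
})

test_that("pearson_test holds its nominal 5% type-I rate at n = 71", {
  set.seed(54)
  n_sim <- 2000
  rejections <- vapply(seq_len(n_sim), function(i) {
    x <- rnorm(71)
    y <- rnorm(71)
    pearson_test(x, y)$p < 0.05
  }, logical(1))
  expect_equal(mean(rejections), 0.05, tolerance = 0.3)  # 5% +/- 1.5 points
  expect_gte(mean(rejections), 0.035)
  expect_lte(mean(rejections), 0.065)
})

test_that("the battery reports every planned test with pairwise df", {
  set.seed(55)
  st <- simulate_study(sim_params(n_participants = 16, duration_s = 400,
                                  n_true_boundaries = 10, seed = 55))
  m <- seg_metrics(st$presses, st$proto, duration_s = 400)
  scores <- score_memory(suppressMessages(filter_rt(st$memory_trials)))
  b <- run_battery(m, scores, st$semantic, st$asrs)

  expect_s3_class(b, "seg_battery")
  res <- tidy(b)
  asrs_tests <- paste0("asrs_x_", c("n_presses", "jaccard", "agreement",
                                    "acc_within", "acc_across", "acc_mean",
                                    "acc_diff", "semantic"))
  expect_true(all(asrs_tests %in% res$test))
  # Table-1 layout: 3 accuracy rows x 3 segmentation predictors
  expect_equal(dim(b$table1), c(3, 4))
  expect_equal(b$table1$condition, c("all", "within", "across"))
  expect_setequal(setdiff(names(b$table1), "condition"),
                  c("n_presses", "jaccard", "agreement"))
  t1_tests <- as.vector(outer(c("all", "within", "across"),
                              c("n_presses", "jaccard", "agreement"),
                              function(a, s) paste0("acc_", a, "_x_", s)))
  expect_true(all(t1_tests %in% res$test))
  expect_true(all(c("within_vs_across_paired_t", "peak_latency_vs_zero_t")
                  %in% res$test))
  expect_equal(nrow(res), 19)

  g <- glance(b)
  expect_equal(g$n, 16L)
  expect_true(g$cronbach_alpha > 0 && g$cronbach_alpha <= 1)
})

test_that("battery correlations agree with directly recomputed values", {
  set.seed(56)
  st <- simulate_study(sim_params(n_participants = 14, duration_s = 400,
                                  n_true_boundaries = 10, seed = 56))
  m <- seg_metrics(st$presses, st$proto, duration_s = 400)
  scores <- score_memory(suppressMessages(filter_rt(st$memory_trials)))
  b <- run_battery(m, scores, st$semantic, st$asrs)

  joined <- b$data
  r_ref <- oracle_pearson_r(joined$total, joined$n_presses)
  got <- tidy(b)
  expect_equal(got$estimate[got$test == "asrs_x_n_presses"], r_ref,
               tolerance = 1e-10)
  expect_equal(b$cronbach_alpha,
               oracle_alpha(as.matrix(st$asrs[, -1])), tolerance = 1e-12)
})

test_that("a permuted ASRS column kills the ASRS correlations", {
  set.seed(57)
  hits <- vapply(1:20, function(i) {
    st <- simulate_study(sim_params(n_participants = 40, duration_s = 400,
                                    n_true_boundaries = 10, seed = 5600 + i))
    asrs <- st$asrs
    perm <- sample(nrow(asrs))
    asrs[, -1] <- asrs[perm, -1]
    m <- seg_metrics(st$presses, st$proto, duration_s = 400)
    scores <- score_memory(suppressMessages(filter_rt(st$memory_trials)))
    b <- suppressWarnings(run_battery(m, scores, st$semantic, asrs))
    res <- tidy(b)
    res$significant[res$test == "asrs_x_n_presses"]
  }, logical(1))
  # under the permutation null, significance is rare
  expect_lte(mean(hits), 0.10 + 0.15)
})
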