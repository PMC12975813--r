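test_that("identical press trains give perfect leave-one-out agreement", {
  times <- c(10, 30, 55, 80)
  presses <- tibble::tibble(
    participant_id = rep(c("a", "b", "c", "d"), each = length(times)),
    time_s = rep(times, 4))
  out <- loo_agreement(presses, duration_s = 100)
  expect_equal(out$agreement, rep(1, 4), tolerance = 1e-12)
})

test_that("a zero-press participant gets an undefined agreement", {
  mat <- rbind(a = c(rep(0, 10), 1, rep(0, 9)),
               b = c(rep(0, 10), 1, rep(0, 9)),
               c = numeric(20))
  expect_warning(out <- loo_agreement(mat, resolution_s = 0.1, sigma_s = 0.2),
                 "constant")
  expect_true(is.na(out$agreement[3]))
  expect_false(anyNA(out$agreement[1:2]))
})

test_that("agreement needs at least three participants", {
  mat <- rbind(a = c(1, 0, 1, 0), b = c(0, 1, 0, 1))
  expect_error(loo_agreement(mat), "3 participants")
})

test_that("agreement matches the brute-force oracle on 20-bin vectors", {
  set.seed(31)
  mat <- matrix(as.numeric(runif(4 * 20) < 0.3), 4, 20)
  mat[1, 3] <- 1  # ensure no all-zero rows
  mat[2, 7] <- 1
  out <- loo_agreement(mat, sigma_s = 0.3, resolution_s = 0.1)
  expect_equal(out$agreement, oracle_loo(mat, 0.3, 0.1), tolerance = 1e-12)
})

test_that("lag curve of a vector with itself peaks at zero", {
  set.seed(32)
  v <- vectorize(sort(runif(10, 5, 95)), 100, 0.1)
  lc <- lag_curve(v, v, max_lag_s = 10)
  expect_s3_class(lc, "eventseg_lag_curve")
  expect_equal(peak_latency(lc), 0)
  # symmetric ascending lag grid with 0.1-s steps
  expect_equal(lc$lag_s, seq(-10, 10, by = 0.1))
})

test_that("an injected 1.2-s delay is recovered to within one bin", {
  set.seed(33)
  proto_times <- c(15, 42, 61, 88, 110)
  v_proto <- vectorize(proto_times, 130, 0.1)
  v_ind <- vectorize(proto_times + 1.2, 130, 0.1)
  lc <- lag_curve(v_ind, v_proto, max_lag_s = 10)
  expect_equal(peak_latency(lc), 1.2, tolerance = 0.1)
  # reversing the arguments negates the latency
  lc_rev <- lag_curve(v_proto, v_ind, max_lag_s = 10)
  expect_equal(peak_latency(lc_rev), -peak_latency(lc), tolerance = 1e-12)
})

test_that("lag correlations match the naive overlap-only Pearson oracle", {
  set.seed(34)
  v1 <- vectorize(sort(runif(6, 0, 20)), 20, 0.1)
  v2 <- vectorize(sort(runif(6, 0, 20)), 20, 0.1)
  lc <- lag_curve(v1, v2, max_lag_s = 3, sigma_s = 0.5)
  s_proto <- oracle_smooth(v2, 0.5, 0.1)
  s_ind <- oracle_smooth(v1, 0.5, 0.1)
  ref <- vapply(-30:30, function(k) oracle_lag_r(s_proto, s_ind, k), numeric(1))
  expect_equal(lc$r, ref, tolerance = 1e-10)
})

test_that("raw (unconvolved) lag mode is available and matches the oracle", {
  v1 <- c(0, 1, 0, 0, 1, 0, 1, 0, 0, 0)
  v2 <- c(0, 0, 1, 0, 0, 1, 0, 1, 0, 0)
  lc <- lag_curve(v1, v2, max_lag_s = 0.3, resolution_s = 0.1, convolve = FALSE)
  ref <- vapply(-3:3, function(k) oracle_lag_r(v2, v1, k), numeric(1))
  expect_equal(lc$r, ref, tolerance = 1e-12)
  # v1 is v2 shifted one bin earlier, so the individual leads: peak at -0.1
  expect_equal(peak_latency(lc), -0.1)
})

test_that("peak ties break toward the smallest absolute lag, then negative", {
  curve <- tibble::tibble(lag_s = c(-0.3, -0.2, 0.2, 0.4),
                          r = c(0.9, 0.5, 0.9, 0.3))
  expect_equal(peak_latency(curve), 0.2)  # |0.2| < |-0.3|
  curve2 <- tibble::tibble(lag_s = c(-0.2, 0.2), r = c(0.9, 0.9))
  expect_equal(peak_latency(curve2), -0.2)  # equal magnitude -> negative
  # NA lags are skipped; all-NA gives NA
  curve3 <- tibble::tibble(lag_s = c(-0.1, 0, 0.1), r = c(NA, NA, 0.4))
  expect_equal(peak_latency(curve3), 0.1)
  expect_true(is.na(peak_latency(tibble::tibble(lag_s = 0, r = NA_real_))))
})

test_that("peak latency recovers any injected shift up to the lag range", {
  set.seed(35)
  for (shift in c(-5, -2.1, 0.7, 3.3, 8)) {
    # >= 3 boundaries separated by more than twice the 5-s window
    base <- cumsum(c(20, runif(4, 12, 25)))
    v_proto <- vectorize(base, 150, 0.1)
    v_ind <- vectorize(base + shift, 150, 0.1)
    lc <- lag_curve(v_ind, v_proto, max_lag_s = 10)
    expect_lt(abs(peak_latency(lc) - shift), 0.11)  # within one 0.1-s bin
  }
})

test_that("unanimous norming presses produce a single exact boundary", {
  presses <- tibble::tibble(participant_id = sprintf("n%02d", 1:10),
                            time_s = rep(100.0, 10))
  proto <- derive_prototypical(presses)
  expect_equal(proto$time_s, 100.0)
  expect_equal(proto$agreement, 10L)
})

test_that("clusters below the 6-of-10 threshold are not emitted", {
  presses <- tibble::tibble(
    participant_id = c(sprintf("n%02d", 1:5), sprintf("n%02d", 1:10)),
    time_s = c(50 + 0.3 * (0:4), rep(200, 10)))
  proto <- derive_prototypical(presses, window_s = 10, min_agree = 6)
  expect_equal(nrow(proto), 1)
  expect_equal(proto$time_s, 200)
})

test_that("greedy clustering matches a hand enumeration on a 20-press fixture", {
  # 10 participants press in 100.0..100.9 (one cluster, mean 100.45 -> grid
  # 100.4 under round-half-to-even), 5 participants add stragglers at 140 s,
  # and participant n01 double-presses inside the first window (second press
  # consumed, not counted)
  presses <- tibble::tibble(
    participant_id = c(sprintf("n%02d", 1:10), "n01", sprintf("n%02d", 1:5)),
    time_s = c(100 + 0.1 * (0:9), 103.0, rep(140, 5)))
  proto <- derive_prototypical(presses, window_s = 10, min_agree = 6)
  expect_equal(nrow(proto), 1)
  expect_equal(proto$agreement, 10L)
  expect_equal(proto$time_s, round(mean(100 + 0.1 * (0:9)) * 10) / 10)
})

test_that("norming recovery is exact when all presses are near true boundaries", {
  set.seed(36)
  true_b <- c(30, 80, 150, 260, 400)
  for (rep in 1:5) {
    presses <- purrr::map_dfr(sprintf("n%02d", 1:10), function(id) {
      tibble::tibble(participant_id = id,
                     time_s = true_b + runif(length(true_b), 0, 4))
    })
    proto <- derive_prototypical(presses, window_s = 10, min_agree = 6)
    expect_equal(nrow(proto), length(true_b))
    expect_equal(proto$agreement, rep(10L, length(true_b)))
  }
})

test_that("derive_prototypical validates its inputs", {
  expect_error(derive_prototypical(tibble::tibble(participant_id = character(0),
                                                  time_s = numeric(0))),
               "empty")
  small <- tibble::tibble(participant_id = c("a", "b"), time_s = c(1, 2))
  expect_error(derive_prototypical(small), "min_agree")
})

test_that("seg_metrics composes its components faithfully", {
  set.seed(37)
  proto_times <- c(20, 60, 95, 130)
  ids <- c("p1", "p2", "p3", "p4")
  press_list <- list(
    p1 = proto_times,                       # identical to the prototype
    p2 = proto_times + 1.0,
    p3 = sort(runif(6, 0, 150)),
    p4 = c(proto_times[1:3] + 0.5, 110))
  presses <- purrr::imap_dfr(press_list, function(t, id) {
    tibble::tibble(participant_id = id, time_s = t)
  })
  m <- seg_metrics(presses, proto_times, duration_s = 150)

  expect_equal(m$participant_id, ids)
  expect_equal(m$n_presses, vapply(press_list, length, integer(1)),
               ignore_attr = TRUE)
  expect_equal(m$jaccard[1], 1)
  expect_equal(m$peak_latency_s[1], 0)
  expect_equal(m$peak_latency_s[2], 1.0, tolerance = 0.1)

  # component-wise oracle recomputation, participant by participant
  proto_v <- vectorize(proto_times, 150, 0.1)
  proto_d <- dilate(proto_v, 5)
  mat <- do.call(rbind, lapply(press_list, vectorize, duration_s = 150,
                               resolution_s = 0.1))
  for (i in seq_along(ids)) {
    expect_equal(m$jaccard[i],
                 oracle_jaccard(dilate(mat[i, ], 5, 0.1), proto_d))
  }
  expect_equal(m$agreement, oracle_loo(mat, 2, 0.1), tolerance = 1e-10)
  lag_curves <- attr(m, "lag_curves")
  expect_equal(sort(unique(lag_curves$participant_id)), ids)
})

test_that("a zero-press participant is scored with empty metrics", {
  presses <- tibble::tibble(
    participant_id = rep(c("p1", "p2", "p3"), each = 3),
    time_s = rep(c(20, 60, 95), 3))
  expect_warning(
    m <- seg_metrics(presses, c(20, 60, 95), duration_s = 120,
                     participants = c("p1", "p2", "p3", "p4")),
    "constant")
  row <- m[m$participant_id == "p4", ]
  expect_equal(row$n_presses, 0L)
  expect_equal(row$jaccard, 0)
  expect_true(is.na(row$agreement))
})
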