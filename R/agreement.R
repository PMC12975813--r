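#' Leave-one-out inter-subject agreement
#'
#' Each participant's binary press vector is Gaussian-convolved and Pearson-
#' correlated with the unweighted mean of all other participants' convolved
#' vectors. The score captures how well an individual's boundary timing
#' aligns with the rest of the cohort. A participant whose convolved vector
#' is constant (e.g. zero presses) gets `NA` with a warning.
#'
#' @param x Either a tibble of presses (`participant_id`, `time_s`) or a
#'   numeric matrix with one binary press vector per row (rownames used as
#'   ids when present).
#' @param duration_s Stimulus duration in seconds (tibble input; defaults to
#'   the tibble's `duration_s` attribute).
#' @param sigma_s Gaussian kernel standard deviation in seconds (default 2).
#' @param resolution_s Bin width in seconds (default 0.1).
#' @return A tibble with columns `participant_id` and `agreement`.
#' @export
loo_agreement <- function(x, duration_s = NULL, sigma_s = 2, resolution_s = 0.1) {
  if (is.matrix(x)) {
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
    smat <- t(apply(x, 1, convolve_gaussian, sigma_s = sigma_s,
                    resolution_s = resolution_s))
  } else {
    duration_s <- duration_s %||% attr(x, "duration_s") %||%
      abort("loo_agreement: duration_s is required for tibble input")
    mat <- press_matrix(x, duration_s, resolution_s)
    ids <- rownames(mat)
    smat <- t(apply(mat, 1, convolve_gaussian, sigma_s = sigma_s,
                    resolution_s = resolution_s))
  }
  tibble::tibble(participant_id = ids, agreement = loo_from_smoothed(smat))
}

# rows = participants (already convolved); leave-one-out mean via column sums
loo_from_smoothed <- function(smat) {
  n <- nrow(smat)
  if (n < 3) abort("leave-one-out agreement requires at least 3 participants")
  tot <- colSums(smat)
  out <- vapply(seq_len(n), function(i) {
    self <- smat[i, ]
    others <- (tot - self) / (n - 1)
    if (sd(self) == 0 || sd(others) == 0) NA_real_ else cor(self, others)
  }, numeric(1))
  if (anyNA(out)) {
    warn(sprintf("agreement undefined (constant series) for %d participant(s)",
                 sum(is.na(out))))
  }
  out
}

# binary press matrix (participants x bins) from a long press tibble
press_matrix <- function(presses, duration_s, resolution_s = 0.1,
                         participants = NULL) {
  ids <- participants %||% sort(unique(presses$participant_id))
  by_id <- split(presses$time_s, factor(presses$participant_id, levels = ids))
  n_bins <- round(duration_s / resolution_s)
  mat <- matrix(0, nrow = length(ids), ncol = n_bins, dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    mat[i, ] <- vectorize(by_id[[i]], duration_s, resolution_s)
  }
  mat
}

#' Lagged cross-correlation between an individual and the prototypical vector
#'
#' Computes the Pearson correlation between the individual's and the
#' prototypical press vectors at every integer-bin lag within
#' `[-max_lag_s, +max_lag_s]`. Positive lag means the individual's responses
#' follow the prototypical boundaries. Both vectors are Gaussian-convolved
#' first by default (binary vectors at 100 ms are too sparse for meaningful
#' lagged Pearson correlations); raw mode is available. Only the overlapping
#' region of the two shifted vectors enters each correlation; a lag whose
#' overlap is constant gets `NA`.
#'
#' @param individual Binary press vector of one participant.
#' @param proto Binary vector of the prototypical boundaries (same length
#'   and resolution).
#' @param max_lag_s Maximum absolute lag in seconds (default 10).
#' @param sigma_s Kernel standard deviation in seconds (default 2); ignored
#'   when `convolve = FALSE`.
#' @param resolution_s Bin width in seconds (default taken from `individual`,
#'   else 0.1).
#' @param convolve Convolve both vectors before correlating (default TRUE).
#' @return A tibble of class `eventseg_lag_curve` with columns `lag_s`, `r`.
#' @export
lag_curve <- function(individual, proto, max_lag_s = 10, sigma_s = 2,
                      resolution_s = NULL, convolve = TRUE) {
  resolution_s <- resolution_s %||% attr(individual, "resolution_s") %||% 0.1
  if (length(individual) != length(proto)) {
    abort("lag_curve: vectors must have equal length")
  }
  if (max_lag_s < resolution_s) {
    abort("lag_curve: max_lag_s must be at least one bin")
  }
  x <- as.numeric(proto)
  y <- as.numeric(individual)
  if (convolve) {
    x <- convolve_centered(x, gaussian_kernel(sigma_s, resolution_s))
    y <- convolve_centered(y, gaussian_kernel(sigma_s, resolution_s))
  }
  K <- round(max_lag_s / resolution_s)
  lags <- (-K):K
  out <- tibble::tibble(lag_s = lags * resolution_s, r = lag_r_all(x, y, K))
  class(out) <- c("eventseg_lag_curve", class(out))
  out
}

# Pearson r at every integer-bin lag in -K..K, overlap-only region.
# Cross products for all lags come from one FFT cross-correlation
# (convolve(x, y, "open")[n - k] = sum x[i] y[i + k]); overlap means and
# variances come from cumulative sums. Lags whose overlap is (numerically)
# constant in either series give NA.
lag_r_all <- function(x, y, K) {
  n <- length(x)
  K <- min(K, n - 1L)
  cc_pos <- cross_products(x, y)  # cc_pos[[1]][k+1] = sum x[i] y[i+k]
  cpx <- c(0, cumsum(x)); cpx2 <- c(0, cumsum(x^2))
  cpy <- c(0, cumsum(y)); cpy2 <- c(0, cumsum(y^2))
  ks <- (-K):K
  m <- n - abs(ks)
  i0 <- pmax(-ks, 0L)  # x window is [i0 + 1, i0 + m]
  j0 <- pmax(ks, 0L)   # y window is [j0 + 1, j0 + m]
  sx <- cpx[i0 + m + 1L] - cpx[i0 + 1L]
  sxx <- cpx2[i0 + m + 1L] - cpx2[i0 + 1L]
  sy <- cpy[j0 + m + 1L] - cpy[j0 + 1L]
  syy <- cpy2[j0 + m + 1L] - cpy2[j0 + 1L]
  sxy <- ifelse(ks >= 0, cc_pos$pos[abs(ks) + 1L], cc_pos$neg[abs(ks) + 1L])
  vx <- m * sxx - sx^2
  vy <- m * syy - sy^2
  eps <- 1e-12 * m * max(c(abs(x), abs(y), 1))^2
  r <- (m * sxy - sx * sy) / sqrt(pmax(vx, 0) * pmax(vy, 0))
  r[vx <= eps | vy <= eps] <- NA_real_
  pmin(1, pmax(-1, r))
}

# All-lag cross products sum x[i] y[i+k] via one power-of-two padded FFT
# (stats::convolve would use an unpadded, possibly prime-length DFT).
cross_products <- function(x, y) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  fx <- stats::fft(c(x, numeric(nfft - n)))
  fy <- stats::fft(c(y, numeric(nfft - n)))
  cc <- Re(stats::fft(Conj(fx) * fy, inverse = TRUE)) / nfft
  list(pos = cc[1:n],                     # lags 0 .. n-1
       neg = c(cc[1], cc[nfft:(nfft - n + 2)]))  # lags 0, -1 .. -(n-1)
}

# r between x (reference) and y shifted so that positive k means y follows x
shifted_cor <- function(x, y, k) {
  n <- length(x)
  if (abs(k) >= n) return(NA_real_)
  if (k >= 0) {
    xs <- x[seq_len(n - k)]
    ys <- y[(k + 1):n]
  } else {
    xs <- x[(-k + 1):n]
    ys <- y[seq_len(n + k)]
  }
  if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
  cor(xs, ys)
}

#' Peak latency of a lag curve
#'
#' The lag (in seconds) at which the lagged correlation is maximal. Ties are
#' broken toward the smallest absolute lag, then toward the negative lag.
#' Undefined lags (`NA` correlations) are skipped; all-`NA` curves give `NA`.
#'
#' @param curve A lag curve as returned by [lag_curve()] (columns `lag_s`, `r`).
#' @return Peak lag in seconds.
#' @export
peak_latency <- function(curve) {
  ok <- !is.na(curve$r)
  if (!any(ok)) return(NA_real_)
  r <- curve$r[ok]
  lag <- curve$lag_s[ok]
  best <- which(r == max(r))
  if (length(best) > 1) {
    best <- best[order(abs(lag[best]), lag[best])]
  }
  lag[best[1]]
}

#' Derive prototypical boundaries from a norming sample
#'
#' Greedy consensus clustering of a norming sample's presses: all presses are
#' pooled and sorted; starting from the earliest unassigned press, a cluster
#' consumes every press within `window_s` (default 10 s) of its earliest
#' press, keeping at most one press per participant (the earliest). Clusters
#' reaching `min_agree` distinct participants (default 6, out of the
#' canonical 10 norming viewers) yield a reliable boundary at the mean of the
#' kept timestamps, rounded to the vector grid.
#'
#' @param presses Tibble of norming presses (`participant_id`, `time_s`).
#' @param window_s Clustering window in seconds (default 10).
#' @param min_agree Minimum distinct participants per reliable boundary
#'   (default 6).
#' @param resolution_s Grid to which boundary means are rounded (default 0.1).
#' @return A tibble with columns `time_s`, `agreement`, sorted by time,
#'   carrying `norming_n` and `duration_s` attributes.
#' @export
derive_prototypical <- function(presses, window_s = 10, min_agree = 6,
                                resolution_s = 0.1) {
  if (nrow(presses) == 0) abort("derive_prototypical: empty norming sample")
  n_norm <- length(unique(presses$participant_id))
  if (n_norm < min_agree) {
    abort(sprintf("derive_prototypical: %d norming participants < min_agree = %d",
                  n_norm, min_agree))
  }
  ord <- order(presses$time_s)
  times <- presses$time_s[ord]
  ids <- presses$participant_id[ord]
  n <- length(times)
  assigned <- logical(n)
  out_t <- numeric(0)
  out_a <- integer(0)
  i <- 1L
  while (i <= n) {
    if (assigned[i]) { i <- i + 1L; next }
    in_win <- which(!assigned & times >= times[i] & times <= times[i] + window_s)
    keep <- in_win[!duplicated(ids[in_win])]  # sorted, so first = earliest
    if (length(keep) >= min_agree) {
      out_t <- c(out_t, round(mean(times[keep]) / resolution_s) * resolution_s)
      out_a <- c(out_a, length(keep))
    }
    assigned[in_win] <- TRUE
    i <- i + 1L
  }
  ord2 <- order(out_t)
  out <- tibble::tibble(time_s = out_t[ord2], agreement = out_a[ord2])
  attr(out, "norming_n") <- n_norm
  attr(out, "duration_s") <- attr(presses, "duration_s")
  out
}

#' Per-participant segmentation metrics
#'
#' Composes the segmentation measures for a cohort against a prototypical
#' boundary set: press count, windowed Jaccard overlap (both vectors dilated
#' by default), leave-one-out convolved agreement, and lagged-correlation
#' peak latency.
#'
#' @param presses Tibble of cohort presses (`participant_id`, `time_s`).
#' @param proto Prototypical boundary set: a tibble with `time_s` or a
#'   numeric vector of boundary times.
#' @param duration_s Stimulus duration in seconds (defaults to the presses
#'   tibble's attribute).
#' @param participants Optional character vector of ids to score (defaults to
#'   ids present in `presses`); ids without presses get zero-press metrics.
#' @param resolution_s Bin width in seconds (default 0.1).
#' @param window_s Dilation window for the Jaccard computation (default 5).
#' @param sigma_s Gaussian kernel SD for agreement and lag curves (default 2).
#' @param max_lag_s Maximum lag for peak-latency estimation (default 10).
#' @param dilate_both Dilate both the idiosyncratic and the prototypical
#'   vector before the Jaccard overlap (default TRUE); when FALSE only the
#'   idiosyncratic vector is dilated.
#' @return A tibble of class `seg_metrics` with columns `participant_id`,
#'   `n_presses`, `jaccard`, `agreement`, `peak_latency_s`; the per-
#'   participant lag curves are attached as the `lag_curves` attribute
#'   (columns `participant_id`, `lag_s`, `r`).
#' @export
seg_metrics <- function(presses, proto, duration_s = NULL, participants = NULL,
                        resolution_s = 0.1, window_s = 5, sigma_s = 2,
                        max_lag_s = 10, dilate_both = TRUE) {
  duration_s <- duration_s %||% attr(presses, "duration_s") %||%
    abort("seg_metrics: duration_s is required")
  proto_times <- if (is.data.frame(proto)) proto$time_s else as.numeric(proto)
  mat <- press_matrix(presses, duration_s, resolution_s, participants)
  ids <- rownames(mat)
  n_presses <- as.integer(table(factor(presses$participant_id, levels = ids)))

  proto_v <- vectorize(proto_times, duration_s, resolution_s)
  proto_ref <- if (dilate_both) dilate(proto_v, window_s, resolution_s) else proto_v
  k <- gaussian_kernel(sigma_s, resolution_s)
  proto_sm <- convolve_centered(proto_v, k)

  smat <- t(apply(mat, 1, function(row) convolve_centered(row, k)))
  agreement <- loo_from_smoothed(smat)
  K <- round(max_lag_s / resolution_s)
  lags <- ((-K):K) * resolution_s

  jac <- numeric(length(ids))
  peak <- numeric(length(ids))
  curves <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    jac[i] <- jaccard(dilate(mat[i, ], window_s, resolution_s), proto_ref)
    r <- lag_r_all(proto_sm, smat[i, ], K)
    curves[[i]] <- tibble::tibble(participant_id = ids[i], lag_s = lags, r = r)
    peak[i] <- peak_latency(tibble::tibble(lag_s = lags, r = r))
  }

  out <- tibble::tibble(participant_id = ids, n_presses = n_presses,
                        jaccard = jac, agreement = agreement,
                        peak_latency_s = peak)
  attr(out, "lag_curves") <- dplyr::bind_rows(curves)
  class(out) <- c("seg_metrics", class(out))
  out
}
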