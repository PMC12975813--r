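# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition (naive loops, direct formulas)
# rather than calling the package's computational paths.

# truncated (+/- 4 sigma), area-normalized Gaussian smoothing by direct loop
oracle_smooth <- function(v, sigma_s, resolution_s) {
  h <- ceiling(4 * sigma_s / resolution_s)
  k <- dnorm(seq(-h, h) * resolution_s, sd = sigma_s)
  k <- k / sum(k)
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq(-h, h)) {
      src <- i + j
      if (src >= 1 && src <= n) acc <- acc + v[src] * k[j + h + 1]
    }
    out[i] <- acc
  }
  out
}

# Pearson r from raw sums (no stats::cor)
oracle_pearson_r <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  if (den == 0) return(NA_real_)
  num / den
}

# two-tailed p for a Pearson r at n points, via the t transform
oracle_pearson_p <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

# per-lag Pearson on the overlap region, naive subsetting
oracle_lag_r <- function(x, y, k) {
  n <- length(x)
  if (k >= 0) {
    xs <- x[seq_len(n - k)]; ys <- y[(k + 1):n]
  } else {
    xs <- x[(-k + 1):n]; ys <- y[seq_len(n + k)]
  }
  if (length(unique(xs)) == 1 || length(unique(ys)) == 1) return(NA_real_)
  oracle_pearson_r(xs, ys)
}

# leave-one-out agreement by definition: smooth every vector, average the
# others elementwise, correlate
oracle_loo <- function(mat, sigma_s, resolution_s) {
  smat <- t(apply(mat, 1, oracle_smooth, sigma_s = sigma_s,
                  resolution_s = resolution_s))
  vapply(seq_len(nrow(smat)), function(i) {
    others <- colMeans(smat[-i, , drop = FALSE])
    if (length(unique(smat[i, ])) == 1 || length(unique(others)) == 1) {
      NA_real_
    } else {
      oracle_pearson_r(smat[i, ], others)
    }
  }, numeric(1))
}

# Jaccard by explicit set enumeration over bin indices
oracle_jaccard <- function(a, b) {
  A <- which(a > 0); B <- which(b > 0)
  u <- union(A, B)
  if (length(u) == 0) return(0)
  length(intersect(A, B)) / length(u)
}

# Cronbach's alpha from the definitional variance ratio, scalar loops
oracle_alpha <- function(m) {
  k <- ncol(m)
  item_vars <- vapply(seq_len(k), function(j) {
    x <- m[, j]; sum((x - mean(x))^2) / (length(x) - 1)
  }, numeric(1))
  tot <- rowSums(m)
  vt <- sum((tot - mean(tot))^2) / (length(tot) - 1)
  k / (k - 1) * (1 - sum(item_vars) / vt)
}

# small cohort press fixture used by several io/pipeline tests
write_press_fixture <- function(path, n = 71, duration_s = 100, seed = 7) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(2:6, 1)
    data.frame(participant_id = sprintf("p%02d", i),
               time_s = round(sort(runif(k, 0, duration_s)), 2))
  }))
  write.csv(rows, path, row.names = FALSE)
  rows
}
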