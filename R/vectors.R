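#' Convert press times to a binary temporal vector
#'
#' Bins press timestamps into a 0/1 vector at a fixed temporal resolution
#' (100 ms by default). Bins are half-open `[k*res, (k+1)*res)`, 0-based, so
#' bin index is `floor(time / res)`; a press at exactly `duration_s` lands in
#' the final bin. Multiple presses within one bin set that bin once, so
#' `sum(v) <= length(times)`. A 1320-s stimulus at 0.1 s yields 13,200 bins.
#'
#' @param times Numeric vector of press times in seconds, all within
#'   `[0, duration_s]`.
#' @param duration_s Stimulus duration in seconds.
#' @param resolution_s Bin width in seconds (default 0.1).
#' @return A numeric 0/1 vector of length `round(duration_s / resolution_s)`
#'   with `resolution_s` and `duration_s` attributes.
#' @examples
#' v <- vectorize(c(5.00, 5.04), duration_s = 10)
#' sum(v)  # one bin set
#' @export
vectorize <- function(times, duration_s = 1320, resolution_s = 0.1) {
  if (!is.numeric(resolution_s) || resolution_s <= 0) {
    abort("vectorize: resolution_s must be a positive number")
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("vectorize: duration_s must be a positive number")
  }
  if (length(times) > 0 && (any(times < 0) || any(times > duration_s))) {
    abort("vectorize: press times must lie within [0, duration_s]")
  }
  n <- round(duration_s / resolution_s)
  v <- numeric(n)
  if (length(times) > 0) {
    # small guard so times on the bin grid are not pushed one bin early by
    # floating-point division (e.g. 5.0 / 0.1 = 49.999...)
    idx <- pmin(floor(times / resolution_s + 1e-9), n - 1) + 1
    v[unique(idx)] <- 1
  }
  attr(v, "resolution_s") <- resolution_s
  attr(v, "duration_s") <- duration_s
  v
}

#' Dilate a binary vector with a centered window
#'
#' Expands each set bin into a centered run of 1s spanning `window_s`
#' (default 5 s, i.e. 0.38% of a 22-minute episode): `round(window_s /
#' (2 * resolution_s))` bins on each side plus the centre, clipped at the
#' vector edges. The output is the union over all presses, so the input's set
#' bins are always contained in the output's.
#'
#' @param v Binary temporal vector (as produced by [vectorize()]).
#' @param window_s Full window width in seconds (default 5).
#' @param resolution_s Bin width in seconds; defaults to the vector's
#'   attribute, else 0.1.
#' @return A binary vector of the same length, attributes preserved.
#' @export
dilate <- function(v, window_s = 5, resolution_s = NULL) {
  resolution_s <- resolution_s %||% attr(v, "resolution_s") %||% 0.1
  if (window_s < resolution_s) {
    abort("dilate: window_s must be at least one bin (>= resolution_s)")
  }
  n <- length(v)
  idx <- which(v > 0)
  out <- numeric(n)
  if (length(idx) > 0) {
    h <- round(window_s / (2 * resolution_s))
    starts <- pmax(1L, idx - h)
    ends <- pmin(n, idx + h)
    # interval union via a +1/-1 difference array (tabulate keeps duplicate
    # start/end bins counted once per interval)
    delta <- tabulate(starts, n + 1) - tabulate(ends + 1, n + 1)
    out[cumsum(delta[seq_len(n)]) > 0] <- 1
  }
  attributes(out) <- attributes(v)
  out
}

#' Jaccard overlap between two binary vectors
#'
#' `J(A, B) = |A intersect B| / |A union B|` over the set bins of two
#' equal-length binary vectors; a measure of overlap between an idiosyncratic
#' and a prototypical segmentation. Defined as 0 (with a message) when both
#' vectors are all-zero.
#'
#' @param a,b Equal-length binary vectors.
#' @return A number in `[0, 1]`.
#' @examples
#' jaccard(c(0, 1, 1, 0), c(0, 0, 1, 1))  # 1/3
#' @export
jaccard <- function(a, b) {
  if (length(a) != length(b)) {
    abort(sprintf("jaccard: length mismatch (%d vs %d)", length(a), length(b)))
  }
  sa <- a > 0
  sb <- b > 0
  un <- sum(sa | sb)
  if (un == 0) {
    message("jaccard: both vectors empty; returning 0")
    return(0)
  }
  sum(sa & sb) / un
}

#' Gaussian smoothing of a binary press vector
#'
#' Convolves a binary vector with a Gaussian kernel of standard deviation
#' `sigma_s` seconds (default 2 s, FWHM = 2.355 * sigma, approximately 4.7 s,
#' i.e. about the 5-s discrete window). The kernel is truncated at +/- 4
#' sigma and normalized; edge bins keep the truncated kernel mass as-is
#' (zero padding). Pearson-based downstream statistics are invariant to the
#' kernel normalization choice.
#'
#' @param v Binary temporal vector.
#' @param sigma_s Kernel standard deviation in seconds (default 2).
#' @param resolution_s Bin width in seconds; defaults to the vector's
#'   attribute, else 0.1.
#' @param normalize `"area"` (kernel sums to 1, the default) or `"peak"`
#'   (kernel maximum is 1).
#' @return A non-negative numeric vector of the same length.
#' @export
convolve_gaussian <- function(v, sigma_s = 2, resolution_s = NULL,
                              normalize = c("area", "peak")) {
  resolution_s <- resolution_s %||% attr(v, "resolution_s") %||% 0.1
  if (!is.numeric(sigma_s) || sigma_s <= 0) {
    abort("convolve_gaussian: sigma_s must be positive")
  }
  normalize <- match.arg(normalize)
  k <- gaussian_kernel(sigma_s, resolution_s, normalize)
  out <- convolve_centered(as.numeric(v), k)
  attributes(out) <- attributes(v)
  out
}

gaussian_kernel <- function(sigma_s, resolution_s, normalize = "area") {
  h <- ceiling(4 * sigma_s / resolution_s)
  k <- dnorm(seq(-h, h) * resolution_s, sd = sigma_s)
  if (normalize == "area") k / sum(k) else k / max(k)
}

# centered convolution with zero padding via a power-of-two padded FFT;
# clamps FFT round-off negatives
convolve_centered <- function(x, k) {
  n <- length(x)
  nk <- length(k)
  h <- (nk - 1L) / 2L
  nfft <- 2^ceiling(log2(n + nk - 1L))
  fx <- stats::fft(c(x, numeric(nfft - n)))
  fk <- stats::fft(c(k, numeric(nfft - nk)))
  full <- Re(stats::fft(fx * fk, inverse = TRUE)) / nfft
  pmax(full[(h + 1L):(h + n)], 0)
}
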