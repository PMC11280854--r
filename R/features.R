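# Per-channel signal feature bank: time-domain, fractal, spectral, wavelet,
# autoregressive and entropy features of sEMG / IMU channels.
#
# Degenerate-input policy: features that are undefined on constant or
# too-short signals return the documented sentinel 0 rather than NaN/Inf, so
# that any segment passing the minimum-duration gate featurizes cleanly.

#' Feature-extraction configuration
#'
#' @param wamp_threshold Willison amplitude threshold (EMG units)
#' @param ar_orders autoregressive model orders; fixed to `c(1, 2, 4, 8)`
#' @param wavelet_levels discrete wavelet decomposition depth (Daubechies-4)
#' @param higuchi_kmax maximum delay for the Higuchi fractal dimension
#' @param hist_bins amplitude-histogram bins for Shannon entropy
#' @param svd_embed_dim delay-embedding dimension for SVD/Fisher entropies
#' @param inactive_threshold |x| below which a sample counts as inactive
#' @return a `feature_config`
#' @export
feature_config <- function(wamp_threshold = 10, ar_orders = c(1, 2, 4, 8),
                           wavelet_levels = 4, higuchi_kmax = 8,
                           hist_bins = 64, svd_embed_dim = 10,
                           inactive_threshold = 3) {
  if (!identical(as.integer(ar_orders), c(1L, 2L, 4L, 8L)))
    stop_invalid("`ar_orders` must be exactly c(1, 2, 4, 8)")
  vals <- list(wamp_threshold = wamp_threshold, ar_orders = c(1L, 2L, 4L, 8L),
               wavelet_levels = as.integer(wavelet_levels),
               higuchi_kmax = as.integer(higuchi_kmax),
               hist_bins = as.integer(hist_bins),
               svd_embed_dim = as.integer(svd_embed_dim),
               inactive_threshold = inactive_threshold)
  for (nm in setdiff(names(vals), "ar_orders"))
    if (vals[[nm]] <= 0) stop_invalid("`", nm, "` must be positive")
  structure(vals, class = "feature_config")
}

is_constant <- function(x) max(x) == min(x)

#' Mean absolute value
#' @param x numeric signal (length >= 1)
#' @return mean of |x|
#' @export
mav <- function(x) {
  if (!length(x)) stop_invalid("`x` must be nonempty")
  mean(abs(x))
}

#' Root mean square amplitude
#' @param x numeric signal (length >= 1)
#' @return sqrt of the mean squared sample
#' @export
rms <- function(x) {
  if (!length(x)) stop_invalid("`x` must be nonempty")
  sqrt(mean(x^2))
}

#' Zero crossing rate
#'
#' Fraction of consecutive sample pairs whose product is negative; a zero
#' sample yields product 0 and counts as no crossing.
#'
#' @param x numeric signal (length >= 2)
#' @return crossings / (N - 1)
#' @export
zcr <- function(x) {
  n <- length(x)
  if (n < 2L) stop_invalid("`x` must have at least 2 samples")
  sum(x[-n] * x[-1L] < 0) / (n - 1L)
}

#' Willison amplitude
#'
#' Number of consecutive-sample absolute differences strictly exceeding the
#' threshold `theta`.
#'
#' @param x numeric signal (length >= 2)
#' @param theta nonnegative threshold
#' @return integer count
#' @export
wamp <- function(x, theta = 10) {
  if (length(x) < 2L) stop_invalid("`x` must have at least 2 samples")
  if (theta < 0) stop_invalid("`theta` must be >= 0")
  sum(abs(diff(x)) > theta)
}

#' Amplitude and shape features
#'
#' Integrated absolute amplitude, mean Teager-Kaiser nonlinear energy,
#' least-squares slope per second, line length, population standard
#' deviation, min/max, counts of strict local minima/maxima, moment skewness
#' and excess kurtosis, zero-crossing rates of the first and second
#' differences, and the count of samples with |x| below
#' `inactive_threshold`.
#'
#' @param x numeric signal (length >= 3)
#' @param fs sampling rate in Hz (for the slope's time axis)
#' @param inactive_threshold inactivity threshold
#' @return named numeric vector of 14 features
#' @export
amplitude_shape_features <- function(x, fs, inactive_threshold = 3) {
  n <- length(x)
  if (n < 3L) stop_invalid("`x` must have at least 3 samples")
  mu <- mean(x)
  xc <- x - mu
  m2 <- mean(xc^2)
  tt <- (seq_len(n) - 1L) / fs
  tc <- tt - mean(tt)
  d1 <- diff(x)
  d2 <- diff(d1)
  inner <- 2:(n - 1L)
  c(iemg = sum(abs(x)),
    nonlinear_energy = mean(x[inner]^2 - x[inner - 1L] * x[inner + 1L]),
    slope = sum(tc * xc) / sum(tc^2),
    line_length = sum(abs(d1)),
    std = sqrt(m2),
    min = min(x),
    max = max(x),
    minima = sum(x[inner] < x[inner - 1L] & x[inner] < x[inner + 1L]),
    maxima = sum(x[inner] > x[inner - 1L] & x[inner] > x[inner + 1L]),
    skewness = if (m2 > 0) mean(xc^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean(xc^4) / m2^2 - 3 else 0,
    zc_d1 = if (length(d1) >= 2L) zcr(d1) else 0,
    zc_d2 = if (length(d2) >= 2L) zcr(d2) else 0,
    inactive = sum(abs(x) < inactive_threshold))
}

#' Hjorth parameters
#'
#' Activity (variance), mobility (sqrt of the variance ratio of the first
#' difference to the signal) and complexity (mobility of the first
#' difference over mobility of the signal). Constant input returns the
#' `(0, 0, 0)` sentinel.
#'
#' @param x numeric signal (length >= 3)
#' @return named vector `c(activity, mobility, complexity)`
#' @export
hjorth <- function(x) {
  if (length(x) < 3L || is_constant(x))
    return(c(activity = 0, mobility = 0, complexity = 0))
  v0 <- var(x)
  d1 <- diff(x)
  v1 <- var(d1)
  mob <- sqrt(v1 / v0)
  v2 <- var(diff(d1))
  comp <- if (v1 > 0) sqrt(v2 / v1) / mob else 0
  c(activity = v0, mobility = mob, complexity = comp)
}

#' Fractal and long-range-dependence features
#'
#' Higuchi fractal dimension (slope of log curve length vs log 1/k, k =
#' 1..kmax), Petrosian fractal dimension (from sign changes of the first
#' difference), detrended fluctuation analysis exponent alpha (linear
#' detrending, log-spaced boxes from 4 to N/4), and the Hurst exponent from
#' Anis-Lloyd-corrected rescaled-range regression. Constant input returns
#' the all-zero sentinel.
#'
#' @param x numeric signal (length >= 20)
#' @param kmax Higuchi maximum delay
#' @return named vector `c(higuchi_fd, petrosian_fd, dfa_alpha, hurst)`
#' @export
fractal_features <- function(x, kmax = 8) {
  n <- length(x)
  if (n < 20L) stop_invalid("fractal features need at least 20 samples")
  if (is_constant(x))
    return(c(higuchi_fd = 0, petrosian_fd = 0, dfa_alpha = 0, hurst = 0))
  c(higuchi_fd = higuchi_fd(x, kmax),
    petrosian_fd = petrosian_fd(x),
    dfa_alpha = dfa_alpha(x),
    hurst = hurst_rs(x))
}

#' Higuchi fractal dimension
#' @param x numeric signal
#' @param kmax maximum delay
#' @return estimated fractal dimension (1 for a straight line, ~2 for noise)
#' @export
higuchi_fd <- function(x, kmax = 8) {
  n <- length(x)
  lk <- vapply(seq_len(kmax), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2L) return(NA_real_)
      sum(abs(diff(x[idx]))) * (n - 1) / (floor((n - m) / k) * k) / k
    }, numeric(1L))
    mean(lm_k, na.rm = TRUE)
  }, numeric(1L))
  ok <- is.finite(lk) & lk > 0
  if (sum(ok) < 2L) return(0)
  unname(stats::lm.fit(cbind(1, log(1 / seq_len(kmax)[ok])),
                       log(lk[ok]))$coefficients[2L])
}

#' Petrosian fractal dimension
#' @param x numeric signal
#' @return log10(N) / (log10(N) + log10(N / (N + 0.4 Ndelta)))
#' @export
petrosian_fd <- function(x) {
  n <- length(x)
  d <- diff(x)
  ndelta <- sum(d[-length(d)] * d[-1L] < 0)
  den <- log10(n) + log10(n / (n + 0.4 * ndelta))
  if (den == 0) return(0)
  log10(n) / den
}

#' Detrended fluctuation analysis exponent
#'
#' Linear-detrended DFA over log-spaced box sizes from `box_min` to N/4;
#' white noise yields alpha ~ 0.5, Brownian motion ~ 1.5.
#'
#' @param x numeric signal
#' @param box_min smallest box size
#' @param n_boxes number of log-spaced box sizes
#' @return the scaling exponent alpha
#' @export
dfa_alpha <- function(x, box_min = 4, n_boxes = 10) {
  n <- length(x)
  y <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(box_min), log(max(box_min + 1, n %/% 4)),
                                length.out = n_boxes))))
  sizes <- sizes[sizes >= 4 & sizes <= n %/% 2]
  if (length(sizes) < 2L) return(0)
  fn <- vapply(sizes, function(s) {
    nb <- n %/% s
    m <- matrix(y[seq_len(nb * s)], nrow = s)
    tt <- seq_len(s) - (s + 1) / 2           # centered time within a box
    stt <- sum(tt^2)
    b <- colSums(m * tt) / stt               # per-box slope
    a <- colMeans(m)                         # per-box intercept at center
    res <- m - outer(tt, b) - rep(a, each = s)
    sqrt(mean(res^2))
  }, numeric(1L))
  ok <- fn > 0
  if (sum(ok) < 2L) return(0)
  unname(stats::lm.fit(cbind(1, log(sizes[ok])), log(fn[ok]))$coefficients[2L])
}

# Expected R/S for i.i.d. data (Anis-Lloyd with the Peters finite-n factor),
# memoised per block size.
.ers_cache <- new.env(parent = emptyenv())
expected_rs <- function(n) {
  key <- as.character(n)
  if (!is.null(.ers_cache[[key]])) return(.ers_cache[[key]])
  i <- seq_len(n - 1L)
  v <- if (n <= 340) {
    (gamma((n - 1) / 2) / (sqrt(pi) * gamma(n / 2))) * sum(sqrt((n - i) / i))
  } else {
    (1 / sqrt(n * pi / 2)) * sum(sqrt((n - i) / i))
  }
  v <- v * (n - 0.5) / n
  .ers_cache[[key]] <- v
  v
}

#' Hurst exponent via corrected rescaled-range regression
#'
#' Averages R/S over non-overlapping blocks for log-spaced block sizes and
#' regresses `log(R/S) - log(E[R/S])` on `log(n)`; the Anis-Lloyd expected
#' value removes the well-known small-sample upward bias, so white noise
#' estimates center on 0.5.
#'
#' @param x numeric signal
#' @param min_block smallest block size
#' @param n_sizes number of log-spaced block sizes
#' @return Hurst exponent estimate
#' @export
hurst_rs <- function(x, min_block = 8, n_sizes = 8) {
  n <- length(x)
  sizes <- unique(round(exp(seq(log(min_block), log(max(min_block + 1, n %/% 2)),
                                length.out = n_sizes))))
  sizes <- sizes[sizes >= 4 & sizes <= n %/% 2]
  if (length(sizes) < 2L) return(0)
  rs <- vapply(sizes, function(s) {
    nb <- n %/% s
    m <- matrix(x[seq_len(nb * s)], nrow = s)
    m <- sweep(m, 2L, colMeans(m))
    cs <- apply(m, 2L, cumsum)
    r <- apply(cs, 2L, max) - apply(cs, 2L, min)
    sdev <- sqrt(colMeans(m^2))
    ok <- sdev > 0
    if (!any(ok)) return(NA_real_)
    mean(r[ok] / sdev[ok])
  }, numeric(1L))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2L) return(0)
  ers <- vapply(sizes[ok], expected_rs, numeric(1L))
  0.5 + unname(stats::lm.fit(cbind(1, log(sizes[ok])),
                             log(rs[ok]) - log(ers))$coefficients[2L])
}

#' Spectral features from the one-sided periodogram
#'
#' The periodogram is `P(f_k) = |X_k|^2 / N` over the one-sided DFT bins
#' `f_k = k fs / N`, `k = 0..floor(N/2)` (DC included). Features: peak
#' frequency (argmax), median frequency (smallest f with cumulative power >=
#' half the total), modified median and modified mean frequency (same
#' statistics on the amplitude spectrum |X|), intensity-weighted mean
#' frequency, intensity-weighted bandwidth, total spectrum and mean power
#' per bin. An all-zero signal returns all-zero sentinels.
#'
#' @param x numeric signal (length >= 8)
#' @param fs sampling rate in Hz
#' @return named numeric vector of 8 features
#' @export
spectral_features <- function(x, fs) {
  n <- length(x)
  if (n < 8L) stop_invalid("spectral features need at least 8 samples")
  if (fs <= 0) stop_invalid("`fs` must be positive")
  xf <- fft(x)
  k <- 0:(n %/% 2)
  f <- k * fs / n
  p <- Mod(xf[k + 1L])^2 / n
  a <- Mod(xf[k + 1L])
  tot <- sum(p)
  if (tot == 0)
    return(c(peak_freq = 0, median_freq = 0, mod_median_freq = 0,
             mod_mean_freq = 0, iw_mean_freq = 0, iw_bandwidth = 0,
             total_spectrum = 0, mean_power = 0))
  medf <- function(wt) f[which(cumsum(wt) >= sum(wt) / 2)[1L]]
  iwm <- sum(f * p) / tot
  c(peak_freq = f[which.max(p)],
    median_freq = medf(p),
    mod_median_freq = medf(a),
    mod_mean_freq = sum(f * a) / sum(a),
    iw_mean_freq = iwm,
    iw_bandwidth = sqrt(sum((f - iwm)^2 * p) / tot),
    total_spectrum = tot,
    mean_power = tot / length(p))
}

# Daubechies-4 (4 vanishing moments, 8 taps) scaling filter.
DB4_H <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
           -0.027983769416984, -0.187034811718881, 0.030841381835987,
           0.032883011666983, -0.010597401784997)
DB4_G <- rev(DB4_H) * c(1, -1)  # (-1)^m h[L-1-m], m = 0..L-1

# One periodized analysis step; length(x) must be even.
dwt_step <- function(x) {
  n <- length(x)
  L <- length(DB4_H)
  idx <- outer(seq(0, n - 2L, by = 2L), 0:(L - 1L), `+`) %% n + 1L
  xm <- matrix(x[idx], ncol = L)
  list(approx = as.numeric(xm %*% DB4_H), detail = as.numeric(xm %*% DB4_G))
}

#' Total wavelet detail energy
#'
#' Sum of squared detail coefficients of a periodized orthogonal
#' Daubechies-4 decomposition at up to `levels` levels (descent stops early
#' if a level's length becomes odd or shorter than the filter). For an
#' orthogonal wavelet, detail energy plus final approximation energy equals
#' the signal energy (Parseval).
#'
#' @param x numeric signal
#' @param levels decomposition depth
#' @return scalar detail energy
#' @export
wavelet_energy <- function(x, levels = 4) {
  e <- 0
  a <- x
  for (l in seq_len(levels)) {
    if (length(a) < length(DB4_H) || length(a) %% 2L != 0L) break
    st <- dwt_step(a)
    e <- e + sum(st$detail^2)
    a <- st$approx
  }
  e
}

# Levinson-Durbin recursion on autocorrelation r[0..p]; returns per-order
# coefficients and prediction-error variances.
levinson_durbin <- function(r, p) {
  a <- numeric(p)
  err <- r[1L]
  out_a1 <- numeric(p)
  out_err <- numeric(p)
  for (m in seq_len(p)) {
    acc <- r[m + 1L]
    if (m > 1L) acc <- acc - sum(a[1:(m - 1L)] * r[m:2L])
    k <- acc / err
    a_new <- a
    a_new[m] <- k
    if (m > 1L) a_new[1:(m - 1L)] <- a[1:(m - 1L)] - k * a[(m - 1L):1L]
    a <- a_new
    err <- err * (1 - k^2)
    out_a1[m] <- a[1L]
    out_err[m] <- err
  }
  list(a1 = out_a1, err = out_err)
}

#' Autoregressive features
#'
#' For each order p in \{1, 2, 4, 8\}, fits an AR(p) model by
#' Levinson-Durbin recursion on the biased autocorrelation of the demeaned
#' signal and reports the first coefficient and the final prediction-error
#' variance (8 values). Constant input returns the all-zero sentinel.
#'
#' @param x numeric signal (length > 16)
#' @param orders model orders (fixed default `c(1, 2, 4, 8)`)
#' @return named numeric vector `ar_coef_p`, `ar_err_p`
#' @export
ar_features <- function(x, orders = c(1, 2, 4, 8)) {
  nm <- c(paste0("ar_coef_", orders), paste0("ar_err_", orders))
  out <- stats::setNames(numeric(2L * length(orders)), nm)
  n <- length(x)
  if (n <= 16L) stop_invalid("AR features need more than 16 samples")
  if (is_constant(x)) return(out)
  xc <- x - mean(x)
  pmax_ <- max(orders)
  r <- vapply(0:pmax_, function(k)
    sum(xc[seq_len(n - k)] * xc[(k + 1L):n]) / n, numeric(1L))
  if (r[1L] == 0) return(out)
  ld <- levinson_durbin(r, pmax_)
  out[paste0("ar_coef_", orders)] <- ld$a1[orders]
  out[paste0("ar_err_", orders)] <- ld$err[orders]
  out
}

#' Shannon entropy of the amplitude histogram
#'
#' Fixed-width histogram with `bins` bins over `range` (defaults to the
#' observed range); natural logarithm, empty bins skipped. Constant input
#' (degenerate range) returns 0.
#'
#' @param x numeric signal
#' @param bins histogram bin count
#' @param range length-2 numeric range; `NULL` for observed min/max
#' @return entropy in nats
#' @export
shannon_entropy <- function(x, bins = 64, range = NULL) {
  if (is.null(range)) range <- c(min(x), max(x))
  if (range[2L] <= range[1L]) return(0)
  b <- pmin(pmax(floor((x - range[1L]) / (range[2L] - range[1L]) * bins), 0),
            bins - 1L)
  p <- tabulate(b + 1L, bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the normalized one-sided periodogram divided by the
#' log of the number of bins, so the value lies in \[0, 1\]; a single-bin
#' spectrum (pure bin-aligned sinusoid) gives 0.
#'
#' @param x numeric signal
#' @param fs sampling rate (unused in the value, kept for interface symmetry)
#' @return normalized entropy in \[0, 1\]
#' @export
spectral_entropy <- function(x, fs = 1) {
  n <- length(x)
  p <- Mod(fft(x)[seq_len(n %/% 2 + 1L)])^2 / n
  tot <- sum(p)
  if (tot == 0) return(0)
  q <- p / tot
  q <- q[q > 0]
  -sum(q * log(q)) / log(length(p))
}

delay_embed <- function(x, m) {
  n <- length(x) - m + 1L
  matrix(x[outer(seq_len(n) - 1L, seq_len(m), `+`)], n, m)
}

embed_singular_values <- function(x, m) {
  e <- delay_embed(x, m)
  sv <- sqrt(pmax(0, eigen(crossprod(e), symmetric = TRUE,
                           only.values = TRUE)$values))
  sv / sum(sv)
}

#' SVD entropy
#'
#' Shannon entropy of the normalized singular values of the delay-embedding
#' matrix (dimension `m`, delay 1).
#'
#' @param x numeric signal (length >= m + 1)
#' @param m embedding dimension
#' @return entropy in nats
#' @export
svd_entropy <- function(x, m = 10) {
  if (length(x) < m + 1L) stop_invalid("svd entropy needs length >= m + 1")
  if (is_constant(x)) return(0)
  sv <- embed_singular_values(x, m)
  sv <- sv[sv > 0]
  -sum(sv * log(sv))
}

#' Fisher information of the singular-value spectrum
#'
#' `sum_i (s[i+1] - s[i])^2 / s[i]` over the normalized singular values of
#' the delay-embedding matrix.
#'
#' @inheritParams svd_entropy
#' @return Fisher information (0 sentinel for constant input)
#' @export
fisher_information <- function(x, m = 10) {
  if (length(x) < m + 1L) stop_invalid("fisher information needs length >= m + 1")
  if (is_constant(x)) return(0)
  sv <- embed_singular_values(x, m)
  i <- seq_len(length(sv) - 1L)
  ok <- sv[i] > 0
  sum((sv[i + 1L][ok] - sv[i][ok])^2 / sv[i][ok])
}

#' Entropy feature group
#'
#' @param x numeric signal
#' @param fs sampling rate in Hz
#' @param config a [feature_config()]
#' @param range amplitude range for the Shannon histogram (`NULL`: observed)
#' @return named vector `c(shannon, spectral_entropy, svd_entropy,
#'   fisher_info)`
#' @export
entropy_features <- function(x, fs, config = feature_config(), range = NULL) {
  if (is_constant(x))
    return(c(shannon = 0, spectral_entropy = 0, svd_entropy = 0,
             fisher_info = 0))
  c(shannon = shannon_entropy(x, config$hist_bins, range),
    spectral_entropy = spectral_entropy(x, fs),
    svd_entropy = svd_entropy(x, config$svd_embed_dim),
    fisher_info = fisher_information(x, config$svd_embed_dim))
}
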