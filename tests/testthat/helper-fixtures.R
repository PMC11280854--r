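# Shared fixtures and independent oracle implementations.
# Oracles are deliberately plain (loops, direct sums) and never call the
# package functions they check.

# Minimal hand-built session: one EMG channel pattern on the left arm's
# channel 1, all other channels zero, IMU frozen at the rest pose.
manual_session <- function(emg_ch1) {
  n <- length(emg_ch1)
  n_imu <- max(2L, ceiling(n / 4))
  emg <- matrix(0L, n, 8L)
  emg[, 1L] <- as.integer(emg_ch1)
  stream <- function(id) {
    signstream:::armband_stream(
      id, (seq_len(n) - 1L) / 200, emg,
      (seq_len(n_imu) - 1L) / 50,
      matrix(rep(c(0, 0, 1), each = n_imu), n_imu, 3L),
      matrix(0, n_imu, 3L),
      matrix(rep(c(1, 0, 0, 0), each = n_imu), n_imu, 4L))
  }
  list(left = stream("left"), right = stream("right"))
}

# A burst of alternating +/-100 frames ending at 0, so the frame after the
# burst has zero delta and the quiet run starts immediately.
burst_frames <- function(n) c(rep_len(c(100L, -100L), n - 1L), 0L)

# --- brute-force oracles ----------------------------------------------------

# Direct O(N^2) one-sided DFT periodogram and the eight spectral features,
# computed with explicit loops/sums.
oracle_spectral <- function(x, fs) {
  n <- length(x)
  ks <- 0:(n %/% 2)
  X <- complex(length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    X[j] <- sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
  }
  f <- ks * fs / n
  p <- Mod(X)^2 / n
  a <- Mod(X)
  tot <- sum(p)
  med <- function(w) {
    cs <- 0
    for (j in seq_along(w)) {
      cs <- cs + w[j]
      if (cs >= sum(w) / 2) return(f[j])
    }
  }
  iwm <- sum(f * p) / tot
  c(peak_freq = f[which.max(p)], median_freq = med(p),
    mod_median_freq = med(a), mod_mean_freq = sum(f * a) / sum(a),
    iw_mean_freq = iwm, iw_bandwidth = sqrt(sum((f - iwm)^2 * p) / tot),
    total_spectrum = tot, mean_power = tot / length(p))
}

oracle_shannon <- function(x, bins, lo, hi) {
  counts <- numeric(bins)
  for (v in x) {
    b <- floor((v - lo) / (hi - lo) * bins) + 1
    b <- min(max(b, 1), bins)
    counts[b] <- counts[b] + 1
  }
  h <- 0
  for (c in counts) if (c > 0) {
    p <- c / length(x)
    h <- h - p * log(p)
  }
  h
}

oracle_spectral_entropy <- function(x) {
  n <- length(x)
  ks <- 0:(n %/% 2)
  p <- numeric(length(ks))
  for (j in seq_along(ks))
    p[j] <- Mod(sum(x * exp(-2i * pi * ks[j] * (0:(n - 1)) / n)))^2 / n
  q <- p / sum(p)
  h <- 0
  for (v in q) if (v > 0) h <- h - v * log(v)
  h / log(length(p))
}

oracle_embed_sv <- function(x, m) {
  rows <- length(x) - m + 1
  E <- matrix(0, rows, m)
  for (i in seq_len(rows)) E[i, ] <- x[i:(i + m - 1)]
  sv <- svd(E)$d
  sv / sum(sv)
}

oracle_svd_entropy <- function(x, m) {
  s <- oracle_embed_sv(x, m)
  h <- 0
  for (v in s) if (v > 0) h <- h - v * log(v)
  h
}

oracle_fisher <- function(x, m) {
  s <- oracle_embed_sv(x, m)
  out <- 0
  for (i in seq_len(length(s) - 1))
    if (s[i] > 0) out <- out + (s[i + 1] - s[i])^2 / s[i]
  out
}

oracle_kappa <- function(cm) {
  total <- sum(cm)
  po <- sum(diag(cm)) / total
  pe <- 0
  for (i in seq_len(nrow(cm))) pe <- pe + sum(cm[i, ]) * sum(cm[, i])
  pe <- pe / total^2
  (po - pe) / (1 - pe)
}

oracle_rmse <- function(proba, truth_idx) {
  s <- 0
  for (i in seq_len(nrow(proba)))
    for (c in seq_len(ncol(proba)))
      s <- s + (proba[i, c] - as.numeric(truth_idx[i] == c))^2
  unname(sqrt(s / (nrow(proba) * ncol(proba))))
}
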