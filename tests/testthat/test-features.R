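test_that("mav, rms, zcr and wamp match their definitions", {
  expect_equal(mav(c(1, -1, 1, -1)), 1)
  expect_equal(mav(rep(-3.5, 10)), 3.5)
  expect_equal(rms(rep(-2, 5)), 2)
  expect_equal(rms(c(3, 4, 0, 0)), 2.5)
  expect_equal(zcr(c(1, -1, 1, -1)), 1)
  expect_equal(zcr(c(2, 5, 1, 7)), 0)
  expect_equal(wamp(c(1, -1, 1, -1, 1), theta = 1), 4)
  expect_equal(wamp(rep(5, 10), theta = 0), 0)
  expect_error(mav(numeric(0)), "nonempty")
  expect_error(zcr(1), "at least 2")

  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(100) * 10
    expect_equal(mav(x), sum(abs(x)) / 100, tolerance = 1e-12)
    expect_equal(rms(x), sqrt(sum(x^2) / 100), tolerance = 1e-12)
    expect_gte(rms(x), mav(x))  # power-mean inequality
    cross <- 0
    for (j in 1:99) if (x[j] * x[j + 1] < 0) cross <- cross + 1
    expect_equal(zcr(x), cross / 99)
  }
})

test_that("wamp is monotone nonincreasing in the threshold", {
  set.seed(32)
  for (i in 1:20) {
    x <- rnorm(200) * 30
    w <- vapply(seq(0, 100, by = 2), function(th) wamp(x, th), 0)
    expect_true(all(diff(w) <= 0))
  }
})

test_that("amplitude/shape features equal brute-force formulas", {
  # closed-form checks
  xc <- rep(4, 50)
  a <- amplitude_shape_features(xc, fs = 200)
  expect_equal(unname(a[c("iemg", "line_length", "std", "minima", "maxima",
                          "nonlinear_energy")]),
               c(200, 0, 0, 0, 0, 0))
  ramp <- 0:99
  r <- amplitude_shape_features(ramp, fs = 200)
  expect_equal(unname(r["slope"]), 200, tolerance = 1e-9)  # 1 unit per sample
  expect_equal(unname(r["maxima"]), 0)

  set.seed(33)
  for (i in 1:100) {
    x <- rnorm(80) * 20
    fs <- 100
    a <- amplitude_shape_features(x, fs, inactive_threshold = 3)
    n <- length(x)
    mu <- sum(x) / n
    m2 <- sum((x - mu)^2) / n
    tt <- (0:(n - 1)) / fs
    beta <- sum((tt - mean(tt)) * (x - mu)) / sum((tt - mean(tt))^2)
    nle <- mean(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])
    expect_equal(unname(a["iemg"]), sum(abs(x)))
    expect_equal(unname(a["slope"]), beta, tolerance = 1e-9)
    expect_equal(unname(a["line_length"]), sum(abs(x[-1] - x[-n])))
    expect_equal(unname(a["std"]), sqrt(m2), tolerance = 1e-12)
    expect_equal(unname(a["nonlinear_energy"]), nle, tolerance = 1e-12)
    expect_equal(unname(a["skewness"]), (sum((x - mu)^3) / n) / m2^1.5,
                 tolerance = 1e-12)
    expect_equal(unname(a["kurtosis"]), (sum((x - mu)^4) / n) / m2^2 - 3,
                 tolerance = 1e-12)
    expect_equal(unname(a["minima"]),
                 sum(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] < x[3:n]))
    expect_equal(unname(a["inactive"]), sum(abs(x) < 3))
    expect_equal(unname(a["zc_d1"]), zcr(diff(x)))
  }
})

test_that("hjorth parameters behave like the textbook quantities", {
  expect_equal(hjorth(rep(2, 100)), c(activity = 0, mobility = 0,
                                      complexity = 0))
  set.seed(34)
  x <- rnorm(1e5, sd = 3)
  h <- hjorth(x)
  expect_equal(unname(h["activity"]), 9, tolerance = 0.05 * 9)
  # densely sampled sinusoid: mobility -> angular frequency per sample
  fs <- 1000; f <- 5
  s <- sin(2 * pi * f * (0:9999) / fs)
  expect_equal(unname(hjorth(s)["mobility"]), 2 * pi * f / fs,
               tolerance = 1e-4)
})

test_that("fractal features hit their known limits", {
  line <- seq(0, 10, length.out = 512)
  expect_lt(abs(higuchi_fd(line, 8) - 1), 0.05)
  expect_equal(fractal_features(rep(1, 100)),
               c(higuchi_fd = 0, petrosian_fd = 0, dfa_alpha = 0, hurst = 0))
  # white noise scaling exponents near 0.5 (light version; the 50-seed
  # n=4096 check lives in the acceptance suite)
  set.seed(35)
  d <- mean(replicate(8, dfa_alpha(rnorm(1024))))
  h <- mean(replicate(8, hurst_rs(rnorm(1024))))
  expect_gt(d, 0.35); expect_lt(d, 0.65)
  expect_gt(h, 0.35); expect_lt(h, 0.65)
  expect_error(fractal_features(rnorm(10)), "20")
})

test_that("petrosian uses sign changes of the first difference", {
  x <- c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1) * 2
  n <- length(x)
  ndelta <- 8  # every interior diff pair alternates
  expect_equal(petrosian_fd(x),
               log10(n) / (log10(n) + log10(n / (n + 0.4 * ndelta))))
})

test_that("spectral features equal an O(N^2) direct-DFT oracle", {
  expect_equal(unname(spectral_features(rep(0, 64), 200)), rep(0, 8))
  # bin-aligned sinusoid concentrates the spectrum in one bin
  fs <- 200; n <- 128; f0 <- fs * 8 / n
  s <- sin(2 * pi * f0 * (0:(n - 1)) / fs)
  sp <- spectral_features(s, fs)
  expect_equal(unname(sp["peak_freq"]), f0)
  expect_equal(unname(sp["median_freq"]), f0)
  expect_equal(unname(sp["iw_mean_freq"]), f0, tolerance = 1e-9)
  expect_equal(unname(sp["iw_bandwidth"]), 0, tolerance = 1e-6)

  set.seed(36)
  for (i in 1:100) {
    x <- rnorm(64) * 5
    got <- spectral_features(x, 200)
    want <- oracle_spectral(x, 200)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("wavelet energy conserves energy and scales quadratically", {
  expect_equal(wavelet_energy(rep(0, 64)), 0)
  set.seed(37)
  x <- rnorm(256)
  # Parseval: detail energy + final approximation energy = signal energy
  a <- x
  for (l in 1:4) a <- signstream:::dwt_step(a)$approx
  expect_equal(wavelet_energy(x, 4) + sum(a^2), sum(x^2), tolerance = 1e-9)
  expect_equal(wavelet_energy(2 * x), 4 * wavelet_energy(x), tolerance = 1e-9)
  # short input: computed at maximal feasible depth, not an error
  expect_gte(wavelet_energy(rnorm(12), 4), 0)
})

test_that("AR features recover simulated processes", {
  set.seed(38)
  # AR(1) with phi = 0.5
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), 1e4))
  ar <- ar_features(x)
  expect_equal(unname(ar["ar_coef_1"]), 0.5, tolerance = 0.05)
  # white noise: leading coefficient near zero
  w <- rnorm(1e4)
  expect_lt(abs(ar_features(w)["ar_coef_1"]), 0.05)
  # prediction error variance nonincreasing with order
  for (i in 1:20) {
    z <- rnorm(200)
    e <- ar_features(z)[c("ar_err_1", "ar_err_2", "ar_err_4", "ar_err_8")]
    expect_true(all(diff(unname(e)) <= 1e-12))
  }
  expect_equal(unname(ar_features(rep(3, 100))), rep(0, 8))
  expect_error(ar_features(rnorm(10)), "16")
})

test_that("entropy features equal brute-force implementations", {
  # uniform over k aligned levels -> ln k
  k <- 8
  x <- rep(0:(k - 1), each = 10)
  expect_equal(shannon_entropy(x, bins = k, range = c(-0.5, k - 0.5)), log(k))
  # bin-aligned sinusoid -> spectral entropy 0
  fs <- 200; n <- 128
  s <- sin(2 * pi * (fs * 8 / n) * (0:(n - 1)) / fs)
  expect_equal(spectral_entropy(s, fs), 0, tolerance = 1e-9)
  # constant signal sentinel
  expect_equal(entropy_features(rep(1, 50), 200),
               c(shannon = 0, spectral_entropy = 0, svd_entropy = 0,
                 fisher_info = 0))

  set.seed(39)
  for (i in 1:100) {
    x <- rnorm(60) * 12
    expect_equal(shannon_entropy(x, 64, range = c(-127, 128)),
                 oracle_shannon(x, 64, -127, 128), tolerance = 1e-9)
    expect_equal(spectral_entropy(x), oracle_spectral_entropy(x),
                 tolerance = 1e-9)
    expect_equal(svd_entropy(x, 10), oracle_svd_entropy(x, 10),
                 tolerance = 1e-9)
    expect_equal(fisher_information(x, 10), oracle_fisher(x, 10),
                 tolerance = 1e-9)
  }
})

test_that("scale behaviors hold", {
  set.seed(40)
  x <- rnorm(100)
  expect_equal(mav(3 * x), 3 * mav(x))
  expect_equal(rms(3 * x), 3 * rms(x))
  expect_equal(zcr(5 * x), zcr(x))
})

test_that("the feature vector has 1044 stable, finite entries", {
  reg <- feature_registry()
  expect_length(reg, 1044L)
  expect_equal(anyDuplicated(reg), 0L)
  # per-group counts of the partition plan
  expect_equal(sum(grepl("\\.emg[1-8]\\.", reg)), 16 * 46)
  expect_equal(sum(grepl("\\.(accel|gyro)\\.", reg)), 12 * 17)
  expect_equal(sum(grepl("\\.quat\\.", reg)), 8 * 13)

  tpl <- make_sign_templates(1, seed = 20)[[1]]
  rec <- synthesize_recording(tpl, 1, 8, seed = 2)
  v1 <- extract_feature_vector(rec)
  v2 <- extract_feature_vector(rec)
  expect_length(v1, 1044L)
  expect_identical(v1, v2)
  expect_true(all(is.finite(v1)))
  expect_identical(names(v1), reg)
})

test_that("too-short segments are refused with the offending channel named", {
  tpl <- make_sign_templates(1, seed = 22)[[1]]
  rec <- synthesize_recording(tpl, 1, 0, seed = 1)
  seg <- as_segment(rec)
  seg$left$emg$values <- seg$left$emg$values[1:40, ]
  seg$right$emg$values <- seg$right$emg$values[1:40, ]
  expect_error(extract_feature_vector(seg), "left.emg1")
})

test_that("feature config validates its fields", {
  expect_error(feature_config(ar_orders = c(1, 2, 3)), "exactly")
  expect_error(feature_config(hist_bins = 0), "positive")
  cfg <- feature_config(wamp_threshold = 5)
  expect_equal(cfg$wamp_threshold, 5)
})
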