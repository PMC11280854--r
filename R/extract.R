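# Assembly of the 1044-value per-segment feature vector.
#
# Channel-group plan (the printed total, 1044, constrains the partition):
#   16 EMG channels x 46 features   = 736
#   12 accel/gyro channels x 17     = 204
#    8 orientation channels x 13    = 104
# Low-rate IMU channels only receive estimators that are stable at >= 20
# samples; the full bank (fractal, DFA, AR, wavelet, SVD entropies) is
# reserved for the 200 Hz EMG channels.

EMG_FEATURES <- c(
  "mav", "iemg", "higuchi_fd", "petrosian_fd", "dfa_alpha",
  "nonlinear_energy", "slope", "line_length", "wamp", "std", "min", "max",
  "hurst", "minima", "maxima", "skewness", "kurtosis", "zc", "zc_d1",
  "zc_d2", "rms", "inactive", "mobility", "activity", "complexity",
  "peak_freq", "median_freq", "mod_median_freq", "mod_mean_freq",
  "iw_mean_freq", "iw_bandwidth", "total_spectrum", "mean_power",
  "wavelet_energy", "ar_coef_1", "ar_err_1", "ar_coef_2", "ar_err_2",
  "ar_coef_4", "ar_err_4", "ar_coef_8", "ar_err_8",
  "shannon", "spectral_entropy", "svd_entropy", "fisher_info")

MOTION_FEATURES <- c(
  "mav", "rms", "min", "max", "std", "skewness", "kurtosis", "zc", "wamp",
  "line_length", "slope", "mobility", "activity", "complexity",
  "peak_freq", "median_freq", "shannon")

QUAT_FEATURES <- c(
  "mav", "rms", "min", "max", "std", "skewness", "kurtosis", "zc",
  "line_length", "slope", "mobility", "activity", "complexity")

emg_channel_names <- function() {
  c(paste0("left.emg", 1:8), paste0("right.emg", 1:8))
}
motion_channel_names <- function() {
  as.vector(t(outer(c("left", "right"),
                    c(paste0("accel.", c("x", "y", "z")),
                      paste0("gyro.", c("x", "y", "z"))), paste, sep = ".")))
}
quat_channel_names <- function() {
  as.vector(t(outer(c("left", "right"),
                    paste0("quat.", c("w", "x", "y", "z")), paste, sep = ".")))
}

#' Feature-name registry
#'
#' The stable ordered list of the 1044 feature names, as
#' `device.channel.feature` strings (e.g. `"left.emg1.mav"`). Column names
#' of every feature matrix and ARFF attribute names come from here; model
#' files embed its hash.
#'
#' @param config a [feature_config()] (reserved; the registry is currently
#'   config-independent)
#' @return character vector of length 1044
#' @export
#' @examples
#' length(feature_registry())  # 1044
feature_registry <- function(config = feature_config()) {
  c(as.vector(t(outer(emg_channel_names(), EMG_FEATURES, paste, sep = "."))),
    as.vector(t(outer(motion_channel_names(), MOTION_FEATURES, paste, sep = "."))),
    as.vector(t(outer(quat_channel_names(), QUAT_FEATURES, paste, sep = "."))))
}

# Shared low-order statistics used by every channel group.
basic_features <- function(x, fs, config) {
  asf <- amplitude_shape_features(x, fs, config$inactive_threshold)
  hj <- hjorth(x)
  c(mav = mav(x), rms = rms(x), min = unname(asf["min"]),
    max = unname(asf["max"]), std = unname(asf["std"]),
    skewness = unname(asf["skewness"]), kurtosis = unname(asf["kurtosis"]),
    zc = zcr(x), wamp = wamp(x, config$wamp_threshold),
    line_length = unname(asf["line_length"]), slope = unname(asf["slope"]),
    mobility = unname(hj["mobility"]), activity = unname(hj["activity"]),
    complexity = unname(hj["complexity"]),
    iemg = unname(asf["iemg"]),
    nonlinear_energy = unname(asf["nonlinear_energy"]),
    minima = unname(asf["minima"]), maxima = unname(asf["maxima"]),
    zc_d1 = unname(asf["zc_d1"]), zc_d2 = unname(asf["zc_d2"]),
    inactive = unname(asf["inactive"]))
}

emg_channel_features <- function(x, fs, config) {
  b <- basic_features(x, fs, config)
  fr <- fractal_features(x, config$higuchi_kmax)
  sp <- spectral_features(x, fs)
  ar <- ar_features(x, config$ar_orders)
  en <- entropy_features(x, fs, config, range = c(EMG_LO, EMG_HI))
  v <- c(b, fr, sp, wavelet_energy = wavelet_energy(x, config$wavelet_levels),
         ar, en)
  v[EMG_FEATURES]
}

motion_channel_features <- function(x, fs, config) {
  b <- basic_features(x, fs, config)
  sp <- spectral_features(x, fs)
  v <- c(b, sp["peak_freq"], sp["median_freq"],
         shannon = shannon_entropy(x, config$hist_bins))
  v[MOTION_FEATURES]
}

quat_channel_features <- function(x, fs, config) {
  basic_features(x, fs, config)[QUAT_FEATURES]
}

segment_channels <- function(segment) {
  out <- list()
  for (arm in c("left", "right")) {
    s <- segment[[arm]]
    for (ch in 1:8)
      out[[paste0(arm, ".emg", ch)]] <-
        list(x = as.numeric(s$emg$values[, ch]), fs = segment$emg_fs,
             group = "emg")
    axes <- c("x", "y", "z")
    for (j in 1:3) {
      out[[paste(arm, "accel", axes[j], sep = ".")]] <-
        list(x = s$imu$accel[, j], fs = segment$imu_fs, group = "motion")
      out[[paste(arm, "gyro", axes[j], sep = ".")]] <-
        list(x = s$imu$gyro[, j], fs = segment$imu_fs, group = "motion")
    }
    comps <- c("w", "x", "y", "z")
    for (j in 1:4)
      out[[paste(arm, "quat", comps[j], sep = ".")]] <-
        list(x = s$imu$orientation[, j], fs = segment$imu_fs, group = "quat")
  }
  out
}

#' Extract the 1044-value feature vector of one segment
#'
#' Computes the per-channel feature bank for all 36 channels of a segment
#' and assembles them in registry order. The result is deterministic, always
#' of length 1044, and free of non-finite values (degenerate channels fall
#' back to the 0 sentinel).
#'
#' @param segment a `sign_segment` (or a `two_arm_recording`, converted via
#'   [as_segment()]); needs >= 80 EMG samples and >= 20 IMU frames per
#'   channel (the 0.4 s minimum record time)
#' @param config a [feature_config()]
#' @return named numeric vector of length 1044
#' @export
extract_feature_vector <- function(segment, config = feature_config()) {
  if (inherits(segment, "two_arm_recording")) segment <- as_segment(segment)
  stopifnot(inherits(segment, "sign_segment"))
  chans <- segment_channels(segment)
  n_emg <- length(chans[[1L]]$x)
  n_imu <- length(chans[["left.accel.x"]]$x)
  if (n_emg < 80L)
    stop_invalid("insufficient data: channel left.emg1 has ", n_emg,
                 " samples (need >= 80)")
  if (n_imu < 20L)
    stop_invalid("insufficient data: channel left.accel.x has ", n_imu,
                 " frames (need >= 20)")
  vals <- unlist(lapply(names(chans), function(nm) {
    ch <- chans[[nm]]
    v <- switch(ch$group,
                emg = emg_channel_features(ch$x, ch$fs, config),
                motion = motion_channel_features(ch$x, ch$fs, config),
                quat = quat_channel_features(ch$x, ch$fs, config))
    v[!is.finite(v)] <- 0
    stats::setNames(v, paste(nm, names(v), sep = "."))
  }))
  reg <- feature_registry(config)
  vals <- vals[reg]
  stopifnot(length(vals) == 1044L, !anyNA(vals))
  vals
}

#' Extract a feature matrix
#'
#' For a `sign_dataset`, featurizes every recording and stores the matrix
#' (plus labels) back in the dataset; for a list of segments, returns the
#' matrix with a `labels` attribute.
#'
#' @param x a `sign_dataset` or a list of `sign_segment`
#' @param config a [feature_config()]
#' @return the updated dataset, or a numeric matrix with registry column
#'   names
#' @export
extract_features <- function(x, config = feature_config()) {
  if (inherits(x, "sign_dataset")) {
    m <- t(vapply(x$recordings, extract_feature_vector,
                  numeric(1044L), config = config))
    colnames(m) <- feature_registry(config)
    x$features <- m
    x$labels <- vapply(x$recordings, `[[`, "", "label")
    return(x)
  }
  if (!length(x)) {
    m <- matrix(numeric(0), 0L, 1044L,
                dimnames = list(NULL, feature_registry(config)))
    return(m)
  }
  m <- t(vapply(x, extract_feature_vector, numeric(1044L), config = config))
  colnames(m) <- feature_registry(config)
  attr(m, "labels") <- vapply(x, `[[`, "", "label")
  m
}
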