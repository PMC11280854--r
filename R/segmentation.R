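# Motion-triggered sign segmentation of continuous two-armband streams.
#
# A segment opens at the first frame (either sensor, either arm) whose motion
# predicate fires, and closes when no predicate fires for `pause_ms` of wall
# time; segments shorter than `min_record_s` are discarded with a warning.
# EMG predicate: max over the 8 channels of the absolute frame-to-frame
# change >= threshold. IMU predicate: |mean of the wrap-aware changes of the
# three Euler angles| > threshold (literal reading; the mean-of-absolutes
# variant is available behind `imu_mean_abs`).

#' Segmenter configuration
#'
#' Defaults reproduce the example interface values of the device software:
#' EMG change threshold 40 (device range -127..128, trackbar max 256), IMU
#' mean-Euler-change threshold 20 degrees (trackbar max 360), end-of-sign
#' pause 60 ms (= 12 EMG frames at 200 Hz), minimum sign duration 0.4 s.
#'
#' @param emg_threshold EMG frame-to-frame change threshold, in \[0, 256\]
#' @param imu_threshold Euler mean-change threshold in degrees, in \[0, 360\]
#' @param pause_ms quiet window ending a sign, in \[20, 1000\] ms
#' @param min_record_s minimum retained segment duration in seconds
#' @param imu_mean_abs if `TRUE`, use mean of absolute Euler changes instead
#'   of the absolute mean (which lets opposite-sign changes cancel)
#' @return a `segmenter_config`
#' @export
#' @examples
#' cfg <- segmenter_config()
#' quiet_run_frames(cfg)  # 12
segmenter_config <- function(emg_threshold = 40, imu_threshold = 20,
                             pause_ms = 60, min_record_s = 0.4,
                             imu_mean_abs = FALSE) {
  emg_threshold <- check_scalar_num(emg_threshold, "emg_threshold")
  imu_threshold <- check_scalar_num(imu_threshold, "imu_threshold")
  pause_ms <- check_scalar_num(pause_ms, "pause_ms")
  min_record_s <- check_scalar_num(min_record_s, "min_record_s")
  if (emg_threshold < 0 || emg_threshold > 256)
    stop_invalid("`emg_threshold` must be in [0, 256]")
  if (imu_threshold < 0 || imu_threshold > 360)
    stop_invalid("`imu_threshold` must be in [0, 360]")
  if (pause_ms < 20 || pause_ms > 1000)
    stop_invalid("`pause_ms` must be in [20, 1000]")
  if (min_record_s < 0) stop_invalid("`min_record_s` must be >= 0")
  structure(list(emg_threshold = emg_threshold, imu_threshold = imu_threshold,
                 pause_ms = pause_ms, min_record_s = min_record_s,
                 imu_mean_abs = isTRUE(imu_mean_abs)),
            class = "segmenter_config")
}

#' Read a segmenter configuration from YAML or JSON
#'
#' Recognized keys: `emg_threshold`, `imu_threshold`, `pause_ms`,
#' `min_record_s` (missing keys keep their defaults).
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`)
#' @return a `segmenter_config`
#' @export
read_segmenter_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path)
  known <- c("emg_threshold", "imu_threshold", "pause_ms", "min_record_s",
             "imu_mean_abs")
  do.call(segmenter_config, cfg[intersect(names(cfg), known)])
}

#' Number of quiet EMG frames that end a sign
#'
#' At 200 Hz each EMG frame takes 5 ms, so a 60 ms pause corresponds to 12
#' consecutive quiet measurements.
#'
#' @param config a [segmenter_config()]
#' @param emg_fs EMG sampling rate in Hz
#' @return integer frame count
#' @export
quiet_run_frames <- function(config, emg_fs = 200) {
  as.integer(round(config$pause_ms / 1000 * emg_fs))
}

#' EMG motion predicate
#'
#' `TRUE` iff the largest absolute change across the 8 EMG channels between
#' two consecutive frames reaches the threshold.
#'
#' @param prev,curr numeric length-8 EMG frames
#' @param threshold change threshold (comparator is `>=`)
#' @return logical
#' @export
emg_motion <- function(prev, curr, threshold = 40) {
  max(abs(curr - prev)) >= threshold
}

#' IMU motion predicate
#'
#' Converts both orientations to Euler angles, takes the signed shortest
#' difference per angle, and reports motion when the absolute value of their
#' mean exceeds the threshold (strict `>`). With `mean_abs = TRUE` the mean
#' of absolute differences is used instead.
#'
#' @param prev,curr length-4 orientation quaternions `c(w, x, y, z)`
#' @param threshold_deg threshold in degrees
#' @param mean_abs use mean of absolute changes instead of absolute mean
#' @return logical
#' @export
imu_motion <- function(prev, curr, threshold_deg = 20, mean_abs = FALSE) {
  e0 <- quaternion_to_euler(prev)
  e1 <- quaternion_to_euler(curr)
  d <- angular_difference(e0, e1)
  m <- if (mean_abs) mean(abs(d)) else abs(mean(d))
  m > threshold_deg
}

# Motion event times for one armband stream; returns list(t, source).
stream_motion_events <- function(stream, config) {
  ev_t <- numeric(0); ev_s <- character(0)
  v <- stream$emg$values
  if (nrow(v) >= 2L) {
    dmax <- apply(abs(diff(v)), 1L, max)
    hit <- dmax >= config$emg_threshold
    ev_t <- c(ev_t, stream$emg$t[-1L][hit])
    ev_s <- c(ev_s, rep("emg", sum(hit)))
  }
  q <- stream$imu$orientation
  if (nrow(q) >= 2L) {
    e <- quat_to_euler_m(q)
    d <- angular_difference(e[-nrow(e), , drop = FALSE], e[-1L, , drop = FALSE])
    m <- if (config$imu_mean_abs) rowMeans(abs(d)) else abs(rowMeans(d))
    hit <- m > config$imu_threshold
    ev_t <- c(ev_t, stream$imu$t[-1L][hit])
    ev_s <- c(ev_s, rep("imu", sum(hit)))
  }
  list(t = ev_t, source = ev_s)
}

slice_stream <- function(stream, start_t, end_t) {
  ei <- stream$emg$t >= start_t & stream$emg$t < end_t
  ii <- stream$imu$t >= start_t & stream$imu$t < end_t
  list(emg = list(t = stream$emg$t[ei],
                  values = stream$emg$values[ei, , drop = FALSE]),
       imu = list(t = stream$imu$t[ii],
                  accel = stream$imu$accel[ii, , drop = FALSE],
                  gyro = stream$imu$gyro[ii, , drop = FALSE],
                  orientation = stream$imu$orientation[ii, , drop = FALSE]))
}

#' Segment a continuous two-armband session
#'
#' Scans the motion predicates of both sensors on both arms; a segment opens
#' at the first firing frame and closes once no predicate fires anywhere for
#' more than `pause_ms` of wall time (at 200 Hz and a 60 ms pause this is 12
#' consecutive quiet EMG frames). Segments shorter than `min_record_s` are
#' dropped with a warning.
#'
#' @param session a `session` (or any list with `left`/`right`
#'   `armband_stream`s on a common clock)
#' @param config a [segmenter_config()]
#' @return list of `sign_segment` (possibly empty), ordered and disjoint
#' @export
segment_stream <- function(session, config = segmenter_config()) {
  for (arm in c("left", "right")) {
    s <- session[[arm]]
    if (is.null(s)) stop_invalid("session must carry `left` and `right` streams")
    for (tt in list(s$emg$t, s$imu$t))
      if (length(tt) > 1L && any(diff(tt) <= 0))
        stop_invalid("stream timestamps must be strictly increasing")
  }
  evl <- stream_motion_events(session$left, config)
  evr <- stream_motion_events(session$right, config)
  t_all <- c(evl$t, evr$t)
  s_all <- c(evl$source, evr$source)
  if (!length(t_all)) return(list())
  o <- order(t_all)
  t_all <- t_all[o]; s_all <- s_all[o]
  pause_s <- config$pause_ms / 1000
  emg_dt <- 1 / session$left$emg_fs
  brk <- c(which(diff(t_all) > pause_s + 1e-9), length(t_all))
  start_i <- c(1L, head(brk, -1L) + 1L)
  segments <- vector("list", length(brk))
  for (g in seq_along(brk)) {
    idx <- start_i[g]:brk[g]
    src <- unique(s_all[idx])
    segments[[g]] <- make_segment(session, t_all[idx[1L]],
                                  t_all[brk[g]] + emg_dt,
                                  if (length(src) > 1L) "both" else src)
  }
  min_duration_filter(segments, config$min_record_s, warn = TRUE)
}

make_segment <- function(session, start_t, end_t, trigger_source) {
  structure(list(start_t = start_t, end_t = end_t,
                 trigger_source = trigger_source,
                 left = slice_stream(session$left, start_t, end_t),
                 right = slice_stream(session$right, start_t, end_t),
                 emg_fs = session$left$emg_fs, imu_fs = session$left$imu_fs,
                 label = NA_character_),
            class = "sign_segment")
}

#' Drop segments shorter than a minimum duration
#'
#' @param segments list of `sign_segment`
#' @param min_record_s minimum duration in seconds
#' @param warn emit a warning naming how many segments were dropped
#' @return filtered list
#' @export
min_duration_filter <- function(segments, min_record_s, warn = FALSE) {
  keep <- vapply(segments, function(s) s$end_t - s$start_t >= min_record_s,
                 logical(1L))
  if (warn && any(!keep))
    warning(sum(!keep), " segment(s) shorter than ", min_record_s,
            " s discarded", call. = FALSE)
  segments[keep]
}

#' Treat a whole recording as one segment
#'
#' Used when featurizing pre-cut recordings (e.g. from
#' [synthesize_dataset()]), where segmentation already happened at record
#' time.
#'
#' @param rec a `two_arm_recording`
#' @return a `sign_segment` spanning the recording, carrying its label
#' @export
as_segment <- function(rec) {
  stopifnot(inherits(rec, "two_arm_recording"))
  seg <- make_segment(rec, 0, rec$duration + 1e-9, "emg")
  seg$end_t <- rec$duration
  seg$label <- rec$label
  seg
}

#' Write segments to a BED-like TSV for inspection
#'
#' Columns: `start_s`, `end_s`, `trigger_source`, `label`.
#'
#' @param segments list of `sign_segment`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_segments_tsv <- function(segments, path) {
  df <- data.frame(
    start_s = vapply(segments, `[[`, 0, "start_t"),
    end_s = vapply(segments, `[[`, 0, "end_t"),
    trigger_source = vapply(segments, `[[`, "", "trigger_source"),
    label = vapply(segments, `[[`, "", "label"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.sign_segment <- function(x, ...) {
  cat(sprintf("<sign_segment> [%.3f, %.3f) s, trigger=%s, label=%s\n",
              x$start_t, x$end_t, x$trigger_source, x$label))
  invisible(x)
}
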