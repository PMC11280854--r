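test_that("emg_motion matches a per-channel brute-force scan", {
  prev <- rep(0, 8)
  curr <- c(40, rep(0, 7))
  expect_true(emg_motion(prev, curr, 40))
  expect_false(emg_motion(prev, prev, 1))
  set.seed(21)
  for (i in 1:1000) {
    a <- sample(-127:128, 8, replace = TRUE)
    b <- sample(-127:128, 8, replace = TRUE)
    thr <- sample(0:256, 1)
    brute <- FALSE
    for (ch in 1:8) if (abs(b[ch] - a[ch]) >= thr) brute <- TRUE
    expect_identical(emg_motion(a, b, thr), brute)
  }
})

test_that("imu_motion thresholds the mean Euler change", {
  q0 <- euler_to_quaternion(c(0, 0, 0))
  expect_false(imu_motion(q0, q0, 20))
  # pure yaw step of 90 deg: mean change 30 deg > 20
  expect_true(imu_motion(q0, euler_to_quaternion(c(0, 0, 90)), 20))
  # opposite-sign roll/pitch changes cancel under the literal mean
  expect_false(imu_motion(q0, euler_to_quaternion(c(30, -30, 0)), 20))
  q1 <- euler_to_quaternion(c(40, -40, 0))   # mean 0, mean of abs ~ 26.7
  expect_false(imu_motion(q0, q1, 20))
  expect_true(imu_motion(q0, q1, 20, mean_abs = TRUE))
  expect_error(imu_motion(c(0, 0, 0, 0), q0), "zero-norm")
})

test_that("a 60 ms pause at 200 Hz is 12 quiet frames", {
  cfg <- segmenter_config()
  expect_equal(quiet_run_frames(cfg), 12L)
  expect_equal(quiet_run_frames(segmenter_config(pause_ms = 20)), 4L)

  cfg0 <- segmenter_config(min_record_s = 0)
  # burst, exactly 12 quiet frames, burst again: the quiet run ends the sign
  ses12 <- manual_session(c(rep(0L, 20), burst_frames(30), rep(0L, 12),
                            burst_frames(30), rep(0L, 20)))
  expect_length(segment_stream(ses12, cfg0), 2L)
  # with only 11 quiet frames the sign continues
  ses11 <- manual_session(c(rep(0L, 20), burst_frames(30), rep(0L, 11),
                            burst_frames(30), rep(0L, 20)))
  expect_length(segment_stream(ses11, cfg0), 1L)
})

test_that("constant and empty sessions yield no segments", {
  ses <- manual_session(rep(0L, 200))
  expect_length(segment_stream(ses), 0L)
  ses2 <- manual_session(rep(50L, 200))  # constant offset, zero delta
  expect_length(segment_stream(ses2), 0L)
})

test_that("misordered timestamps are rejected", {
  ses <- manual_session(rep(0L, 100))
  ses$left$emg$t[5] <- ses$left$emg$t[7]
  expect_error(segment_stream(ses), "strictly increasing")
})

test_that("segment boundaries recover session annotations within one IMU frame", {
  tpl <- make_sign_templates(4, seed = 8)
  for (noise in c(0, 8)) {
    ses <- synthesize_session(tpl, reps = 2, rest_ms = 400, seed = 3,
                              noise_level = noise)
    segs <- segment_stream(ses)
    expect_length(segs, nrow(ses$annotations))
    for (i in seq_along(segs)) {
      expect_lt(abs(segs[[i]]$start_t - ses$annotations$start[i]), 0.02)
      expect_lt(abs(segs[[i]]$end_t - ses$annotations$end[i]), 0.02)
    }
  }
})

test_that("segment_stream agrees with a brute-force predicate re-scan", {
  tpl <- make_sign_templates(3, seed = 12)
  ses <- synthesize_session(tpl, reps = 1, rest_ms = 300, seed = 2,
                            noise_level = 8)
  cfg <- segmenter_config()
  segs <- segment_stream(ses, cfg)

  # independent re-scan: collect every motion time with plain loops
  ev <- numeric(0)
  for (arm in c("left", "right")) {
    s <- ses[[arm]]
    v <- s$emg$values
    for (i in 2:nrow(v)) {
      moved <- FALSE
      for (ch in 1:8) if (abs(v[i, ch] - v[i - 1, ch]) >= cfg$emg_threshold)
        moved <- TRUE
      if (moved) ev <- c(ev, s$emg$t[i])
    }
    q <- s$imu$orientation
    for (i in 2:nrow(q)) {
      e0 <- quaternion_to_euler(q[i - 1, ])
      e1 <- quaternion_to_euler(q[i, ])
      if (abs(mean(angular_difference(e0, e1))) > cfg$imu_threshold)
        ev <- c(ev, s$imu$t[i])
    }
  }
  ev <- sort(ev)
  gaps <- which(diff(ev) > cfg$pause_ms / 1000 + 1e-9)
  starts <- ev[c(1, gaps + 1)]
  ends <- ev[c(gaps, length(ev))] + 1 / 200
  keep <- ends - starts >= cfg$min_record_s
  expect_equal(vapply(segs, `[[`, 0, "start_t"), starts[keep])
  expect_equal(vapply(segs, `[[`, 0, "end_t"), ends[keep])
})

test_that("appending quiet frames does not change closed segments", {
  tpl <- make_sign_templates(2, seed = 14)
  ses <- synthesize_session(tpl, reps = 1, rest_ms = 300, seed = 5)
  before <- segment_stream(ses)
  n_extra <- 100L
  for (arm in c("left", "right")) {
    s <- ses[[arm]]
    last_t <- max(s$emg$t)
    ses[[arm]]$emg$t <- c(s$emg$t, last_t + (1:n_extra) / 200)
    ses[[arm]]$emg$values <- rbind(s$emg$values, matrix(0L, n_extra, 8))
    n_iq <- 25L
    ses[[arm]]$imu$t <- c(s$imu$t, max(s$imu$t) + (1:n_iq) / 50)
    ses[[arm]]$imu$orientation <- rbind(s$imu$orientation,
                                        matrix(rep(c(1, 0, 0, 0), each = n_iq),
                                               n_iq, 4))
    ses[[arm]]$imu$accel <- rbind(s$imu$accel,
                                  matrix(rep(c(0, 0, 1), each = n_iq), n_iq, 3))
    ses[[arm]]$imu$gyro <- rbind(s$imu$gyro, matrix(0, n_iq, 3))
  }
  after <- segment_stream(ses)
  expect_equal(vapply(after, `[[`, 0, "start_t"),
               vapply(before, `[[`, 0, "start_t"))
  expect_equal(vapply(after, `[[`, 0, "end_t"),
               vapply(before, `[[`, 0, "end_t"))
})

test_that("min_duration_filter keeps exactly the long-enough segments", {
  mk <- function(len) structure(list(start_t = 0, end_t = len),
                                class = "sign_segment")
  segs <- list(mk(0.3), mk(0.5))
  expect_length(min_duration_filter(segs, 0.4), 1L)
  expect_equal(min_duration_filter(segs, 0.4)[[1]]$end_t, 0.5)
  expect_length(min_duration_filter(segs, 0), 2L)
  set.seed(3)
  lens <- runif(50, 0, 1)
  segs <- lapply(lens, mk)
  brute <- sum(lens >= 0.4)
  expect_length(min_duration_filter(segs, 0.4), brute)
  expect_warning(segment_stream_warn <- min_duration_filter(segs, 0.4, warn = TRUE),
                 "discarded")
})

test_that("segments serialize to a BED-like TSV", {
  tpl <- make_sign_templates(2, seed = 1)
  ses <- synthesize_session(tpl, reps = 1, rest_ms = 300, seed = 1)
  segs <- segment_stream(ses)
  path <- tempfile(fileext = ".tsv")
  write_segments_tsv(segs, path)
  df <- read.delim(path)
  expect_equal(nrow(df), length(segs))
  expect_named(df, c("start_s", "end_s", "trigger_source", "label"))
})
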