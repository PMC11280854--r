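# Seeded synthetic two-armband sessions.
#
# Stands in for the access-restricted human recordings: per-sign smooth EMG
# activation envelopes modulating an alternating carrier plus Gaussian noise
# (quantized to the device's [-127, 128] integer range), and smooth
# orientation trajectories interpolated through seeded waypoints, with rest
# gaps that are exactly quiet so the segmenter can be tested end-to-end.

EMG_FS <- 200
IMU_FS <- 50
EMG_LO <- -127
EMG_HI <- 128

# 80 frequent everyday words (greetings, family, pronouns, verbs, question
# words, daily life) in Turkish, mirroring the kind of dictionary a sign
# vocabulary test uses. Extended programmatically beyond 80.
default_words <- c(
  "merhaba", "sevindim", "görüşürüz", "tanışmak",
  "anne", "baba", "abi", "abla", "kardeş", "aile",
  "ben", "sen", "o", "biz", "siz", "onlar",
  "gel", "git", "al", "ver", "yap", "bak", "otur", "kalk", "ye", "iç",
  "ne", "neden", "nasıl", "nerede", "kim", "hangi",
  "ev", "isim", "iyi", "kötü", "sıcak", "soğuk", "kolay", "zor",
  "evli", "yıl", "gün", "gece", "sabah", "akşam", "bugün", "yarın",
  "su", "ekmek", "para", "okul", "iş", "araba", "yol", "şehir",
  "büyük", "küçük", "uzun", "kısa", "yeni", "eski",
  "evet", "hayır", "lütfen", "teşekkür", "özür", "yardım",
  "sağlık", "hasta", "doktor", "aç", "tok", "mutlu", "üzgün",
  "sevmek", "istemek", "bilmek", "anlamak", "beklemek"
)

word_list <- function(n) {
  if (n <= length(default_words)) return(default_words[seq_len(n)])
  c(default_words, sprintf("isaret%03d", seq_len(n - length(default_words))))
}

#' Create seeded sign templates
#'
#' A template is the generative description of one sign: per-channel EMG
#' activation envelopes (a baseline plateau plus 1-3 Gaussian bumps) for the
#' 16 EMG channels, and per-arm orientation waypoints interpolated smoothly
#' during synthesis. Templates are pairwise distinct and deterministic for a
#' given seed.
#'
#' @param n_signs number of templates (>= 1)
#' @param seed integer seed; all template parameters derive from it
#' @return list of `sign_template` objects, one per word
#' @export
#' @examples
#' tpl <- make_sign_templates(3, seed = 1)
#' tpl[[1]]$word
make_sign_templates <- function(n_signs, seed = 1) {
  if (!is.numeric(n_signs) || length(n_signs) != 1L || !is.finite(n_signs) || n_signs < 1)
    stop_invalid("`n_signs` must be >= 1")
  n_signs <- as.integer(n_signs)
  words <- word_list(n_signs)
  with_seed(seed, lapply(seq_len(n_signs), function(i) {
    emg <- lapply(seq_len(16L), function(ch) {
      # Channel 1 of each arm carries a strong plateau so sign onsets and
      # offsets step past the default EMG threshold (40) in one 5 ms frame.
      base <- if (ch %in% c(1L, 9L)) runif(1, 48, 64) else runif(1, 8, 34)
      nb <- sample(1:3, 1L)
      list(base = base,
           centers = runif(nb, 0.1, 0.9),
           widths = runif(nb, 0.04, 0.15),
           amps = runif(nb, 20, 70))
    })
    orient <- lapply(c("left", "right"), function(arm) {
      k <- sample(2:4, 1L)
      # Interior Euler waypoints (degrees); pitch kept off gimbal lock.
      cbind(roll = runif(k, -60, 60),
            pitch = runif(k, -55, 55),
            yaw = runif(k, -60, 60))
    })
    names(orient) <- c("left", "right")
    structure(list(word = words[i],
                   duration = round(runif(1, 0.9, 1.5) / 0.02) * 0.02,
                   emg = emg, orient = orient),
              class = "sign_template")
  }))
}

# Evaluate a channel envelope at normalized times u in [0, 1).
envelope_at <- function(par, u) {
  v <- rep(par$base, length(u))
  for (j in seq_along(par$centers))
    v <- v + par$amps[j] * exp(-(u - par$centers[j])^2 / (2 * par$widths[j]^2))
  v
}

# Smoothstep easing so interpolated orientation has zero angular velocity at
# waypoints (and hence at sign boundaries, where it meets the rest pose).
smoothstep <- function(u) u * u * (3 - 2 * u)

# Orientation trajectory through identity -> waypoints -> identity.
orientation_track <- function(waypoints_euler, u) {
  wp <- rbind(c(0, 0, 0), waypoints_euler, c(0, 0, 0))
  qs <- euler_to_quat_m(wp)
  k <- nrow(qs) - 1L
  seg <- pmin(floor(u * k), k - 1L)
  frac <- smoothstep(u * k - seg)
  out <- matrix(0, length(u), 4L)
  for (s in unique(seg)) {
    idx <- seg == s
    out[idx, ] <- quat_slerp(qs[s + 1L, ], qs[s + 2L, ], frac[idx])
  }
  out
}

armband_stream <- function(device_id, emg_t, emg_values, imu_t, accel, gyro,
                           orientation) {
  structure(list(device_id = device_id,
                 emg = list(t = emg_t, values = emg_values),
                 imu = list(t = imu_t, accel = accel, gyro = gyro,
                            orientation = orientation),
                 emg_fs = EMG_FS, imu_fs = IMU_FS),
            class = "armband_stream")
}

#' Synthesize one two-armband recording of a sign
#'
#' EMG per channel is the template envelope times an alternating unit carrier
#' plus Gaussian noise of standard deviation `noise_level` (EMG units),
#' rounded and clipped to the device range \[-127, 128\]. Orientation follows
#' the template waypoint trajectory; gyroscope and accelerometer are derived
#' from it (finite-difference angular rate; gravity rotated into the sensor
#' frame) plus small noise. `speed_factor` time-warps the whole sign.
#'
#' @param template a `sign_template`
#' @param speed_factor positive time-warp factor (>1 = faster/shorter)
#' @param noise_level EMG noise standard deviation in EMG units (>= 0)
#' @param seed integer seed
#' @return a `two_arm_recording` with fields `left`, `right`, `label`,
#'   `duration`
#' @export
synthesize_recording <- function(template, speed_factor = 1, noise_level = 0,
                                 seed = 1) {
  stopifnot(inherits(template, "sign_template"))
  check_scalar_num(speed_factor, "speed_factor")
  check_scalar_num(noise_level, "noise_level")
  if (speed_factor <= 0) stop_invalid("`speed_factor` must be positive")
  if (noise_level < 0) stop_invalid("`noise_level` must be >= 0")
  d <- max(0.4, round(template$duration / speed_factor / 0.02) * 0.02)
  n_emg <- round(EMG_FS * d)
  n_imu <- round(IMU_FS * d)
  emg_t <- (seq_len(n_emg) - 1L) / EMG_FS
  imu_t <- (seq_len(n_imu) - 1L) / IMU_FS
  u_emg <- emg_t / d
  u_imu <- imu_t / d
  carrier <- rep_len(c(1, -1), n_emg)
  with_seed(seed, {
    arms <- lapply(c(left = 1L, right = 2L), function(a) {
      chans <- (a - 1L) * 8L + 1:8
      vals <- vapply(chans, function(ch) {
        v <- envelope_at(template$emg[[ch]], u_emg) * carrier
        if (noise_level > 0) v <- v + rnorm(n_emg, 0, noise_level)
        as.integer(pmin(EMG_HI, pmax(EMG_LO, round(v))))
      }, integer(n_emg))
      q <- orientation_track(template$orient[[a]], u_imu)
      if (noise_level > 0) {
        jitter <- matrix(rnorm(n_imu * 3L, 0, noise_level * 0.02), n_imu, 3L)
        q <- t(vapply(seq_len(n_imu), function(i)
          quat_multiply(q[i, ], euler_to_quat_m(jitter[i, , drop = FALSE])[1L, ]),
          numeric(4L)))
        q <- q / sqrt(rowSums(q^2))
      }
      dt <- 1 / IMU_FS
      gyro <- matrix(0, n_imu, 3L)
      if (n_imu > 1L) {
        for (i in seq_len(n_imu - 1L)) {
          dq <- quat_multiply(quat_conjugate(q[i, ]), q[i + 1L, ])
          gyro[i, ] <- 2 * dq[2:4] * sign(dq[1L]) / dt
        }
        gyro[n_imu, ] <- gyro[n_imu - 1L, ]
      }
      accel <- quat_rotate_inv(q, c(0, 0, 1))
      if (noise_level > 0) {
        accel <- accel + matrix(rnorm(n_imu * 3L, 0, noise_level * 0.002), n_imu, 3L)
        gyro <- gyro + matrix(rnorm(n_imu * 3L, 0, noise_level * 0.005), n_imu, 3L)
      }
      armband_stream(c("left", "right")[a], emg_t, vals, imu_t, accel, gyro, q)
    })
    structure(list(left = arms$left, right = arms$right,
                   label = template$word, duration = d),
              class = "two_arm_recording")
  })
}

#' Total raw scalar samples stored for a recording
#'
#' Counts every stored scalar across both armbands: 8 EMG values per 200 Hz
#' frame plus 10 IMU values (3 accel, 3 gyro, 4 orientation) per 50 Hz frame,
#' i.e. 4200 per second of recording.
#'
#' @param rec a `two_arm_recording`
#' @return integer count of raw scalars
#' @export
raw_scalar_count <- function(rec) {
  stopifnot(inherits(rec, "two_arm_recording"))
  n <- 0L
  for (arm in list(rec$left, rec$right))
    n <- n + length(arm$emg$values) + 10L * length(arm$imu$t)
  n
}

#' Synthesize a continuous session with rest gaps
#'
#' Places one recording per template per repetition sequentially on a common
#' clock, separated by rest blocks in which EMG is constant zero (zero
#' frame-to-frame delta) and orientation holds the rest pose, so no motion
#' predicate can fire. Returns the streams plus ground-truth annotations for
#' oracle comparison with the segmenter.
#'
#' @param templates list of `sign_template`
#' @param reps repetitions of the full template cycle
#' @param rest_ms rest-gap length in ms; must exceed `config$pause_ms`
#' @param config a [segmenter_config()] the session is intended for
#' @param seed integer seed
#' @param noise_level EMG noise sd during signs (rests stay exactly quiet)
#' @param speed_range range per-recording speed factors are drawn from
#' @return a `session`: list with `left`, `right` (`armband_stream`) and
#'   `annotations` (data.frame start, end, word)
#' @export
synthesize_session <- function(templates, reps = 1, rest_ms = 500,
                               config = segmenter_config(), seed = 1,
                               noise_level = 0, speed_range = c(1, 1)) {
  if (inherits(templates, "sign_template")) templates <- list(templates)
  stopifnot(length(templates) >= 1L, reps >= 1)
  if (rest_ms <= config$pause_ms)
    stop_invalid("`rest_ms` must exceed the segmenter pause (",
                 config$pause_ms, " ms)")
  rest_d <- ceiling(rest_ms / 20) * 0.02
  n_total <- length(templates) * reps
  subseeds <- draw_subseeds(seed, n_total + 1L)
  speeds <- with_seed(subseeds[n_total + 1L],
                      runif(n_total, speed_range[1L], speed_range[2L]))
  order_idx <- rep(seq_along(templates), times = reps)

  rest_emg <- matrix(0L, round(EMG_FS * rest_d), 8L)
  n_rimu <- round(IMU_FS * rest_d)
  rest_q <- matrix(rep(c(1, 0, 0, 0), each = n_rimu), n_rimu, 4L)
  rest_accel <- matrix(rep(c(0, 0, 1), each = n_rimu), n_rimu, 3L)
  rest_gyro <- matrix(0, n_rimu, 3L)

  pieces <- list(left = list(), right = list())
  ann <- data.frame(start = numeric(0), end = numeric(0), word = character(0),
                    stringsAsFactors = FALSE)
  t_cursor <- 0
  add_rest <- function() {
    for (arm in c("left", "right"))
      pieces[[arm]][[length(pieces[[arm]]) + 1L]] <<-
        list(emg = rest_emg, accel = rest_accel, gyro = rest_gyro, q = rest_q)
    t_cursor <<- t_cursor + rest_d
  }
  add_rest()
  for (i in seq_len(n_total)) {
    rec <- synthesize_recording(templates[[order_idx[i]]], speeds[i],
                                noise_level, subseeds[i])
    for (arm in c("left", "right")) {
      s <- rec[[arm]]
      pieces[[arm]][[length(pieces[[arm]]) + 1L]] <-
        list(emg = s$emg$values, accel = s$imu$accel, gyro = s$imu$gyro,
             q = s$imu$orientation)
    }
    ann <- rbind(ann, data.frame(start = t_cursor, end = t_cursor + rec$duration,
                                 word = rec$label, stringsAsFactors = FALSE))
    t_cursor <- t_cursor + rec$duration
    add_rest()
  }
  streams <- lapply(c("left", "right"), function(arm) {
    emg <- do.call(rbind, lapply(pieces[[arm]], `[[`, "emg"))
    accel <- do.call(rbind, lapply(pieces[[arm]], `[[`, "accel"))
    gyro <- do.call(rbind, lapply(pieces[[arm]], `[[`, "gyro"))
    q <- do.call(rbind, lapply(pieces[[arm]], `[[`, "q"))
    armband_stream(arm, (seq_len(nrow(emg)) - 1L) / EMG_FS, emg,
                   (seq_len(nrow(q)) - 1L) / IMU_FS, accel, gyro, q)
  })
  structure(list(left = streams[[1L]], right = streams[[2L]],
                 annotations = ann),
            class = "session")
}

#' Synthesize a labelled dataset of sign recordings
#'
#' Emulates the recording protocol of an n-word dictionary repeated `reps`
#' times: every (sign, repetition) pair yields one `two_arm_recording`, with
#' a per-recording speed factor drawn from `speed_range` (default 0.8-1.25,
#' emulating signer speed variability) and EMG noise `noise_level`.
#'
#' @param n_signs number of distinct signs (>= 1)
#' @param reps recordings per sign (>= 1)
#' @param noise_level EMG noise sd in EMG units (default 8, moderate)
#' @param seed integer seed
#' @param speed_range per-recording speed factor range
#' @return a `sign_dataset` (recordings populated, features `NULL` until
#'   [extract_features()] is called)
#' @export
#' @examples
#' ds <- synthesize_dataset(2, 3, noise_level = 0, seed = 1)
#' length(ds$recordings)  # 6
synthesize_dataset <- function(n_signs, reps, noise_level = 8, seed = 1,
                               speed_range = c(0.8, 1.25)) {
  if (!is.numeric(n_signs) || n_signs < 1 || !is.numeric(reps) || reps < 1)
    stop_invalid("`n_signs` and `reps` must be >= 1")
  n_signs <- as.integer(n_signs); reps <- as.integer(reps)
  templates <- make_sign_templates(n_signs, seed)
  n_total <- n_signs * reps
  subseeds <- draw_subseeds(seed + 1, n_total + 1L)
  speeds <- with_seed(subseeds[n_total + 1L],
                      runif(n_total, speed_range[1L], speed_range[2L]))
  recordings <- vector("list", n_total)
  k <- 0L
  for (i in seq_len(n_signs)) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      rec <- synthesize_recording(templates[[i]], speeds[k], noise_level,
                                  subseeds[k])
      rec$rep <- r
      recordings[[k]] <- rec
    }
  }
  sign_dataset(dictionary = vapply(templates, `[[`, "", "word"),
               recordings = recordings)
}

#' Construct a sign dataset container
#'
#' @param dictionary character vector of unique sign words
#' @param recordings list of labelled `two_arm_recording`
#' @param features optional numeric feature matrix (one row per recording)
#' @param labels optional labels for the feature rows
#' @return a `sign_dataset`
#' @export
sign_dataset <- function(dictionary, recordings = list(), features = NULL,
                         labels = NULL) {
  dictionary <- as.character(dictionary)
  if (anyDuplicated(dictionary)) stop_invalid("dictionary words must be unique")
  labs <- vapply(recordings, `[[`, "", "label")
  if (length(labs) && !all(labs %in% dictionary))
    stop_invalid("every recording label must be in the dictionary")
  if (!is.null(features) && !all(labels %in% dictionary))
    stop_invalid("every feature label must be in the dictionary")
  structure(list(dictionary = dictionary, recordings = recordings,
                 features = features, labels = labels),
            class = "sign_dataset")
}

#' @export
print.sign_dataset <- function(x, ...) {
  cat(sprintf("<sign_dataset> %d words, %d recordings, %s feature rows\n",
              length(x$dictionary), length(x$recordings),
              if (is.null(x$features)) "no" else nrow(x$features)))
  invisible(x)
}

#' @export
print.two_arm_recording <- function(x, ...) {
  cat(sprintf("<two_arm_recording> '%s', %.2f s, %d raw scalars\n",
              x$label, x$duration, raw_scalar_count(x)))
  invisible(x)
}
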