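# Synthetic audiences: stimulus-coupled inhomogeneous point processes for
# heartbeats and breaths, with boundary-locked orienting responses. The
# generator is the ground-truth side of every round-trip test downstream.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify synthetic audience members
#'
#' One row per participant. Base rhythms default to the neighbourhood of the
#' population means for seated adults listening to music: heart ~1.01 Hz,
#' respiration ~0.30 Hz. `coupling_gain` is the rate modulation (BPM per unit
#' of normalised spectral flux) applied at `lag_ms` after the stimulus;
#' `orienting_depth_bpm` is the depth of the deceleration–acceleration dip at
#' section boundaries; `noise_sd_bpm` scales slow stochastic rate wander.
#'
#' @param n Number of participants.
#' @param base_heart_hz,base_resp_hz Baseline cycle frequencies (Hz);
#'   vectors are recycled to length `n`. Heart must exceed respiration.
#' @param coupling_gain BPM per unit normalised flux (>= 0).
#' @param lag_ms Stimulus-to-heart-rate lag (ms, >= 0, less than one mean
#'   heart cycle).
#' @param resp_lag_ms Stimulus-to-respiration-rate lag (ms, less than one
#'   mean respiration cycle).
#' @param resp_coupling_scale,resp_orienting_scale Fractions of the heart
#'   coupling gain / orienting depth applied to respiration.
#' @param orienting_depth_bpm Peak magnitude of the boundary dip (BPM).
#' @param noise_sd_bpm Standard deviation of smooth rate noise (BPM).
#' @param seed Integer seed per participant (recycled with offsets).
#' @param id Participant identifiers.
#' @return Tibble of class `participant_specs`, one row per participant.
#' @export
participant_specs <- function(n,
                              base_heart_hz = 1.01,
                              base_resp_hz = 0.30,
                              coupling_gain = 1,
                              lag_ms = 600,
                              resp_lag_ms = 1600,
                              resp_coupling_scale = 0.5,
                              resp_orienting_scale = 0.3,
                              orienting_depth_bpm = 0.5,
                              noise_sd_bpm = 1.5,
                              seed = seq_len(n),
                              id = sprintf("p%02d", seq_len(n))) {
  out <- tibble::tibble(
    participant_id = rep_len(as.character(id), n),
    base_heart_hz = rep_len(base_heart_hz, n),
    base_resp_hz = rep_len(base_resp_hz, n),
    coupling_gain = rep_len(coupling_gain, n),
    lag_ms = rep_len(lag_ms, n),
    resp_lag_ms = rep_len(resp_lag_ms, n),
    resp_coupling_scale = rep_len(resp_coupling_scale, n),
    resp_orienting_scale = rep_len(resp_orienting_scale, n),
    orienting_depth_bpm = rep_len(orienting_depth_bpm, n),
    noise_sd_bpm = rep_len(noise_sd_bpm, n),
    seed = rep_len(as.integer(seed), n)
  )
  if (any(out$base_heart_hz <= out$base_resp_hz)) {
    abort("base_heart_hz must exceed base_resp_hz for every participant")
  }
  if (any(out$lag_ms < 0) || any(out$coupling_gain < 0) ||
      any(out$orienting_depth_bpm < 0) || any(out$noise_sd_bpm < 0)) {
    abort("coupling_gain, lag_ms, orienting_depth_bpm, noise_sd_bpm must be >= 0")
  }
  if (any(out$lag_ms / 1000 >= 1 / out$base_heart_hz)) {
    abort("lag_ms must be below one mean heart cycle")
  }
  class(out) <- c("participant_specs", class(out))
  out
}

#' Draw a heterogeneous audience
#'
#' Participants with base rates jittered around the population means, for
#' realistic between-subject variability (heart sd 0.04 Hz, respiration sd
#' 0.015 Hz).
#'
#' @inheritParams participant_specs
#' @param seed Seed for the draw (also seeds each participant's noise).
#' @param ... Passed on to [participant_specs()].
#' @return A `participant_specs` tibble.
#' @export
draw_audience <- function(n, seed = 1, ...) {
  with_local_seed(seed, {
    heart <- pmax(0.7, rnorm(n, 1.01, 0.04))
    resp <- pmax(0.15, pmin(rnorm(n, 0.30, 0.015), heart - 0.3))
    participant_specs(n, base_heart_hz = heart, base_resp_hz = resp,
                      seed = seed * 1000L + seq_len(n), ...)
  })
}

# Raised-cosine deceleration-acceleration dip: rate falls over the 10 s into
# the boundary and recovers over the 10 s after it, minimum -depth at the
# boundary itself. Summed over boundaries.
orienting_waveform <- function(t, boundary_times_s, depth_bpm, half_span_s = 10) {
  o <- numeric(length(t))
  for (b in boundary_times_s) {
    idx <- which(abs(t - b) <= half_span_s)
    if (length(idx)) {
      o[idx] <- o[idx] - depth_bpm / 2 * (1 + cos(pi * (t[idx] - b) / half_span_s))
    }
  }
  o
}

# Smooth noise: white noise on a 2 Hz grid, spline-interpolated to the
# generation grid, rescaled to the requested sd.
smooth_noise <- function(t, sd_bpm) {
  if (sd_bpm == 0) return(numeric(length(t)))
  knots <- seq(min(t), max(t), by = 0.5)
  z <- rnorm(length(knots))
  x <- stats::spline(knots, z, xout = t)$y
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) return(numeric(length(t)))
  x * (sd_bpm / s)
}

# Normalised stimulus drive: z-scored flux low-passed at 0.5 Hz (zero-phase,
# so the drive stays time-locked to the flux it smooths) on the 20 Hz grid.
normalized_drive <- function(stimulus, fs_out = 20) {
  fx <- flux_to_grid(spectral_flux(stimulus), fs_out = fs_out,
                     duration_s = stimulus$duration_s)
  x <- fx$flux
  if (sd(x) > 0) x <- (x - mean(x)) / sd(x) else x <- x * 0
  lp <- signal::butter(4, 0.5 / (fs_out / 2), type = "low")
  tibble::tibble(time_s = fx$time_s, drive = zero_phase_filter(lp, x))
}

# Time-rescaling point process: emit a peak each time the integral of
# rate(t)/60 since the last peak reaches 1. Crossing times by linear
# interpolation of the cumulative integral.
peaks_from_rate <- function(t, rate_bpm) {
  if (any(rate_bpm <= 0)) abort("rate must stay positive everywhere")
  dt <- diff(t)
  cum <- c(0, cumsum((rate_bpm[-1] + rate_bpm[-length(rate_bpm)]) / 2 * dt)) / 60
  targets <- seq_len(floor(cum[length(cum)]))
  if (!length(targets)) return(numeric())
  idx <- pmin(findInterval(targets, cum), length(cum) - 1L)
  frac <- (targets - cum[idx]) / (cum[idx + 1] - cum[idx])
  t[idx] + frac * (t[idx + 1] - t[idx])
}

#' Generate heartbeat and breath peak trains for an audience
#'
#' Each participant's instantaneous rate is
#' `base + coupling_gain * drive(t - lag) + orienting(t) + smooth noise`,
#' where `drive` is normalised (z-scored, 0.5 Hz low-passed) spectral flux of
#' the stimulus, and `orienting` is the boundary-locked deceleration-
#' acceleration dip (applied only when `enable_orienting` is `TRUE`, e.g. in
#' the audio-visual condition). Peak trains are realised by time-rescaling,
#' so rate modulation maps exactly onto inter-beat intervals.
#'
#' @param stimulus A `stimulus` from [generate_stimulus()].
#' @param participants A [participant_specs()] tibble (>= 2 rows for group
#'   measures; 1 row is allowed for single-participant fixtures).
#' @param condition `"AV"` or `"AO"`.
#' @param enable_orienting Whether boundary orienting responses are active;
#'   defaults to `TRUE` in the AV condition only.
#' @param fs_gen Internal rate-grid frequency (Hz).
#' @return List with `peaks` (tibble: `participant_id`, `condition`,
#'   `signal` in heart/resp, `peak_time_s`) and `ground_truth` (one row per
#'   participant with the true parameters and flags).
#' @export
generate_audience <- function(stimulus, participants,
                              condition = c("AV", "AO"),
                              enable_orienting = NULL,
                              fs_gen = 100) {
  condition <- match.arg(condition)
  stopifnot(inherits(participants, "participant_specs"))
  enable_orienting <- enable_orienting %||% (condition == "AV")
  dur <- stimulus$duration_s
  t <- seq(0, dur, by = 1 / fs_gen)
  drv <- normalized_drive(stimulus)
  boundaries <- stimulus$boundaries$boundary_time_s

  one <- function(row) {
    drive_heart <- approx(drv$time_s + row$lag_ms / 1000, drv$drive,
                          xout = t, rule = 2)$y
    drive_resp <- approx(drv$time_s + row$resp_lag_ms / 1000, drv$drive,
                         xout = t, rule = 2)$y
    orient <- if (enable_orienting && length(boundaries)) {
      orienting_waveform(t, boundaries, row$orienting_depth_bpm)
    } else numeric(length(t))
    with_local_seed(row$seed, {
      noise_h <- smooth_noise(t, row$noise_sd_bpm)
      noise_r <- smooth_noise(t, row$noise_sd_bpm * 0.3)
      rate_h <- row$base_heart_hz * 60 + row$coupling_gain * drive_heart +
        orient + noise_h
      rate_r <- row$base_resp_hz * 60 +
        row$coupling_gain * row$resp_coupling_scale * drive_resp +
        row$resp_orienting_scale * orient + noise_r
      list(heart = peaks_from_rate(t, rate_h),
           resp = peaks_from_rate(t, rate_r))
    })
  }

  rows <- split(participants, seq_len(nrow(participants)))
  trains <- purrr::map(rows, one)
  peaks <- purrr::map2_dfr(rows, trains, function(row, tr) {
    tibble::tibble(
      participant_id = row$participant_id,
      condition = condition,
      signal = rep(c("heart", "resp"), c(length(tr$heart), length(tr$resp))),
      peak_time_s = c(tr$heart, tr$resp)
    )
  })
  ground_truth <- dplyr::mutate(
    tibble::as_tibble(participants),
    condition = condition,
    orienting_applied = enable_orienting,
    piece_id = stimulus$piece_id
  )
  list(peaks = peaks, ground_truth = ground_truth)
}

#' Render peak trains to continuous 1000 Hz signals
#'
#' ECG-like signal: a QRS-like template (narrow R spike with small Q/S
#' deflections) plus a low, wide T-like bump 250 ms after each R peak, over
#' Gaussian baseline noise. Respiration-like signal: piecewise cosine, value
#' 1 at each inspiration peak and minimum at mid-cycle. Both exercise the
#' preprocessing chain end-to-end.
#'
#' @param heart_peaks,resp_peaks Numeric peak times (s).
#' @param duration_s Signal span.
#' @param fs_hz Sampling rate; must be at least 200 Hz for the template.
#' @param noise_sd Baseline noise sd (signal units).
#' @param t_wave_amp T-bump amplitude relative to the R spike.
#' @param seed Seed for baseline noise.
#' @param ids Named list of metadata columns carried on the recordings
#'   (participant_id, concert_id, piece_id, condition).
#' @return List with `heart` and `resp`, each a [raw_recording()].
#' @export
render_waveforms <- function(heart_peaks, resp_peaks, duration_s,
                             fs_hz = 1000, noise_sd = 0.01,
                             t_wave_amp = 0.25, seed = 1, ids = list()) {
  if (fs_hz < 200) abort("fs_hz too low for the QRS template bandwidth")
  n <- round(duration_s * fs_hz) + 1
  tt <- (seq_len(n) - 1) / fs_hz
  ecg <- numeric(n)
  add_bump <- function(sig, center, amp, width_s) {
    idx <- which(abs(tt - center) <= 4 * width_s)
    sig[idx] <- sig[idx] + amp * exp(-((tt[idx] - center)^2) / (2 * width_s^2))
    sig
  }
  for (p in heart_peaks) {
    ecg <- add_bump(ecg, p, 1, 0.008)            # R
    ecg <- add_bump(ecg, p - 0.025, -0.15, 0.006) # Q
    ecg <- add_bump(ecg, p + 0.025, -0.15, 0.006) # S
    ecg <- add_bump(ecg, p + 0.25, t_wave_amp, 0.05) # T
  }
  resp <- numeric(n)
  if (length(resp_peaks) >= 2) {
    ibr <- diff(resp_peaks)
    k <- findInterval(tt, resp_peaks)
    # continue the first/last cycle's phase beyond the end peaks so no
    # spurious maximum is fabricated at the piece edges
    k <- pmax(1, pmin(k, length(ibr)))
    phase <- 2 * pi * (tt - resp_peaks[k]) / ibr[k]
    # clamp at mid-cycle outside the end peaks (exhale plateau) so rendered
    # maxima correspond one-to-one with manifest peaks
    phase[tt < resp_peaks[1]] <- pmax(phase[tt < resp_peaks[1]], -pi)
    last <- resp_peaks[length(resp_peaks)]
    phase[tt > last] <- pmin(phase[tt > last], pi)
    resp <- cos(phase)
  } else if (length(resp_peaks) == 1) {
    resp <- cos(2 * pi * (tt - resp_peaks) * 0.3)
  }
  with_local_seed(seed, {
    ecg <- ecg + rnorm(n, 0, noise_sd)
    resp <- resp + rnorm(n, 0, noise_sd)
  })
  make <- function(x, channel) {
    do.call(raw_recording,
            c(list(samples = x, fs_hz = fs_hz, channel = channel), ids))
  }
  list(heart = make(ecg, "heart"), resp = make(resp, "resp"))
}
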