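#' Describe a synthetic stimulus
#'
#' A stimulus specification stands in for one music piece: a schedule of
#' pure-tone segments (each change of tone produces a spectral-flux peak at a
#' known time) plus annotated section boundaries.
#'
#' @param duration_s Piece duration in seconds.
#' @param boundary_times_s Strictly increasing section-boundary onsets in
#'   seconds, inside `(0, duration_s)`.
#' @param tone_schedule Tibble from [tone_schedule()]: columns `onset_s`,
#'   `freq_hz`, `amplitude`. Each tone sounds from its onset until the next
#'   onset (or the end of the piece). May be empty (silence).
#' @param sample_rate_hz Audio sampling rate; synthetic audio defaults to
#'   8000 Hz mono, which keeps short-time analysis cheap while leaving
#'   plenty of spectral headroom for pure tones.
#' @param piece_id Identifier used in annotation tables.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(duration_s,
                          boundary_times_s = numeric(),
                          tone_schedule = NULL,
                          sample_rate_hz = 8000,
                          piece_id = "piece1") {
  stopifnot(duration_s > 0, sample_rate_hz > 0)
  if (is.null(tone_schedule)) {
    tone_schedule <- tibble::tibble(onset_s = numeric(), freq_hz = numeric(),
                                    amplitude = numeric())
  }
  boundary_times_s <- as.numeric(boundary_times_s)
  check_strictly_increasing(boundary_times_s, "boundary times")
  if (length(boundary_times_s) &&
      (min(boundary_times_s) <= 0 || max(boundary_times_s) >= duration_s)) {
    abort("boundary times must lie strictly inside (0, duration_s)")
  }
  if (anyDuplicated(tone_schedule$onset_s)) {
    abort("tone onsets must be unique (overlapping tones are not supported)")
  }
  if (nrow(tone_schedule) && (min(tone_schedule$onset_s) < 0 ||
                              max(tone_schedule$onset_s) >= duration_s)) {
    abort("tone onsets must lie within [0, duration_s)")
  }
  structure(
    list(duration_s = duration_s,
         boundary_times_s = boundary_times_s,
         tone_schedule = dplyr::arrange(tone_schedule, .data$onset_s),
         sample_rate_hz = sample_rate_hz,
         piece_id = piece_id),
    class = "stimulus_spec"
  )
}

#' @rdname stimulus_spec
#' @param onset_s,freq_hz,amplitude Vectors (recycled to common length)
#'   describing tone segments.
#' @export
tone_schedule <- function(onset_s, freq_hz, amplitude = 1) {
  tibble::tibble(onset_s = as.numeric(onset_s),
                 freq_hz = as.numeric(freq_hz),
                 amplitude = as.numeric(amplitude))
}

#' Render a stimulus specification to audio plus boundary annotations
#'
#' Tones are rendered as phase-continuous sinusoids whose frequency and
#' amplitude switch at schedule onsets, so the spectrum is stationary within
#' a segment and changes abruptly at segment starts — giving spectral flux a
#' known peak at every scheduled change. An empty schedule yields silence.
#'
#' @param spec A [stimulus_spec()].
#' @return A list of class `stimulus` with elements `wave` (numeric samples
#'   in \[-1, 1\]), `fs_hz`, `duration_s`, `boundaries` (tibble `piece_id`,
#'   `boundary_time_s`, `section_label`) and `piece_id`.
#' @export
generate_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  fs <- spec$sample_rate_hz
  n <- round(spec$duration_s * fs)
  wave <- numeric(n)
  sched <- spec$tone_schedule
  if (nrow(sched)) {
    starts <- round(sched$onset_s * fs) + 1
    ends <- c(starts[-1] - 1, n)
    for (k in seq_len(nrow(sched))) {
      idx <- seq(starts[k], ends[k])
      tt <- (idx - 1) / fs
      wave[idx] <- sched$amplitude[k] * sin(2 * pi * sched$freq_hz[k] * tt)
    }
    peak <- max(abs(wave))
    if (peak > 1) wave <- wave / peak
  }
  nb <- length(spec$boundary_times_s)
  boundaries <- tibble::tibble(
    piece_id = rep(spec$piece_id, nb),
    boundary_time_s = spec$boundary_times_s,
    section_label = if (nb) paste0("S", seq_len(nb)) else character()
  )
  structure(
    list(wave = wave, fs_hz = fs, duration_s = spec$duration_s,
         boundaries = boundaries, piece_id = spec$piece_id),
    class = "stimulus"
  )
}

#' Random tone schedule with irregular change times
#'
#' Convenience builder for stimuli whose spectral flux has broadband,
#' irregular structure (tone changes every `min_step`–`max_step` seconds with
#' varying amplitudes), which is what the stimulus-coupled response model and
#' the lag-recovery procedure need.
#'
#' @param duration_s Piece duration.
#' @param min_step,max_step Bounds on the gap between tone changes (s).
#' @param freqs_hz Pool of tone frequencies to draw from.
#' @return A [tone_schedule()] tibble.
#' @export
random_tone_schedule <- function(duration_s, min_step = 0.5, max_step = 2,
                                 freqs_hz = c(220, 330, 440, 660, 880)) {
  onsets <- 0
  while (TRUE) {
    nxt <- onsets[length(onsets)] + runif(1, min_step, max_step)
    if (nxt >= duration_s - min_step / 2) break
    onsets <- c(onsets, nxt)
  }
  tone_schedule(
    onset_s = onsets,
    freq_hz = sample(freqs_hz, length(onsets), replace = TRUE),
    amplitude = runif(length(onsets), 0.3, 1)
  )
}
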