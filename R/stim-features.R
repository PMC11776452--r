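#' Spectral flux of an audio waveform
#'
#' Short-time spectral flux: the Euclidean distance between the magnitude
#' spectra of consecutive Hann-windowed frames (25 ms frames, 50% overlap by
#' default, the usual short-term acoustic-feature setting). The first frame
#' has flux 0 by convention. Flux tracks note onsets and spectrum changes and
#' serves as the stimulus feature against which physiological responses are
#' correlated.
#'
#' @param wave Numeric mono waveform, or a `stimulus` object.
#' @param fs_hz Audio sampling rate (ignored when `wave` is a `stimulus`).
#' @param frame_ms Frame length in milliseconds.
#' @param overlap Fractional frame overlap in \[0, 1).
#' @param rectify If `TRUE`, only spectral increases contribute (half-wave
#'   rectified flux); the default is the plain Euclidean distance.
#' @return A tibble of class `flux_series` with columns `time_s` (frame
#'   centers) and `flux`, and attributes `frame_rate_hz`, `frame_hop_s`,
#'   `band` (`"full"`), and `duration_s`.
#' @export
spectral_flux <- function(wave, fs_hz = NULL, frame_ms = 25, overlap = 0.5,
                          rectify = FALSE) {
  if (inherits(wave, "stimulus")) {
    fs_hz <- wave$fs_hz
    wave <- wave$wave
  }
  stopifnot(is.numeric(wave), !is.null(fs_hz), fs_hz > 0)
  L <- max(2L, round(fs_hz * frame_ms / 1000))
  hop <- max(1L, round(L * (1 - overlap)))
  n <- length(wave)
  if (n < L + hop) abort("audio shorter than two frames")
  starts <- seq(1L, n - L + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann
  frames <- matrix(wave[outer(seq_len(L) - 1L, starts, "+")], nrow = L)
  mag <- Mod(stats::mvfft(frames * win))[seq_len(floor(L / 2) + 1L), , drop = FALSE]
  d <- mag[, -1, drop = FALSE] - mag[, -ncol(mag), drop = FALSE]
  if (rectify) d <- pmax(d, 0)
  flux <- c(0, sqrt(colSums(d^2)))
  out <- tibble::tibble(
    time_s = (starts - 1 + L / 2) / fs_hz,
    flux = flux
  )
  structure(out,
            class = c("flux_series", class(out)),
            frame_rate_hz = fs_hz / hop,
            frame_hop_s = hop / fs_hz,
            band = "full",
            duration_s = n / fs_hz)
}

#' Resample a flux series onto the common 20 Hz analysis grid
#'
#' Applies an anti-alias low-pass (Butterworth, zero phase, cutoff at 80% of
#' the target Nyquist) at the native frame rate, then interpolates linearly
#' onto a uniform grid starting at the piece onset. Stimulus and response
#' series are aligned sample-for-sample on this grid.
#'
#' @param flux A `flux_series` from [spectral_flux()].
#' @param fs_out Output rate (Hz).
#' @param duration_s Grid extent; defaults to the audio duration.
#' @return Tibble with columns `time_s` and `flux`, attribute `fs_hz`.
#' @export
flux_to_grid <- function(flux, fs_out = 20, duration_s = NULL) {
  stopifnot(inherits(flux, "flux_series"))
  frame_rate <- attr(flux, "frame_rate_hz")
  duration_s <- duration_s %||% attr(flux, "duration_s")
  x <- flux$flux
  if (frame_rate > 2 * fs_out) {
    lp <- signal::butter(4, (0.8 * fs_out / 2) / (frame_rate / 2), type = "low")
    x <- zero_phase_filter(lp, x)
  }
  t_out <- seq(0, duration_s, by = 1 / fs_out)
  out <- tibble::tibble(
    time_s = t_out,
    flux = approx(flux$time_s, x, xout = t_out, rule = 2)$y
  )
  attr(out, "fs_hz") <- fs_out
  attr(out, "band") <- attr(flux, "band")
  out
}

#' Audience frequency band from participants' mean rates
#'
#' The interquartile range (linear-interpolation quantiles) of the retained
#' participants' mean heart or respiration frequencies, used to band-limit
#' spectral flux before phase extraction so that stimulus rhythms are
#' compared only at rates the audience's physiology actually occupies. A
#' degenerate band (all participants identical) is widened by ±0.05 Hz and
#' flagged.
#'
#' @param mean_rates_hz One mean frequency (Hz) per retained participant.
#' @param widen_hz Half-width applied when the interquartile range collapses.
#' @return A list of class `frequency_band`: `lo_hz`, `hi_hz`, `provenance`.
#' @export
audience_band <- function(mean_rates_hz, widen_hz = 0.05) {
  stopifnot(is.numeric(mean_rates_hz), all(mean_rates_hz > 0))
  if (length(mean_rates_hz) < 4) {
    warn("audience_band(): fewer than 4 participants; band is poorly determined")
  }
  qs <- quantile(mean_rates_hz, c(0.25, 0.75), names = FALSE, type = 7)
  provenance <- "audience_iqr"
  if (diff(qs) <= 0) {
    qs <- qs + c(-widen_hz, widen_hz)
    provenance <- "audience_iqr_degenerate_widened"
  }
  frequency_band(qs[1], qs[2], provenance)
}

#' @rdname audience_band
#' @param lo_hz,hi_hz Band edges in Hz (`0 < lo_hz < hi_hz`).
#' @param provenance How the band was obtained.
#' @export
frequency_band <- function(lo_hz, hi_hz, provenance = "fixed") {
  stopifnot(lo_hz > 0, hi_hz > lo_hz)
  structure(list(lo_hz = lo_hz, hi_hz = hi_hz, provenance = provenance),
            class = "frequency_band")
}

#' Phase of band-limited spectral flux
#'
#' Band-passes the flux series inside an audience frequency band (Butterworth
#' 4th order, zero-phase) and takes the analytic-signal angle, yielding the
#' stimulus phase series for the phase-coherence measures. Filtering happens
#' on the 20 Hz analysis grid, where the narrow physiological bands are
#' numerically stable. Angle 0 falls at local maxima of the band-limited
#' flux (cosine convention), matching the peak-zero convention of the
#' physiological phase series.
#'
#' @param flux A `flux_series` (native frames) or a 20 Hz grid tibble from
#'   [flux_to_grid()].
#' @param band A [frequency_band()].
#' @param fs_out Analysis grid rate (Hz).
#' @param duration_s Grid extent; defaults to the audio duration.
#' @param low_power_ratio Flag threshold: if the band-limited RMS is below
#'   this fraction of the full-band (demeaned) RMS, the result carries
#'   attribute `low_power = TRUE`.
#' @return Tibble of class `phase_series` with columns `time_s`, `angle_rad`
#'   in (-pi, pi]; attributes `fs_hz`, `band`, `low_power`.
#' @export
subband_phase <- function(flux, band, fs_out = 20, duration_s = NULL,
                          low_power_ratio = 0.05) {
  stopifnot(inherits(band, "frequency_band"))
  grid <- if (inherits(flux, "flux_series")) {
    flux_to_grid(flux, fs_out = fs_out, duration_s = duration_s)
  } else {
    stopifnot(all(c("time_s", "flux") %in% names(flux)))
    flux
  }
  nyq <- fs_out / 2
  if (band$hi_hz >= nyq) abort("band upper edge must be below the grid Nyquist")
  bp <- signal::butter(4, c(band$lo_hz, band$hi_hz) / nyq, type = "pass")
  y <- zero_phase_filter(bp, grid$flux - mean(grid$flux))
  full_rms <- sd(grid$flux)
  low_power <- full_rms > 0 && sd(y) / full_rms < low_power_ratio
  ang <- wrap_angle(Arg(analytic_signal(y)))
  out <- tibble::tibble(time_s = grid$time_s, angle_rad = ang)
  structure(out,
            class = c("phase_series", class(out)),
            fs_hz = fs_out, band = band, low_power = low_power)
}

#' Pearson similarity between two flux series
#'
#' Used to check that performances of the same piece are acoustically
#' comparable across presentation conditions before contrasting audience
#' responses (similar performances correlate strongly, typically r > 0.9).
#' Series of unequal length are truncated to the common length.
#'
#' @param flux_a,flux_b `flux_series` tibbles or numeric vectors.
#' @return Pearson r, or `NA` (with a warning) if either input has zero
#'   variance.
#' @export
flux_similarity <- function(flux_a, flux_b) {
  a <- if (is.data.frame(flux_a)) flux_a$flux else as.numeric(flux_a)
  b <- if (is.data.frame(flux_b)) flux_b$flux else as.numeric(flux_b)
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]
  b <- b[seq_len(n)]
  if (sd(a) == 0 || sd(b) == 0) {
    warn("flux_similarity(): zero-variance input; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}
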