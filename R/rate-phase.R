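#' Convert a peak train to an instantaneous rate series
#'
#' Each inter-peak interval becomes a rate `60/interval` BPM anchored at the
#' interval midpoint: the interval measures the average rate over its span,
#' so the midpoint is the anchor that keeps the rate series time-unbiased
#' (anchoring at the second peak would delay the series by half a cycle and
#' bias every stimulus-response lag estimate upward by that amount). The
#' anchored rates are linearly interpolated on a fine grid (1000 Hz by
#' default, matching the raw sampling rate), held constant beyond the first
#' and last anchors, then decimated to the 20 Hz analysis grid through an
#' anti-alias low-pass.
#'
#' @param peaks A [peak_series()] or numeric vector of peak times (s).
#' @param duration_s Piece duration; defaults to the peak-series span.
#' @param fs_out Output rate (Hz); the analysis grid is 20 Hz.
#' @param fs_interp Interpolation rate (Hz); must be an integer multiple of
#'   `fs_out`. 100 Hz is numerically indistinguishable for BPM-bandwidth
#'   signals and much cheaper in simulation studies.
#' @return Tibble of class `rate_series` with columns `time_s`, `bpm`;
#'   attribute `fs_hz`.
#' @export
peaks_to_rate <- function(peaks, duration_s = NULL, fs_out = 20,
                          fs_interp = 1000) {
  times <- if (inherits(peaks, "peak_series")) peaks$peak_time_s else as.numeric(peaks)
  check_strictly_increasing(times)
  if (length(times) < 2) abort("peaks_to_rate() needs at least 2 peaks")
  duration_s <- duration_s %||%
    (if (inherits(peaks, "peak_series")) attr(peaks, "span_s")[2] else max(times))
  y <- rate_on_grid(times, duration_s, fs_out, fs_interp)
  out <- tibble::tibble(time_s = seq(0, by = 1 / fs_out,
                                     length.out = length(y)),
                        bpm = y)
  structure(out, class = c("rate_series", class(out)), fs_hz = fs_out)
}

# numeric core of peaks_to_rate(): BPM per interval anchored at the interval
# midpoint, linear interpolation at fs_interp, anti-alias decimation to
# fs_out (a no-op pass-through when fs_interp == fs_out).
rate_on_grid <- function(times, duration_s, fs_out = 20, fs_interp = 1000) {
  bpm <- 60 / diff(times)
  anchors <- (times[-1] + times[-length(times)]) / 2
  t_fine <- seq(0, duration_s, by = 1 / fs_interp)
  x <- approx(anchors, bpm, xout = t_fine, rule = 2)$y
  decimate_series(x, fs_interp, fs_out)
}

#' Wrapped cycle phase from a peak train
#'
#' Per cycle k, one period of a sinusoid `A*sin(2*pi*f_k*t + theta)` with
#' `f_k = 1/interval_k` and phase chosen so the sine's maximum falls on the
#' detected peak is synthesised; the concatenated surrogate's analytic-signal
#' angle then gives the cycle phase: 0 at each peak, ±pi at mid-cycle. The
#' angle is resampled to the analysis grid by interpolating the unwrapped
#' phase. Samples before the first or after the last peak, and cycles whose
#' interval falls outside `plausible_s`, are masked (`NA`).
#'
#' @param peaks A [peak_series()] or numeric peak times (s).
#' @param duration_s Piece duration; defaults to the peak-series span.
#' @param fs_out Analysis grid rate (Hz).
#' @param fs_surrogate Sampling rate of the synthesised sinusoid train.
#' @param amplitude Cycle amplitude `A` (does not affect the angle).
#' @param plausible_s Optional interval bounds `c(lo, hi)` in seconds;
#'   out-of-bounds cycles are masked rather than interpolated.
#' @return Tibble of class `phase_series` with columns `time_s`,
#'   `angle_rad` in (-pi, pi]; attribute `fs_hz`.
#' @export
cycle_phase_from_peaks <- function(peaks, duration_s = NULL, fs_out = 20,
                                   fs_surrogate = 200, amplitude = 1,
                                   plausible_s = NULL) {
  times <- if (inherits(peaks, "peak_series")) peaks$peak_time_s else as.numeric(peaks)
  check_strictly_increasing(times)
  if (length(times) < 2) abort("cycle_phase_from_peaks() needs at least 2 peaks")
  duration_s <- duration_s %||%
    (if (inherits(peaks, "peak_series")) attr(peaks, "span_s")[2] else max(times))
  p1 <- times[1]
  pN <- times[length(times)]
  ibi <- diff(times)
  # half-open [p1, pN): whole cycles only, so a perfectly periodic train is
  # an exact DFT grid for the analytic signal (no spectral leakage)
  t_surr <- seq(p1, pN - 1 / fs_surrogate, by = 1 / fs_surrogate)
  k <- pmin(findInterval(t_surr, times), length(ibi))
  arg <- 2 * pi * (t_surr - times[k]) / ibi[k] + pi / 2
  surrogate <- amplitude * sin(arg)
  ang <- Arg(analytic_signal(surrogate))
  t_out <- seq(0, duration_s, by = 1 / fs_out)
  angle_out <- rep(NA_real_, length(t_out))
  inside <- t_out >= p1 & t_out <= pN
  unw <- unwrap_angle(ang)
  ti <- t_out[inside]
  val <- approx(t_surr, unw, xout = ti, rule = 1)$y
  # extend the final partial step to pN with the last cycle's slope
  tail_idx <- which(is.na(val) & ti > t_surr[length(t_surr)])
  if (length(tail_idx)) {
    val[tail_idx] <- unw[length(unw)] +
      2 * pi / ibi[length(ibi)] * (ti[tail_idx] - t_surr[length(t_surr)])
  }
  angle_out[inside] <- wrap_angle(val)
  if (!is.null(plausible_s)) {
    bad <- which(ibi < plausible_s[1] | ibi > plausible_s[2])
    for (j in bad) {
      angle_out[t_out >= times[j] & t_out < times[j + 1]] <- NA_real_
    }
  }
  out <- tibble::tibble(time_s = t_out, angle_rad = angle_out)
  structure(out, class = c("phase_series", class(out)), fs_hz = fs_out)
}

#' Cycle phase from a recording plus its detected peaks
#'
#' Detrends (linear) and z-scores the filtered signal per piece, measures the
#' mean peak amplitude `A`, and delegates to [cycle_phase_from_peaks()] with
#' channel-appropriate interval plausibility bounds (0.33-3 s heart,
#' 1-20 s respiration).
#'
#' @param rec A filtered [raw_recording()].
#' @param peaks The matching [peak_series()].
#' @param fs_out Analysis grid rate (Hz).
#' @return A `phase_series` tibble (see [cycle_phase_from_peaks()]).
#' @export
fit_cycle_phase <- function(rec, peaks, fs_out = 20) {
  stopifnot(inherits(rec, "raw_recording"))
  x <- rec$samples
  tt <- (seq_along(x) - 1) / rec$fs_hz
  trend <- stats::lm.fit(cbind(1, tt), x)$fitted.values
  z <- x - trend
  s <- sd(z)
  if (s > 0) z <- z / s
  times <- if (inherits(peaks, "peak_series")) peaks$peak_time_s else as.numeric(peaks)
  amp_idx <- pmax(1L, pmin(length(z), round(times * rec$fs_hz) + 1L))
  amplitude <- if (length(amp_idx)) mean(z[amp_idx]) else 1
  bounds <- if (rec$channel == "heart") c(0.33, 3) else c(1, 20)
  cycle_phase_from_peaks(peaks,
                         duration_s = (length(x) - 1) / rec$fs_hz,
                         fs_out = fs_out,
                         amplitude = max(amplitude, 0.1),
                         plausible_s = bounds)
}
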