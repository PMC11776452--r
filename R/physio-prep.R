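#' Raw physiological recording
#'
#' Container for one continuous channel (ECG or respiration belt) cut to one
#' piece, sampled uniformly (1000 Hz in the study design). Missing samples
#' are carried as an explicit mask, never as silent zeros.
#'
#' @param samples Numeric samples; `NA`s are added to the missing mask.
#' @param fs_hz Sampling rate (Hz).
#' @param channel `"heart"` or `"resp"`.
#' @param participant_id,concert_id,piece_id,condition Optional metadata.
#' @param missing_mask Logical vector marking missing samples.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs_hz, channel = c("heart", "resp"),
                          participant_id = NA_character_,
                          concert_id = NA_character_,
                          piece_id = NA_character_,
                          condition = NA_character_,
                          missing_mask = NULL) {
  channel <- match.arg(channel)
  stopifnot(is.numeric(samples), fs_hz > 0)
  missing_mask <- missing_mask %||% rep(FALSE, length(samples))
  missing_mask <- missing_mask | is.na(samples)
  structure(
    list(samples = as.numeric(samples), fs_hz = fs_hz, channel = channel,
         participant_id = participant_id, concert_id = concert_id,
         piece_id = piece_id, condition = condition,
         missing_mask = missing_mask, filtered = FALSE,
         long_gaps = tibble::tibble(start_s = numeric(), end_s = numeric())),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s, %.1f s @ %g Hz, %d missing sample(s)%s\n",
              x$channel, length(x$samples) / x$fs_hz, x$fs_hz,
              sum(x$missing_mask), if (x$filtered) ", filtered" else ""))
  invisible(x)
}

#' Read and write preprocessing artefacts
#'
#' `read_signal_csv()` loads a raw signal table (columns `time_s`, `value`;
#' missing samples as empty/NA) into a [raw_recording()], inferring the
#' sampling rate from the time column when `fs_hz` is not given.
#' `read_edit_list()` loads a manual-override table (columns `action`,
#' `time_s`) for [apply_peak_overrides()]. `write_peaks_csv()` /
#' `read_peaks_csv()` round-trip long peak tables in the standard dialect
#' (`participant_id`, `concert_id`, `piece_id`, `condition`, `signal`,
#' `peak_time_s`).
#'
#' @param path File path.
#' @param fs_hz Sampling rate; inferred from `time_s` when `NULL`.
#' @param channel,... Passed to [raw_recording()].
#' @return See each function's description.
#' @export
read_signal_csv <- function(path, fs_hz = NULL, channel = "heart", ...) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(d)))
  fs_hz <- fs_hz %||% round(1 / stats::median(diff(d$time_s)))
  raw_recording(d$value, fs_hz, channel = channel, ...)
}

#' @rdname read_signal_csv
#' @export
read_edit_list <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("action", "time_s") %in% names(d)))
  tibble::as_tibble(d[c("action", "time_s")])
}

#' @rdname read_signal_csv
#' @param peaks Long peak tibble to write.
#' @export
write_peaks_csv <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_signal_csv
#' @export
read_peaks_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Interpolate short gaps in a raw recording
#'
#' Gaps up to `max_gap_ms` (the study's recordings had none longer than
#' 60 ms) are filled by linear interpolation at the original sampling rate.
#' Longer gaps are left in place, flagged in the `long_gaps` table, and
#' reported with a warning; they count against piece rejection downstream.
#'
#' @param rec A [raw_recording()].
#' @param max_gap_ms Longest gap (ms) that may be interpolated.
#' @return The recording with short gaps filled and `missing_mask` updated.
#' @export
interpolate_gaps <- function(rec, max_gap_ms = 60) {
  stopifnot(inherits(rec, "raw_recording"))
  m <- rec$missing_mask
  if (!any(m)) return(rec)
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  max_len <- max_gap_ms / 1000 * rec$fs_hz
  x <- rec$samples
  idx_all <- seq_along(x)
  good <- idx_all[!m]
  long_gaps <- list()
  for (k in which(r$values)) {
    gap <- starts[k]:ends[k]
    if (length(gap) <= max_len && starts[k] > 1 && ends[k] < length(x)) {
      x[gap] <- approx(good, x[good], xout = gap)$y
      m[gap] <- FALSE
    } else {
      long_gaps[[length(long_gaps) + 1]] <-
        tibble::tibble(start_s = (starts[k] - 1) / rec$fs_hz,
                       end_s = ends[k] / rec$fs_hz)
    }
  }
  if (length(long_gaps)) {
    rec$long_gaps <- dplyr::bind_rows(long_gaps)
    warn(sprintf("%d gap(s) longer than %g ms left unfilled and flagged",
                 length(long_gaps), max_gap_ms))
  }
  rec$samples <- x
  rec$missing_mask <- m
  rec
}

#' Filter a physiological recording
#'
#' Respiration: low-pass at 2 Hz. ECG: band-pass 0.6-20 Hz. Both Butterworth
#' 4th order, applied forward-backward (zero phase, so filtering cannot bias
#' the phase-coherence measures), and demeaned.
#'
#' @param rec A [raw_recording()] with gaps already handled.
#' @return The filtered, demeaned recording (`filtered = TRUE`).
#' @export
filter_physio <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  nyq <- rec$fs_hz / 2
  if (rec$channel == "resp") {
    if (nyq <= 2) abort("sampling rate too low for a 2 Hz low-pass")
    filt <- signal::butter(4, 2 / nyq, type = "low")
  } else {
    if (nyq <= 20) abort("sampling rate too low for a 0.6-20 Hz band-pass")
    filt <- signal::butter(4, c(0.6, 20) / nyq, type = "pass")
  }
  x <- rec$samples
  x[is.na(x)] <- 0  # long unfilled gaps; flagged upstream
  y <- zero_phase_filter(filt, x)
  rec$samples <- y - mean(y)
  rec$filtered <- TRUE
  rec
}

#' Peak series
#'
#' Strictly increasing event times (R peaks or inspiration peaks) for one
#' participant/piece/condition, with provenance per peak.
#'
#' @param times_s Strictly increasing peak times (s, relative to piece
#'   onset).
#' @param source `"detected"` or `"manual"` (recycled).
#' @param span_s Piece span `c(start, end)`; all times must lie inside.
#' @return Tibble of class `peak_series` with columns `peak_time_s`,
#'   `source`; attribute `span_s`.
#' @export
peak_series <- function(times_s, source = "detected", span_s = NULL) {
  times_s <- as.numeric(times_s)
  check_strictly_increasing(times_s)
  span_s <- span_s %||% c(0, if (length(times_s)) max(times_s) else 0)
  if (length(times_s) && (min(times_s) < span_s[1] || max(times_s) > span_s[2])) {
    abort("peak times must lie within the piece span")
  }
  out <- tibble::tibble(peak_time_s = times_s,
                        source = rep_len(source, length(times_s)))
  structure(out, class = c("peak_series", class(out)), span_s = span_s)
}

# Local maxima of x (interior strict maxima).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Enforce a refractory interval: keep the stronger of any pair closer than
# min_gap samples, scanning by descending strength.
enforce_refractory <- function(idx, strength, min_gap) {
  keep <- logical(length(idx))
  for (j in order(strength, decreasing = TRUE)) {
    if (!any(keep & abs(idx - idx[j]) < min_gap)) keep[j] <- TRUE
  }
  sort(idx[keep])
}

#' Detect R peaks in a filtered ECG recording
#'
#' Amplitude-normalised derivative-energy detector: the squared derivative of
#' the band-passed ECG is smoothed over 120 ms; candidate beats are energy
#' maxima above an adaptive threshold (a fraction of the rolling 10-s energy
#' ceiling); each candidate is refined to the signal maximum within ±50 ms; a
#' 250 ms refractory interval suppresses T waves and double counts.
#'
#' @param rec A filtered heart [raw_recording()].
#' @param threshold_frac Energy threshold as a fraction of the rolling
#'   ceiling.
#' @param refractory_s Minimum inter-peak interval (s).
#' @return A [peak_series()].
#' @export
detect_r_peaks <- function(rec, threshold_frac = 0.2, refractory_s = 0.25) {
  stopifnot(inherits(rec, "raw_recording"), rec$channel == "heart")
  x <- rec$samples
  fs <- rec$fs_hz
  span <- c(0, (length(x) - 1) / fs)
  d <- c(0, diff(x)) * fs
  w <- max(3L, round(0.12 * fs))
  energy <- as.numeric(stats::filter(d^2, rep(1 / w, w), sides = 2))
  energy[is.na(energy)] <- 0
  ceil <- stats::quantile(energy, 0.995)
  if (ceil <= 0) return(peak_series(numeric(), span_s = span))
  # noise floor: QRS energy maxima stand orders of magnitude above the
  # median smoothed energy; a flat ratio means no clear QRS anywhere
  if (ceil < 5 * stats::median(energy)) {
    warn("detect_r_peaks(): no clear QRS energy above the noise floor")
    return(peak_series(numeric(), span_s = span))
  }
  cand <- local_maxima(energy)
  cand <- cand[energy[cand] > threshold_frac * ceil]
  if (!length(cand)) {
    warn("detect_r_peaks(): no peaks found on a nonempty signal")
    return(peak_series(numeric(), span_s = span))
  }
  cand <- enforce_refractory(cand, energy[cand], round(refractory_s * fs))
  # refine to the local signal maximum (R wave apex) within +/- 50 ms
  half <- round(0.05 * fs)
  refined <- vapply(cand, function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(x), i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  refined <- enforce_refractory(unique(refined), x[unique(refined)],
                                round(refractory_s * fs))
  peak_series((refined - 1) / fs, span_s = span)
}

#' Detect inspiration peaks in a filtered respiration recording
#'
#' Local maxima exceeding `threshold_frac` of the rolling signal range
#' (60 s window, robust to amplitude drift), separated by at least
#' `min_interval_s`; ties are resolved in favour of the larger peak.
#'
#' @param rec A filtered respiration [raw_recording()].
#' @param threshold_frac Peak threshold as a fraction of the rolling range,
#'   measured from the rolling midpoint.
#' @param min_interval_s Minimum interval between retained peaks (s).
#' @param range_window_s Rolling-range window (s).
#' @return A [peak_series()].
#' @export
detect_resp_peaks <- function(rec, threshold_frac = 0.3, min_interval_s = 1.5,
                              range_window_s = 60) {
  stopifnot(inherits(rec, "raw_recording"), rec$channel == "resp")
  x <- rec$samples
  fs <- rec$fs_hz
  span <- c(0, (length(x) - 1) / fs)
  cand <- local_maxima(x)
  if (!length(cand)) return(peak_series(numeric(), span_s = span))
  w <- min(length(x), round(range_window_s * fs))
  # rolling range on a coarse grid (1 s), interpolated back: cheap and ample
  step <- max(1L, round(fs))
  centers <- seq(1L, length(x), by = step)
  lo <- pmax(1L, centers - w %/% 2L)
  hi <- pmin(length(x), centers + w %/% 2L)
  rmin <- vapply(seq_along(centers), function(k) min(x[lo[k]:hi[k]]), numeric(1))
  rmax <- vapply(seq_along(centers), function(k) max(x[lo[k]:hi[k]]), numeric(1))
  thr_at <- function(i) {
    mn <- approx(centers, rmin, xout = i, rule = 2)$y
    mx <- approx(centers, rmax, xout = i, rule = 2)$y
    (mn + mx) / 2 + threshold_frac * (mx - mn) / 2
  }
  cand <- cand[x[cand] > thr_at(cand)]
  if (!length(cand)) {
    warn("detect_resp_peaks(): no peaks found on a nonempty signal")
    return(peak_series(numeric(), span_s = span))
  }
  cand <- enforce_refractory(cand, x[cand], round(min_interval_s * fs))
  peak_series((cand - 1) / fs, span_s = span)
}

#' Apply a reproducible manual edit list to detected peaks
#'
#' Manual screening is captured as an edit list (add/remove with times)
#' rather than interactive state, so cleaning is replayable. Removals must
#' match an existing peak within `tol_s`.
#'
#' @param peaks A [peak_series()].
#' @param overrides Tibble with columns `action` (`"add"`/`"remove"`) and
#'   `time_s`.
#' @param tol_s Matching tolerance for removals (s).
#' @return The edited [peak_series()]; added peaks carry `source = "manual"`.
#' @export
apply_peak_overrides <- function(peaks, overrides, tol_s = 0.02) {
  stopifnot(inherits(peaks, "peak_series"))
  span <- attr(peaks, "span_s")
  if (is.null(overrides) || nrow(overrides) == 0) return(peaks)
  stopifnot(all(c("action", "time_s") %in% names(overrides)))
  if (any(overrides$time_s < span[1] | overrides$time_s > span[2])) {
    abort("override times must lie within the piece span")
  }
  times <- peaks$peak_time_s
  source <- peaks$source
  for (k in seq_len(nrow(overrides))) {
    act <- overrides$action[k]
    tm <- overrides$time_s[k]
    if (act == "add") {
      times <- c(times, tm)
      source <- c(source, "manual")
      o <- order(times)
      times <- times[o]
      source <- source[o]
    } else if (act == "remove") {
      if (!length(times)) abort("cannot remove a peak from an empty series")
      j <- which.min(abs(times - tm))
      if (abs(times[j] - tm) > tol_s) {
        abort(sprintf("no peak within %g s of %g s to remove", tol_s, tm))
      }
      times <- times[-j]
      source <- source[-j]
    } else {
      abort("override action must be 'add' or 'remove'")
    }
  }
  check_strictly_increasing(times)
  out <- peak_series(times, source = source, span_s = span)
  out
}

#' Decide whether a peak series is usable
#'
#' A piece is rejected for a participant when too many intervals are
#' physiologically implausible (outside 0.33-3 s for heartbeats, 1-20 s for
#' breaths), when the underlying recording had too many long unfilled gaps,
#' or when the series is (nearly) empty. The thresholds are configurable and
#' are echoed in the decision so analyses can report them.
#'
#' @param peaks A [peak_series()].
#' @param signal `"heart"` or `"resp"` (selects plausibility bounds).
#' @param max_implausible_frac Largest tolerated fraction of implausible
#'   intervals.
#' @param max_long_gaps Largest tolerated number of long unfilled gaps.
#' @param n_long_gaps Number of long gaps observed for this recording.
#' @param min_peaks Minimum peak count for a usable series.
#' @return One-row tibble: `keep`, `reason`, `frac_implausible`,
#'   `n_long_gaps`, plus the thresholds used.
#' @export
reject_piece <- function(peaks, signal = c("heart", "resp"),
                         max_implausible_frac = 0.1, max_long_gaps = 0,
                         n_long_gaps = 0, min_peaks = 5) {
  signal <- match.arg(signal)
  bounds <- if (signal == "heart") c(0.33, 3) else c(1, 20)
  n <- nrow(peaks)
  frac <- if (n >= 2) {
    ibi <- diff(peaks$peak_time_s)
    mean(ibi < bounds[1] | ibi > bounds[2])
  } else NA_real_
  keep <- TRUE
  reason <- "ok"
  if (n < min_peaks) {
    keep <- FALSE
    reason <- sprintf("too few peaks (%d < %d)", n, min_peaks)
  } else if (frac > max_implausible_frac) {
    keep <- FALSE
    reason <- sprintf("%.0f%% of intervals outside %g-%g s",
                      100 * frac, bounds[1], bounds[2])
  } else if (n_long_gaps > max_long_gaps) {
    keep <- FALSE
    reason <- sprintf("%d long unfilled gap(s)", n_long_gaps)
  }
  tibble::tibble(keep = keep, reason = reason, frac_implausible = frac,
                 n_long_gaps = n_long_gaps, signal = signal,
                 max_implausible_frac = max_implausible_frac,
                 max_long_gaps = max_long_gaps)
}
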