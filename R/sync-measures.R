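# The four synchrony families on the 20 Hz grid: stimulus-response and
# inter-subject correlation (SRC, ISC) on rate series, and their
# phase-coherence counterparts (SRPC, ISPC) on wrapped cycle phase.

window_starts <- function(n, L, hop) {
  if (n < L) abort("series shorter than one window")
  seq(1L, n - L + 1L, by = hop)
}

# Windowed sums via cumulative sums; NAs are zero-filled and windows that
# touch any NA are masked afterwards.
window_sums <- function(v, starts, L) {
  cs <- c(0, cumsum(v))
  cs[starts + L] - cs[starts]
}

sync_series <- function(center_s, value, measure, window_s, hop_s, fs,
                        n_pairs = NA_integer_) {
  out <- tibble::tibble(window_center_s = center_s, value = value)
  if (!is.na(n_pairs)) out$n_pairs <- n_pairs
  structure(out, class = c("sync_series", class(out)),
            measure = measure, window_s = window_s, hop_s = hop_s, fs_hz = fs)
}

#' Sliding-window Pearson correlation
#'
#' Pearson r between two equal-grid series in 10-s windows advanced by 1 s
#' (defaults). Windows containing missing samples or with zero variance in
#' either input are masked (`NA`). Values are clipped to \[-1, 1\] against
#' floating-point overshoot.
#'
#' @param x,y Numeric vectors on the same uniform grid (or `rate_series` /
#'   grid tibbles with a `bpm`/`flux`/`value` column).
#' @param fs Grid rate (Hz).
#' @param window_s Window length (s).
#' @param hop_s Window advance (s). The study phrase "1-s overlap" is read
#'   as a 1 s hop (9 s overlap) so that boundary epochs have per-second
#'   resolution; see the methods vignette.
#' @param measure Label carried on the result.
#' @return A `sync_series` tibble: `window_center_s`, `value`.
#' @export
windowed_correlation <- function(x, y, fs = 20, window_s = 10, hop_s = 1,
                                 measure = "correlation") {
  x <- series_values(x)
  y <- series_values(y)
  n <- min(length(x), length(y))
  L <- round(window_s * fs)
  hop <- max(1L, round(hop_s * fs))
  starts <- window_starts(n, L, hop)
  r <- win_r(x[seq_len(n)], y[seq_len(n)], starts, L)
  centers <- (starts - 1 + (L - 1) / 2) / fs
  sync_series(centers, r, measure, window_s, hop_s, fs)
}

# numeric core of windowed_correlation(): Pearson r per window via
# cumulative sums; windows touching NAs or with (near-)zero variance are NA.
win_r <- function(x, y, starts, L) {
  bad <- is.na(x) | is.na(y)
  x0 <- ifelse(bad, 0, x)
  y0 <- ifelse(bad, 0, y)
  n_bad <- window_sums(as.numeric(bad), starts, L)
  sx <- window_sums(x0, starts, L)
  sy <- window_sums(y0, starts, L)
  sxx <- window_sums(x0^2, starts, L)
  syy <- window_sums(y0^2, starts, L)
  sxy <- window_sums(x0 * y0, starts, L)
  vx <- sxx - sx^2 / L
  vy <- syy - sy^2 / L
  denom <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  r <- ifelse(denom > 0, (sxy - sx * sy / L) / denom, NA_real_)
  scale <- sqrt(mean(x0^2) * mean(y0^2)) + 1e-300
  r[abs(vx) < 1e-12 * L * scale | abs(vy) < 1e-12 * L * scale] <- NA_real_
  r[n_bad > 0] <- NA_real_
  pmin(1, pmax(-1, r))
}

series_values <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.data.frame(x)) {
    for (col in c("bpm", "flux", "angle_rad", "value")) {
      if (col %in% names(x)) return(x[[col]])
    }
  }
  abort("cannot extract series values; pass a numeric vector or a series tibble")
}

#' Phase-clustering coherence of a set of angles
#'
#' Modulus of the mean unit phasor, `|mean(exp(i * angle))|`: 1 when all
#' angles coincide, 0 for perfectly dispersed angles. Returns `NA` if any
#' angle is missing.
#'
#' @param angles Numeric vector of wrapped angles (rad), length >= 2.
#' @return A value in \[0, 1\].
#' @export
phase_cluster <- function(angles) {
  if (length(angles) < 2) abort("phase_cluster() needs at least 2 angles")
  if (anyNA(angles)) return(NA_real_)
  min(1, Mod(mean(exp(1i * angles))))
}

#' Sliding-window phase coherence between two phase series
#'
#' Two readings of windowed two-signal coherence are available.
#' `"timepoint"` (default): the two-signal phase-clustering modulus
#' `|cos((theta_x - theta_y)/2)|` is computed at every sample and averaged
#' within the window. `"plv"`: the phase-locking value, the modulus of the
#' window-averaged phasor of the phase difference. For a constant offset
#' `d` the first gives `|cos(d/2)|`, the second gives 1.
#'
#' @param theta_x,theta_y Wrapped phase series (rad) on the same grid
#'   (numeric vectors or `phase_series` tibbles).
#' @param fs,window_s,hop_s Grid and window parameters as in
#'   [windowed_correlation()].
#' @param mode `"timepoint"` or `"plv"`.
#' @param measure Label carried on the result.
#' @return A `sync_series` tibble with values in \[0, 1\]; windows with no
#'   valid samples are `NA`.
#' @export
windowed_coherence <- function(theta_x, theta_y, fs = 20, window_s = 10,
                               hop_s = 1, mode = c("timepoint", "plv"),
                               measure = "coherence") {
  mode <- match.arg(mode)
  tx <- series_values(theta_x)
  ty <- series_values(theta_y)
  n <- min(length(tx), length(ty))
  tx <- tx[seq_len(n)]
  ty <- ty[seq_len(n)]
  L <- round(window_s * fs)
  hop <- max(1L, round(hop_s * fs))
  starts <- window_starts(n, L, hop)
  ok <- !(is.na(tx) | is.na(ty))
  n_ok <- window_sums(as.numeric(ok), starts, L)
  if (mode == "timepoint") {
    c_t <- abs(cos((tx - ty) / 2))
    c_t[!ok] <- 0
    val <- ifelse(n_ok > 0, window_sums(c_t, starts, L) / n_ok, NA_real_)
  } else {
    ph <- exp(1i * (tx - ty))
    ph[!ok] <- 0 + 0i
    re <- window_sums(Re(ph), starts, L)
    im <- window_sums(Im(ph), starts, L)
    val <- ifelse(n_ok > 0, sqrt(re^2 + im^2) / n_ok, NA_real_)
  }
  val <- pmin(1, pmax(0, val))
  centers <- (starts - 1 + (L - 1) / 2) / fs
  sync_series(centers, val, measure, window_s, hop_s, fs)
}

shift_response <- function(stim, resp, lag_ms, fs) {
  k <- as.integer(round(lag_ms / 1000 * fs))
  if (k < 0) abort("lag_ms must be >= 0")
  n <- min(length(stim), length(resp) - k)
  if (n < 1) abort("lag longer than the series")
  list(stim = stim[seq_len(n)], resp = resp[seq_len(n) + k])
}

#' Stimulus-response correlation (SRC)
#'
#' Sliding-window Pearson correlation between the stimulus spectral flux and
#' a participant's rate series shifted by the (group) lag: flux at time t is
#' paired with rate at t + lag.
#'
#' @param rate A `rate_series` (or numeric BPM vector on the grid).
#' @param flux A 20 Hz flux tibble from [flux_to_grid()] (or numeric).
#' @param lag_ms Constant response lag (ms), typically the group lag from
#'   [estimate_group_lag()].
#' @param fs,window_s,hop_s Grid and window parameters.
#' @param measure Label (`"SRC-HR"` / `"SRC-RR"`).
#' @return A `sync_series` tibble.
#' @export
src <- function(rate, flux, lag_ms = 0, fs = 20, window_s = 10, hop_s = 1,
                measure = "SRC-HR") {
  sh <- shift_response(series_values(flux), series_values(rate), lag_ms, fs)
  windowed_correlation(sh$stim, sh$resp, fs = fs, window_s = window_s,
                       hop_s = hop_s, measure = measure)
}

#' Stimulus-response phase coherence (SRPC)
#'
#' Windowed phase coherence between the band-limited stimulus flux phase and
#' a participant's cycle phase shifted by the constant group lag.
#'
#' @param phase A `phase_series` (participant cycle phase).
#' @param flux_phase A `phase_series` from [subband_phase()].
#' @inheritParams windowed_coherence
#' @param lag_ms Constant response lag (ms).
#' @param measure Label (`"SRPC-heart"` / `"SRPC-resp"`).
#' @return A `sync_series` tibble.
#' @export
srpc <- function(phase, flux_phase, lag_ms = 0, fs = 20, window_s = 10,
                 hop_s = 1, mode = c("timepoint", "plv"),
                 measure = "SRPC-heart") {
  mode <- match.arg(mode)
  sh <- shift_response(series_values(flux_phase), series_values(phase),
                       lag_ms, fs)
  windowed_coherence(sh$stim, sh$resp, fs = fs, window_s = window_s,
                     hop_s = hop_s, mode = mode, measure = measure)
}

# Long tibble (participant_id, value column on a common grid) -> matrix with
# one column per participant, ordered by time within participant.
participants_matrix <- function(data, value_col) {
  stopifnot(all(c("participant_id", value_col) %in% names(data)))
  split_vals <- split(data[[value_col]], data$participant_id)
  lens <- lengths(split_vals)
  if (length(unique(lens)) != 1) abort("participants must share one grid")
  do.call(cbind, split_vals)
}

#' Inter-subject correlation (ISC)
#'
#' Per window, Pearson r for every unordered participant pair within one
#' concert; pair values are Fisher z-transformed (r clipped to
#' `|r| <= 1 - 1e-12`), averaged, and transformed back. Pairs are formed
#' strictly within the supplied group; never mix concerts in one call.
#'
#' @param data Long tibble with columns `participant_id` and the value
#'   column, all participants on one common grid, or a numeric matrix with
#'   one column per participant.
#' @param value_col Name of the value column (`"bpm"` for HR/RR).
#' @param fs,window_s,hop_s Grid and window parameters.
#' @param measure Label (`"ISC-HR"` / `"ISC-RR"`).
#' @param by_participant If `TRUE`, return one series per participant (the
#'   Fisher-z mean over the pairs that participant belongs to), giving the
#'   participant-level observations the mixed models group on; the plain
#'   group ISC is the all-pairs average.
#' @return A `sync_series` tibble with an `n_pairs` column; with
#'   `by_participant = TRUE` a long tibble with a `participant_id` column.
#' @export
isc <- function(data, value_col = "bpm", fs = 20, window_s = 10, hop_s = 1,
                measure = "ISC-HR", by_participant = FALSE) {
  m <- if (is.matrix(data)) data else participants_matrix(data, value_col)
  if (ncol(m) < 2) abort("isc() needs at least 2 participants")
  pairs <- utils::combn(ncol(m), 2)
  zsum <- NULL
  for (j in seq_len(ncol(pairs))) {
    s <- windowed_correlation(m[, pairs[1, j]], m[, pairs[2, j]], fs = fs,
                              window_s = window_s, hop_s = hop_s)
    r <- pmin(1 - 1e-12, pmax(-1 + 1e-12, s$value))
    z <- atanh(r)
    if (is.null(zsum)) {
      zsum <- matrix(0, length(z), ncol(m))
      n_ok <- matrix(0, length(z), ncol(m))
      centers <- s$window_center_s
    }
    ok <- !is.na(z)
    for (p in pairs[, j]) {
      zsum[ok, p] <- zsum[ok, p] + z[ok]
      n_ok[, p] <- n_ok[, p] + ok
    }
  }
  if (by_participant) {
    val <- ifelse(n_ok > 0, tanh(zsum / n_ok), NA_real_)
    ids <- colnames(m) %||% as.character(seq_len(ncol(m)))
    return(tidyr::pivot_longer(
      dplyr::bind_cols(tibble::tibble(window_center_s = centers),
                       stats::setNames(as.data.frame(val), ids)),
      -"window_center_s", names_to = "participant_id", values_to = "value"
    ))
  }
  # each pair was added to two participants; the all-pairs mean halves it
  tot_z <- rowSums(zsum) / 2
  tot_n <- rowSums(n_ok) / 2
  val <- ifelse(tot_n > 0, tanh(tot_z / tot_n), NA_real_)
  sync_series(centers, val, measure, window_s, hop_s, fs,
              n_pairs = ncol(pairs))
}

#' Inter-subject phase coherence (ISPC)
#'
#' Windowed phase coherence ([windowed_coherence()]) for every unordered
#' participant pair within one concert, averaged over pairs per window.
#'
#' @param data Long tibble with `participant_id` and the angle column on a
#'   common grid, or a numeric matrix (columns = participants).
#' @param value_col Name of the angle column.
#' @inheritParams windowed_coherence
#' @inheritParams isc
#' @param measure Label (`"ISPC-heart"` / `"ISPC-resp"`).
#' @return A `sync_series` tibble with an `n_pairs` column; with
#'   `by_participant = TRUE` a long tibble with a `participant_id` column.
#' @export
ispc <- function(data, value_col = "angle_rad", fs = 20, window_s = 10,
                 hop_s = 1, mode = c("timepoint", "plv"),
                 measure = "ISPC-heart", by_participant = FALSE) {
  mode <- match.arg(mode)
  m <- if (is.matrix(data)) data else participants_matrix(data, value_col)
  if (ncol(m) < 2) abort("ispc() needs at least 2 participants")
  pairs <- utils::combn(ncol(m), 2)
  vsum <- NULL
  for (j in seq_len(ncol(pairs))) {
    s <- windowed_coherence(m[, pairs[1, j]], m[, pairs[2, j]], fs = fs,
                            window_s = window_s, hop_s = hop_s, mode = mode)
    if (is.null(vsum)) {
      vsum <- matrix(0, nrow(s), ncol(m))
      n_ok <- matrix(0, nrow(s), ncol(m))
      centers <- s$window_center_s
    }
    ok <- !is.na(s$value)
    for (p in pairs[, j]) {
      vsum[ok, p] <- vsum[ok, p] + s$value[ok]
      n_ok[, p] <- n_ok[, p] + ok
    }
  }
  if (by_participant) {
    val <- ifelse(n_ok > 0, vsum / n_ok, NA_real_)
    ids <- colnames(m) %||% as.character(seq_len(ncol(m)))
    return(tidyr::pivot_longer(
      dplyr::bind_cols(tibble::tibble(window_center_s = centers),
                       stats::setNames(as.data.frame(val), ids)),
      -"window_center_s", names_to = "participant_id", values_to = "value"
    ))
  }
  tot_v <- rowSums(vsum) / 2
  tot_n <- rowSums(n_ok) / 2
  val <- ifelse(tot_n > 0, tot_v / tot_n, NA_real_)
  sync_series(centers, val, measure, window_s, hop_s, fs,
              n_pairs = ncol(pairs))
}

#' Estimate the constant group lag between stimulus and responses
#'
#' For each participant, candidate lags on the grid quantum (50 ms at 20 Hz)
#' from 0 up to that participant's mean cycle duration are scanned; the
#' score is the correlation (or time-point phase coherence) between the
#' stimulus and the lag-shifted response over the first `window_s` seconds
#' after stimulus onset, where the onset response is most reliable. Each
#' participant's optimum is the lag with the highest positive score;
#' participants with no positive score at any lag are excluded (and logged).
#' The group lag is the mean of the individual optima and is applied as a
#' constant for everyone downstream.
#'
#' @param responses Named list of response vectors on the grid (one per
#'   participant), or a long tibble with `participant_id` and a value
#'   column.
#' @param stimulus Stimulus series on the same grid (flux for correlation,
#'   flux phase for coherence).
#' @param max_lag_s Per-participant search bound (s): one mean cycle. A
#'   single value is recycled; a named vector is matched by participant.
#' @param fs Grid rate (Hz).
#' @param measure `"correlation"` or `"coherence"`.
#' @param window_s Length of the onset window (s).
#' @param value_col Value column when `responses` is a tibble.
#' @param smooth_stimulus_hz For the correlation measure, the stimulus is
#'   low-passed (zero phase) at this cutoff before scanning: heart and
#'   respiration rates cannot track flux modulation faster than a fraction
#'   of a cycle, and restricting the scan to the response band sharpens the
#'   lag objective without shifting its peak. `NULL` disables smoothing.
#' @return List of class `lag_estimate`: `per_participant` tibble
#'   (`participant_id`, `lag_ms`, `score`, `excluded`), `group_lag_ms`,
#'   `measure`, `window_s`.
#' @export
estimate_group_lag <- function(responses, stimulus, max_lag_s, fs = 20,
                               measure = c("correlation", "coherence"),
                               window_s = 10, value_col = "bpm",
                               smooth_stimulus_hz = 0.5) {
  measure <- match.arg(measure)
  if (is.data.frame(responses)) {
    responses <- asplit(participants_matrix(responses, value_col), 2)
  }
  stim <- series_values(stimulus)
  if (measure == "correlation" && !is.null(smooth_stimulus_hz) &&
      smooth_stimulus_hz < fs / 2) {
    lp <- signal::butter(4, smooth_stimulus_hz / (fs / 2), type = "low")
    stim <- zero_phase_filter(lp, stim)
  }
  ids <- names(responses) %||% as.character(seq_along(responses))
  if (!is.null(names(max_lag_s))) max_lag_s <- max_lag_s[ids]
  max_lag_s <- rep_len(unname(max_lag_s), length(responses))
  W <- round(window_s * fs)
  score_at <- function(stim_w, resp_w) {
    if (measure == "correlation") {
      if (sd(stim_w) == 0 || sd(resp_w) == 0) return(NA_real_)
      cor(stim_w, resp_w)
    } else {
      mean(abs(cos((stim_w - resp_w) / 2)), na.rm = TRUE)
    }
  }
  rows <- purrr::map2_dfr(responses, seq_along(responses), function(resp, i) {
    resp <- series_values(resp)
    ks <- 0:floor(max_lag_s[i] * fs)
    ks <- ks[W + ks <= length(resp)]
    scores <- vapply(ks, function(k) {
      score_at(stim[seq_len(W)], resp[seq_len(W) + k])
    }, numeric(1))
    pos <- which(is.finite(scores) & scores > 0)
    if (!length(pos)) {
      tibble::tibble(participant_id = ids[i], lag_ms = NA_real_,
                     score = NA_real_, excluded = TRUE)
    } else {
      best <- pos[which.max(scores[pos])]
      tibble::tibble(participant_id = ids[i],
                     lag_ms = ks[best] / fs * 1000,
                     score = scores[best], excluded = FALSE)
    }
  })
  if (any(rows$excluded)) {
    warn(sprintf("estimate_group_lag(): %d participant(s) had no positive %s at any lag and were excluded",
                 sum(rows$excluded), measure))
  }
  structure(
    list(per_participant = rows,
         group_lag_ms = mean(rows$lag_ms, na.rm = TRUE),
         measure = measure, window_s = window_s),
    class = "lag_estimate"
  )
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat(sprintf("<lag_estimate> group lag %.0f ms (%s, %d participants, %d excluded)\n",
              x$group_lag_ms, x$measure, nrow(x$per_participant),
              sum(x$per_participant$excluded)))
  invisible(x)
}
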