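#' Circularly shift a peak train
#'
#' Rotates event times by `offset_s` modulo the piece length, preserving the
#' train's interval structure (up to the single wrap seam) while destroying
#' its time-locking to the stimulus. Rate and phase series derived from the
#' shifted train inherit the shift coherently.
#'
#' @param times_s Peak times (s).
#' @param offset_s Shift (s).
#' @param piece_len_s Piece length (s).
#' @return Sorted shifted times in `[0, piece_len_s)`.
#' @export
circular_shift_peaks <- function(times_s, offset_s, piece_len_s) {
  sort((times_s + offset_s) %% piece_len_s)
}

#' Circular-shift permutation test for time-locked synchrony
#'
#' The observed statistic is a one-sample t over the measure's time-averaged
#' observations (per participant/pair x section, pooled). Each of `n_perm`
#' permutations independently rotates every participant's peak train(s) by a
#' uniform random offset over the piece length and recomputes the statistic
#' through the full measure pipeline, building a null distribution of
#' time-"unlocked" data. `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param peaks Named list with one element per participant: a numeric
#'   vector of peak times, or a named list of such vectors (e.g. heart and
#'   resp); all trains of one participant are rotated by the same offset.
#' @param piece_len_s Piece length (s).
#' @param statistic_fn Function mapping a `peaks`-shaped list to the vector
#'   of time-averaged observations (e.g. per-section SRC values pooled over
#'   participants).
#' @param n_perm Number of permutations (the study used 1000).
#' @param seed Seed for the offsets.
#' @param measure Label carried on the result.
#' @return Object of class `perm_test`: `observed_stat`, `null_stats`,
#'   `p_value`, `n_perm`, `seed`, `measure`, `observations`.
#' @export
circular_null_test <- function(peaks, piece_len_s, statistic_fn,
                               n_perm = 1000, seed = 1, measure = "synchrony") {
  if (n_perm < 100) warn("fewer than 100 permutations gives coarse p-value resolution")
  obs_values <- statistic_fn(peaks)
  observed <- t_stat_one_sample(obs_values)
  shift_one <- function(trains, offset) {
    if (is.list(trains)) {
      lapply(trains, circular_shift_peaks, offset_s = offset,
             piece_len_s = piece_len_s)
    } else {
      circular_shift_peaks(trains, offset, piece_len_s)
    }
  }
  null_stats <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      offsets <- runif(length(peaks), 0, piece_len_s)
      shifted <- purrr::map2(peaks, offsets, shift_one)
      t_stat_one_sample(statistic_fn(shifted))
    }, numeric(1))
  })
  p <- (1 + sum(null_stats >= observed, na.rm = TRUE)) / (1 + n_perm)
  structure(
    list(observed_stat = observed, null_stats = null_stats, p_value = p,
         n_perm = n_perm, seed = seed, measure = measure,
         observations = obs_values),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s: t = %.3f, p = %.4f (%d permutations)\n",
              x$measure, x$observed_stat, x$p_value, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values across the family of synchrony measures
#' (monotone, capped at 1).
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric())
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Observation builders for the permutation test
#'
#' Closures mapping a per-participant peak-train list to time-averaged
#' observations (per participant x section for SRC, per section for ISC),
#' running the real rate and synchrony pipeline. These are the
#' `statistic_fn` arguments of [circular_null_test()].
#'
#' @param flux_grid 20 Hz stimulus flux tibble ([flux_to_grid()]).
#' @param sections [section_annotation()] rows for the piece.
#' @param duration_s Piece length (s).
#' @param lag_ms Constant group lag applied to responses.
#' @param fs,window_s,hop_s Grid and window parameters.
#' @param fs_interp Rate-interpolation grid passed to [peaks_to_rate()].
#' @return A function of a named list of heart-peak vectors.
#' @export
statistic_src <- function(flux_grid, sections, duration_s, lag_ms = 0,
                          fs = 20, window_s = 10, hop_s = 1,
                          fs_interp = 1000) {
  edges <- c(sections$start_s[1], sections$end_s)
  flux_v <- series_values(flux_grid)
  k_lag <- as.integer(round(lag_ms / 1000 * fs))
  L <- round(window_s * fs)
  hop <- max(1L, round(hop_s * fs))
  n_grid <- length(seq(0, duration_s, by = 1 / fs))
  n <- min(length(flux_v), n_grid - k_lag)
  starts <- window_starts(n, L, hop)
  centers <- (starts - 1 + (L - 1) / 2) / fs
  sec_f <- factor(findInterval(centers, edges, rightmost.closed = TRUE),
                  levels = seq_len(length(edges) - 1))
  stim <- flux_v[seq_len(n)]
  function(peaks) {
    unlist(lapply(peaks, function(p) {
      if (is.list(p)) p <- p$heart
      rate <- rate_on_grid(p, duration_s, fs_out = fs, fs_interp = fs_interp)
      r <- win_r(stim, rate[seq_len(n) + k_lag], starts, L)
      tapply(r, sec_f, mean, na.rm = TRUE)
    }), use.names = FALSE)
  }
}

#' @rdname statistic_src
#' @export
statistic_isc <- function(sections, duration_s, fs = 20, window_s = 10,
                          hop_s = 1, fs_interp = 1000) {
  edges <- c(sections$start_s[1], sections$end_s)
  L <- round(window_s * fs)
  hop <- max(1L, round(hop_s * fs))
  n <- length(seq(0, duration_s, by = 1 / fs))
  starts <- window_starts(n, L, hop)
  centers <- (starts - 1 + (L - 1) / 2) / fs
  sec_f <- factor(findInterval(centers, edges, rightmost.closed = TRUE),
                  levels = seq_len(length(edges) - 1))
  function(peaks) {
    rates <- lapply(peaks, function(p) {
      if (is.list(p)) p <- p$heart
      rate_on_grid(p, duration_s, fs_out = fs, fs_interp = fs_interp)
    })
    pairs <- utils::combn(length(rates), 2)
    zsum <- numeric(length(starts))
    n_ok <- numeric(length(starts))
    for (j in seq_len(ncol(pairs))) {
      r <- win_r(rates[[pairs[1, j]]], rates[[pairs[2, j]]], starts, L)
      z <- atanh(pmin(1 - 1e-12, pmax(-1 + 1e-12, r)))
      ok <- !is.na(z)
      zsum[ok] <- zsum[ok] + z[ok]
      n_ok <- n_ok + ok
    }
    val <- ifelse(n_ok > 0, tanh(zsum / n_ok), NA_real_)
    as.numeric(tapply(val, sec_f, mean, na.rm = TRUE))
  }
}

#' @rdname statistic_src
#' @param flux_phase_grid 20 Hz band-limited stimulus phase
#'   ([subband_phase()]).
#' @param mode Coherence mode (see [windowed_coherence()]).
#' @export
statistic_srpc <- function(flux_phase_grid, sections, duration_s, lag_ms = 0,
                           fs = 20, window_s = 10, hop_s = 1,
                           mode = "timepoint") {
  edges <- c(sections$start_s[1], sections$end_s)
  stim <- series_values(flux_phase_grid)
  function(peaks) {
    unlist(lapply(peaks, function(p) {
      if (is.list(p)) p <- p$heart
      ph <- cycle_phase_from_peaks(p, duration_s, fs_out = fs)
      s <- srpc(ph, stim, lag_ms = lag_ms, fs = fs, window_s = window_s,
                hop_s = hop_s, mode = mode)
      idx <- findInterval(s$window_center_s, edges, rightmost.closed = TRUE)
      tapply(s$value, factor(idx, levels = seq_len(length(edges) - 1)),
             mean, na.rm = TRUE)
    }), use.names = FALSE)
  }
}

#' @rdname statistic_src
#' @export
statistic_ispc <- function(sections, duration_s, fs = 20, window_s = 10,
                           hop_s = 1, mode = "timepoint") {
  edges <- c(sections$start_s[1], sections$end_s)
  function(peaks) {
    m <- do.call(cbind, lapply(peaks, function(p) {
      if (is.list(p)) p <- p$heart
      cycle_phase_from_peaks(p, duration_s, fs_out = fs)$angle_rad
    }))
    s <- ispc(m, fs = fs, window_s = window_s, hop_s = hop_s, mode = mode)
    idx <- findInterval(s$window_center_s, edges, rightmost.closed = TRUE)
    as.numeric(tapply(s$value, factor(idx, levels = seq_len(length(edges) - 1)),
                      mean, na.rm = TRUE))
  }
}
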