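#' Simulate a full synthetic concert study
#'
#' The default layout is the smallest design exercising every grouping
#' factor of the analysis: 2 concerts x 8 participants, 3 synthetic
#' "pieces" (180 s each, with 7/9/9 sections so that section averaging
#' yields 25 observations per participant, condition and measure) x 2
#' presentation conditions (AV with boundary orienting responses, AO
#' without). Stimuli are irregular tone schedules shared across conditions,
#' as the study's AO recordings matched the AV performances.
#'
#' @param n_concerts,n_per_concert Audience layout.
#' @param piece_length_s Piece durations (recycled over pieces).
#' @param sections_per_piece Section counts per piece.
#' @param conditions Conditions to generate.
#' @param seed Master seed; every cell derives its own sub-seed.
#' @param audience_args Extra arguments to [draw_audience()] (coupling
#'   gain, lags, orienting depth, noise sd, ...).
#' @return List of class `audience_study`: `stimuli` (list by piece),
#'   `flux` (native `flux_series` by piece), `flux20` (20 Hz grids),
#'   `sections` ([section_annotation()] rows for all pieces), `peaks`
#'   (long tibble: `concert_id`, `piece_id`, `condition`,
#'   `participant_id`, `signal`, `peak_time_s`), `ground_truth`,
#'   `participants` (specs per concert), `seed`.
#' @export
simulate_audience_study <- function(n_concerts = 2, n_per_concert = 8,
                                    piece_length_s = 180,
                                    sections_per_piece = c(7, 9, 9),
                                    conditions = c("AV", "AO"),
                                    seed = 1,
                                    audience_args = list()) {
  n_pieces <- length(sections_per_piece)
  piece_length_s <- rep_len(piece_length_s, n_pieces)
  piece_ids <- sprintf("piece%d", seq_len(n_pieces))

  stimuli <- purrr::map(seq_len(n_pieces), function(j) {
    len <- piece_length_s[j]
    nb <- sections_per_piece[j] - 1
    boundaries <- len * seq_len(nb) / (nb + 1)
    sched <- with_local_seed(seed * 7919L + j, random_tone_schedule(len))
    generate_stimulus(stimulus_spec(len, boundaries, sched,
                                    piece_id = piece_ids[j]))
  })
  names(stimuli) <- piece_ids
  flux <- purrr::map(stimuli, spectral_flux)
  flux20 <- purrr::map2(flux, stimuli,
                        function(f, s) flux_to_grid(f, duration_s = s$duration_s))
  sections <- dplyr::bind_rows(purrr::map(seq_len(n_pieces), function(j) {
    section_annotation(piece_ids[j], piece_length_s[j],
                       stimuli[[j]]$boundaries$boundary_time_s)
  }))
  class(sections) <- c("section_annotation", class(sections))

  participants <- purrr::map(seq_len(n_concerts), function(ci) {
    ids <- sprintf("c%d_p%02d", ci, seq_len(n_per_concert))
    do.call(draw_audience,
            c(list(n = n_per_concert, seed = seed * 100L + ci, id = ids),
              audience_args))
  })
  names(participants) <- sprintf("concert%d", seq_len(n_concerts))

  cells <- tidyr::crossing(concert = seq_len(n_concerts),
                           piece = seq_len(n_pieces),
                           condition = conditions)
  generated <- purrr::pmap(cells, function(concert, piece, condition) {
    specs <- participants[[concert]]
    specs$seed <- specs$seed + 977L * piece +
      104729L * match(condition, conditions)
    out <- generate_audience(stimuli[[piece]], specs, condition = condition)
    out$peaks$concert_id <- sprintf("concert%d", concert)
    out$peaks$piece_id <- piece_ids[piece]
    out$ground_truth$concert_id <- sprintf("concert%d", concert)
    out
  })
  structure(
    list(stimuli = stimuli, flux = flux, flux20 = flux20,
         sections = sections,
         peaks = dplyr::bind_rows(purrr::map(generated, "peaks")),
         ground_truth = dplyr::bind_rows(purrr::map(generated, "ground_truth")),
         participants = participants, seed = seed,
         conditions = conditions),
    class = "audience_study"
  )
}

#' @export
print.audience_study <- function(x, ...) {
  cat(sprintf("<audience_study> %d concert(s), %d piece(s), conditions: %s; %d peak events\n",
              length(x$participants), length(x$stimuli),
              paste(x$conditions, collapse = "/"), nrow(x$peaks)))
  invisible(x)
}

#' Export a synthetic study to disk
#'
#' Writes the stimulus audio (mono 16-bit WAV per piece), the peak tables
#' (CSV: `participant_id`, `concert_id`, `piece_id`, `condition`, `signal`,
#' `peak_time_s`), the boundary annotations (CSV: `piece_id`,
#' `boundary_time_s`, `section_label`) and the ground-truth manifest (JSON)
#' so a study can be re-analysed from files alone.
#'
#' @param study An `audience_study` from [simulate_audience_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_study <- function(study, dir) {
  stopifnot(inherits(study, "audience_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pid in names(study$stimuli)) {
    st <- study$stimuli[[pid]]
    write_wav(st$wave, st$fs_hz, file.path(dir, paste0(pid, ".wav")))
  }
  utils::write.csv(study$peaks, file.path(dir, "peaks.csv"),
                   row.names = FALSE)
  boundaries <- dplyr::bind_rows(
    purrr::map(study$stimuli, "boundaries"))
  utils::write.csv(boundaries, file.path(dir, "boundaries.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = study$seed, conditions = study$conditions,
         ground_truth = study$ground_truth),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Rate and phase series for every participant/piece/condition of a study
#'
#' Runs [peaks_to_rate()] and [cycle_phase_from_peaks()] over the peak
#' trains of a simulated (or imported) study and returns long tibbles on
#' the 20 Hz grid.
#'
#' @param peaks Long peak tibble (`concert_id`, `piece_id`, `condition`,
#'   `participant_id`, `signal`, `peak_time_s`).
#' @param durations Named vector of piece durations (s) by `piece_id`.
#' @param fs_out Analysis grid rate.
#' @param fs_interp Rate-interpolation grid (see [peaks_to_rate()]).
#' @param what `"rate"`, `"phase"`, or both.
#' @return List with `rates` and/or `phases`: long tibbles with columns
#'   `concert_id`, `piece_id`, `condition`, `participant_id`, `signal`,
#'   `time_s`, and `bpm` / `angle_rad`.
#' @export
derive_series <- function(peaks, durations, fs_out = 20, fs_interp = 1000,
                          what = c("rate", "phase")) {
  groups <- dplyr::group_split(
    peaks, .data$concert_id, .data$piece_id, .data$condition,
    .data$participant_id, .data$signal
  )
  rates <- list()
  phases <- list()
  for (g in groups) {
    dur <- unname(durations[g$piece_id[1]])
    meta <- g[1, c("concert_id", "piece_id", "condition",
                   "participant_id", "signal")]
    if (nrow(g) < 2) next
    if ("rate" %in% what) {
      r <- peaks_to_rate(g$peak_time_s, dur, fs_out = fs_out,
                         fs_interp = fs_interp)
      rates[[length(rates) + 1]] <- dplyr::bind_cols(meta, r)
    }
    if ("phase" %in% what) {
      bounds <- if (g$signal[1] == "heart") c(0.33, 3) else c(1, 20)
      ph <- cycle_phase_from_peaks(g$peak_time_s, dur, fs_out = fs_out,
                                   plausible_s = bounds)
      phases[[length(phases) + 1]] <- dplyr::bind_cols(meta, ph)
    }
  }
  out <- list()
  if ("rate" %in% what) out$rates <- dplyr::bind_rows(rates)
  if ("phase" %in% what) out$phases <- dplyr::bind_rows(phases)
  out
}
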