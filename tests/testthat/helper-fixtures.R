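# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# Irregular-tone stimulus with one mid-piece boundary.
fix_stimulus <- function(duration_s = 60, boundaries = duration_s / 2,
                         seed = 3, min_step = 2, max_step = 4) {
  key <- paste("stim", duration_s, paste(boundaries, collapse = "_"),
               seed, min_step, max_step, sep = "|")
  cached(key, {
    sched <- with_seed_local(seed, random_tone_schedule(duration_s, min_step,
                                                        max_step))
    generate_stimulus(stimulus_spec(duration_s, boundaries, sched,
                                    piece_id = "piece1"))
  })
}

fix_flux20 <- function(stimulus) {
  key <- paste("flux20", stimulus$duration_s, length(stimulus$wave),
               round(sum(abs(stimulus$wave))), sep = "|")
  cached(key, flux_to_grid(spectral_flux(stimulus),
                           duration_s = stimulus$duration_s))
}

# Seed-scoped RNG without touching the session RNG.
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Peak trains (list by participant) for one generated audience cell.
trains_of <- function(audience, signal = "heart") {
  pk <- audience$peaks[audience$peaks$signal == signal, ]
  split(pk$peak_time_s, pk$participant_id)
}

# Balanced synthetic time-averaged table with a known modality offset and
# realistic random-effect structure (16 participants, 2 concerts, 3 pieces,
# 7/9/9 sections).
make_modality_table <- function(seed, offset = 0.02, sd_participant = 0.02,
                                sd_piece = 0.005, sd_slope = 0.005,
                                sd_resid = 0.03) {
  with_seed_local(seed, {
    d <- tidyr::crossing(concert_id = c("c1", "c2"), pnum = 1:8,
                         piece_id = c("p1", "p2", "p3"),
                         condition = c("AO", "AV"))
    d$participant_id <- paste0(d$concert_id, "_", d$pnum)
    secs <- c(p1 = 7, p2 = 9, p3 = 9)
    d <- tidyr::uncount(d, secs[d$piece_id])
    ids <- unique(d$participant_id)
    re_p <- stats::setNames(rnorm(length(ids), 0, sd_participant), ids)
    re_pc <- stats::setNames(rnorm(3, 0, sd_piece), c("p1", "p2", "p3"))
    slope <- stats::setNames(rnorm(length(ids), 0, sd_slope), ids)
    d$value <- 0.05 + offset * (d$condition == "AV") +
      re_p[d$participant_id] + re_pc[d$piece_id] +
      slope[d$participant_id] * (d$condition == "AV") +
      rnorm(nrow(d), 0, sd_resid)
    d
  })
}
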