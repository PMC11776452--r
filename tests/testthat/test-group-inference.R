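test_that("circular shifting preserves the event count and range", {
  times <- with_seed_local(1, sort(runif(50, 0, 60)))
  sh <- circular_shift_peaks(times, 17.3, 60)
  expect_equal(length(sh), 50)
  expect_true(all(sh >= 0 & sh < 60))
  expect_false(is.unsorted(sh))
  expect_equal(circular_shift_peaks(times, 0, 60), times)
})

test_that("a shift-invariant statistic gives p = 1 (null equals observed)", {
  peaks <- list(p1 = seq(1, 29), p2 = seq(1.5, 29.5))
  pt <- suppressWarnings(circular_null_test(
    peaks, 30, statistic_fn = function(p) c(0.4, 0.5, 0.6),
    n_perm = 50, seed = 1))
  expect_true(all(pt$null_stats == pt$observed_stat))
  expect_equal(pt$p_value, 1)
})

test_that("a strongly coupled audience is detected by the permutation test", {
  st <- fix_stimulus(60, 30, seed = 41)
  flux <- fix_flux20(st)
  secs <- section_annotation("piece1", 60, c(20, 40))
  parts <- participant_specs(4, coupling_gain = 6, lag_ms = 600,
                             noise_sd_bpm = 0.5, orienting_depth_bpm = 0,
                             base_heart_hz = c(0.95, 1, 1.05, 1.1))
  aud <- generate_audience(st, parts, "AO")
  stat <- statistic_src(flux, secs, 60, lag_ms = 600, fs_interp = 100)
  pt <- circular_null_test(trains_of(aud), 60, stat, n_perm = 200, seed = 7,
                           measure = "SRC-HR")
  expect_lte(pt$p_value, 0.01)
  td <- tidy(pt)
  expect_equal(td$p.value, pt$p_value)
})

test_that("FDR adjustment equals brute-force Benjamini-Hochberg", {
  expect_equal(fdr_adjust(c(0.001, 0.01, 0.02, 0.04, 0.05)),
               c(0.005, 0.025, 1 / 30, 0.05, 0.05), tolerance = 1e-12)
  expect_equal(fdr_adjust(0.3), 0.3)
  expect_equal(fdr_adjust(rep(0.07, 6)), rep(0.07, 6))
  expect_equal(fdr_adjust(numeric()), numeric())
  bh_brute <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
  }
  with_seed_local(3, {
    for (i in 1:20) {
      p <- runif(sample(3:40, 1))
      expect_equal(fdr_adjust(p), bh_brute(p), tolerance = 1e-12)
    }
  })
})

test_that("section averaging yields 25 observations per participant, condition and measure", {
  sections <- dplyr::bind_rows(
    section_annotation("p1", 180, 180 * (1:6) / 7),
    section_annotation("p2", 180, 180 * (1:8) / 9),
    section_annotation("p3", 180, 180 * (1:8) / 9)
  )
  sync <- tidyr::crossing(
    participant_id = c("a", "b"), condition = c("AO", "AV"),
    measure = "SRC-HR", piece_id = c("p1", "p2", "p3"),
    window_center_s = seq(4.975, 174.975, by = 1)
  )
  sync$value <- 0.25
  agg <- aggregate_time_averaged(sync, sections)
  counts <- dplyr::count(agg, .data$participant_id, .data$condition,
                         .data$measure)
  expect_true(all(counts$n == 25))
  expect_true(all(agg$value == 0.25))
})

test_that("30-s binning of a 180-s piece yields 6 bins", {
  sections <- section_annotation("p1", 180, 180 * (1:6) / 7)
  sync <- tibble::tibble(piece_id = "p1", participant_id = "a",
                         window_center_s = seq(4.975, 174.975, by = 1),
                         value = 1)
  agg <- aggregate_time_averaged(sync, sections, mode = "bins30s")
  expect_equal(nrow(agg), 6)
})

test_that("empty sections are masked and reported", {
  sections <- section_annotation("p1", 60, c(20, 40))
  sync <- tibble::tibble(piece_id = "p1", participant_id = "a",
                         window_center_s = seq(5, 18, by = 1), value = 1)
  expect_warning(agg <- aggregate_time_averaged(sync, sections), "masked")
  expect_equal(sum(is.na(agg$value)), 2)
})

test_that("epochs around one boundary produce five 6-s windows of 6 values", {
  sections <- section_annotation("p1", 60, 30)
  sync <- tibble::tibble(piece_id = "p1", participant_id = "a",
                         window_center_s = seq(0.5, 59.5, by = 1),
                         value = seq(0.5, 59.5, by = 1))
  ep <- epoch_around_boundaries(sync, sections)
  expect_equal(nrow(ep), 5)
  expect_equal(levels(ep$window), c("-10", "-5", "0", "5", "10"))
  # window "0" covers [27, 33): centers 27.5 .. 32.5, mean = 30
  expect_equal(ep$value[ep$window == "0"], 30)
  expect_equal(ep$value[ep$window == "-10"], 30 - 12)
  expect_equal(ep$value[ep$window == "10"], 30 + 12)
})

test_that("boundaries too close to a piece edge are dropped", {
  sections <- section_annotation("p1", 60, c(10, 30))
  sync <- tibble::tibble(piece_id = "p1", participant_id = "a",
                         window_center_s = seq(0.5, 59.5, by = 1), value = 1)
  expect_warning(ep <- epoch_around_boundaries(sync, sections), "dropped")
  expect_equal(unique(ep$boundary_time_s), 30)
  expect_equal(nrow(attr(ep, "dropped_boundaries")), 1)
})

test_that("epoch tables have exactly 5 rows per boundary, participant and measure", {
  sections <- dplyr::bind_rows(section_annotation("p1", 90, c(30, 60)),
                               section_annotation("p2", 90, 45))
  sync <- tidyr::crossing(piece_id = c("p1", "p2"),
                          participant_id = c("a", "b"),
                          measure = c("m1", "m2"),
                          window_center_s = seq(0.5, 89.5, by = 1))
  sync$value <- 1
  ep <- epoch_around_boundaries(sync, sections)
  n_boundaries <- c(p1 = 2, p2 = 1)
  expect_equal(nrow(ep), 5 * (2 + 1) * 2 * 2)
})
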