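test_that("short gaps are linearly interpolated, long gaps flagged", {
  rec <- raw_recording(c(1, NA, NA, NA, 2, 3), fs_hz = 50, channel = "heart")
  out <- interpolate_gaps(rec)  # 3 samples at 50 Hz = 60 ms, at threshold
  expect_equal(out$samples, c(1, 1.25, 1.5, 1.75, 2, 3))
  expect_false(any(out$missing_mask))

  rec2 <- raw_recording(c(1:10, rep(NA, 100), 1:10), fs_hz = 1000,
                        channel = "heart")
  expect_warning(out2 <- interpolate_gaps(rec2), "flagged")
  expect_true(all(is.na(out2$samples[11:110])))
  expect_equal(nrow(out2$long_gaps), 1)

  rec3 <- raw_recording(sin(1:100), fs_hz = 1000, channel = "resp")
  expect_identical(interpolate_gaps(rec3)$samples, rec3$samples)
})

test_that("filters match their analytic Butterworth magnitude response", {
  fs <- 1000
  tt <- seq(0, 30, by = 1 / fs)
  # 0.3 Hz through the 2 Hz respiration low-pass: passband, < 5% loss
  rec <- raw_recording(sin(2 * pi * 0.3 * tt), fs, "resp")
  out <- filter_physio(rec)
  mid <- out$samples[tt > 5 & tt < 25]
  gain <- (max(mid) - min(mid)) / 2
  oracle <- (1 / sqrt(1 + (0.3 / 2)^8))^2  # 4th order, applied twice
  expect_equal(gain, oracle, tolerance = 0.01)
  expect_gt(gain, 0.95)
  # 50 Hz through the 0.6-20 Hz cardiac band-pass: > 90% attenuation
  rec2 <- raw_recording(sin(2 * pi * 50 * tt), fs, "heart")
  out2 <- filter_physio(rec2)
  expect_lt(max(abs(out2$samples[tt > 5 & tt < 25])), 0.1)
  # demeaning
  rec3 <- raw_recording(5 + sin(2 * pi * 1 * tt), fs, "heart")
  expect_lt(abs(mean(filter_physio(rec3)$samples)), 1e-9)
})

test_that("passband filtering is nearly idempotent", {
  fs <- 1000
  tt <- seq(0, 20, by = 1 / fs)
  rec <- raw_recording(sin(2 * pi * 0.3 * tt), fs, "resp")
  once <- filter_physio(rec)
  twice <- filter_physio(once)
  mid <- tt > 5 & tt < 15
  a1 <- (max(once$samples[mid]) - min(once$samples[mid])) / 2
  a2 <- (max(twice$samples[mid]) - min(twice$samples[mid])) / 2
  expect_lt(abs(a2 - a1) / a1, 0.05)
})

test_that("rendered peaks are recovered by the detectors (round trip)", {
  st <- fix_stimulus(60, 30)
  aud <- generate_audience(st, draw_audience(1, seed = 11), "AO")
  heart <- trains_of(aud, "heart")[[1]]
  resp <- trains_of(aud, "resp")[[1]]
  rw <- render_waveforms(heart, resp, 60, seed = 4)
  det_h <- detect_r_peaks(filter_physio(rw$heart))
  det_r <- detect_resp_peaks(filter_physio(rw$resp))
  # interior peaks (outside the filter's edge-transient zone)
  interior <- function(x, lo = 1, hi = 59) x[x > lo & x < hi]
  h_true <- interior(heart)
  r_true <- interior(resp)
  h_err <- vapply(h_true, function(t) min(abs(t - det_h$peak_time_s)),
                  numeric(1))
  r_err <- vapply(r_true, function(t) min(abs(t - det_r$peak_time_s)),
                  numeric(1))
  expect_true(all(h_err <= 0.010))   # recall 1 at +/- 10 ms
  expect_true(all(r_err <= 0.050))
  # precision: no extra interior detections
  h_extra <- vapply(interior(det_h$peak_time_s),
                    function(t) min(abs(t - heart)), numeric(1))
  expect_true(all(h_extra <= 0.010))
  # refractory: T waves never mistaken for R waves
  expect_true(all(diff(det_h$peak_time_s) >= 0.25))
})

test_that("pronounced T waves are not detected as beats", {
  heart <- seq(1, 59, by = 1)
  rw <- render_waveforms(heart, numeric(), 60, t_wave_amp = 0.45,
                         noise_sd = 0.005, seed = 2)
  det <- detect_r_peaks(filter_physio(rw$heart))
  expect_equal(nrow(det), length(heart))
  expect_true(all(diff(det$peak_time_s) >= 0.25))
})

test_that("degenerate signals give empty detections", {
  flat <- raw_recording(rep(0, 5000), 1000, "heart")
  flat$filtered <- TRUE
  expect_equal(nrow(detect_r_peaks(flat)), 0)
  const <- raw_recording(rep(0, 5000), 1000, "resp")
  expect_equal(nrow(detect_resp_peaks(const)), 0)
  rw <- render_waveforms(numeric(), numeric(), 10, seed = 1)
  det <- suppressWarnings(detect_r_peaks(filter_physio(rw$heart)))
  expect_equal(nrow(det), 0)
})

test_that("close respiration maxima are resolved in favour of the larger", {
  fs <- 100
  tt <- seq(0, 20, by = 1 / fs)
  x <- exp(-((tt - 10)^2) / 0.08) + 0.6 * exp(-((tt - 11)^2) / 0.08) +
    exp(-((tt - 15)^2) / 0.08)
  rec <- raw_recording(x - mean(x), fs, "resp")
  det <- detect_resp_peaks(rec, min_interval_s = 1.5)
  expect_equal(nrow(det), 2)
  expect_equal(det$peak_time_s, c(10, 15), tolerance = 0.05)
})

test_that("peak overrides are applied, validated, and invertible", {
  pk <- peak_series(c(11, 13), span_s = c(0, 20))
  added <- apply_peak_overrides(
    pk, tibble::tibble(action = "add", time_s = 12))
  expect_equal(added$peak_time_s, c(11, 12, 13))
  expect_equal(added$source, c("detected", "manual", "detected"))
  expect_identical(apply_peak_overrides(pk, NULL), pk)
  roundtrip <- apply_peak_overrides(
    pk, tibble::tibble(action = c("add", "remove"), time_s = c(12, 12)))
  expect_equal(roundtrip$peak_time_s, pk$peak_time_s)
  expect_error(
    apply_peak_overrides(pk, tibble::tibble(action = "remove", time_s = 15)),
    "no peak within")
  expect_error(
    apply_peak_overrides(pk, tibble::tibble(action = "add", time_s = 25)),
    "span")
})

test_that("piece rejection follows the interval-plausibility rule", {
  clean <- peak_series(seq(0, 60, by = 1), span_s = c(0, 60))
  expect_true(reject_piece(clean, "heart")$keep)
  # 30% of intervals below 0.33 s
  times <- cumsum(rep(c(0.2, 1, 1, 1, 0.2, 1, 1, 0.2, 1, 1), 5))
  bad <- peak_series(times, span_s = c(0, max(times)))
  dec <- reject_piece(bad, "heart")
  expect_false(dec$keep)
  expect_match(dec$reason, "outside")
  empty <- peak_series(numeric(), span_s = c(0, 60))
  expect_false(reject_piece(empty, "heart")$keep)
  # long-gap criterion
  dec2 <- reject_piece(clean, "heart", n_long_gaps = 2)
  expect_false(dec2$keep)
  expect_match(dec2$reason, "gap")
})

test_that("detection stays near-perfect at the generator's default noise", {
  st <- fix_stimulus(60, 30)
  aud <- generate_audience(st, draw_audience(2, seed = 21), "AV")
  ok <- vapply(names(trains_of(aud, "heart")), function(id) {
    heart <- trains_of(aud, "heart")[[id]]
    rw <- render_waveforms(heart, numeric(), 60, seed = 5)
    det <- detect_r_peaks(filter_physio(rw$heart))
    h_true <- heart[heart > 1 & heart < 59]
    errs <- vapply(h_true, function(t) min(abs(t - det$peak_time_s)),
                   numeric(1))
    mean(errs <= 0.01)
  }, numeric(1))
  expect_true(all(ok >= 0.98))
})
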