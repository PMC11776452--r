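test_that("constant inter-beat intervals give the exact constant BPM", {
  r1 <- peaks_to_rate(seq(0.5, 59.5, by = 1), 60)
  expect_equal(r1$bpm, rep(60, nrow(r1)), tolerance = 1e-9)
  r2 <- peaks_to_rate(seq(0.5, 59.9, by = 0.99), 60)
  expect_equal(unique(round(r2$bpm, 6)), round(60 / 0.99, 6))
  expect_equal(r2$time_s[2] - r2$time_s[1], 0.05)
})

test_that("alternating intervals stay inside the piecewise-linear envelope", {
  times <- cumsum(c(0, rep(c(0.9, 1.1), 30)))
  r <- peaks_to_rate(times, max(times))
  # oracle: linear interpolation between 60/1.1 and 60/0.9 anchored at
  # interval midpoints cannot leave the anchor range; the anti-alias
  # low-pass may ring past it by a few hundredths of a BPM
  expect_gte(min(r$bpm), 60 / 1.1 - 0.05)
  expect_lte(max(r$bpm), 60 / 0.9 + 0.05)
  direct <- approx((times[-1] + times[-length(times)]) / 2,
                   60 / diff(times), xout = r$time_s, rule = 2)$y
  expect_lt(max(abs(r$bpm - direct)), 1.5)  # anti-alias smoothing only
})

test_that("interpolation grids of 1000, 100 and 20 Hz agree", {
  times <- with_seed_local(5, cumsum(runif(60, 0.8, 1.2)))
  dur <- ceiling(max(times))
  r1000 <- peaks_to_rate(times, dur, fs_interp = 1000)$bpm
  r100 <- peaks_to_rate(times, dur, fs_interp = 100)$bpm
  r20 <- peaks_to_rate(times, dur, fs_interp = 20)$bpm
  expect_gt(cor(r1000, r100), 0.9999)
  expect_gt(cor(r1000, r20), 0.9999)
  expect_lt(mean(abs(r1000 - r20)), 0.1)
})

test_that("time-averaged rate conserves the mean of 60/IBI on constant fixtures", {
  times <- seq(0.25, 120, by = 0.8)
  r <- peaks_to_rate(times, 120)
  expect_lt(abs(mean(r$bpm) - mean(60 / diff(times))), 0.1)
})

test_that("rate and phase pipelines commute with on-grid time shifts", {
  times <- with_seed_local(8, cumsum(runif(40, 0.8, 1.2)))
  dur <- 60
  delta <- 2  # on the 20 Hz grid
  r0 <- peaks_to_rate(times, dur)
  r1 <- peaks_to_rate(times + delta, dur)
  k <- delta * 20
  inner <- seq(k + 41, 20 * (max(times) - 2))  # away from edge-hold regions
  expect_equal(r1$bpm[inner], r0$bpm[inner - k], tolerance = 1e-6)
  p0 <- cycle_phase_from_peaks(times, dur)
  p1 <- cycle_phase_from_peaks(times + delta, dur)
  expect_equal(p1$angle_rad[inner], p0$angle_rad[inner - k], tolerance = 1e-3)
})

test_that("perfectly periodic peaks give a wrapping phase ramp, zero at peaks", {
  times <- 0:30  # 1 Hz, integer-period surrogate
  ph <- cycle_phase_from_peaks(times, 30, fs_out = 20, fs_surrogate = 200)
  at_peaks <- ph$angle_rad[ph$time_s %in% times]
  expect_true(all(abs(at_peaks) < 1e-6))
  # midpoints sit at the +/- pi wrap
  mids <- ph$time_s %in% (times[-1] - 0.5)
  expect_true(all(abs(abs(ph$angle_rad[mids]) - pi) < 0.05))
  # ramp: unwrapped phase advances 2*pi per cycle
  inner <- !is.na(ph$angle_rad)
  unwrapped <- cardiosync:::unwrap_angle(ph$angle_rad[inner])
  per_cycle <- diff(unwrapped[seq(1, sum(inner), by = 20)])
  expect_true(all(abs(per_cycle - 2 * pi) < 1e-3))
})

test_that("physiologically jittered cycles stay near zero phase at peaks", {
  # +/- 10% beat-to-beat interval variability
  times <- with_seed_local(9, cumsum(runif(30, 0.9, 1.1)))
  dur <- ceiling(max(times)) + 1
  ph <- cycle_phase_from_peaks(times, dur, fs_out = 200, fs_surrogate = 200)
  interior <- times[3:(length(times) - 2)]
  errs <- vapply(interior, function(p) {
    i <- which.min(abs(ph$time_s - p))
    abs(ph$angle_rad[i] -
          cardiosync:::wrap_angle(2 * pi * (ph$time_s[i] - p) /
                                    diff(times)[findInterval(p, times)]))
  }, numeric(1))
  expect_true(all(abs(cardiosync:::wrap_angle(errs)) < 0.1))
})

test_that("out-of-bounds cycles are masked rather than interpolated", {
  times <- c(1, 2, 3, 3.1, 4.1, 5.1)  # one 0.1 s cycle
  ph <- cycle_phase_from_peaks(times, 6, plausible_s = c(0.33, 3))
  masked <- ph$time_s >= 3 & ph$time_s < 3.1
  expect_true(all(is.na(ph$angle_rad[masked])))
  kept <- ph$time_s >= 1.2 & ph$time_s < 2.8
  expect_true(all(!is.na(ph$angle_rad[kept])))
})

test_that("identical peak trains give identical phase series", {
  times <- with_seed_local(3, cumsum(runif(20, 0.8, 1.2)))
  expect_identical(cycle_phase_from_peaks(times, 25),
                   cycle_phase_from_peaks(times, 25))
})

test_that("fit_cycle_phase handles a filtered recording end to end", {
  heart <- seq(1, 29, by = 1)
  rw <- render_waveforms(heart, numeric(), 30, seed = 6)
  rec <- filter_physio(rw$heart)
  pk <- detect_r_peaks(rec)
  ph <- fit_cycle_phase(rec, pk)
  at_peaks <- approx(ph$time_s[!is.na(ph$angle_rad)],
                     cardiosync:::unwrap_angle(ph$angle_rad[!is.na(ph$angle_rad)]),
                     xout = pk$peak_time_s[3:26])$y
  expect_true(all(abs(cardiosync:::wrap_angle(at_peaks)) < 0.1))
})

test_that("degenerate peak inputs error clearly", {
  expect_error(peaks_to_rate(1.5, 10), "at least 2")
  expect_error(peaks_to_rate(c(2, 1), 10), "increasing")
  expect_error(cycle_phase_from_peaks(3, 10), "at least 2")
})
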