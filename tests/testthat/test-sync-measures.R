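test_that("windowed correlation honours identity, affine invariance, and the window count", {
  x <- with_seed_local(1, rnorm(1201))
  s1 <- windowed_correlation(x, x)
  expect_equal(nrow(s1), 51)  # 60 s at 20 Hz, 10 s window, 1 s hop
  expect_true(all(s1$value == 1))
  s2 <- windowed_correlation(x, 2 * x + 1)
  expect_equal(s2$value, rep(1, 51), tolerance = 1e-9)
  expect_error(windowed_correlation(x[1:100], x[1:100]), "shorter")
})

test_that("windowed correlation masks NA and zero-variance windows and stays in [-1, 1]", {
  x <- with_seed_local(2, rnorm(1201))
  y <- with_seed_local(3, rnorm(1201))
  y[300] <- NA
  s <- windowed_correlation(x, y)
  touched <- s$window_center_s > (300 - 200) / 20 & s$window_center_s < 300 / 20
  expect_true(any(is.na(s$value[touched])))
  expect_true(all(abs(s$value) <= 1, na.rm = TRUE))
  z <- rep(5, 1201)
  expect_true(all(is.na(windowed_correlation(x, z)$value)))
  # oracle: plain cor() on each window
  starts <- seq(1, 1002, by = 20)
  oracle <- vapply(starts, function(i) cor(x[i:(i + 199)], y[i:(i + 199)]),
                   numeric(1))
  ok <- !is.na(s$value)
  expect_equal(s$value[ok], oracle[ok], tolerance = 1e-12)
})

test_that("phase clustering equals the brute-force complex mean", {
  expect_equal(phase_cluster(c(0.7, 0.7, 0.7)), 1)
  expect_equal(phase_cluster(c(0, pi)), 0, tolerance = 1e-12)
  expect_equal(phase_cluster(c(0, 2 * pi / 3, 4 * pi / 3)), 0,
               tolerance = 1e-12)
  with_seed_local(4, {
    for (i in 1:25) {
      angs <- runif(sample(2:12, 1), -pi, pi)
      expect_equal(phase_cluster(angs), Mod(sum(exp(1i * angs)) / length(angs)),
                   tolerance = 1e-12)
    }
  })
  expect_true(is.na(phase_cluster(c(0.1, NA))))
})

test_that("two-signal coherence matches closed forms for offset phase ramps", {
  fs <- 20
  tt <- seq(0, 60, by = 1 / fs)
  ramp <- cardiosync:::wrap_angle(2 * pi * 1 * tt)
  same <- windowed_coherence(ramp, ramp, mode = "timepoint")
  expect_equal(same$value, rep(1, nrow(same)), tolerance = 1e-9)
  expect_equal(windowed_coherence(ramp, ramp, mode = "plv")$value,
               rep(1, nrow(same)), tolerance = 1e-9)
  for (delta in c(0.5, 1.5, 2.8)) {
    shifted <- cardiosync:::wrap_angle(ramp + delta)
    tp <- windowed_coherence(ramp, shifted, mode = "timepoint")
    expect_equal(tp$value, rep(abs(cos(delta / 2)), nrow(tp)),
                 tolerance = 1e-9)
    plv <- windowed_coherence(ramp, shifted, mode = "plv")
    expect_equal(plv$value, rep(1, nrow(plv)), tolerance = 1e-9)
  }
})

test_that("incommensurate phase ramps give low PLV over 10-s windows", {
  fs <- 20
  tt <- seq(0, 120, by = 1 / fs)
  r1 <- cardiosync:::wrap_angle(2 * pi * 1.0 * tt)
  r2 <- cardiosync:::wrap_angle(2 * pi * 1.13 * tt)
  plv <- windowed_coherence(r1, r2, mode = "plv")
  # oracle: |(1/T) integral over T of exp(i 2 pi df t)| = |sinc(df T)|,
  # df = 0.13 Hz, T = 10 s
  oracle <- abs(sin(pi * 0.13 * 10) / (pi * 0.13 * 10))
  expect_lt(max(plv$value), 0.3)
  expect_equal(mean(plv$value), oracle, tolerance = 0.05)
})

test_that("SRC tracks an affine response exactly and flips sign at a half-period lag", {
  fs <- 20
  tt <- seq(0, 120, by = 1 / fs)
  flux <- 1 + 0.5 * sin(2 * pi * 0.25 * tt)
  rate <- 60 + 3 * flux
  s <- src(rate, flux, lag_ms = 0)
  expect_equal(s$value, rep(1, nrow(s)), tolerance = 1e-9)
  # misspecify the lag by half the 4-s flux period: correlation flips sign
  s_flip <- src(rate, flux, lag_ms = 2000)
  expect_equal(s_flip$value, rep(-1, nrow(s_flip)), tolerance = 1e-6)
})

test_that("SRC of stimulus-independent rates averages to ~0", {
  st <- fix_stimulus(180, 90)
  flux <- fix_flux20(st)
  vals <- with_seed_local(11, {
    unlist(lapply(1:2, function(i) {
      rate <- 60 + as.numeric(stats::filter(rnorm(nrow(flux), 0, 1.5),
                                            rep(1 / 40, 40), sides = 2))
      rate[is.na(rate)] <- 60
      src(rate, flux, lag_ms = 0)$value
    }))
  })
  expect_gte(length(vals), 150)
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.05)
})

test_that("ISC matches a brute-force Fisher-z pairwise oracle", {
  n_t <- 605
  m <- with_seed_local(7, matrix(rnorm(n_t * 4, 60, 2), n_t, 4))
  m[, 2] <- m[, 1] + rnorm(n_t, 0, 1)   # a correlated pair
  s <- isc(m, fs = 20, window_s = 10, hop_s = 1)
  starts <- seq(1, n_t - 200 + 1, by = 20)
  pairs <- combn(4, 2)
  oracle <- vapply(starts, function(i) {
    rs <- apply(pairs, 2, function(p) {
      cor(m[i:(i + 199), p[1]], m[i:(i + 199), p[2]])
    })
    tanh(mean(atanh(pmin(1 - 1e-12, pmax(-1 + 1e-12, rs)))))
  }, numeric(1))
  expect_equal(s$value, oracle, tolerance = 1e-10)
  expect_equal(s$n_pairs, rep(6L, nrow(s)))
})

test_that("ISC is exactly 1 for shared signals and permutation-invariant", {
  base <- with_seed_local(8, rnorm(605, 60, 2))
  shared <- cbind(base, base, base)
  expect_equal(isc(shared)$value, rep(1, 21), tolerance = 1e-6)
  m <- with_seed_local(9, matrix(rnorm(605 * 4, 60, 2), 605, 4))
  expect_equal(isc(m)$value, isc(m[, c(3, 1, 4, 2)])$value, tolerance = 1e-12)
  expect_error(isc(m[, 1, drop = FALSE]), "at least 2")
})

test_that("per-participant ISC averages the pairs each participant belongs to", {
  m <- with_seed_local(10, matrix(rnorm(605 * 3, 60, 2), 605, 3))
  colnames(m) <- c("a", "b", "c")
  long <- isc(m, by_participant = TRUE)
  expect_setequal(unique(long$participant_id), c("a", "b", "c"))
  # oracle for participant a, first window: mean z over pairs (a,b), (a,c)
  r_ab <- cor(m[1:200, "a"], m[1:200, "b"])
  r_ac <- cor(m[1:200, "a"], m[1:200, "c"])
  oracle <- tanh(mean(atanh(c(r_ab, r_ac))))
  got <- long$value[long$participant_id == "a"][1]
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("ISPC averages pairwise coherences and is 1 for identical groups", {
  fs <- 20
  tt <- seq(0, 60, by = 1 / fs)
  ramp <- cardiosync:::wrap_angle(2 * pi * tt)
  m <- cbind(ramp, ramp, ramp)
  expect_equal(ispc(m)$value, rep(1, 51), tolerance = 1e-9)
  # brute-force mean-over-pairs oracle on random phases
  mp <- with_seed_local(12, matrix(runif(605 * 3, -pi, pi), 605, 3))
  s <- ispc(mp, mode = "timepoint")
  pairs <- combn(3, 2)
  starts <- seq(1, 605 - 200 + 1, by = 20)
  oracle <- vapply(starts, function(i) {
    mean(apply(pairs, 2, function(p) {
      mean(abs(cos((mp[i:(i + 199), p[1]] - mp[i:(i + 199), p[2]]) / 2)))
    }))
  }, numeric(1))
  expect_equal(s$value, oracle, tolerance = 1e-10)
})

test_that("group lag is recovered exactly on literally shifted series", {
  st <- fix_stimulus(60, 30)
  flux <- fix_flux20(st)$flux
  expect_equal(estimate_group_lag(list(p1 = flux), flux,
                                  max_lag_s = 0.99)$group_lag_ms, 0)
  delayed <- c(rep(flux[1], 12), flux[seq_len(length(flux) - 12)])
  est <- estimate_group_lag(list(p1 = delayed, p2 = delayed), flux,
                            max_lag_s = 0.99)
  expect_equal(est$group_lag_ms, 600, tolerance = 50)
})

test_that("participants with no positive correlation at any lag are excluded", {
  fs <- 20
  tt <- seq(0, 30, by = 1 / fs)
  stim <- sin(2 * pi * 0.2 * tt)
  resp <- -stim  # anti-correlated at every lag below a quarter period
  expect_warning(
    est <- estimate_group_lag(list(p1 = resp), stim, max_lag_s = 0.5),
    "excluded")
  expect_true(est$per_participant$excluded[1])
  expect_true(is.nan(est$group_lag_ms) || is.na(est$group_lag_ms))
})

test_that("synchrony bounds hold on arbitrary seeded inputs", {
  with_seed_local(13, {
    for (i in 1:5) {
      x <- rnorm(605)
      y <- rnorm(605)
      expect_true(all(abs(windowed_correlation(x, y)$value) <= 1,
                      na.rm = TRUE))
      tx <- runif(605, -pi, pi)
      ty <- runif(605, -pi, pi)
      v <- windowed_coherence(tx, ty)$value
      expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
    }
  })
})
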