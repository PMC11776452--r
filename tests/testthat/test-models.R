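test_that("an injected modality offset is recovered with a sensible CI", {
  fit <- fit_modality_models(make_modality_table(1, offset = 0.02),
                             outcome = "value", fixed = "condition")
  est <- fit$coefficients[fit$coefficients$term == "conditionAV", ]
  expect_lt(abs(est$estimate - 0.02), 0.012)
  expect_true(est$conf_low <= 0.02 && 0.02 <= est$conf_high)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true(all(c("stage", "r2.marginal") %in% names(glance(fit))))
})

test_that("a zero-effect table gives an estimate within noise of zero", {
  hits <- vapply(1:10, function(s) {
    fit <- fit_modality_models(make_modality_table(100 + s, offset = 0),
                               outcome = "value", fixed = "condition")
    est <- fit$coefficients[fit$coefficients$term == "conditionAV", ]
    abs(est$estimate) < 2 * est$std_error
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a singular maximal structure is simplified along the declared path", {
  # no concert/piece/slope variance at all: maximal model must be singular
  d <- make_modality_table(5, offset = 0.02, sd_piece = 0, sd_slope = 0,
                           sd_participant = 0.02)
  fit <- fit_modality_models(d, outcome = "value", fixed = "condition")
  expect_true(fit$stage != "maximal")
  expect_true(any(!fit$path$ok[fit$path$stage == "maximal"]))
  expect_false(is.null(fit$model))
})

test_that("window contrasts produce AO-AV rows per window with Bonferroni scaling", {
  d <- with_seed_local(9, {
    base <- tidyr::crossing(concert_id = c("c1", "c2"), pnum = 1:6,
                            piece_id = c("p1", "p2"),
                            condition = c("AO", "AV"),
                            window = c("-10", "-5", "0", "5", "10"),
                            boundary_index = 1:3)
    base$participant_id <- paste0(base$concert_id, "_", base$pnum)
    base$value <- 0.05 +
      0.02 * (base$condition == "AV" & base$window == "0") +
      rnorm(nrow(base), 0, 0.02)
    base$window <- factor(base$window,
                          levels = c("-10", "-5", "0", "5", "10"))
    base
  })
  fit <- fit_modality_models(d, outcome = "value",
                             fixed = c("condition", "window",
                                       "condition:window"),
                             slope = "condition")
  ct <- window_contrasts(fit)
  mw <- ct$modality_by_window
  expect_equal(nrow(mw), 5)
  expect_equal(mw$p_adjusted, pmin(1, mw$p.value * 5))
  # the AV-only boost at window 0 shows up as the most negative AO-AV gap
  expect_equal(as.character(mw$window[which.min(mw$estimate)]), "0")
  wb <- ct$window_vs_boundary
  expect_equal(nrow(wb), 8)  # 4 contrasts x 2 modalities
})

test_that("the paired sanity test picks its branch via the normality gate", {
  expect_equal(sanity_paired_test(rep(1, 10), rep(1, 10))$p_value, 1)
  expect_equal(sanity_paired_test(rep(1, 10), rep(1, 10))$statistic, 0)
  with_seed_local(11, {
    ao <- 0.08 + rnorm(16, 0, 0.01)
    av <- 0.05 + rnorm(16, 0, 0.01)
    out <- sanity_paired_test(ao, av)
    expect_equal(out$test, "t")
    expect_lt(out$p_value, 0.01)
    # heavy-tailed differences trip the Shapiro gate
    d_heavy <- rt(30, df = 1) * 0.01
    out2 <- sanity_paired_test(d_heavy, rep(0, 30))
    expect_equal(out2$test, "wilcoxon")
  })
  expect_error(sanity_paired_test(1:2, 2:3), "at least 3")
})

test_that("the boundary rate profile exposes the deceleration-acceleration dip", {
  st <- generate_stimulus(stimulus_spec(90, c(30, 60), piece_id = "p1"))
  parts <- participant_specs(4, base_heart_hz = c(0.95, 1, 1.05, 1.1),
                             coupling_gain = 0, orienting_depth_bpm = 0.5,
                             noise_sd_bpm = 0.2, lag_ms = 0)
  aud <- generate_audience(st, parts, "AV", enable_orienting = TRUE)
  rates <- purrr::imap_dfr(trains_of(aud), function(tr, id) {
    r <- peaks_to_rate(tr, 90, fs_interp = 100)
    tibble::tibble(participant_id = id, concert_id = "c1", piece_id = "p1",
                   time_s = r$time_s, bpm = r$bpm)
  })
  sections <- section_annotation("p1", 90, c(30, 60))
  prof <- boundary_rate_profile(rates, sections, fit_model = TRUE)
  wm <- prof$window_means
  at <- function(w) wm$mean_bpm[wm$window == w]
  expect_gt(at("-10"), at("0"))
  expect_gt(at("10"), at("0"))
  est <- prof$fit$coefficients
  expect_gt(est$estimate[est$term == "window-10"], 0)
  expect_gt(est$estimate[est$term == "window10"], 0)
})

test_that("a constant-rate audience shows no window structure", {
  rates <- tidyr::crossing(participant_id = c("a", "b"), concert_id = "c1",
                           piece_id = "p1", time_s = seq(0, 90, by = 0.05))
  rates$bpm <- 61
  sections <- section_annotation("p1", 90, c(30, 60))
  prof <- boundary_rate_profile(rates, sections, fit_model = FALSE)
  expect_equal(unique(prof$window_means$mean_bpm), 61)
})
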