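# Mixed-model contrasts between presentation modalities, with the explicit
# simplification ladder the maximal random-effect structure falls back
# through when it cannot be fit cleanly.

# Nakagawa variance decomposition: marginal R2 uses fixed effects only,
# conditional adds the summed random-effect variance components.
nakagawa_r2 <- function(model) {
  var_fixed <- var(as.numeric(lme4::getME(model, "X") %*% lme4::fixef(model)))
  vc <- lme4::VarCorr(model)
  var_rand <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
  var_resid <- stats::sigma(model)^2
  tot <- var_fixed + var_rand + var_resid
  c(marginal = var_fixed / tot, conditional = (var_fixed + var_rand) / tot)
}

fit_clean <- function(formula, data) {
  warnings <- character()
  model <- withCallingHandlers(
    tryCatch(
      lmerTest::lmer(formula, data = data,
                     control = lme4::lmerControl(calc.derivs = FALSE)),
      error = function(e) e
    ),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      warnings <<- c(warnings, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  if (inherits(model, "error")) {
    return(list(model = NULL, ok = FALSE, singular = NA,
                notes = conditionMessage(model)))
  }
  singular <- lme4::isSingular(model, tol = 1e-4)
  conv_bad <- any(grepl("converge|Hessian|eigenvalue", warnings,
                        ignore.case = TRUE))
  list(model = model, ok = !singular && !conv_bad, singular = singular,
       notes = paste(warnings, collapse = "; "))
}

simplification_ladder <- function(outcome, fixed_rhs, slope_var,
                                  group_vars) {
  pid <- group_vars$participant
  ints <- c(group_vars$concert, group_vars$piece)
  int_terms <- paste(sprintf("(1 | %s)", ints), collapse = " + ")
  stages <- c(
    maximal = sprintf("%s + (%s | %s)", int_terms, slope_var, pid),
    uncorrelated_slope = sprintf("%s + (%s || %s)", int_terms, slope_var, pid),
    intercepts_only = sprintf("%s + (1 | %s)", int_terms, pid),
    drop_concert = sprintf("(1 | %s) + (1 | %s)", group_vars$piece, pid),
    drop_piece = sprintf("(1 | %s) + (1 | %s)", group_vars$concert, pid),
    participant_only = sprintf("(1 | %s)", pid)
  )
  stats::setNames(sprintf("%s ~ %s + %s", outcome, fixed_rhs, stages),
                  names(stages))
}

#' Fit a (possibly simplified) mixed model for a modality contrast
#'
#' Fits the maximal structure the design calls for — fixed effect(s) of
#' modality (and time window for epoched tables), random intercepts for
#' concert, piece and participant (participants nested within concerts via
#' globally unique ids; participant and piece crossed), and a by-participant
#' modality slope — and, when the fit does not converge cleanly or is
#' singular, walks a declared simplification ladder: drop the slope
#' correlation, drop the slope, then drop the smaller-variance of the
#' concert/piece intercepts, down to a participant-only intercept. The path
#' taken is recorded. If even the final stage errors, the function aborts
#' with diagnostics; a final-stage fit that is merely singular is returned
#' with a note.
#'
#' @param data Long tibble of time-averaged or epoched values.
#' @param outcome Name of the outcome column.
#' @param fixed Character vector of fixed-effect terms, e.g. `"condition"`
#'   or `c("condition", "window", "condition:window")`.
#' @param participant,concert,piece Names of the grouping columns.
#' @param slope Random-slope variable for participants (default the first
#'   fixed term); `NULL` skips the slope stages.
#' @return Object of class `modality_fit`: `model`, `path` (tibble of
#'   attempted stages), `coefficients` (estimates, Wald 95% CIs,
#'   Satterthwaite p-values), `r2` (marginal/conditional), `formula`.
#' @export
fit_modality_models <- function(data, outcome = "value",
                                fixed = "condition",
                                participant = "participant_id",
                                concert = "concert_id",
                                piece = "piece_id",
                                slope = fixed[1]) {
  stopifnot(outcome %in% names(data))
  for (v in c(participant, concert, piece)) {
    if (!v %in% names(data)) abort(sprintf("grouping column '%s' missing", v))
  }
  data <- dplyr::filter(data, !is.na(.data[[outcome]]))
  fixed_rhs <- paste(fixed, collapse = " + ")
  groups <- list(participant = participant, concert = concert, piece = piece)
  formulas <- simplification_ladder(outcome, fixed_rhs,
                                    slope %||% "1", groups)
  if (is.null(slope)) formulas <- formulas[-(1:2)]
  path <- list()
  chosen <- NULL
  # order the two single-intercept drops by the fitted variances at the
  # intercepts-only stage: drop the smaller-variance intercept first
  for (i in seq_along(formulas)) {
    nm <- names(formulas)[i]
    if (nm == "drop_concert" && !is.null(path$intercepts_only$model)) {
      vc <- as.data.frame(lme4::VarCorr(path$intercepts_only$model))
      v_concert <- vc$vcov[vc$grp == concert]
      v_piece <- vc$vcov[vc$grp == piece]
      if (length(v_concert) && length(v_piece) && v_piece < v_concert) {
        formulas[c("drop_concert", "drop_piece")] <-
          formulas[c("drop_piece", "drop_concert")]
      }
    }
    fit <- fit_clean(stats::as.formula(formulas[i]), data)
    path[[nm]] <- fit
    if (fit$ok) {
      chosen <- nm
      break
    }
  }
  if (is.null(chosen)) {
    last <- path[[length(path)]]
    if (is.null(last$model)) {
      abort(paste0("no model in the simplification ladder could be fitted; ",
                   "last error: ", last$notes))
    }
    chosen <- names(path)[length(path)]  # singular but identifiable
  }
  model <- path[[chosen]]$model
  coefs <- summary(model)$coefficients
  ci <- stats::confint(model, parm = "beta_", method = "Wald")
  coefficients <- tibble::tibble(
    term = rownames(coefs),
    estimate = unname(coefs[, "Estimate"]),
    std_error = unname(coefs[, "Std. Error"]),
    df = unname(coefs[, "df"]),
    statistic = unname(coefs[, "t value"]),
    p_value = unname(coefs[, "Pr(>|t|)"]),
    conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2])
  )
  path_tbl <- purrr::imap_dfr(path, function(f, nm) {
    tibble::tibble(stage = nm, formula = unname(formulas[nm]),
                   ok = f$ok, singular = f$singular,
                   notes = f$notes %||% "")
  })
  structure(
    list(model = model, path = path_tbl, stage = chosen,
         coefficients = coefficients, r2 = nakagawa_r2(model),
         formula = unname(formulas[chosen]), outcome = outcome,
         n_obs = nrow(data)),
    class = "modality_fit"
  )
}

#' @export
print.modality_fit <- function(x, ...) {
  cat(sprintf("<modality_fit> %s  [stage: %s, n = %d]\n", x$formula,
              x$stage, x$n_obs))
  print(x$coefficients)
  cat(sprintf("R2 marginal %.3f / conditional %.3f\n",
              x$r2["marginal"], x$r2["conditional"]))
  invisible(x)
}

#' Pairwise window contrasts from an epoched modality model
#'
#' Estimated marginal means of a `condition x window` model: (i) AO-AV
#' contrasts within each time window, Bonferroni-adjusted across the five
#' windows; (ii) each window against the boundary window (label "0") within
#' each modality, Bonferroni-adjusted within modality.
#'
#' @param fit A [fit_modality_models()] result whose fixed effects include
#'   `condition`, `window` and their interaction.
#' @param condition,window Names of the factors in the model frame.
#' @return List of class `window_contrasts`: `modality_by_window` and
#'   `window_vs_boundary` tibbles.
#' @export
window_contrasts <- function(fit, condition = "condition",
                             window = "window") {
  stopifnot(inherits(fit, "modality_fit"))
  model <- fit$model
  frame <- model@frame
  if (!all(c(condition, window) %in% names(frame))) {
    abort("model must contain the condition and window factors")
  }
  em_mw <- emmeans::emmeans(model, stats::as.formula(paste0("~ ", condition,
                                                            " | ", window)))
  mw <- as.data.frame(emmeans::contrast(em_mw, method = "pairwise",
                                        adjust = "none"))
  mw$p_adjusted <- pmin(1, mw$p.value * dplyr::n_distinct(mw[[window]]))
  em_w <- emmeans::emmeans(model, stats::as.formula(paste0("~ ", window,
                                                           " | ", condition)))
  lev <- levels(frame[[window]])
  ref <- match("0", lev)
  if (is.na(ref)) ref <- ceiling(length(lev) / 2)
  wb <- as.data.frame(emmeans::contrast(em_w, method = "trt.vs.ctrl",
                                        ref = ref, adjust = "bonferroni"))
  structure(
    list(modality_by_window = tibble::as_tibble(mw),
         window_vs_boundary = tibble::as_tibble(wb)),
    class = "window_contrasts"
  )
}

#' Paired sanity test of a modality difference
#'
#' The conventional check run alongside the mixed models: per-participant
#' AO-AV differences are tested against zero with a one-sample t-test, or a
#' Wilcoxon signed-rank test if a Shapiro-Wilk gate (alpha = 0.05) rejects
#' normality of the differences. The branch taken is reported.
#'
#' @param ao,av Paired per-participant means (same order and length >= 3).
#' @param alpha_normality Shapiro gate level.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n`,
#'   `shapiro_p`, `mean_difference`.
#' @export
sanity_paired_test <- function(ao, av, alpha_normality = 0.05) {
  stopifnot(length(ao) == length(av))
  d <- ao - av
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3) abort("sanity_paired_test() needs at least 3 complete pairs")
  if (all(d == 0)) {
    return(tibble::tibble(test = "t", statistic = 0, p_value = 1, n = n,
                          shapiro_p = NA_real_, mean_difference = 0))
  }
  shapiro_p <- tryCatch(stats::shapiro.test(d)$p.value,
                        error = function(e) 0)
  if (sd(d) == 0) {
    # constant nonzero difference: the t statistic diverges
    return(tibble::tibble(test = "t", statistic = sign(mean(d)) * Inf,
                          p_value = 0, n = n, shapiro_p = shapiro_p,
                          mean_difference = mean(d)))
  }
  if (shapiro_p >= alpha_normality) {
    tt <- stats::t.test(d)
    tibble::tibble(test = "t", statistic = unname(tt$statistic),
                   p_value = tt$p.value, n = n, shapiro_p = shapiro_p,
                   mean_difference = mean(d))
  } else {
    wt <- stats::wilcox.test(d, exact = FALSE)
    tibble::tibble(test = "wilcoxon", statistic = unname(wt$statistic),
                   p_value = wt$p.value, n = n, shapiro_p = shapiro_p,
                   mean_difference = mean(d))
  }
}

#' Heart/respiration rate profile around section boundaries
#'
#' Epochs raw BPM series around the annotated boundaries (same ±15 s / five
#' 6-s window geometry as the synchrony epochs), returns the per-window mean
#' table, and fits a window-effect mixed model with the boundary window as
#' the reference level — the machinery that shows the orienting
#' deceleration-acceleration pattern (windows ±10 above window 0).
#'
#' @param rates Long tibble with columns `time_s`, `bpm`, `piece_id`,
#'   `participant_id`, `concert_id` (and optionally `condition`).
#' @param sections A [section_annotation()] table.
#' @param half_width_s,window_len_s Epoch geometry.
#' @return List of class `rate_profile`: `epochs` (epoch table),
#'   `window_means` (mean ± se per window), `fit` (a `modality_fit` with
#'   window fixed effect), or `fit = NULL` if the model is unwanted
#'   (`fit_model = FALSE`).
#' @param fit_model Whether to fit the window-effect model.
#' @export
boundary_rate_profile <- function(rates, sections, half_width_s = 15,
                                  window_len_s = 6, fit_model = TRUE) {
  stopifnot(all(c("time_s", "bpm", "piece_id") %in% names(rates)))
  d <- dplyr::rename(rates, value = "bpm")
  epochs <- epoch_around_boundaries(d, sections, half_width_s = half_width_s,
                                    window_len_s = window_len_s,
                                    time_col = "time_s")
  window_means <- dplyr::summarise(
    epochs,
    mean_bpm = mean(.data$value, na.rm = TRUE),
    se_bpm = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
    .by = "window"
  )
  fit <- NULL
  if (fit_model) {
    ep <- dplyr::mutate(epochs,
                        window = stats::relevel(factor(.data$window), ref = "0"))
    fit <- fit_modality_models(ep, outcome = "value", fixed = "window",
                               slope = NULL)
  }
  structure(list(epochs = epochs, window_means = window_means, fit = fit),
            class = "rate_profile")
}
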