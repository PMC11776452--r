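#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a circular-shift permutation test
#'
#' @param x A `perm_test` from [circular_null_test()].
#' @param ... Unused.
#' @return One-row tibble: `measure`, `statistic` (observed one-sample t),
#'   `p.value`, `n.perm`, `null.mean`, `null.sd`.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(measure = x$measure, statistic = x$observed_stat,
                 p.value = x$p_value, n.perm = x$n_perm,
                 null.mean = mean(x$null_stats, na.rm = TRUE),
                 null.sd = sd(x$null_stats, na.rm = TRUE))
}

#' Tidy / summarise a modality mixed-model fit
#'
#' `tidy()` returns the coefficient table (estimates, Wald 95% CIs,
#' Satterthwaite p-values); `glance()` the one-row fit summary including the
#' simplification stage reached and Nakagawa R².
#'
#' @param x A `modality_fit` from [fit_modality_models()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.modality_fit <- function(x, ...) {
  dplyr::rename(x$coefficients, std.error = "std_error",
                p.value = "p_value", conf.low = "conf_low",
                conf.high = "conf_high")
}

#' @rdname tidy.modality_fit
#' @export
glance.modality_fit <- function(x, ...) {
  tibble::tibble(stage = x$stage, formula = x$formula, nobs = x$n_obs,
                 sigma = stats::sigma(x$model),
                 r2.marginal = x$r2[["marginal"]],
                 r2.conditional = x$r2[["conditional"]],
                 singular = lme4::isSingular(x$model, tol = 1e-4))
}

#' Tidy a group-lag estimate
#'
#' @param x A `lag_estimate` from [estimate_group_lag()].
#' @param ... Unused.
#' @return The per-participant tibble with the group lag attached.
#' @export
tidy.lag_estimate <- function(x, ...) {
  dplyr::mutate(x$per_participant, group_lag_ms = x$group_lag_ms,
                measure = x$measure)
}
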