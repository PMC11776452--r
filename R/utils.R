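#' @importFrom stats approx cor fft median quantile rnorm runif sd var
#' @importFrom rlang %||% abort warn .data
NULL

# Wrap angles into (-pi, pi].
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Analytic signal via the frequency-domain construction: double positive
# frequencies, zero negative ones. Returns complex vector, same length.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) abort("analytic_signal() needs at least 2 samples")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# Zero-phase IIR filtering with odd-reflection edge padding and DC-matched
# initial conditions; signal::filtfilt uses zero initial conditions and
# leaves large edge transients (even on constant input). Padding length
# scales with the filter's settling time (largest pole modulus), capped at
# the series length.
zero_phase_filter <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  ord <- max(length(a), length(b)) - 1L
  dc <- sum(b) / sum(a)
  pmax_mod <- tryCatch(min(max(Mod(polyroot(rev(a)))), 0.9995),
                       error = function(e) 0.9)
  settle <- ceiling(log(1e-6) / log(max(pmax_mod, 0.1)))
  npad <- min(length(x) - 1L, max(3L * ord, settle))
  mu <- mean(x)
  xc <- x - mu
  n <- length(xc)
  pre <- 2 * xc[1] - xc[seq(npad + 1, 2)]
  post <- 2 * xc[n] - xc[seq(n - 1, n - npad)]
  xp <- c(pre, xc, post)
  run <- function(v) {
    as.numeric(signal::filter(b, a, v, init.x = rep(v[1], ord),
                              init.y = rep(v[1] * dc, ord)))
  }
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[seq(npad + 1, npad + n)] + mu
}

# Low-pass + subsample decimation; ratio must be a whole number.
decimate_series <- function(x, fs_in, fs_out) {
  ratio <- fs_in / fs_out
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort("fs_in must be an integer multiple of fs_out")
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(x)
  lp <- signal::butter(4, (0.8 * fs_out / 2) / (fs_in / 2), type = "low")
  y <- zero_phase_filter(lp, x)
  y[seq(1, length(y), by = ratio)]
}

# Linear interpolation of a wrapped angle series: interpolate the unwrapped
# phase (monotone for cycle phase) and re-wrap.
interp_wrapped <- function(t_in, theta, t_out) {
  unwrapped <- unwrap_angle(theta)
  wrap_angle(approx(t_in, unwrapped, xout = t_out, rule = 1)$y)
}

unwrap_angle <- function(theta) {
  d <- diff(theta)
  jumps <- cumsum(c(0, round(-d / (2 * pi))))
  theta + 2 * pi * jumps
}

# One-sample t statistic against zero; NA if fewer than 2 finite values.
t_stat_one_sample <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) return(NA_real_)
  s <- sd(x)
  if (s == 0) return(if (mean(x) == 0) 0 else Inf * sign(mean(x)))
  mean(x) / (s / sqrt(n))
}

check_strictly_increasing <- function(times, what = "peak times") {
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort(paste0(what, " must be strictly increasing"))
  }
  invisible(times)
}
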