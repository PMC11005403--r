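#' Doubling time from a growth curve
#'
#' Least-squares fit of ln(cell density) against time within a window of
#' the exponential phase; the doubling time is tau = ln(2)/slope, reported
#' in minutes with a delta-method standard error from the slope SE. With
#' `window = "auto"` the contiguous span of at least four points that
#' maximizes the R-squared of the log-linear fit is used, a simple
#' exponential-phase selector for lag/log/stationary shaped curves.
#'
#' @param times Sampling times in hours, strictly increasing.
#' @param densities Cell densities (cells/mL), > 0.
#' @param window Either `"auto"` or a numeric `c(t_start, t_end)` in hours.
#' @return An object of class `doubling_time`: `tau` (min), `se` (min),
#'   `window` (hours), `r_squared`, `slope` (per hour), `n`.
#' @examples
#' t <- seq(0, 6, by = 1)
#' d <- 1e6 * 2^(t * 60 / 90.6)
#' fit_doubling_time(t, d)$tau # 90.6
#' @export
fit_doubling_time <- function(times, densities, window = "auto") {
  if (length(times) != length(densities)) {
    stop("`times` and `densities` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(densities)) || any(densities <= 0)) {
    stop("densities must be finite and > 0", call. = FALSE)
  }
  if (identical(window, "auto")) {
    window <- auto_growth_window(times, densities)
  }
  if (!is.numeric(window) || length(window) != 2L || window[1L] >= window[2L]) {
    stop("`window` must be \"auto\" or c(t_start, t_end) with t_start < t_end",
         call. = FALSE)
  }
  keep <- times >= window[1L] & times <= window[2L]
  if (sum(keep) < 3L) stop("need >= 3 points inside the window", call. = FALSE)
  t <- times[keep]
  y <- log(densities[keep])
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2L])
  if (slope <= 0) stop("non-positive growth slope: no exponential growth in window",
                       call. = FALSE)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  se_slope <- sqrt(ssr / (length(t) - 2) / sum((t - mean(t))^2))
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  tau_min <- log(2) / slope * 60
  se_min <- log(2) / slope^2 * se_slope * 60
  structure(
    list(tau = tau_min, se = se_min, window = window, r_squared = r2,
         slope = slope, n = sum(keep)),
    class = "doubling_time"
  )
}

auto_growth_window <- function(times, densities) {
  n <- length(times)
  if (n < 4L) stop("auto window needs >= 4 points", call. = FALSE)
  y <- log(densities)
  best <- NULL
  best_r2 <- -Inf
  for (i in seq_len(n - 3L)) {
    for (j in (i + 3L):n) {
      t <- times[i:j]
      yy <- y[i:j]
      fit <- stats::lm(yy ~ t)
      if (unname(stats::coef(fit)[2L]) <= 0) next
      sst <- sum((yy - mean(yy))^2)
      r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
      if (r2 > best_r2 + 1e-12) {
        best_r2 <- r2
        best <- c(times[i], times[j])
      }
    }
  }
  if (is.null(best)) stop("no growing window found", call. = FALSE)
  best
}

#' @export
print.doubling_time <- function(x, ...) {
  cat(sprintf("<doubling_time> tau = %.1f +/- %.1f min (window %.2g-%.2g h, R^2 = %.4f, n = %d)\n",
              x$tau, x$se, x$window[1L], x$window[2L], x$r_squared, x$n))
  invisible(x)
}

#' Ratio of two doubling times
#'
#' `a$tau / b$tau` with first-order (delta-method) propagation of the two
#' standard errors. Accepts `doubling_time` objects or plain
#' `list(tau =, se =)` values, so printed literature values can be compared
#' directly.
#'
#' @param a,b Doubling times (numerator, denominator).
#' @return List with `ratio` and `se`.
#' @examples
#' doubling_ratio(list(tau = 215.3, se = 35.7), list(tau = 90.6, se = 7.5))
#' @export
doubling_ratio <- function(a, b) {
  get_tau <- function(x) {
    if (is.numeric(x)) list(tau = x[1L], se = 0)
    else list(tau = x$tau, se = if (is.null(x$se)) 0 else x$se)
  }
  a <- get_tau(a); b <- get_tau(b)
  if (!is.finite(a$tau) || !is.finite(b$tau) || a$tau <= 0 || b$tau <= 0) {
    stop("doubling times must be finite and > 0", call. = FALSE)
  }
  ratio <- a$tau / b$tau
  se <- ratio * sqrt((a$se / a$tau)^2 + (b$se / b$tau)^2)
  list(ratio = ratio, se = se)
}
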