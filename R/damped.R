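# Damped-oscillation fitting for tissue-explant luminescence traces
# (e.g. PER2::LUC liver slices): y(t) = m + A * exp(-lambda*t) * cos(2*pi*(t - phi)/tau).

damped_model <- function(t, A, lambda, tau, phi) {
  A * exp(-lambda * t) * cos(2 * pi * (t - phi) / tau)
}

# Centered running mean over a window of `width` hours; returned only where
# the full window fits, together with the index range kept.
running_mean <- function(times, values, width) {
  dt <- stats::median(diff(times))
  half <- round(width / dt / 2)
  n <- length(values)
  if (n < 2 * half + 1) return(NULL)
  cs <- c(0, cumsum(values))
  idx <- (half + 1):(n - half)
  trend <- (cs[idx + half + 1] - cs[idx - half]) / (2 * half + 1)
  list(idx = idx, trend = trend)
}

#' Fit a damped cosine to a luminescence trace
#'
#' Fits `y(t) = m + A * exp(-lambda t) * cos(2*pi*(t - phi)/tau)` by
#' nonlinear least squares after removing the slow baseline with a centered
#' running mean (default window 24 h, one nominal circadian period; a
#' full-period running mean of a damped cosine is itself a damped cosine
#' with the same `lambda` and `tau`, so the detrend does not bias period or
#' damping). Optimisation is multi-started over 8 phase offsets and 3
#' period starts inside `period_bounds`; the `converged` flag is honest:
#' a flat trace, or failure of every start, yields `converged = FALSE`
#' with `NA` parameters.
#'
#' @param times Hours, near-uniformly sampled; must span at least twice the
#'   lower period bound.
#' @param values Luminescence values.
#' @param period_bounds Search interval for the period `tau`, hours.
#' @param detrend_window Running-mean window in hours.
#' @return List of class `"damped_fit"`: `mesor`, `amplitude`,
#'   `damping_lambda` (per hour), `period_tau` (hours), `phase` (hours),
#'   `rss`, `converged`.
#' @export
fit_damped_oscillation <- function(times, values,
                                   period_bounds = c(16, 32),
                                   detrend_window = 24) {
  stopifnot(length(times) == length(values), length(period_bounds) == 2)
  o <- order(times)
  times <- times[o]; values <- values[o]
  if (diff(range(times)) < 2 * period_bounds[1]) {
    stop("trace must span at least twice the lower period bound", call. = FALSE)
  }
  failed <- structure(list(mesor = NA_real_, amplitude = NA_real_,
                           damping_lambda = NA_real_, period_tau = NA_real_,
                           phase = NA_real_, rss = NA_real_, converged = FALSE),
                      class = "damped_fit")

  rm_ <- running_mean(times, values, detrend_window)
  if (is.null(rm_)) return(failed)
  t_ <- times[rm_$idx]
  y <- values[rm_$idx] - rm_$trend
  if (stats::sd(y) < 1e-10 * max(1, abs(mean(values)))) return(failed)

  rssf <- function(par) {
    if (par[1] < 0 || par[2] < 0 ||
        par[3] < period_bounds[1] || par[3] > period_bounds[2]) return(Inf)
    sum((y - damped_model(t_, par[1], par[2], par[3], par[4]))^2)
  }
  A0 <- stats::sd(y) * sqrt(2)
  tau_starts <- c(period_bounds[1], mean(period_bounds), period_bounds[2])
  best <- NULL
  for (tau0 in tau_starts) {
    for (phi0 in seq(0, tau0, length.out = 9)[1:8]) {
      res <- try(stats::optim(c(A0, 0.02, tau0, phi0), rssf,
                              method = "Nelder-Mead",
                              control = list(maxit = 2000, reltol = 1e-12)),
                 silent = TRUE)
      if (inherits(res, "try-error") || !is.finite(res$value)) next
      if (is.null(best) || res$value < best$value) best <- res
    }
  }
  if (is.null(best)) return(failed)
  # polish the winner
  res <- try(stats::optim(best$par, rssf, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-14)),
             silent = TRUE)
  if (!inherits(res, "try-error") && is.finite(res$value) &&
      res$value <= best$value) best <- res
  par <- best$par
  # oscillation must explain the detrended signal; otherwise not converged
  if (best$value > 0.5 * sum(y^2)) return(failed)
  structure(list(mesor = mean(rm_$trend),
                 amplitude = par[1],
                 damping_lambda = par[2],
                 period_tau = par[3],
                 phase = par[4] %% par[3],
                 rss = best$value,
                 converged = TRUE),
            class = "damped_fit")
}
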