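# Circular statistics on acrophases and phase shifts. Hours are mapped to
# angles by theta = 2*pi*h/T; all outputs come back in hours.

#' Signed circular phase difference
#'
#' `phi_B - phi_A` wrapped into `(-T/2, T/2]`; negative values are phase
#' advances, positive values delays (so a corticosterone peak moving from
#' ZT12 to ZT6 is `-6`, a 6 h advance). The boundary case of exactly half a
#' period is reported as `+T/2` (a delay), making the difference
#' single-valued.
#'
#' @param phi_A,phi_B Phases in hours.
#' @param T Period in hours.
#' @return Difference in hours, vectorised over the inputs.
#' @export
#' @examples
#' signed_phase_difference(12, 6)   # -6: advance
#' signed_phase_difference(19, 1)   # +6: wrap-around delay
signed_phase_difference <- function(phi_A, phi_B, T = 24) {
  if (!is.numeric(T) || T <= 0) stop("period T must be positive", call. = FALSE)
  stopifnot(all(is.finite(phi_A)), all(is.finite(phi_B)))
  d <- ((phi_B - phi_A + T / 2) %% T) - T / 2
  d[d == -T / 2] <- T / 2
  d
}

#' Mean resultant vector and Rayleigh statistic of circular data
#'
#' Maps hours to angles, sums the unit vectors and reports the mean
#' resultant length `R = |sum(exp(i*theta))| / n`, the mean direction in
#' hours (undefined when `R = 0`), and the Rayleigh statistic `Z = n R^2`
#' with its p-value (see [rayleigh_test()]). This is the "normalization
#' vector" summary of a phase-shift wedge plot: the arrow's length is `R`
#' and its direction the mean shift.
#'
#' @param hours Phases or shifts in hours.
#' @param T Period in hours.
#' @return List of class `"circular_summary"`: `n`, `mean_direction`
#'   (hours in `[0, T)`, `NA` when `R` is 0), `resultant_length_R`,
#'   `rayleigh_Z`, `rayleigh_p` (`NA` when `n < 2`).
#' @export
circular_mean_vector <- function(hours, T = 24) {
  if (length(hours) < 1) stop("need at least one value", call. = FALSE)
  stopifnot(all(is.finite(hours)))
  theta <- 2 * pi * hours / T
  C <- sum(cos(theta)); S <- sum(sin(theta))
  n <- length(hours)
  R <- sqrt(C^2 + S^2) / n
  mean_dir <- if (R < 1e-12) NA_real_ else (atan2(S, C) * T / (2 * pi)) %% T
  Z <- n * R^2
  p <- if (n >= 2) rayleigh_p_value(Z, n) else NA_real_
  structure(list(n = n, mean_direction = mean_dir, resultant_length_R = R,
                 rayleigh_Z = Z, rayleigh_p = p),
            class = "circular_summary")
}

rayleigh_p_value <- function(Z, n) {
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  min(max(p, 1e-300), 1)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that the angles are uniformly distributed on
#' the circle, `Z = n R^2`, with the standard series-corrected p-value
#' `p = exp(-Z) [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288 n^2)]`,
#' clipped into `(0, 1]`. Used to ask whether phase shifts have a preferred
#' direction.
#'
#' @param hours Angles in hours.
#' @param T Period in hours.
#' @return List with `Z` and `p`.
#' @export
rayleigh_test <- function(hours, T = 24) {
  if (length(hours) < 2) stop("Rayleigh test needs n >= 2", call. = FALSE)
  cs <- circular_mean_vector(hours, T)
  list(Z = cs$rayleigh_Z, p = cs$rayleigh_p)
}

#' Wedge histogram of phase shifts
#'
#' Converts hours to degrees (`h * 360/T`, wrapped into `[0, 360)`) and
#' counts values in half-open wedges `[lo, hi)` of `wedge_width` degrees,
#' the binning used for polar shift plots ("number of genes per 20°
#' wedge").
#'
#' @param hours Shifts or phases in hours.
#' @param T Period in hours.
#' @param wedge_width Wedge width in degrees; must divide 360.
#' @return `data.frame` with `wedge_start_deg`, `wedge_end_deg`, `count`.
#' @export
wedge_histogram <- function(hours, T = 24, wedge_width = 20) {
  if (360 %% wedge_width != 0) {
    stop("wedge_width must divide 360", call. = FALSE)
  }
  n_wedge <- 360 / wedge_width
  deg <- (hours * 360 / T) %% 360
  idx <- floor(deg / wedge_width)        # 0 .. n_wedge-1
  idx[idx == n_wedge] <- 0               # guard against deg == 360 - eps rounding
  counts <- tabulate(idx + 1, nbins = n_wedge)
  data.frame(wedge_start_deg = wedge_width * (seq_len(n_wedge) - 1),
             wedge_end_deg = wedge_width * seq_len(n_wedge),
             count = counts)
}
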