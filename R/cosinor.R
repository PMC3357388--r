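# Cosinor / harmonic regression rhythm detection.
#
# Model: y(t) = m + sum_{k=1..K} [ a_k cos(2*pi*k*t/T) + b_k sin(2*pi*k*t/T) ] + e
# Rhythmicity is the F-test of the full harmonic model against the
# intercept-only null.

harmonic_design <- function(times, K, T) {
  X <- matrix(1, nrow = length(times), ncol = 1 + 2 * K)
  for (k in seq_len(K)) {
    w <- 2 * pi * k * times / T
    X[, 2 * k] <- cos(w)
    X[, 2 * k + 1] <- sin(w)
  }
  colnames(X) <- c("mesor",
                   as.vector(rbind(paste0("a", seq_len(K)), paste0("b", seq_len(K)))))
  X
}

# Fits the harmonic model to every row of Y (genes x samples) with one QR
# decomposition; returns per-row parameter vectors. Degenerate-variance
# conventions: rss_null ~ 0 -> flat profile (F = 0, p = 1); otherwise
# rss_full ~ 0 -> saturated fit (F = Inf, p = 0, saturated flag).
cosinor_fit_matrix <- function(times, Y, K = 1, T = 24) {
  n <- length(times)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1)
  stopifnot(ncol(Y) == n)
  n_distinct <- length(unique(round(times %% T, 10)))
  if (2 * K + 1 >= n_distinct) {
    stop(sprintf("K = %d harmonics need > %d distinct timepoints; have %d",
                 K, 2 * K + 1, n_distinct), call. = FALSE)
  }
  df_model <- 2 * K
  df_resid <- n - 2 * K - 1
  if (df_resid < 1) stop("zero residual degrees of freedom", call. = FALSE)

  X <- harmonic_design(times, K, T)
  qrx <- qr(X)
  coef <- t(qr.coef(qrx, t(Y)))            # genes x (2K+1)
  fitted <- coef %*% t(X)
  rss_full <- rowSums((Y - fitted)^2)
  mu <- rowMeans(Y)
  rss_null <- rowSums((Y - mu)^2)
  # guard against tiny negative differences from floating point
  rss_full <- pmin(rss_full, rss_null)

  a1 <- coef[, 2]
  b1 <- coef[, 3]
  if (K == 1) {
    amplitude <- sqrt(a1^2 + b1^2)
    acrophase <- ((T / (2 * pi)) * atan2(b1, a1)) %% T
    acrophase[amplitude < 1e-12] <- NA_real_
  } else {
    # acrophase = argmax of the fitted curve on a 0.01 h grid
    grid <- seq(0, T, by = 0.01)
    grid <- grid[-length(grid)]
    Xg <- harmonic_design(grid, K, T)
    curves <- coef %*% t(Xg)
    acrophase <- grid[max.col(curves, ties.method = "first")]
    amplitude <- (apply(curves, 1, max) - apply(curves, 1, min)) / 2
    acrophase[amplitude < 1e-12] <- NA_real_
  }

  eps <- 1e-10
  flat <- rss_null <= eps * pmax(1, mu^2) * n
  saturated <- !flat & (rss_full <= 1e-8 * rss_null)
  F_stat <- ((rss_null - rss_full) / df_model) / (rss_full / df_resid)
  F_stat[flat] <- 0
  F_stat[saturated] <- Inf
  p <- stats::pf(F_stat, df_model, df_resid, lower.tail = FALSE)
  p[flat] <- 1
  p[saturated] <- 0

  list(mesor = coef[, 1], a1 = a1, b1 = b1,
       amplitude = amplitude, acrophase = acrophase,
       rss_full = rss_full, rss_null = rss_null,
       df_model = df_model, df_resid = df_resid,
       F_stat = F_stat, p_value = p, saturated = saturated)
}

#' Fit a cosinor (harmonic regression) model to one time course
#'
#' Ordinary least squares fit of `K` harmonic pairs at period `T` plus a
#' mesor (rhythm-adjusted mean). For `K = 1` the amplitude is
#' `sqrt(a1^2 + b1^2)` and the acrophase (fitted peak time) is
#' `(T/2*pi) * atan2(b1, a1) mod T`; for `K > 1` the acrophase is taken as
#' the argmax of the fitted curve on a 0.01 h grid. Rhythmicity is the
#' F-statistic of the harmonic terms against the intercept-only model,
#' `F = [(rss_null - rss_full)/2K] / [rss_full/(n - 2K - 1)]`.
#'
#' A perfectly flat profile returns `F = 0, p = 1`; a saturated fit
#' (`rss_full = 0` with non-zero variance, as for noiseless rhythmic data)
#' returns `p = 0` with `saturated = TRUE`.
#'
#' @param times Sampling times in hours (ZT).
#' @param values Log2 expression values, same length as `times`.
#' @param K Number of harmonic pairs; identifiability requires
#'   `2K + 1 <` the number of distinct timepoints.
#' @param T Period in hours.
#' @return Object of class `"cosinor_fit"`: list with `mesor`, `a1`, `b1`,
#'   `amplitude`, `acrophase`, `rss_full`, `rss_null`, `df_model`,
#'   `df_resid`, `F_stat`, `p_value`, `saturated`.
#' @export
#' @examples
#' zt <- rep(c(1, 7, 13, 19), each = 3)
#' y <- 10 + 2 * cos(2 * pi * (zt - 13) / 24) + rnorm(12, sd = 0.3)
#' fit <- fit_cosinor(zt, y)
#' c(fit$mesor, fit$amplitude, fit$acrophase)
fit_cosinor <- function(times, values, K = 1, T = 24) {
  stopifnot(length(times) == length(values), all(is.finite(times)))
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  res <- cosinor_fit_matrix(times, matrix(values, nrow = 1), K = K, T = T)
  out <- lapply(res, function(x) unname(x[1]))
  out$df_model <- res$df_model
  out$df_resid <- res$df_resid
  structure(out, class = "cosinor_fit")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} (p_(j) * m / j)` capped at 1, returned in the
#' input order.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, q_sorted)[order(o)]
}

#' Detect rhythmic genes within one condition
#'
#' Fits the cosinor model to every gene for the samples of `condition`,
#' adjusts the per-gene F-test p-values by Benjamini-Hochberg across all
#' genes of the condition, and calls a gene rhythmic when `q < alpha`.
#'
#' @param mat Expression matrix (genes x samples, log2), as from
#'   [read_expression_matrix()] or [generate_transcriptome()].
#' @param samples Sample table matching `colnames(mat)`.
#' @param condition Condition label to analyse.
#' @param config [analysis_config()] list.
#' @return `data.frame` (one row per gene): gene, condition, mesor,
#'   amplitude, acrophase, F_stat, p_value, q_value, rhythmic.
#' @export
detect_rhythms <- function(mat, samples, condition, config = analysis_config()) {
  if (!condition %in% samples$condition) {
    stop("condition '", condition, "' not present in sample table", call. = FALSE)
  }
  if (!all(samples$sample_id %in% colnames(mat))) {
    stop("sample table and matrix columns are inconsistent", call. = FALSE)
  }
  sel <- samples[samples$condition == condition, ]
  Y <- mat[, sel$sample_id, drop = FALSE]
  fit <- cosinor_fit_matrix(sel$zt, Y, K = config$max_harmonics_K,
                            T = config$period_T)
  q <- bh_adjust(fit$p_value)
  data.frame(gene = rownames(mat),
             condition = condition,
             mesor = fit$mesor,
             amplitude = fit$amplitude,
             acrophase = fit$acrophase,
             F_stat = fit$F_stat,
             p_value = fit$p_value,
             q_value = q,
             rhythmic = q < config$alpha,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
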