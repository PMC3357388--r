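# Statistics for diurnal physiological profiles (hormones, metabolites,
# food intake) and tolerance tests.

#' Two-way fixed-effects ANOVA (condition x time) with Bonferroni post-hoc
#'
#' Decomposes a physiological time-course into condition, time and
#' interaction effects. Unbalanced designs use type-II sums of squares
#' (each main effect adjusted for the other, the interaction adjusted for
#' both). Post-hoc per-timepoint condition contrasts use the pooled
#' residual variance, with the p-value Bonferroni-multiplied by the number
#' of timepoints. Degenerate profiles (zero residual variance) report
#' `F = 0, p = 1` for null effects and `F = Inf, p = 0` for non-null ones.
#'
#' @param profile `data.frame` with columns `condition`, `zt`, `value`
#'   (extra columns such as `replicate` are ignored).
#' @return List of class `"anova_result"`: `effects` (`data.frame`:
#'   effect, sum_sq, df, F_stat, p_value), `posthoc` (`data.frame`: zt,
#'   diff, t_stat, p_value, p_adj; only when there are exactly two
#'   conditions), `ms_resid`, `df_resid`.
#' @export
two_way_anova <- function(profile) {
  stopifnot(all(c("condition", "zt", "value") %in% names(profile)))
  A <- factor(profile$condition)
  B <- factor(profile$zt)
  y <- profile$value
  if (nlevels(A) < 2 || nlevels(B) < 2) {
    stop("need >= 2 conditions and >= 2 timepoints", call. = FALSE)
  }
  tab <- table(A, B)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: condition '%s' at zt %s",
                 levels(A)[empty[1]], levels(B)[empty[2]]), call. = FALSE)
  }
  n <- length(y)
  rss <- function(f) sum(stats::lm.fit(stats::model.matrix(f), y)$residuals^2)
  r_a   <- rss(~A)
  r_b   <- rss(~B)
  r_ab  <- rss(~A + B)
  r_int <- rss(~A * B)
  ss <- c(condition = r_b - r_ab, time = r_a - r_ab, interaction = r_ab - r_int)
  ss <- pmax(ss, 0)
  df <- c(condition = nlevels(A) - 1, time = nlevels(B) - 1,
          interaction = (nlevels(A) - 1) * (nlevels(B) - 1))
  df_res <- n - nlevels(A) * nlevels(B)
  if (df_res < 1) stop("no residual degrees of freedom (need replicates)",
                       call. = FALSE)
  ms_res <- r_int / df_res
  scale_ <- max(1, mean(y)^2)
  degen <- ms_res <= 1e-20 * scale_
  F_stat <- (ss / df) / ms_res
  p <- stats::pf(F_stat, df, df_res, lower.tail = FALSE)
  if (degen) {
    null_eff <- ss <= 1e-20 * scale_
    F_stat <- ifelse(null_eff, 0, Inf)
    p <- ifelse(null_eff, 1, 0)
  }
  effects <- data.frame(effect = names(ss), sum_sq = unname(ss),
                        df = unname(df), F_stat = unname(F_stat),
                        p_value = unname(p), stringsAsFactors = FALSE)

  posthoc <- NULL
  if (nlevels(A) == 2) {
    zts <- levels(B)
    rows <- lapply(zts, function(z) {
      y1 <- y[A == levels(A)[1] & B == z]
      y2 <- y[A == levels(A)[2] & B == z]
      d <- mean(y2) - mean(y1)
      se <- sqrt(ms_res * (1 / length(y1) + 1 / length(y2)))
      if (se <= 0 || !is.finite(se) || degen) {
        t_stat <- if (d == 0) 0 else Inf * sign(d)
        pv <- if (d == 0) 1 else 0
      } else {
        t_stat <- d / se
        pv <- 2 * stats::pt(-abs(t_stat), df_res)
      }
      data.frame(zt = as.numeric(z), diff = d, t_stat = t_stat,
                 p_value = pv, p_adj = min(1, pv * length(zts)))
    })
    posthoc <- do.call(rbind, rows)
  }
  structure(list(effects = effects, posthoc = posthoc,
                 ms_resid = ms_res, df_resid = df_res),
            class = "anova_result")
}

#' Cosinor peak phase of a physiological profile
#'
#' Averages replicates within each timepoint of one condition and fits the
#' single-harmonic cosinor; returns the acrophase in ZT hours. At least 4
#' distinct timepoints are required.
#'
#' @param profile `data.frame` with `condition`, `zt`, `value`.
#' @param condition Condition label.
#' @param T Period in hours.
#' @return Acrophase in `[0, T)`.
#' @export
profile_peak_phase <- function(profile, condition, T = 24) {
  sel <- profile[profile$condition == condition, ]
  if (nrow(sel) == 0) stop("condition '", condition, "' not present", call. = FALSE)
  means <- tapply(sel$value, sel$zt, mean)
  zts <- as.numeric(names(means))
  if (length(zts) < 4) stop("need >= 4 distinct timepoints", call. = FALSE)
  fit <- fit_cosinor(zts, as.numeric(means), K = 1, T = T)
  fit$acrophase
}

#' Trapezoidal area under a tolerance-test curve
#'
#' Total AUC by the trapezoid rule, plus the baseline-corrected variant
#' that subtracts `value at t = 0` times the duration (no flooring: a
#' response below baseline yields a negative corrected AUC).
#'
#' @param times Minutes, starting at 0, strictly increasing.
#' @param values Glucose (mg/dl) at `times`.
#' @return List: `total_auc`, `baseline_corrected_auc` (mg/dl x min).
#' @export
tolerance_auc <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  if (times[1] != 0) stop("time grid must start at 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  total <- sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
  corrected <- total - values[1] * (times[length(times)] - times[1])
  list(total_auc = total, baseline_corrected_auc = corrected)
}

#' Relative qPCR quantitation (delta-delta-Ct)
#'
#' For each sample and target gene: `delta_ct = Ct_target - Ct_reference`
#' (reference replicates averaged on the Ct scale),
#' `delta_delta_ct = delta_ct - delta_ct(calibrator sample)`, and
#' `fold_change = 2^(-delta_delta_ct)`. The calibrator's own fold change
#' is 1 by construction.
#'
#' @param ct `data.frame` with columns `sample`, `gene`, `ct` (long
#'   format; several rows per sample/gene are treated as replicates).
#' @param reference_gene Housekeeping gene id.
#' @param calibrator_sample Sample id used as the calibrator.
#' @return `data.frame`: sample, gene, delta_ct, delta_delta_ct,
#'   fold_change (target genes only).
#' @export
ddct_fold_change <- function(ct, reference_gene, calibrator_sample) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  samples <- unique(ct$sample)
  if (!calibrator_sample %in% samples) {
    stop("calibrator sample '", calibrator_sample, "' absent", call. = FALSE)
  }
  ref_ct <- sapply(samples, function(s) {
    v <- ct$ct[ct$sample == s & ct$gene == reference_gene]
    if (length(v) == 0) {
      stop("missing Ct for sample '", s, "', gene '", reference_gene, "'",
           call. = FALSE)
    }
    mean(v)
  })
  targets <- setdiff(unique(ct$gene), reference_gene)
  rows <- lapply(targets, function(g) {
    dct <- sapply(samples, function(s) {
      v <- ct$ct[ct$sample == s & ct$gene == g]
      if (length(v) == 0) {
        stop("missing Ct for sample '", s, "', gene '", g, "'", call. = FALSE)
      }
      mean(v) - ref_ct[[s]]
    })
    ddct <- dct - dct[[calibrator_sample]]
    data.frame(sample = samples, gene = g, delta_ct = unname(dct),
               delta_delta_ct = unname(ddct),
               fold_change = 2^(-unname(ddct)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
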