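# Six-class taxonomy of between-condition rhythm changes:
#   I   rhythmic in both, acrophase conserved (|dphi| < threshold)
#   II  rhythmic in both, phase-shifted       (|dphi| >= threshold)
#   III rhythmic in condition 1 only ("rhythmic to arrhythmic")
#   IV  arrhythmic in both, baseline up in condition 2
#   V   arrhythmic in both, baseline down in condition 2
#   VI  rhythmic in condition 2 only (de-novo rhythm)
#   NC  no change

#' Welch two-sample test of baseline expression change
#'
#' Pools all samples of a gene across timepoints within each condition and
#' compares the means by Welch's unequal-variance t-test. The log2 fold
#' change is `mean(condition 2) - mean(condition 1)`. When both groups have
#' (numerically) zero variance the test is degenerate: `p` is 0 if the
#' means differ and 1 otherwise, and `degenerate = TRUE` is flagged.
#'
#' @param values1,values2 Log2 expression values in conditions 1 and 2
#'   (>= 2 each).
#' @return List: `baseline_lfc`, `t_stat`, `df`, `p_value`, `degenerate`.
#' @export
baseline_change_test <- function(values1, values2) {
  n1 <- length(values1); n2 <- length(values2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per condition", call. = FALSE)
  m1 <- mean(values1); m2 <- mean(values2)
  v1 <- stats::var(values1); v2 <- stats::var(values2)
  lfc <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  if (se2 <= 0 || !is.finite(se2) ||
      se2 < 1e-24 * max(1, m1^2, m2^2)) {
    return(list(baseline_lfc = lfc, t_stat = if (lfc == 0) 0 else Inf * sign(lfc),
                df = NA_real_, p_value = if (lfc == 0) 1 else 0,
                degenerate = TRUE))
  }
  t_stat <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(baseline_lfc = lfc, t_stat = t_stat, df = df, p_value = p,
       degenerate = FALSE)
}

#' Baseline-change tests for every gene of a matrix
#'
#' Applies [baseline_change_test()] row-wise, comparing the samples of
#' `condition2` against `condition1`.
#'
#' @param mat Expression matrix (genes x samples, log2).
#' @param samples Sample table.
#' @param condition1,condition2 Condition labels (reference first).
#' @return `data.frame`: gene, baseline_lfc, baseline_p.
#' @export
baseline_change_table <- function(mat, samples, condition1, condition2) {
  s1 <- samples$sample_id[samples$condition == condition1]
  s2 <- samples$sample_id[samples$condition == condition2]
  if (length(s1) < 2 || length(s2) < 2) {
    stop("need >= 2 samples per condition", call. = FALSE)
  }
  res <- apply(mat, 1, function(y) {
    b <- baseline_change_test(y[s1], y[s2])
    c(b$baseline_lfc, b$p_value)
  })
  data.frame(gene = rownames(mat),
             baseline_lfc = res[1, ], baseline_p = res[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify genes into the six rhythm-change classes
#'
#' Joins the per-condition rhythm tables on the (identical) gene universe
#' and assigns every gene exactly one label, in rule order: rhythmic in
#' both conditions and `|delta_phase| <` threshold gives class I, `>=`
#' threshold class II; rhythmic only in condition 1 class III; rhythmic
#' only in condition 2 class VI; rhythmic in neither with a significant
#' baseline change (BH within the non-rhythmic stratum, `q < alpha`, and
#' `|lfc| >` `baseline_lfc_threshold`) class IV (up) or V (down);
#' otherwise NC. `delta_phase` is the signed circular difference
#' (condition 2 minus condition 1) and is reported for classes I/II only.
#'
#' @param rhythms1,rhythms2 Outputs of [detect_rhythms()] for the two
#'   conditions, same gene universe.
#' @param baseline Output of [baseline_change_table()] on the same genes.
#' @param config [analysis_config()] list.
#' @return `data.frame`: gene, class_label, delta_phase, baseline_lfc,
#'   baseline_p, baseline_q.
#' @export
classify_genes <- function(rhythms1, rhythms2, baseline,
                           config = analysis_config()) {
  if (!identical(rhythms1$gene, rhythms2$gene) ||
      !identical(rhythms1$gene, baseline$gene)) {
    stop("gene universes of the inputs do not match", call. = FALSE)
  }
  T <- config$period_T
  r1 <- rhythms1$rhythmic
  r2 <- rhythms2$rhythmic
  dphi <- rep(NA_real_, nrow(rhythms1))
  both <- r1 & r2
  dphi[both] <- signed_phase_difference(rhythms1$acrophase[both],
                                        rhythms2$acrophase[both], T)

  # BH across the non-rhythmic stratum only
  neither <- !r1 & !r2
  q <- rep(NA_real_, nrow(baseline))
  if (any(neither)) q[neither] <- bh_adjust(baseline$baseline_p[neither])

  lab <- rep("NC", nrow(rhythms1))
  lab[both & abs(dphi) < config$phase_shift_threshold] <- "I"
  lab[both & abs(dphi) >= config$phase_shift_threshold] <- "II"
  lab[r1 & !r2] <- "III"
  lab[!r1 & r2] <- "VI"
  sig_base <- neither & !is.na(q) & q < config$alpha &
    abs(baseline$baseline_lfc) > config$baseline_lfc_threshold
  lab[sig_base & baseline$baseline_lfc > 0] <- "IV"
  lab[sig_base & baseline$baseline_lfc < 0] <- "V"
  dphi[!(lab %in% c("I", "II"))] <- NA_real_

  data.frame(gene = rhythms1$gene,
             class_label = lab,
             delta_phase = dphi,
             baseline_lfc = baseline$baseline_lfc,
             baseline_p = baseline$baseline_p,
             baseline_q = q,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Peak-time histogram of rhythmic genes
#'
#' Assigns each rhythmic gene's acrophase to the nearest bin center on the
#' circle (ties go to the earlier center) and counts genes per bin. With
#' the default bin centers equal to the sampled ZTs this reproduces the
#' peak-time distribution plots of two-condition time-course studies.
#'
#' @param rhythms Output of [detect_rhythms()].
#' @param bin_centers ZT hours of the bin centers (default `c(1,7,13,19)`).
#' @param T Period in hours.
#' @return `data.frame`: condition, bin_center, count. Counts sum to the
#'   number of rhythmic genes; an empty rhythmic subset gives all-zero
#'   counts.
#' @export
peak_time_histogram <- function(rhythms, bin_centers = c(1, 7, 13, 19), T = 24) {
  centers <- sort(bin_centers %% T)
  phis <- rhythms$acrophase[rhythms$rhythmic]
  phis <- phis[!is.na(phis)]
  counts <- integer(length(centers))
  if (length(phis)) {
    # circular distance to every center; ties -> earlier (smaller) center
    d <- abs(outer(phis, centers, function(p, c) {
      x <- ((p - c + T / 2) %% T) - T / 2
      x
    }))
    nearest <- apply(d, 1, which.min)   # which.min takes the first minimum
    counts <- tabulate(nearest, nbins = length(centers))
  }
  data.frame(condition = if (nrow(rhythms)) rhythms$condition[1] else NA_character_,
             bin_center = centers,
             count = counts,
             stringsAsFactors = FALSE)
}

#' Restrict class assignments to genes of named gene sets
#'
#' Returns the rows of `assignments` whose gene belongs to the union of
#' the named sets, preserving order; used e.g. to study phase shifts of
#' metabolism-annotated genes only.
#'
#' @param assignments Output of [classify_genes()].
#' @param collection Gene-set collection from [read_gmt()].
#' @param set_names Names of the sets to keep.
#' @return Subset of `assignments`.
#' @export
filter_by_gene_sets <- function(assignments, collection, set_names) {
  unknown <- setdiff(set_names, names(collection))
  if (length(unknown)) {
    stop("unknown set name(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(collection), collapse = ", "),
         call. = FALSE)
  }
  members <- unique(unlist(collection[set_names], use.names = FALSE))
  assignments[assignments$gene %in% members, , drop = FALSE]
}
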