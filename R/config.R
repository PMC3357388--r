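#' Analysis configuration
#'
#' Bundles the tunable parameters of the rhythm-detection and classification
#' pipeline into a validated list. All phase quantities throughout the
#' package use the same convention: hours since lights-on (Zeitgeber time),
#' reduced modulo `period_T` into `[0, period_T)`.
#'
#' @param period_T Rhythm period in hours. The entrained light:dark design
#'   fixes this at 24; it is not estimated.
#' @param max_harmonics_K Number of harmonic pairs in the cosinor model.
#'   A 4-timepoint design identifies only `K = 1` (see [fit_cosinor()]).
#' @param alpha Significance level for rhythmicity (applied to BH-adjusted
#'   q-values) and for baseline-change calls.
#' @param fdr_method Multiplicity procedure label; only `"BH"`
#'   (Benjamini-Hochberg step-up) is implemented.
#' @param phase_shift_threshold Hours of circular acrophase shift separating
#'   "conserved" (class I) from "phase-shifted" (class II) genes. Default 3 h,
#'   half the 6-h sampling interval.
#' @param baseline_lfc_threshold Minimum absolute log2 fold change required
#'   (in addition to significance) for baseline classes IV/V. Default 0.
#' @param seed Integer seed recorded in run manifests.
#'
#' @return A list with class `"desync_config"`.
#' @export
#' @examples
#' cfg <- analysis_config(alpha = 0.01)
#' cfg$phase_shift_threshold
analysis_config <- function(period_T = 24,
                            max_harmonics_K = 1,
                            alpha = 0.05,
                            fdr_method = "BH",
                            phase_shift_threshold = 3,
                            baseline_lfc_threshold = 0,
                            seed = 1L) {
  stopifnot(is.numeric(period_T), length(period_T) == 1, period_T > 0)
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1)) {
    stop("alpha must be a single number in (0, 1)", call. = FALSE)
  }
  if (!(phase_shift_threshold > 0 && phase_shift_threshold <= period_T / 2)) {
    stop("phase_shift_threshold must lie in (0, period_T/2]", call. = FALSE)
  }
  stopifnot(max_harmonics_K >= 1, baseline_lfc_threshold >= 0)
  if (!identical(fdr_method, "BH")) {
    stop("only fdr_method = \"BH\" is supported", call. = FALSE)
  }
  structure(list(
    period_T = as.numeric(period_T),
    max_harmonics_K = as.integer(max_harmonics_K),
    alpha = as.numeric(alpha),
    fdr_method = fdr_method,
    phase_shift_threshold = as.numeric(phase_shift_threshold),
    baseline_lfc_threshold = as.numeric(baseline_lfc_threshold),
    seed = as.integer(seed)
  ), class = "desync_config")
}

#' Read a flat-key YAML configuration file
#'
#' Parses the flat `key: value` subset of YAML used for pipeline
#' configuration files (one scalar per line, `#` comments allowed) and
#' returns an [analysis_config()] built from the recognised keys.
#' Unknown keys are an error so that typos do not silently fall back to
#' defaults.
#'
#' @param path Path to the configuration file.
#' @param overrides Named list of values taking precedence over the file
#'   (the CLI maps `--alpha` etc. here).
#' @return A `"desync_config"` list.
#' @export
read_config <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) {
      stop("config line is not 'key: value': ", ln, call. = FALSE)
    }
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    num <- suppressWarnings(as.numeric(val))
    kv[[key]] <- if (!is.na(num)) num else val
  }
  for (nm in names(overrides)) kv[[nm]] <- overrides[[nm]]
  known <- names(formals(analysis_config))
  bad <- setdiff(names(kv), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; known keys: ", paste(known, collapse = ", "), call. = FALSE)
  }
  do.call(analysis_config, kv)
}
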