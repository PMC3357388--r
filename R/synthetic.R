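# Ground-truth synthetic data emulating a two-condition diurnal microarray
# study: 4 timepoints (ZT1/7/13/19) x 3 replicates x 2 conditions, a
# rhythmic fraction that largely loses rhythmicity in the treated
# condition, symmetric phase shifts, baseline shifts, de-novo rhythms with
# a bimodal (ZT1/ZT13) peak-time distribution, 8-point hormone profiles
# with a 6 h acrophase advance, and pyruvate-tolerance glucose curves with
# a blunted treated response.

#' Synthetic-data generator configuration
#'
#' Defaults state the emulated study design once; see the methods vignette
#' for the rationale behind every value that the design itself does not
#' fix. The transcriptome waveform is the single-harmonic cosinor
#' `y(t) = m + A cos(2*pi*(t - phi)/T) + e`, `e ~ N(0, noise_sd)` on the
#' log2 scale.
#'
#' @param n_genes Number of genes.
#' @param timepoints Sampled ZT hours.
#' @param replicates Chips per timepoint, condition.
#' @param conditions Two condition labels, reference first.
#' @param class_proportions Named fractions for classes I, II, III, IV, V,
#'   VI, NC; must sum to 1.
#' @param control_phase_distribution `"uniform"` (acrophases spread evenly
#'   over the day in the reference condition).
#' @param tsr_phase_distribution `"bimodal"`: de-novo (class VI) acrophases
#'   from an equal-weight von Mises mixture at `bimodal_centers`.
#' @param bimodal_centers,bimodal_kappa Mixture centers (ZT hours) and
#'   concentration.
#' @param phase_shift_delta Magnitude (hours) of class II phase shifts;
#'   sign is random with equal probability, so planted shifts are
#'   directionally symmetric.
#' @param conserved_shift_max Class I acrophase jitter, uniform on
#'   `(-conserved_shift_max, conserved_shift_max)` hours.
#' @param amplitude_meanlog,amplitude_sdlog Log-normal amplitude (log2
#'   units); median `exp(meanlog)`.
#' @param baseline_meanlog,baseline_sdlog Log-normal mesor (log2 units).
#' @param baseline_shift Log2 shift applied to classes IV (+) and V (-).
#' @param noise_sd Gaussian noise SD, log2 units.
#' @param period Hours.
#' @param hormone List: `analyte`, `n_timepoints`, `replicates`,
#'   `acrophase` (named per condition; defaults realise a 6 h advance of
#'   the treated condition), `mesor`, `amplitude` (ng/ml), `noise_frac`
#'   (noise SD as a fraction of amplitude).
#' @param tolerance List for the pyruvate tolerance test: `times`
#'   (minutes post-injection), `replicates`, `baseline` (mg/dl), `pulse`
#'   (named per condition, mg/dl/min; treated < control, i.e. impaired
#'   gluconeogenesis), `tau` (minutes), `noise_sd` (mg/dl).
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(n_genes = 2000,
                             timepoints = c(1, 7, 13, 19),
                             replicates = 3,
                             conditions = c("control", "TSR"),
                             class_proportions = c(I = 0.03, II = 0.03,
                                                   III = 0.20, IV = 0.03,
                                                   V = 0.03, VI = 0.10,
                                                   NC = 0.58),
                             control_phase_distribution = "uniform",
                             tsr_phase_distribution = "bimodal",
                             bimodal_centers = c(1, 13),
                             bimodal_kappa = 4,
                             phase_shift_delta = 6,
                             conserved_shift_max = 1,
                             amplitude_meanlog = log(0.8),
                             amplitude_sdlog = 0.25,
                             baseline_meanlog = log(8),
                             baseline_sdlog = 0.1,
                             baseline_shift = 1,
                             noise_sd = 0.3,
                             period = 24,
                             hormone = list(),
                             tolerance = list()) {
  cp <- class_proportions[c("I", "II", "III", "IV", "V", "VI", "NC")]
  if (any(is.na(cp))) stop("class_proportions must name I..VI and NC", call. = FALSE)
  if (abs(sum(cp) - 1) > 1e-9) {
    stop("class_proportions must sum to 1 (got ", sum(cp), ")", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(timepoints < 0 | timepoints >= period)) {
    stop("timepoints must lie in [0, period)", call. = FALSE)
  }
  if (length(conditions) != 2) stop("exactly two conditions are supported", call. = FALSE)
  h_def <- list(analyte = "corticosterone", n_timepoints = 8, replicates = 4,
                acrophase = stats::setNames(c(12, 6), conditions),
                mesor = 100, amplitude = 50, noise_frac = 0.1)
  h <- utils::modifyList(h_def, hormone)
  if (h$noise_frac < 0) stop("hormone noise_frac must be >= 0", call. = FALSE)
  if (h$n_timepoints < 4) stop("hormone n_timepoints must be >= 4", call. = FALSE)
  t_def <- list(times = c(0, 15, 30, 60, 90, 120), replicates = 5,
                baseline = 70,
                pulse = stats::setNames(c(9, 4.5), conditions),
                tau = 30, noise_sd = 8)
  tl <- utils::modifyList(t_def, tolerance)
  if (any(diff(tl$times) <= 0) || tl$times[1] != 0) {
    stop("tolerance time grid must start at 0 and be strictly increasing",
         call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), timepoints = timepoints,
                 replicates = as.integer(replicates), conditions = conditions,
                 class_proportions = cp,
                 control_phase_distribution = control_phase_distribution,
                 tsr_phase_distribution = tsr_phase_distribution,
                 bimodal_centers = bimodal_centers,
                 bimodal_kappa = bimodal_kappa,
                 phase_shift_delta = phase_shift_delta,
                 conserved_shift_max = conserved_shift_max,
                 amplitude_meanlog = amplitude_meanlog,
                 amplitude_sdlog = amplitude_sdlog,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 baseline_shift = baseline_shift,
                 noise_sd = noise_sd, period = period,
                 hormone = h, tolerance = tl),
            class = "generator_config")
}

# von Mises sampler (Best & Fisher rejection); returns radians.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

# per-gene reproducible stream: truth for gene i depends on (seed, i) only
gene_seed <- function(seed, i) (as.integer(seed) + i) %% 2147483647L

#' Generate a synthetic two-condition diurnal transcriptome
#'
#' Draws per-gene ground truth (class, mesor, amplitude, acrophase) and a
#' log2 expression matrix under the design of `config`. Randomness is
#' streamed per gene from `seed + gene index`, so gene `i`'s truth is
#' unchanged when `n_genes` changes.
#'
#' @param config [generator_config()].
#' @param seed Integer seed.
#' @return List of class `"synthetic_transcriptome"`: `expression`
#'   (matrix), `samples` (sample table), `truth` (`data.frame`: gene,
#'   class, per-condition mesor/amplitude/acrophase, noise_sd; acrophase is
#'   `NA` where a condition is non-rhythmic). The config and seed are
#'   attached as attributes.
#' @export
generate_transcriptome <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  cond <- config$conditions
  T <- config$period
  samples <- expand.grid(replicate = seq_len(config$replicates),
                         zt = config$timepoints,
                         condition = cond,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("condition", "zt", "replicate")]
  samples$sample_id <- sprintf("%s_ZT%g_r%d", samples$condition,
                               samples$zt, samples$replicate)
  samples <- samples[, c("sample_id", "condition", "zt", "replicate")]
  n_s <- nrow(samples)

  cum <- cumsum(config$class_proportions)
  labels <- names(config$class_proportions)
  n_g <- config$n_genes
  mat <- matrix(NA_real_, n_g, n_s)
  truth <- data.frame(gene = sprintf("g%05d", seq_len(n_g)),
                      class = NA_character_,
                      m1 = NA_real_, m2 = NA_real_,
                      A1 = 0, A2 = 0,
                      phi1 = NA_real_, phi2 = NA_real_,
                      noise_sd = config$noise_sd,
                      stringsAsFactors = FALSE)
  is2 <- samples$condition == cond[2]
  zt <- samples$zt

  for (i in seq_len(n_g)) {
    set.seed(gene_seed(seed, i))
    cls <- labels[findInterval(stats::runif(1), cum, left.open = TRUE) + 1]
    m1 <- stats::rlnorm(1, config$baseline_meanlog, config$baseline_sdlog)
    m2 <- m1
    A <- stats::rlnorm(1, config$amplitude_meanlog, config$amplitude_sdlog)
    A1 <- 0; A2 <- 0; phi1 <- NA_real_; phi2 <- NA_real_
    if (cls %in% c("I", "II", "III")) {
      A1 <- A
      phi1 <- stats::runif(1, 0, T)
    }
    if (cls == "I") {
      A2 <- A
      phi2 <- (phi1 + stats::runif(1, -config$conserved_shift_max,
                                   config$conserved_shift_max)) %% T
    } else if (cls == "II") {
      A2 <- A
      sgn <- if (stats::runif(1) < 0.5) -1 else 1
      phi2 <- (phi1 + sgn * config$phase_shift_delta) %% T
    } else if (cls == "IV") {
      m2 <- m1 + config$baseline_shift
    } else if (cls == "V") {
      m2 <- m1 - config$baseline_shift
    } else if (cls == "VI") {
      A2 <- A
      ctr <- config$bimodal_centers[(stats::runif(1) < 0.5) + 1]
      phi2 <- (rvonmises(1, 2 * pi * ctr / T, config$bimodal_kappa) *
                 T / (2 * pi)) %% T
    }
    mean1 <- m1 + if (A1 > 0) A1 * cos(2 * pi * (zt - phi1) / T) else 0
    mean2 <- m2 + if (A2 > 0) A2 * cos(2 * pi * (zt - phi2) / T) else 0
    mu <- ifelse(is2, mean2, mean1)
    mat[i, ] <- mu + stats::rnorm(n_s, 0, config$noise_sd)
    truth$class[i] <- cls
    truth$m1[i] <- m1; truth$m2[i] <- m2
    truth$A1[i] <- A1; truth$A2[i] <- A2
    truth$phi1[i] <- phi1; truth$phi2[i] <- phi2
  }
  dimnames(mat) <- list(truth$gene, samples$sample_id)
  names(truth)[3:8] <- c(paste0("mesor_", cond[1]), paste0("mesor_", cond[2]),
                         paste0("amplitude_", cond[1]), paste0("amplitude_", cond[2]),
                         paste0("acrophase_", cond[1]), paste0("acrophase_", cond[2]))
  structure(list(expression = mat, samples = samples, truth = truth),
            class = "synthetic_transcriptome",
            config = config, seed = seed)
}

#' Plant gene sets enriched for a truth class
#'
#' Builds gene sets whose members are drawn from the generated universe
#' with sampling weight `odds` for genes of the target class and 1 for all
#' others (`odds = Inf` draws members exclusively from the class;
#' `odds = 1` gives unenriched random sets).
#'
#' @param truth Truth table from [generate_transcriptome()].
#' @param planting Named list; each element is
#'   `list(class = <label>, odds = <weight>, size = <members>)`.
#' @param seed Integer seed.
#' @return Named list of member vectors (a gene-set collection), with set
#'   descriptions recording the planting parameters.
#' @export
generate_gene_sets <- function(truth, planting, seed = 1L) {
  set.seed(as.integer(seed))
  sets <- list()
  desc <- character(0)
  for (nm in names(planting)) {
    pl <- planting[[nm]]
    if (pl$size > nrow(truth)) {
      stop("set '", nm, "' size exceeds the number of genes", call. = FALSE)
    }
    target <- truth$class == pl$class
    if (!any(target)) stop("target class '", pl$class, "' absent from truth",
                           call. = FALSE)
    if (is.infinite(pl$odds)) {
      pool <- truth$gene[target]
      if (pl$size > length(pool)) {
        stop("set '", nm, "' size exceeds the target class size", call. = FALSE)
      }
      sets[[nm]] <- sample(pool, pl$size)
    } else {
      w <- ifelse(target, pl$odds, 1)
      sets[[nm]] <- sample(truth$gene, pl$size, prob = w)
    }
    desc[nm] <- sprintf("planted class=%s odds=%s size=%d",
                        pl$class, format(pl$odds), pl$size)
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Generate a synthetic diurnal hormone profile
#'
#' Cosinor waveform per condition (`mesor + amplitude *
#' cos(2*pi*(t - acrophase)/period)`) at `n_timepoints` equally spaced ZTs
#' with Gaussian noise of SD `noise_frac * amplitude`. With the default
#' acrophases (reference ZT12, treated ZT6) the treated profile is phase
#' advanced by 6 h; the two conditions differ in nothing else.
#'
#' @param config [generator_config()] (its `hormone` component is used).
#' @param seed Integer seed.
#' @return `data.frame`: analyte, condition, zt, replicate, value.
#' @export
generate_hormone_profile <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  h <- config$hormone
  T <- config$period
  set.seed(as.integer(seed))
  zts <- seq(0, T, length.out = h$n_timepoints + 1)[seq_len(h$n_timepoints)]
  out <- expand.grid(replicate = seq_len(h$replicates), zt = zts,
                     condition = config$conditions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  phi <- h$acrophase[out$condition]
  mu <- h$mesor + h$amplitude * cos(2 * pi * (out$zt - phi) / T)
  out$value <- mu + stats::rnorm(nrow(out), 0, h$noise_frac * h$amplitude)
  data.frame(analyte = h$analyte,
             condition = out$condition, zt = out$zt,
             replicate = out$replicate, value = out$value,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic pyruvate tolerance test
#'
#' Blood glucose after a pyruvate bolus follows a rise-decay pulse
#' `g(t) = b + c * t * exp(-t/tau) + e`; the condition-specific pulse
#' height `c` encodes gluconeogenic capacity (treated < control by
#' default).
#'
#' @param config [generator_config()] (its `tolerance` component is used).
#' @param seed Integer seed.
#' @return `data.frame`: condition, minutes, replicate, glucose (mg/dl).
#' @export
generate_tolerance_test <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  tl <- config$tolerance
  set.seed(as.integer(seed))
  out <- expand.grid(replicate = seq_len(tl$replicates), minutes = tl$times,
                     condition = config$conditions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  c_ <- tl$pulse[out$condition]
  mu <- tl$baseline + c_ * out$minutes * exp(-out$minutes / tl$tau)
  out$glucose <- mu + stats::rnorm(nrow(out), 0, tl$noise_sd)
  out[, c("condition", "minutes", "replicate", "glucose")]
}
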