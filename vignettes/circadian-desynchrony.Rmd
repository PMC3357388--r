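---
title: "Methods: diurnal transcriptome desynchrony analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diurnal transcriptome desynchrony analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the statistical model behind `circadesync`, the
meaning and default of every tunable parameter, what the synthetic-data
generator does and does not emulate, and the design choices made where the
design was genuinely open. It states no empirical number that the test
suite or `scripts/acceptance.R` does not itself compute.

## The model

Diurnal expression of gene $g$ in condition $c$ is modelled as a
single-harmonic cosinor on the log2 scale,

$$y_{g,c}(t) = M_{g,c} + A_{g,c}\cos\!\big(2\pi (t-\varphi_{g,c})/T\big) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

with period $T = 24$ h fixed by the entrained light:dark design (period is
*not* estimated; free-running period estimation is a different problem and
out of scope). The fit is ordinary least squares on the equivalent linear
basis $\{1, \cos 2\pi t/T, \sin 2\pi t/T\}$; amplitude and acrophase are
recovered as $A = \sqrt{a^2+b^2}$, $\varphi = (T/2\pi)\,\mathrm{atan2}(b,a)
\bmod T$. Rhythmicity is the F-test of the harmonic pair against the
intercept-only model,

$$F = \frac{(\mathrm{RSS}_0-\mathrm{RSS}_1)/2K}{\mathrm{RSS}_1/(n-2K-1)},$$

with Benjamini–Hochberg adjustment across genes within each condition and
the call $q < \alpha$.

**Why $K = 1$.** The model supports $K$ harmonic pairs, but
identifiability requires $2K+1$ strictly fewer than the number of distinct
timepoints: a 4-timepoint design therefore admits only $K=1$. Forward
harmonic addition is implemented in the sense that `max_harmonics_K` is a
config parameter, but it is inert at this design and documented as such.
This is also why the generator plants single-harmonic waveforms — with 4
timepoints per cycle, higher harmonics are not identifiable and planting
them would only alias into the fundamental.

**Degenerate fits.** A zero-variance profile returns $F=0, p=1$ (flat, not
rhythmic). A zero-residual fit with non-zero variance — which occurs for
every rhythmic gene of a noiseless simulation — is reported as $p=0$ with
a `saturated` flag rather than an error, so that noiseless recovery tests
exercise the same code path as real data.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `period_T` | 24 | h | entrained LD design |
| `max_harmonics_K` | 1 | – | forced by 4 timepoints (above) |
| `alpha` | 0.05 | – | the study family's stated significance level |
| `fdr_method` | BH | – | the study family's multiplicity procedure |
| `phase_shift_threshold` | 3 | h | half the 6 h sampling interval: a shift smaller than half the spacing between samples cannot be resolved reliably, so it separates "conserved" (I) from "shifted" (II) |
| `baseline_lfc_threshold` | 0 | log2 | significance alone defines classes IV/V; a magnitude filter is available but off |

The rhythmicity criterion (BH $q<\alpha$ within condition) is an explicit
choice: the original CircWave-based analyses this package generalises do
not state whether their per-gene sine-fit calls were FDR-corrected. BH is
used because it is the multiplicity procedure the study family names for
large-scale comparisons; users wanting unadjusted calls can read
`p_value` directly from the rhythm table.

## The class taxonomy

Classes I/II/III/VI are fully determined by the two rhythmicity calls and
the circular shift $\Delta\varphi$ (condition 2 minus condition 1, wrapped
into $(-T/2, T/2]$, boundary mapped to $+T/2$ so the difference is
single-valued; negative = advance). Classes IV and V are a reconstruction:
the phenomenon ("altered baseline expression of non-rhythmic genes") is
named in the literature but its boundaries are not, so here they are
defined as *significant* baseline change — Welch t-test pooling all
timepoints, BH-adjusted *within the non-rhythmic stratum only* — with the
sign of the log2 fold change splitting up (IV) from down (V). Pooling
across timepoints is deliberate: for genes non-rhythmic in both
conditions the pooled mean is the natural baseline estimate, and
stratum-restricted BH avoids diluting the baseline FDR with thousands of
rhythmicity p-values that answer a different question.

The Welch test is written out from first principles rather than delegated
to `stats::t.test` because the degenerate zero-within-variance case
(exactly separated conditions, which every noiseless simulation contains)
must yield a defined answer ($p \to 0$, flagged `degenerate`) rather than
an error.

## Circular statistics and "no directional shift"

Phase shifts are summarised by the mean resultant vector
$R e^{i\bar\theta} = n^{-1}\sum_j e^{i\theta_j}$ — the "normalization
vector" arrow of a polar wedge plot — and the Rayleigh statistic
$Z = nR^2$ with the standard $O(n^{-2})$ series p-value.

One subtlety is worth recording. The Rayleigh test rejects *uniformity*,
not *directional asymmetry*: any shift population with many near-zero
shifts (class I genes, by definition) concentrates at angle 0 and the
Rayleigh test will reject regardless of whether advances and delays
balance. The scientific claim "no directional shift" is therefore
operationalised on the genuinely shifted (class II) set, whose planted
shifts are symmetric $\pm\delta$; the pipeline's circular summary table
reports both the I+II and the II-only rows, and the mean direction of the
full I+II set (≈ 0 when advances and delays balance) carries the "no net
displacement" information.

## The synthetic-data generator

The generator is a stated world, fixed once:

* **Design**: 4 timepoints (ZT1/7/13/19) × 3 replicates × 2 conditions,
  matching the emulated microarray study ("three chips per time point and
  condition"); Gaussian noise on the log2 scale, sd 0.3.
* **Class proportions**: I 3%, II 3%, III 20%, IV 3%, V 3%, VI 10%,
  NC 58%. Chosen so that 26% of genes are rhythmic under control
  conditions (within the range reported for liver) and ~77% of those lose
  rhythmicity — "the vast majority" — while the de-novo class is large
  enough that the treated condition's peak-time histogram is visibly
  bimodal, as the emulated study describes.
* **Phases**: control acrophases uniform on $[0,24)$ ("evenly distributed
  along the day"); class I jitter uniform on $\pm 1$ h; class II shifts
  exactly $\pm 6$ h with random sign (symmetric by construction); class VI
  acrophases from an equal-weight von Mises mixture ($\kappa = 4$)
  centred at ZT1 and ZT13.
* **Magnitudes**: amplitudes log-normal with median 0.8 log2 units and
  `sdlog` 0.25. The median is a stated default (the emulated study prints
  no array amplitudes). `sdlog` was fixed a priori by a power
  calculation: at noise sd 0.3 the 4×3 design then detects ~94% of
  rhythmic genes at the BH-adjusted threshold, consistent with the ≥ 90%
  class-III recovery band the tests assert. Mesors are log-normal
  (median 8 log2 units, `sdlog` 0.1); classes IV/V shift the mesor by
  ±1 log2 unit.
* **Hormone profile**: 8 equally spaced timepoints × 4 replicates,
  mesor 100, amplitude 50 (ng/ml scale), noise sd = 10% of amplitude.
  The treated acrophase is ZT6 against a control ZT12 — the emulated
  study prints only the 6 h *difference* (an advance); the absolute
  control phase is a free choice, fixed at ZT12 (early dark phase, where
  rodent corticosterone peaks).
* **Tolerance test**: glucose $g(t) = b + c\,t\,e^{-t/\tau} + \varepsilon$
  on a 0–120 min grid, $b = 70$ mg/dl (overnight-fasted mice),
  $\tau = 30$ min, $c$ = 9 (control) vs 4.5 (treated) mg/dl/min — the
  treated pulse is blunted, encoding impaired gluconeogenic capacity —
  noise sd 8 mg/dl, $n = 5$ per condition.
* **Reproducibility**: every gene draws its truth from a stream seeded by
  `seed + gene index`, so per-gene truth is invariant to `n_genes`.

**What a green test establishes — and does not.** The generator emulates
sampling design, effect structure and Gaussian log-scale noise. It does
*not* emulate probe-level artifacts, batch effects, heteroskedastic or
count-based noise, correlated genes, or annotation error. Recovery
results therefore validate the *inference machinery* under the stated
world; they are not a claim about any particular deposited dataset, and
reproducing the gene lists of the emulated study is explicitly out of
scope (it would require the deposited arrays and era-specific
annotation).

## Damped-oscillation fitting

Explant luminescence traces are fit with
$y(t) = M + A e^{-\lambda t}\cos(2\pi(t-\varphi)/\tau)$. The slow baseline
is removed first with a centered running mean whose window defaults to
24 h (one nominal circadian period). A full-period centered running mean
of a damped cosine is itself a damped cosine with the same $\lambda$ and
$\tau$ (only amplitude and phase are attenuated), so the detrend does not
bias the two parameters of scientific interest — period and damping — and
it absorbs additive drift. The nonlinear least-squares stage multi-starts
over 8 phase offsets × 3 period starts within the search bounds (default
[16, 32] h, bracketing circadian periods), and the `converged` flag is
honest: flat traces or universal optimiser failure return
`converged = FALSE` with `NA` parameters rather than a fabricated fit.

## Enrichment

The overrepresentation test is the standard one-sided hypergeometric tail
(`stats::phyper` under the hood; the test suite cross-checks it against
explicit binomial-coefficient enumeration for every universe up to
$N = 12$). Two deliberate divergences from the DAVID web tool it
replaces: the universe is all genes on the matrix (DAVID's background is
version-dependent and unstated in the emulated analyses), and the
standard tail is used rather than DAVID's EASE variant (which substitutes
$k-1$ for $k$); both choices are the conservative, reproducible ones.
Odds ratios use a Haldane +0.5 correction only when a 2×2 cell is empty.

## Physiology statistics

The two-way ANOVA is fixed-effects condition × time on cell means, with
type-II sums of squares for unbalanced data (no ordering assumption
between the factors) and per-timepoint condition contrasts using the
pooled residual variance, Bonferroni-multiplied by the number of
timepoints. Pooled (rather than per-cell) variance is a choice the
emulated protocols leave open; pooling matches the ANOVA framework the
contrasts come from. Degenerate (zero-residual) designs report $p \in
\{0, 1\}$ by the sign of the effect rather than erroring, for the same
reason as the Welch test above.

AUC is trapezoidal; the baseline-corrected variant subtracts the $t=0$
value times the duration and is deliberately *not* floored at zero, so a
below-baseline excursion is visible as a negative number. ΔΔ-Ct follows
the textbook formulas with reference-gene replicates averaged on the Ct
scale (averaging before exponentiation is the convention that keeps the
calibrator's fold change exactly 1).

## Numerical conventions

* ZT is reduced modulo the period on input; all phase outputs live in
  $[0, T)$ and all shift outputs in $(-T/2, T/2]$.
* Flat/saturated tolerances are relative (`rss_null` ~ 0 at
  $10^{-10}$-relative; `rss_full`/`rss_null` $< 10^{-8}$), so they scale
  with the data.
* Peak-time histogram ties (acrophase equidistant from two bin centers)
  go to the earlier center; wedge histograms use half-open $[lo, hi)$
  wedges.
* Result tables are written with 17 significant digits and no
  row names, making pipeline outputs byte-reproducible; the JSON manifest
  records config, seed and md5 hashes of all inputs and outputs.

## Known limitations

* Period is fixed, not estimated; nonparametric rhythm detectors are not
  provided.
* The two-condition design is hard-wired in the classifier; multi-arm
  studies need pairwise runs.
* The ANOVA is fixed-effects; repeated-measures or mixed-effects designs
  are out of scope.
* The Rayleigh p-value is the asymptotic series; for $n < 10$ the test
  suite's permutation oracle shows it is accurate to ~0.01, but exact
  small-sample tables are not implemented.
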