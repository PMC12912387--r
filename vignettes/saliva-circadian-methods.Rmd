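---
title: "Methods: circadian profiling of saliva time courses"
author: "SalivaClock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian profiling of saliva time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SalivaClock)
```

# The problem

Human circadian phase and amplitude are usually inferred from hormones
(dim-light melatonin onset, cortisol) or questionnaires (MEQ). An
alternative is to read the molecular clock directly: quantify core-clock
transcripts (*ARNTL1*/BMAL1, *PER2*, *NR1D1*) in saliva sampled a few times
per day over two consecutive days, and fit a fixed-period oscillation.
SalivaClock implements that pipeline end to end — qPCR quantification,
rhythm fitting and testing, day-to-day reproducibility, cross-layer
association (hormones, cell composition, chronotype), and an in-silico
assessment of how few samples per day still support a rhythm call — plus a
synthetic-cohort generator so every stage is testable without participant
data.

# Quantification: the ΔΔCT scheme

`deltaDeltaCt()` uses the two-step Livak normalization. Per timepoint,
$\Delta CT = CT_\text{target} - CT_\text{ref}$ (reference gene *GAPDH*);
per participant × gene, $\Delta\Delta CT$ subtracts the mean $\Delta CT$
over that participant's time course, and
$\text{fold change} = 2^{-\Delta\Delta CT}$. Two conventions are worth
stating because instrument vendors differ on them:

* **Sign.** We use the standard Livak $2^{-\Delta\Delta CT}$ (lower CT ⇒
  more transcript). The opposite sign only mirrors fold changes around 1
  and flips the sign of downstream level-correlations; it is available via
  `sign = +1`.
* **Normalization window.** One mean over the participant's full time
  course (both days), so day-to-day level differences survive into the
  paired-day comparison; `normalization_scope = "per_day"` is available.

Fold changes are mean-centred by construction (geometric mean 1 over the
window), so they carry no between-participant level information. Each point
therefore also retains $2^{-\Delta CT}$ (`rel_expr`), the
reference-normalized expression, whose participant mean is what enters the
level ("mesor") columns of the feature table.

Missing single CT values: the affected timepoint is dropped for that gene
and logged (`exclusionLog()`), never silently; this is the default policy
for a protocol without technical replicates.

# Rhythm model and tests

`fitHarmonic()` fits the three-parameter cosinor
$y(t) = \mu + a\cos(\omega t) + b\sin(\omega t)$, $\omega = 2\pi/24$, by
ordinary least squares on the absolute time axis
$t = 24(\text{day}-1) + \text{clock hour}$ (day-folded fitting is the
same model when the two days share sampling times). Amplitude is
$\sqrt{a^2+b^2}$ and the acrophase — the clock time of the fitted peak —
is $\frac{24}{2\pi}\,\mathrm{atan2}(b, a) \bmod 24$. Phase is circular:
distances are computed with `circularDiff()`, so 23.5 h and 0.5 h are 1 h
apart.

Rhythmicity is decided against the intercept-only model. Two forms are
implemented in `rhythmicityTest()`:

* `"chisq"`: the asymptotic likelihood-ratio statistic
  $n\,\ln(RSS_0/RSS_1) \sim \chi^2_2$;
* `"ftest"`: the exact nested-model F statistic on $(2, n-3)$ degrees of
  freedom.

At the study's series length ($n = 8$) the $\chi^2$ form is strongly
anticonservative — its empirical type-I error at $\alpha = 0.05$ is about
0.15 in our simulations — so **the package default is the exact F test**,
which the test suite verifies is calibrated (empirical level within
Monte-Carlo error of 0.05 on 1000 flat-noise series). The $\chi^2$ form is
kept because it is the classical likelihood-ratio reading and is the
default inside the sampling-design screen (below), whose purpose is to
reproduce the published subsampling procedure.

Degenerate cases are flagged, not fudged: a 3-point fit is `saturated`
(zero residual degrees of freedom, no p-value); a fit with
$RSS_1 < 10^{-12} RSS_0$ is a `perfect_fit` and reports $p = 0$ rather
than dividing by a vanishing residual; constant series give $p = 1$.

## Robust cortisol fitting

Salivary cortisol is sampled at up to seven offsets after awakening
(directly after waking, then 0.5, 1, 2, 5, 8, 12 h) and single gross
outliers are common. `fitHarmonicRobust()` minimizes the soft-L1
(pseudo-Huber) cost $\sum_i f^2 \rho\!\left((r_i/f)^2\right)$ with
$\rho(z) = 2(\sqrt{1+z}-1)$: quadratic for residuals well under the scale
$f$ (`f_scale`, default 0.1 concentration units), linear beyond it. The
default start `c(a = -0.31084448, b = 2.33838041, mu = 6.33268443)` is the
published cortisol initialization; since the objective is convex in
$(\mu, a, b)$ (a convex function of a linear residual), the start affects
only iteration count, never the optimum — BFGS with the analytic gradient
converges from any finite start.

One geometric caveat, which the test suite respects: if a single outlier
sits exactly at the fitted peak or trough, symmetry confines its effect to
amplitude and mesor, so OLS and robust acrophases are equally (un)affected
and "robust beats OLS on phase" becomes a coin flip. The robustness checks
therefore use a generating acrophase off the sampling grid — the generic
configuration — where the robust fit wins essentially always.

## Descriptive summaries

`circadianSummary()` reports the model-free quantities used alongside the
fit: max–min (range of observed values — not the harmonic amplitude; for a
cosine, max–min ≤ 2·amplitude), maximum, mean, time of the **first**
observed maximum (tie rule: earliest), and max–min divided by the mean.
Because the generator holds relative amplitude roughly constant across
participants, max–min scales with the mean — the amplitude–mean coupling
seen in dense reference data. `restrictToInterval()` restricts a series to
closed absolute-time windows (e.g. 4–14 h and 26–38 h since wake) before
summarizing, for comparisons with dense reference series.

# Reproducibility metrics

`pairDays()` matches identical clock times across the two days (the
protocol fixes sampling times, so no nearest-neighbour pairing) and
excludes series with two or fewer total points, logging every exclusion.
With Day 1 as "predicted" and Day 2 as "observed",
`errorMetrics()` returns MAE, MSE, RMSE and MBE; the identities
$RMSE \ge MAE \ge |MBE|$ and the day-swap symmetries (MBE flips sign, the
others are invariant) are asserted property-style in the tests.
`wilcoxonBonferroni()` runs the two-sided paired signed-rank test per gene
— zeros dropped (the Wilcoxon convention), exact null distribution up to
25 non-zero differences, normal approximation with continuity correction
above — then Bonferroni caps $p \cdot n_\text{genes}$ at 1. All-zero
difference vectors are reported as degenerate with $p = 1$ instead of
erroring. `meanProfileWithSem()` treats each participant × day series as
one independent unit and reports SEM as missing when only one unit
contributes.

# Association layer

`cohortFeatures()` assembles one row per participant: per-gene mesor
(mean $2^{-\Delta CT}$), harmonic amplitude and acrophase; cortisol mesor,
amplitude and acrophase from the robust fit; mean melatonin (above-ULOQ
values excluded); bedtime, MEQ and mean L/E ratio.

**Circular variables in rank correlations.** Acrophases wrap at 24 h; rank
statistics on raw wrapped values are distorted when the distribution
straddles the cut. `spearmanMatrix()` can unwrap designated circular
columns by cutting the circle at a reference hour far from the
distribution (`circular_cut`, default 4 h, the typical human activity
trough) — `centerPhase()` maps values to signed offsets in (−12, 12]. The
uncentered mode (`circular = NULL`) rank-correlates raw phases, matching
analyses that do so. For cortisol phases expressed as hours since
awakening (mass near 0) the natural cut is ~12 h.

Mutual information (`mutualInformation()`) is the plug-in estimate on a
discretized joint, in nats; the default discretization is equal-frequency
with $\text{round}(n^{1/3})$ bins per axis, the convention of the common
discretization packages, and both knobs are exposed. The maximal
information coefficient (`maximalInformationCoefficient()`) maximizes
$MI/\ln(\min(r,c))$ over grids with $rc \le n^{0.6}$ (the original MIC
budget); each grid's axis partitions start at equal-frequency cuts and are
refined by hill-climbing over cut positions. This search is a heuristic:
the tests bound it from above by an exhaustive enumeration of *all*
contiguous partitions on tiny inputs and check its calibration on nulls
(mean MIC < 0.3 at $n = 200$) and its value of exactly 1 on noiseless
functional relationships. No multiple-testing correction is applied to the
association matrix by default (raw Spearman p-values are reported);
`p.adjust` can be applied downstream.

Cell composition uses `leRatio()` (summed leukocyte and epithelial counts
over the eight fields of a slide; undefined when no epithelial cells were
seen) and `onewayAnova()` for time-dependence. `classifyChronotype()`
applies the standard MEQ cut-offs (≤41 evening, 42–58 intermediate, ≥59
morning).

# Synthetic cohorts: what they emulate

`generateCohort()` draws, per participant: bedtime $\sim N(23, 1^2)$ h;
per-gene acrophase = gene prior + 1 h/h × (bedtime − 23) + $N(0, 1.5^2)$
jitter, wrapped; per-gene mesor lognormal (log-sd 0.3) around the gene
default; relative amplitude ≈ 0.4 with small jitter (held roughly constant
so max–min tracks the mean). Gene priors: *ARNTL1* peaks at 18 h,
*PER2*/*NR1D1* at 10 h — the evening/morning split observed in saliva.
Expression $E(t) = \text{mesor}(1 + \text{rel\_amp}\cos(2\pi(t-\phi)/24))$
is converted to CT via
$CT_\text{target} = CT_\text{ref} + \text{offset}_g - \log_2 E + \delta_{pd} + \varepsilon$,
with $\varepsilon \sim N(0, 0.2)$ cycles and a per-day offset
$\delta \sim N(0, 0.1)$ cycles: additive CT noise (approximately
homoscedastic in cycles, as qPCR error is) becomes lognormal fold-change
noise after the $2^x$ transform.

Hormone couplings encode the cross-layer structure the association stage
is meant to detect: cortisol acrophase (peak ≈ 0.75 h after waking,
consistent with the awakening response) is coupled to the participant's
*ARNTL1* acrophase with slope −0.8 h/h; melatonin is log-linearly coupled
negatively to the cortisol mesor (−1.2) and positively to the *PER2* mesor
(+1.2) around a 20 pg/mL base. The bedtime–acrophase slope (1 h/h) and all
coupling magnitudes are free modelling choices — no quantitative effect
sizes exist to copy — selected once as values that produce rank
correlations of magnitude ~0.3–0.6 at cohort scale, the order reported for
such couplings, and documented here rather than tuned. Cortisol values
below 2 units are emitted as the censoring token `"<2"` (analyzed as 1),
melatonin above 100 as `">100"` (excluded from analysis sets), so the
parsers' censoring paths are exercised by realistic data. Cell counts are
Poisson per field with a time-independent 64%/36% leukocyte/epithelial
split; MEQ scores are rounded $N(50, 8^2)$, putting most participants in
the intermediate band.

What the generator does **not** emulate: ultradian components and
waveform asymmetry, assay efficiency differences between genes,
participant dropout/missingness patterns, seasonal photoperiod effects,
sex-stratified parameters, and any microbiome contribution. Passing tests
on synthetic cohorts therefore demonstrate correctness of the estimators
under the stated generative model, not field performance on real saliva.

## Known limitation: phase-dependent recovery

With sampling restricted to the 9–21 h waking window, phase precision
depends on where the true acrophase falls: at CT-noise 0.2 cycles and
relative amplitude 0.4, the probability of recovering the acrophase within
1.5 h (circular) is ≈0.90 for an evening gene (18 h) but ≈0.84 for the
morning genes (10 h), ≈0.86 averaged over the package's three-gene mix.
A blanket ≥90% recovery at these settings is therefore not attainable for
the morning-phase genes — visible in the one deliberately strict
acceptance-style test — while the median relative amplitude error stays
below 15%.

# Sampling-design screen

`evaluateDesign()` asks which reduced schedules still support a rhythm
call. Per Monte-Carlo replicate it obtains noisy observations at a
design's offsets — either simulated directly, or subsampled
nearest-timepoint from a dense synthetic series (every 3 h over 30 h, the
dense reference geometry) — fits the cosinor, and records feasibility
(non-saturated), detection (p < 0.05; the $\chi^2$ LRT form by default
here, matching the published screen) and circular phase error. "Success"
is operationalized — no quantitative criterion exists to inherit — as:
100% feasible, ≥80% detection, median circular phase error ≤ 2 h; all
three thresholds are arguments and are stamped into the run manifest.
Under this criterion, three points in one day are never successful (three
parameters, three points: saturated by construction), and the smallest
successful single-day design on the 9–21 h window is **4 points** —
`scripts/acceptance.R` recomputes this from scratch. Five points spread
over two days also succeed at moderate noise, matching the practical
advice that spreading fewer daily samples over 48 h works.

# Numerical choices and problem sizes

Tolerances: OLS vs grid-search oracle agreement 1e−4; robust-vs-OLS
agreement on clean data 1e−6; noise-free pipeline round-trip 1e−9
relative. Ties in `peak_time_h` resolve to the earliest time. Degenerate
inputs (constant series, zero epithelial totals, all-zero paired
differences, saturated fits) return flagged results rather than errors
wherever a flag is representable. The shipped simulations use 200
replicates per sampling design, ~200 participant × gene series for
recovery checks, 1000 series for test calibration, and cohorts of n = 200
for coupling-sign checks — sizes at which Monte-Carlo error is comfortably
below every asserted margin while a full test run stays in the minutes
range on one CPU. All simulation entry points take explicit seeds;
identical config + seed reproduces outputs byte-for-byte.
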