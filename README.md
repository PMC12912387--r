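# SalivaClock

Circadian rhythm analysis for sparse human saliva time courses.

Saliva can report the molecular circadian clock non-invasively: qPCR of the
core-clock transcripts *ARNTL1* (BMAL1), *PER2* and *NR1D1* (REV-ERBα) at a
few timepoints per day over two consecutive days, measured alongside
salivary cortisol and melatonin, cell composition (leukocyte/epithelial
ratio) and chronotype questionnaires (MEQ). SalivaClock is the analysis
layer for such studies: it turns raw cycle-threshold tables into relative
expression, fits fixed-period oscillations, quantifies day-to-day
reproducibility, relates the molecular, hormonal and behavioural layers,
and answers the design question "how few samples per day still support a
rhythm call?". A synthetic-cohort generator with a known truth table makes
the whole pipeline testable without participant data.

## The model

Relative expression comes from the Livak ΔΔCT scheme
(CT normalized to *GAPDH*, then to the participant's mean for that gene;
fold change = 2^(−ΔΔCT)). Each series is fitted with the three-parameter
cosinor at a fixed 24 h period,

    y(t) = μ + a·cos(2πt/24) + b·sin(2πt/24),

giving mesor μ, amplitude √(a²+b²) and acrophase (peak clock time)
(24/2π)·atan2(b,a) mod 24. Rhythmicity is tested against the
intercept-only model — exact F test (2, n−3) by default (calibrated at the
study's n = 8), or the asymptotic likelihood-ratio χ²₂ form. Cortisol
profiles (7 offsets after awakening) are fitted by robust soft-L1
(pseudo-Huber) harmonic regression, which shrugs off single gross
outliers. Between-day reproducibility uses MAE/MSE/RMSE/MBE and paired
Wilcoxon tests with Bonferroni correction; cross-layer association uses
Spearman matrices (with proper handling of circular phases), mutual
information and the maximal information coefficient.

## Worked example

Simulate a small cohort at the study protocol (4 timepoints at 9/13/17/21 h
× 2 days), quantify, fit, and screen sampling designs:

```r
library(SalivaClock)

cfg <- list(simulate = list(n_participants = 6), seed = 11,
            design = list(points_per_day = 3:6, n_replicates = 200))
res <- runPipeline(cfg)

subset(res$fits, participant == "P01")[, c("gene","mesor","amplitude","acrophase_h","lrt_p")]
#>     gene mesor amplitude acrophase_h  lrt_p
#> 1 ARNTL1 1.070     0.314       21.82 0.0814
#> 2  NR1D1 0.986     0.417       10.63 0.0339
#> 3   PER2 1.020     0.352        9.67 0.0152

res$error_metrics
#>   metric  value
#> 1    mae 0.1800
#> 2    mse 0.0566
#> 3   rmse 0.2379
#> 4    mbe 0.0268

res$minimal_design
#>   n_days min_points_per_day
#> 1      1                  4
```

Participant P01 shows the expected phase split — *ARNTL1* peaking in the
late evening, *PER2*/*NR1D1* in the morning — with fold-change amplitudes
around 0.3–0.4 and rhythmicity p-values from the exact F test. The error
metrics summarize Day-1 vs Day-2 agreement of paired fold changes (here
MAE 0.18 at the generator's default measurement noise; MBE near zero means
no systematic day bias). The design screen reports that, of the evenly
spaced single-day schedules in the 9–21 h waking window, 4 points per day
is the smallest that reliably supports a rhythm call — 3 points exactly
saturate the three-parameter model.

`runPipeline()` also accepts a YAML config path and writes every result
table as TSV plus a JSON manifest (seed, config hash, versions) when
`out_dir` is set.

## Layout

* `R/` — implementation: I/O and censoring dialects, ΔΔCT, harmonic and
  robust fitting, reproducibility, association, sampling design,
  synthetic cohorts, pipeline orchestration.
* `tests/testthat/` — unit, property and acceptance-style tests with
  independent oracles (grid search, sign enumeration, exhaustive MIC).
* `vignettes/saliva-circadian-methods.Rmd` — the model, its assumptions,
  parameter defaults and limitations.
* `scripts/acceptance.R` — the headline recomputation above.
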