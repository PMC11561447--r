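# keydyn

Smartphone keystroke dynamics as digital biomarkers for screening mild
cognitive impairment (MCI).

## The problem

MCI is a preclinical stage of cognitive decline whose detection with
clinic-administered screening instruments (MoCA-type tests) suffers from
limited sensitivity and poor ecological validity. Typing on a smartphone
keyboard, by contrast, is produced continuously during daily life, and
its temporal microstructure degrades with the working-memory and fine
motor deficits that accompany MCI. Two latencies carry most of the
signal:

- **Hold time (HT)** — the interval between pressing and releasing one
  key, `HT_i = release_i − press_i` (ms);
- **Flight time (FT)** — the interval between releasing a key and
  pressing the next, `FT_j = press_{j+1} − release_j` (ms), negative
  under rollover typing.

`keydyn` implements the full analysis pipeline for studies of this kind,
for biostatisticians and digital-biomarker researchers:

1. **Feature extraction** — parse raw time-stamped press/release event
   logs (JSON or NDJSON), pair presses with their earliest subsequent
   same-key release, compute HT/FT, exclude implausible values
   (HT > 700 ms, FT > 3 s, strict inequalities), retain sessions with
   more than 40 key presses, and aggregate to per-participant pooled
   means.
2. **Discriminant evaluation** — empirical ROC curves (trapezoidal AUC,
   equal to the all-pairs concordance probability with ties weighted
   1/2), DeLong or bootstrap confidence intervals, optimal cutoffs by
   the maximal Youden index `J = sensitivity + specificity − 1`, and
   fusion of a keystroke marker with a cognitive score through the
   predicted probability of a logistic regression.
3. **Group and association statistics** — pooled two-sample *t* tests
   (from raw data or from printed summary statistics), uncorrected 2×2
   chi-square, and Spearman rank correlations with average ranks for
   ties.
4. **Synthetic cohorts** — a Gaussian-copula generator reproducing a
   two-group study's printed means/SDs and *pooled-sample* Spearman
   correlation structure (the latent within-group correlation is found
   by root-solving the mixture's population grade correlation), plus a
   raw event-stream simulator (negative-binomial session/press counts,
   gamma within-participant noise, injected outliers) so the entire
   pipeline is testable without access to any raw study data.

## Worked example

Generate a reference cohort (64 healthy controls, 47 MCI; marginals and
pooled rank correlations at their published defaults) and evaluate the
marker panel:

```r
library(keydyn)

cfg    <- calibrate_cohort_config(cohort_config())  # copula calibration, ~1 s
cohort <- generate_cohort(cfg, seed = 20)
evaluate_marker_panel(cohort)
#>       marker   auc auc_ci_low auc_ci_high  cutoff sensitivity specificity
#>       MoCA-K 0.823      0.742       0.904  24.500       0.766       0.766
#>      HT (ms) 0.970      0.946       0.995 145.005       0.894       0.922
#>      FT (ms) 0.993      0.985       1.000 833.170       1.000       0.906
#>  MoCA-K + HT 0.986      0.972       1.000   0.535       0.915       0.969
#>  MoCA-K + FT 1.000      0.999       1.000   0.296       1.000       0.984
#>  youden_j p_value separation
#>     0.532       0         NA
#>     0.815       0         NA
#>     0.906       0         NA
#>     0.884       0      FALSE
#>     0.984       0       TRUE
```

Each row is one marker: its AUC with 95% DeLong CI, the Youden-optimal
cutoff (in marker units; predicted probability for the fused rows), and
the sensitivity/specificity attained there. On cohorts drawn from the
reference configuration the keystroke markers dominate the cognitive
score (FT ≈ 0.99 > HT ≈ 0.97 > MoCA-K ≈ 0.83), the ordering such a study
design implies.

Group comparisons work directly from printed summaries too:

```r
pooled_t_from_summary(184.85, 25.24, 47, 108.77, 25.25, 64)  # HT, MCI vs HC
#> <kd_ttest: t = 15.688, df = 109, p = 1.01e-29>
```

The same pipeline runs from the command line on files:

```sh
Rscript inst/scripts/keydyn simulate --out study/ --seed 1
Rscript inst/scripts/keydyn extract  --events study/events.json --out study/feat
Rscript inst/scripts/keydyn evaluate --features study/feat/features.csv \
        --metadata study/metadata.csv --out study/report.json
Rscript inst/scripts/keydyn report   --report study/report.json
```

Exit codes: 0 success, 2 validation error, 3 degenerate data.

## Learn more

The methods vignette (`vignettes/keystroke-dynamics-screening.Rmd`)
documents the model assumptions, every tunable parameter with its
default and rationale, what the synthetic generator does and does not
emulate, and the package's numerical choices.
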