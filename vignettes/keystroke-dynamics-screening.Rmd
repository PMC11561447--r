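---
title: "Keystroke dynamics for cognitive screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keystroke dynamics for cognitive screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keydyn)
```

This vignette is the package's own account of its methods: the feature
extraction model, the discriminant statistics, the synthetic-cohort
generator, and the numerical and design choices made where the problem
left them open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. From raw events to participant features

The unit of observation is a *typing session*: an ordered stream of
time-stamped key press ("down") and release ("up") events with opaque,
anonymized key tokens, recorded in the background while a participant
types normally on their phone. Timestamps are milliseconds since an
arbitrary epoch.

**Pairing.** The press/release stream does not come pre-paired, and
rollover typing (pressing the next key before releasing the previous
one) is common, so pairing by adjacency would corrupt the features. The
rule used here is *same-key, earliest-subsequent-release, first-in
first-out*: each press is matched to the earliest not-yet-consumed
release of the same key token at or after it. The rule is deterministic,
independent of the interleaving of other keys, and standard in
keystroke-dynamics work. Unmatched presses and releases are dropped and
counted; pairing conserves events (`n_pairs + n_orphan_presses =
n_press_events`), which is property-tested on random streams.

**Features.** Hold time `HT_i = release_i − press_i` per keystroke;
flight time `FT_j = press_{j+1} − release_j` between keystrokes ordered
by press time, length `n − 1` per session. FT is never computed across a
session boundary: sessions are independent typing episodes. Negative FT
(rollover) is legitimate data and is retained; a configurable lower
bound (`ft_min_ms`) exists but defaults to off.

**Exclusion filters.** `HT > 700` ms and `FT > 3000` ms are excluded as
artifacts (key held during a distraction; a pause between bursts of
typing rather than a latency within one). The published threshold for HT
reads "700 microseconds", which cannot be meant literally — typical HT
*means* are above 100 ms, so a µs threshold would exclude every
keystroke — and is read as 700 ms. Both rules are strict inequalities
exactly as printed; boundary values are retained, and the filter is
idempotent.

**Session retention.** Only sessions with *more than 40* key presses are
analyzed (`min_presses = 41`), so that short fragments do not dilute the
features. The retention fraction is reported by the extractor.

**Aggregation.** Published group tables report one HT/FT mean per
participant without stating the aggregation level. The default here is
the *pooled keystroke-level mean* across the participant's retained
sessions — the simplest consistent estimator, which weights sessions by
keystroke count; `aggregation = "session_mean"` (mean of per-session
means) is available for sensitivity analyses. Participants whose
sessions all fail the press filter are flagged `no_data` and excluded
downstream with a logged reason rather than silently dropped — studies
of this design do encounter enrolled participants who contribute no
usable sessions.

## 2. Discriminant evaluation

**ROC construction.** MCI is the positive class throughout. Candidate
thresholds are midpoints between consecutive distinct observed values
plus sentinels beyond the extremes — the style in which clinical cutoffs
are conventionally printed (e.g. 22.50 points, 159.50 ms). Markers
declare a direction: cognitive scores call MCI *below* the threshold,
keystroke latencies and fused probabilities *above*. AUC is the
trapezoidal area, which equals the all-pairs concordance probability
with ties weighted 1/2; the equivalence is enforced in the test suite by
a brute-force oracle on instances up to 200 subjects.

**Confidence intervals.** Publications of this kind usually report SPSS
output without naming the CI method. The default here is DeLong's
nonparametric variance of the concordance statistic with a normal
interval truncated to [0, 1] — the de facto standard, deterministic and
cheap; a stratified percentile bootstrap is available as
`method = "bootstrap"`. Perfect separation yields zero DeLong variance;
the interval degenerates to `[auc, auc]` with a warning rather than
pretending precision.

**Youden cutoff.** The operating point maximizes
`J = sensitivity + specificity − 1`. Ties on `J` are broken toward
higher sensitivity — in a screening context a missed case costs more
than a false alarm — then toward the cutoff closest to the score median
(the least extreme, hence most transferable, choice). The search is
verified against exhaustive threshold enumeration.

**Logistic fusion.** To evaluate a keystroke marker *combined* with a
cognitive score as a single variable, the two are fused into the
predicted probability of a maximum-likelihood logistic regression
(IRLS, ≤ 100 iterations, log-likelihood tolerance 1e−8, starting from
zero coefficients). Because ROC analysis depends only on the ordering of
the fused marker, complete or quasi-complete separation (detected as a
linear predictor exceeding 30 in absolute value) is *flagged but not
penalized*: the probabilities are still returned. An optional ridge
penalty (`ridge = 1e-6`) stabilizes the coefficients when finite
estimates are wanted. With a single marker the fitted probability is a
monotone transform of it, so the fused ROC reproduces the raw marker's
ROC exactly — a useful internal consistency check that the tests
exercise.

## 3. Group-comparison and association statistics

- **Pooled (Student) t test**, not Welch: published degrees of freedom
  `n1 + n2 − 2` identify the equal-variance form. The summary-statistic
  entry point makes printed tables reproducible; on raw data it agrees
  with the direct computation to machine precision (property-tested).
- **2×2 chi-square without continuity correction**: the uncorrected
  Pearson statistic is what matches published sex-table values (the
  Yates-corrected statistic differs by an order of magnitude at these
  counts). Zero margins raise a degenerate-data error.
- **Spearman correlation** with average ranks for ties and the t
  approximation `t = r sqrt((n−2)/(1−r²))` for the p value — adequate at
  cohort sizes around 100. An exact permutation p is available for
  `n ≤ 8`; the cap (rather than, say, 10) keeps full enumeration at
  8! = 40,320 permutations, instant in pure R, and the facility is only
  used at toy sizes in tests.

## 4. The synthetic cohort generator

The generator's purpose is to make every stage of the pipeline testable
— with known ground truth — when no raw study data can be shared. Its
defaults *are* the published study conditions; they are stated once and
not tuned against test outcomes.

**Marginals.** Group tables publish only means and SDs, so participant
marginals are normal with those parameters: 64 healthy controls and 47
MCI participants; HT 108.77 (25.25) vs 184.85 (25.24) ms; FT 622.925
(135.14) vs 1351.51 (242.75) ms; MoCA-K 25.83 (2.11) vs 22.77 (2.26);
CBT accuracy .773 (.06) vs .687 (.07); plus age, education, MMSE-K and a
sex fraction per group. Instrument realism is then applied: MoCA-K and
MMSE-K are rounded to integers and clipped to [0, 30] (instruments are
integer-scored, so ties exist and tie handling is genuinely exercised
downstream), CBT accuracy is clipped to [0, 1], and HT/FT are truncated
below at 1 ms. At the published effect sizes the clips are essentially
never active, so the normal marginals are preserved in practice.

**Dependence.** MoCA-K, CBT, HT and FT are coupled through a Gaussian
copula. The subtlety is that published correlation tables from two-group
studies report the *pooled-sample* Spearman correlation, and pooling two
groups with different means inflates the rank correlation relative to
the within-group dependence: two markers that both separate the groups
are pooled-correlated even if conditionally independent. The generator
therefore calibrates on the pooled scale by default: for each variable
pair it solves, by bisection, for the common within-group latent Pearson
correlation whose *population* pooled grade correlation
`r_s = 12·E[F(X)G(Y)] − 3` (computed semi-analytically via bivariate
normal quadrature) equals the published target. At the published group
separations the required within-group correlations turn out to be small
(|ρ| ≈ 0.1 or less) — most of the printed dependence is carried by the
group structure itself. Targets that no within-group correlation can
reach are clamped to the boundary with a warning; the assembled matrix
receives a nearest-PSD repair (eigenvalue clipping, diagonal restored)
if needed. `calibration = "within_group"` applies the plain copula
identity `ρ = 2 sin(π r_s / 6)` instead, which is also the right tool
when marginal behavior alone matters (it is cheaper and leaves marginals
identical).

**Event streams.** Each participant's raw stream is built keystroke by
keystroke around their latent HT/FT means: session counts and per-session
press counts are negative binomial (`dispersion d` meaning variance
`μ(1 + dμ)`; `d = NA` fixes the count, `d = 0` is Poisson);
per-keystroke HT and FT are gamma with the participant mean and a common
coefficient of variation (positive, right-skewed — the shape of real
typing latencies); timestamps accumulate as
`press_{j+1} = release_j + FT_j`, `release_j = press_j + HT_j`, rounded
to integer ms, with sessions spaced an hour apart. Contamination is
injected per keystroke: with the configured rates an HT is replaced by a
uniform draw on (700, 1400] ms and an FT on (3000, 10000] ms — values
the preprocessing filters must remove.

Stream defaults: 32 sessions per participant (dispersion 0.3) and 120
presses per session, dispersion 0.7342. The press dispersion is the one
calibrated quantity: it is the value at which
`P(presses > 40) = 77.6%`, the session-retention rate the pipeline is
designed around (a study collecting ~3,530 sessions from 111
participants retains ~2,740). Within-participant CV is 0.35 and outlier
rates 0.02 — stated assumptions in the realistic range for smartphone
typing, since no publication reports within-participant variance. The
FT shift (`ft_shift_ms`), which would generate rollover, defaults to 0:
published FT means near and above 600 ms indicate hunt-and-peck typing
in this population, where rollover is rare; the extraction path for
negative FT is tested directly on constructed sessions instead.

**What a green test establishes — and what it does not.** The generator
reproduces group sizes, participant-level marginal means/SDs, pooled
rank correlations, session/press count structure, the retention rate,
and filterable contamination. It does *not* emulate: linguistic content
or key-identity structure (keys are uniform tokens), diurnal or
longitudinal usage patterns, heavy-tailed or skewed participant-level
marginals (only mean/SD are published, so normality is an assumption),
learning or fatigue within sessions, or correlation between a
participant's latent level and their usage volume. A passing end-to-end
test therefore establishes that the *pipeline arithmetic* is correct
under the stated statistical structure, not that the published empirical
results would replicate on new human data.

## 5. Numerical choices and degenerate inputs

- Strict (`>`) exclusion thresholds, boundary values retained — exactly
  as the preprocessing rule is printed.
- ROC with all scores identical returns AUC 0.5 with a warning; a
  single-class label vector is a degenerate-data error.
- The round-trip recovery test (extraction vs latent truth) treats the
  ±2-SE Monte-Carlo tolerance as a distributional statement: each
  participant-level z-score is ~N(0, 1) under correctness, so the test
  requires all |z| < 4 and at least 80% within 2 — a fixed-seed check
  that does not false-alarm on the ~5% of individual z-scores expected
  beyond 2 SE.
- IRLS floors the working weights at 1e−10 and falls back to a jittered
  solve if the weighted normal equations become numerically singular
  near separation.
- The copula quadrature integrates the bivariate normal CDF to relative
  tolerance 1e−9; calibration bisection tolerance is 1e−5 on the latent
  correlation, well inside the ±0.02 acceptance band on recovered
  correlations.
- All generators are deterministic in `(config, seed)`; identical seeds
  produce byte-identical event-log files (hash-tested).
- CLI exit codes: 0 success, 2 validation error, 3 degenerate data.

## 6. Known limitations

- The positive-class orientation of published sensitivity/specificity
  for the cognitive-score row in tables of this kind is sometimes
  inconsistent with the keystroke rows (the printed fractions match
  swapped group sizes). This package fixes MCI as the positive class
  everywhere and documents, rather than reproduces, such anomalies.
- Where an abstract and a results table disagree on a correlation value
  (−.497 vs −.491 for FT with MoCA-K), the results-table value is used.
- In-sample (apparent) discrimination only: no cross-validation or
  held-out evaluation is implemented, matching the evaluation design the
  package targets.
- Session boundaries are taken as given in the input; the package does
  not re-segment streams by inactivity gaps.
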