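---
title: "Scoring bacterial growth curves: the model, the metrics, and the simulation study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring bacterial growth curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthscore)
```

## The problem

A 96-well phenotype microarray plate pairs one bacterial culture with 96
different nutrient conditions and records absorbance (OD) over hours to
days. Downstream analysis wants one number per well: *how much did this
culture grow on this substrate?* `growthscore` computes two such numbers —
the Growth Score (GS), built only from fitted curve parameters, and the
legacy Growth Level (GL), a harmonic-mean statistic over the fitted curve —
plus ordinal growth classes, and ships the simulation study that compares
them.

## The growth model

Each well's time series is summarised by the Zwietering reparameterization
of the logistic curve,

$$\hat y(t) = y_0 + \frac{A - y_0}{1 + \exp\!\left[\frac{4\mu}{A}(\lambda - t) + 2\right]},$$

whose four parameters are directly interpretable: $y_0$ the absorbance at
inoculation (OD), $\lambda$ the lag time (h), $\mu$ the maximum growth
rate (OD/h), and $A$ the biomass yield, the asymptotic OD of stationary
phase. At $t = \lambda$ the exponent is exactly 2, so
$\hat y(\lambda) - y_0 = (A - y_0)/(1 + e^2)$ — a useful analytic anchor
for testing.

One subtlety of this parameterization is worth recording: because the
amplitude is $A - y_0$ while the exponent is scaled by $4\mu/A$, the
analytic slope at the inflection point is $\mu\,(A - y_0)/A$, not $\mu$
itself. It tends to $\mu$ as $y_0/A \to 0$; for shallow curves
($A - y_0 \ll A$) the observed steepest slope can be far below $\mu$. The
package treats $\mu$ as the exponent-scale rate of the formula throughout
(it is what the Growth Score consumes), and the fitting code accounts for
the gap (below). $\mu$ is an absolute slope in OD/h, consistent with the
simulation ranges where $\mu$ runs up to $1.1A$ — yield reached within
about an hour.

OD values are assumed blank-corrected; no background subtraction is done.
Time is always handled in hours internally; the readers convert from
minutes or seconds on request.

## The two metrics

**Growth Score.** $GS = (A - y_0) + 0.25\,\mu$. The dominant term is the
amplitude — total biomass accumulated — with the maximum rate added at 25%
weight so that a short burst of fast growth with low yield cannot dominate
the score, while faster growth at equal yield still ranks higher. GS uses
no fitted values, so it is independent of lag time and experiment length
and can score parameter tables produced by any curve-fitting software (the
CLI `score` verb does exactly that). A non-growing fit ($A \le y_0$) gives
$GS \le 0$; the value is reported unclamped so cohort statistics stay
unbiased, and classification maps it to the lowest class.

**Growth Level.** $GL = n / \sum_i 1/x_i$ with
$x_i = (\hat y_i - y_0) + (A - y_0)$: a harmonic mean of the fitted curve
shifted by the amplitude. It is always computed on the model curve
$\hat y$, never on raw readings, and over exactly the observed time grid —
so it depends on the grid spacing and on how long the instrument ran,
which is the main criticism GS answers. If any $x_i \le 0$ (flat or
shrinking wells), GL is defined as 0 and flagged `degenerate` rather than
erroring, because no-growth wells are routine inputs.

**Classes.** Both metrics map to ordinal labels `-`, `+`, `++`, `+++`,
`++++` (no growth to very high growth) by thresholding. Cutoffs are
*inclusive lower bounds*: a value exactly on a cutoff takes the higher
class (the convention had to be fixed somewhere; inclusive lower bounds
keep `classify` monotone and predictable at boundaries). The historical
PMAnalyzer cutoff values are not published, so the package ships
implementation defaults in `inst/extdata/thresholds.conf`: GL cutoffs
0.25 / 0.75 / 1.25 / 1.75 (quarter-OD steps spanning the realistic GL
range), and GS cutoffs obtained by mapping those through the GS-on-GL
regression line of a seed-1 default cohort (0.2115 / 0.5428 / 0.8740 /
1.2053), so that the two label sets partition curves comparably. Both are
fully overridable via `class_thresholds()`, a config file, or the CLI
`--thresholds` flag, and no quantitative result in the package depends on
them.

## Fitting

`fit_logistic()` minimises the plain, unweighted residual sum of squares —
no robust loss, matching the least-squares formulation — with a bounded
Levenberg–Marquardt optimizer. Choices that matter:

* **Start.** `initial_guess()` works on a median-smoothed copy of the
  curve (window 3 by default; the objective always uses raw OD): $y_0$
  from the first readings, $A$ from the maximum, $\lambda$ from the
  tangent through the steepest segment, clipped into the observed window.
  The $\mu$ start inverts the steepest observed slope through the
  amplitude ratio $A/(A - y_0)$ — the correction implied by the inflection
  slope above. Without it, shallow curves (small $A - y_0$) start an order
  of magnitude low and the bound below can exclude the true value; with
  it, noise-free recovery is essentially exact across the whole
  simulation range. The ratio is guarded at $0.05A$ so near-flat curves
  cannot blow it up.
* **Bounds.** $y_0 \in [0, \max od]$, $A \in [\min od, 2\max od]$,
  $\mu \in [10^{-6}, 10\times\text{corrected slope estimate}]$,
  $\lambda \in [0, \max t]$. These keep the exponent well scaled and the
  parameters physical; the $\mu$ floor ($10^{-6}$ OD/h) stands in for
  "no measurable growth".
* **Exponent clamp.** The exponent argument is clamped to $[-700, 700]$
  before `exp()`, so extreme $\mu(\lambda - t)/A$ products return the
  exact asymptote instead of overflowing to `Inf`/`NaN`. A side effect is
  that far from the lag the curve equals $y_0$ (or $A$) to the last
  double-precision bit, so "strictly inside $(y_0, A)$" holds only where
  the increment is representable — the tests assert strictness near the
  inflection and monotone non-decrease globally.
* **Determinism.** The fit is a deterministic function of the curve: one
  start, tolerances $10^{-10}$ on cost and step, at most 200 iterations.
  An optional seeded multistart (5 perturbed starts, keep the best RSS)
  exists behind `fit_options(multistart = TRUE)` for hard curves; it never
  returns a worse fit than the single start.

Curves with fewer than 4 points (4 free parameters) or non-finite
readings are rejected up front. A flat well converges to $A \approx y_0$
and is flagged non-growing downstream rather than failing.

## The simulation study

`simulate_cohort()` generates the comparison cohort: by default 1,000
noise-free curves on the grid $0, 0.5, \ldots, 240$ h (481 points), with
independent uniform draws per curve of

* $y_0 \sim U(0.05, 0.10)$ — realistic inoculation turbidity,
* $\lambda \sim U(0, 120)$ h — up to half the experiment,
* $A \sim U(0.1, 1.2)$ — drawn **before** $\mu$,
* $\mu \sim U(A/240,\; 1.1A)$ — the rate range is tied to the drawn
  yield: the lower end reaches the yield only at the end of the 240 h
  experiment (very slow growth), the upper end within about an hour
  (very fast growth).

These defaults are the study conditions, not tuning knobs. The sampling
order ($y_0$, $\lambda$, $A$, $\mu$) is fixed so seeded cohorts are
reproducible across versions. Grid spacing is not part of the original
design statement; 0.5 h is a typical plate-reader cadence, and since GL
averages over grid points, `dt` is a first-class config field echoed in
every report. No observation noise is added in the comparison (the curves
*are* the model, so refitting would be an identity operation, and the
comparison therefore uses the true parameters directly); a Gaussian noise
option (`noise_sd`) exists to exercise the fitter.

`compare_metrics()` reports the Pearson correlation between GL and GS
with its two-sided p-value, the adjusted Fisher–Pearson sample skewness
of each metric, the GS-on-GL least-squares line, and two class-agreement
counts: curves labelled differently by the two metrics, and the subset of
those crossing the no-growth boundary (`-` versus any `+` class). Across
seeds the correlation is stable near 0.96–0.97; the skewness pair and
the class-change counts are single-realization quantities that depend on
the RNG seed and on the class cutoffs, so the package checks only their
ordering (GL more skewed than GS; reclassifications at least as many as
boundary crossings) rather than exact values.

### What the generator does and does not emulate

The synthetic cohort contains ideal, noise-free, strictly logistic
curves. Real plate-reader data have measurement noise, condensation and
bubble artefacts, diauxic shifts, death phases, and wells that never
leave baseline. Passing the cohort-based checks therefore validates the
metric algebra, the fitting machinery, and the metric comparison under
the model's own assumptions — it does not validate the logistic model
against misbehaving biology. The noisy-recovery tests ($\sigma = 0.01$
OD) cover the first-order robustness question; structured artefacts are
out of scope.

## Numerical choices and degenerate inputs

* Harmonic-mean degeneracy: any $x_i \le 0$ short-circuits GL to 0 with a
  flag (never an error, never `Inf`).
* Classification at a cutoff goes to the higher class; classification of
  negative GS goes to `-`.
* Problem sizes in the test suite: 20 cohorts of 1,000 curves for the
  correlation band, 200 noise-free + 100 noisy fits for parameter
  recovery, 10,000 draws for range conservation — sizes at which the
  checked statistics are stable to well inside their asserted tolerances
  while the suite stays quick to run.
* Well labels are normalised to zero-padded form (`A1` → `A01`) on read,
  so joins against condition maps never depend on the instrument's
  padding habits.

## Limitations

* Only the Zwietering logistic form is implemented; Gompertz, Richards,
  and Baranyi alternatives are out of scope, as are confidence intervals
  on parameters and model selection.
* The shipped class cutoffs are implementation defaults, not the
  historical PMAnalyzer values; absolute class counts are only
  meaningful relative to a stated threshold set.
* GL values depend on the time grid by construction; comparisons of GL
  across experiments are only valid at matching `total_time` and `dt`.
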