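# growthscore

Single-number growth metrics for 96-well bacterial phenotype assays.

A phenotype microarray plate grows one culture under 96 nutrient
conditions while a plate reader records absorbance (OD) over hours to
days. To compare wells, strains, or substrates, each time series must be
reduced to one number. `growthscore` does this in three steps:

1. **Fit** the four-parameter Zwietering logistic model to each well,

   $$\hat y(t) = y_0 + \frac{A - y_0}{1 + \exp\!\left[\tfrac{4\mu}{A}(\lambda - t) + 2\right]}$$

   with $y_0$ the starting absorbance, $\lambda$ the lag time (h), $\mu$
   the maximum growth rate (OD/h), and $A$ the biomass yield, by bounded
   least squares.

2. **Score** each curve with
   * the **Growth Score** $GS = (A - y_0) + 0.25\,\mu$ — amplitude plus a
     quarter of the rate, independent of lag time and experiment length,
     computable from any fitter's parameter table; and
   * the legacy **Growth Level** $GL = n / \sum_i 1/x_i$ with
     $x_i = (\hat y_i - y_0) + (A - y_0)$ — a harmonic mean over the
     fitted curve, retained for comparison.

   Both map to ordinal growth classes `-` … `++++` via configurable
   thresholds.

3. **Compare** the two metrics on a simulated cohort: 1,000 noise-free
   logistic curves over 240 h with $y_0 \sim U(0.05, 0.10)$,
   $\lambda \sim U(0, 120)$, $A \sim U(0.1, 1.2)$ and
   $\mu \sim U(A/240,\ 1.1A)$, reporting their Pearson correlation,
   skewness, regression line, and class-change counts.

## Worked example

Fit and score one noisy well, then run the metric comparison:

```r
library(growthscore)

p <- growth_params(y0 = 0.06, lag = 18, mu = 0.35, A = 0.95)
t <- seq(0, 48, by = 0.25)
set.seed(7)
cv <- growth_curve(t, zwietering(p, t) + rnorm(length(t), 0, 0.01),
                   well_id = "A01")
fit <- fit_logistic(cv)
fit
#> Logistic fit on 193 points: rss = 0.01725, converged = TRUE
#> Zwietering parameters: y0 = 0.06276, lag = 18.04 h, mu = 0.3572 OD/h, A = 0.9512
score_curve(fit)
#> GL = 1.274 (+++)   GS = 0.9777 (+++)
```

The fit recovers the generating parameters to about 2% despite
$\sigma = 0.01$ OD noise; GS ≈ 0.98 says the culture accumulated ~0.89 OD
of biomass with a brisk maximum rate, landing in the `+++` (high growth)
class under the shipped default thresholds.

The simulation study in one call:

```r
compare_metrics(simulate_cohort(simulation_config(seed = 1)))
#> GL vs GS over 1000 curves (dt = 0.5 h):
#>   Pearson r      0.9637  (p = 0)
#>   skewness       GL 0.2166, GS 0.1302
#>   GS ~ GL        slope 0.6625, intercept 0.0459
#>   reclassified   222  (of which 20 cross the no-growth line)
```

The two metrics are almost collinear (r ≈ 0.96), GL is the more skewed of
the two, and roughly a fifth of curves change ordinal class between the
metrics while only a handful cross the growth/no-growth boundary.

## Command line

The installed `exec/growthscore` script exposes the same machinery as
shell verbs, logging to stderr and writing results to files/stdout:

```sh
growthscore fit      --input plate.tsv --format long --conditions media.tsv --out results.tsv
growthscore score    --input params.tsv --out scored.tsv     # works with external fitters
growthscore simulate --n 1000 --seed 1 --out cohort.tsv
growthscore compare  --input cohort.tsv --json report.json
```

Input formats: a long tab-delimited table (`sample`, `well`, `time`,
`od`), a wide CSV (a `time` column plus one column per 96-well label),
and a tab-delimited well→condition map. `--time-unit` converts
minutes/seconds to hours on read; well labels are normalised (`A1` →
`A01`).

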