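---
title: "Growth-law plasticity: model, estimators, and synthetic-data design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-law plasticity: model, estimators, and synthetic-data design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthplast)
```

## The model

The steady-state growth laws balance two fluxes over a constrained
proteome. Translation by the ribosomal sector produces protein at rate
$\lambda = \kappa_t(\phi_R - \phi_0)$; nutrient influx through the
catabolic P-sector supplies precursors at rate
$\lambda = \kappa_n \phi_P$; and the two sectors share a fixed budget,
$\phi_R + \phi_P = \phi_R^{max}$. The original formulation states the
two flux relations as proportionalities; we treat them as equalities
with the proportionality constants absorbed into $\kappa_t$ and
$\kappa_n$ — that is exactly the convention under which eliminating the
sector fractions yields the closed form

$$\lambda \;=\; \lambda_{max}\,\frac{\kappa_n}{\kappa_n + \kappa_t},
\qquad \lambda_{max} = \kappa_t(\phi_R^{max} - \phi_0)
 = (1-\phi_{fixed})\,\kappa_t .$$

`growth_context()` therefore takes only $\kappa_t$, $\phi_0$ and
$\phi_R^{max}$ and *derives* $\lambda_{max}$ and $\phi_{fixed}$, so the
identity between them can never be violated by construction.

The plasticity extension decomposes nutrient quality. The
substrate-specific transporters and first enzymes (the C\*-sector) are
an expression fraction $f$ of the whole P-sector, and

$$\kappa_n = f\,\kappa_n^{*},$$

with $\kappa_n^{*}$ the core quality set by enzyme kinetics. The
remainder $\phi_{AD} = \phi_P(1-f)$ is the adaptability sector:
alternative uptake systems, stress and motility proteins that buy lag
time, starvation survival and motility rather than current growth.
Individual enzyme $V_{max}$ values are never parameterised separately:
they enter only through $\kappa_n^{*}$, because nothing in the
steady-state theory distinguishes faster enzymes from more of them.

### Parameters, units, defaults

| parameter | meaning | units | valid range |
|---|---|---|---|
| $\kappa_t$ | translational capacity | 1/h per unit proteome fraction | $>0$ |
| $\phi_0$ | offset ribosomal fraction | – | $[0,1)$ |
| $\phi_R^{max}$ | max P+R fraction | – | $(\phi_0, 1]$ |
| $\kappa_n^{*}$ | core nutrient quality | 1/h per unit fraction | $>0$ |
| $f$ | C\*-sector expression fraction | – | $(0,1]$ |

The model fixes no numeric values for the global parameters, so the set
used in every example and in the self-consistency checks —
$\kappa_t = 4$, $\phi_0 = 0.1$, $\phi_R^{max} = 0.6$, hence
$\lambda_{max} = 2$ /h — is *illustrative*: round numbers of the right
physiological order, not measurements. Fraction arguments are validated
strictly and out-of-range values raise classed errors rather than being
clamped; silent clamping would mask configuration mistakes.

## Titration: imposed induction

When the catabolic-sector fraction $x$ is imposed externally (cAMP
titration) rather than set by regulation, growth is limited by the
smaller of nutrient influx $\kappa_n x$ and translation
$\kappa_t(\phi_R^{max} - x - \phi_0)$. Two combination rules are
implemented:

* `hard_min` (default): $\lambda = \min$ of the two fluxes. Its optimum
  $x^\star = \kappa_t(\phi_R^{max}-\phi_0)/(\kappa_n+\kappa_t)$ makes the
  two fluxes equal, and the peak rate *equals* the closed-form growth
  law — the titration picture and the growth law are two views of one
  balance, which is why `hard_min` is the default.
* `harmonic`: the smooth series-bottleneck combination
  $ab/(a+b)$, bounded above by `hard_min` pointwise. Measured titration
  curves are smooth, so this is offered as an alternative likelihood for
  fitting; it trades the exact optimum identity for smoothness.

The abscissa is the induction *fraction* itself, not a cAMP
concentration: no dose–response mapping from cAMP level to sector
fraction is part of the model, so none is guessed here. A user-supplied
monotone map can be composed externally, and every monotone map leaves
the package's rank-based trade-off statements unchanged.

`fit_titration()` estimates only $\kappa_n$, with the growth context
held fixed: a single titration curve cannot identify all four model
parameters (the rising branch constrains $\kappa_n$, the falling branch
$\kappa_t$ and the span, but jointly they are badly confounded through
the peak), and in this framing the substrate-specific unknown *is* the
nutrient quality. The search is a coarse grid over
$\log_{10}\kappa_n \in [-3, 3]$ (step 0.1) followed by golden-section
refinement of the bracketing interval to tolerance $10^{-12}$; on
noiseless model curves this recovers $\kappa_n$ to better than
$10^{-6}$ relative error.

## Protein-cost integration

The integration analysis joins three tables on gene id (inner join;
dropped genes are counted and reported), rescales copy numbers to a
common slow-growth reference by the measured fold change, converts to
amino-acid cost by multiplying with protein length, and rank-correlates
both copy number and cost against the growth rate on each substrate.
Choices worth stating:

* **Spearman, not Pearson**, is the primary statistic, because the claim
  being tested is rank-ordered anticorrelation, and because copy numbers
  span orders of magnitude. Pearson on log cost is emitted as a
  secondary output.
* **Ties get average ranks** (midranks) — the standard convention.
* **Exact permutation p-values for $n \le 8$** (all $n!$ orderings,
  two-sided by $|\rho|$), the t approximation with $n-2$ degrees of
  freedom otherwise. With the handful of substrates such datasets have,
  the exact branch is the one that matters; it agrees with
  `cor.test(..., exact = TRUE)` in the no-ties case.
* **Zero reference abundance is rejected**, not imputed: a fold change
  applied to zero is meaningless.
* The slow reference growth rate (0.45 /h in the source datasets) is
  metadata; the fold-change table is assumed pre-selected for that
  condition and the value is never used in computation.

## Phenotype estimators

**Growth rate.** Ordinary least squares of $\ln OD$ on time — the
semi-log method — over a window of at least 4 points;
`doubling_time = ln 2 / λ`. `auto_window()` automates the manual
"pick steady-state points" step: among all contiguous windows with
$r^2 \ge$ a bar (default 0.99), it returns the one with maximal fitted
rate, ties broken by longer window then earlier start. Maximising the
rate (rather than, say, window length) selects the unarrested
exponential phase and is insensitive to plateau or lag points, which
can only drag the slope down.

**Shift detection.** The instantaneous rate is estimated by centred
finite differences of $\ln OD$, smoothed with a 3-point moving average;
the shift onset is the first time the smoothed rate falls below
$\theta\,\lambda_1$ (default $\theta = 0.5$, configurable — no published
criterion exists, and 0.5 sits safely between typical glycolytic and
acetate rates). A persistence requirement (`min_run`, default 3
consecutive sub-threshold points) is part of the criterion: with
multiplicative OD noise the smoothed derivative has a standard
deviation of roughly $\sigma_{\ln}/ (3\,\Delta t)$, large enough that a
single-point criterion false-triggers during healthy growth. On
noiseless piecewise-exponential curves the detected onset is the first
grid point after the true breakpoint.

**Lag time.** The "time lost" definition: fit the post-shift
exponential, back-extrapolate it to the OD at shift onset, and report
$lag = t^\star - t_{shift}$ where $t^\star$ is when the fitted second
exponential reaches $OD(t_{shift})$. Because the fitted line is used,
the result is independent of any reference-point choice inside an exact
second exponential, and an instantaneous shift gives lag 0. Detection
can land one grid point late on an instantaneous shift, which makes the
raw extrapolation marginally negative; estimates are truncated at 0 to
respect the lag's definition as a non-negative delay.
`analyze_diauxie()` wires the steps together and then refines the
post-shift window once: after a provisional lag estimate from the tail
of the series, the second exponential is refit on all points later than
$t_{shift} + \widehat{lag} + 0.5$ h. The refit both lengthens the
window (tightening $\widehat{\lambda_2}$) and shortens the
extrapolation distance, which is where most of the lag variance comes
from.

**Survival.** CFU density is $colonies \times dilution / volume$;
densities are averaged over replicate plates at each stage and the
survival percentage is the ratio of means — matching triplicate plating
with a mean survival report. Per-plate densities are attached to the
result so per-replicate ratios can be formed when the pairing is known.
The percentage is invariant to the dilution scheme as long as counts and
dilutions are consistent.

**Motility.** Colony-area fold changes are per-colony ratios between
two imaging days, summarised by mean and sample SD; the swarming
fraction is a simple proportion over flags or thresholded areas. Image
segmentation is out of scope — inputs are area tables.

OD background subtraction is the caller's responsibility; the
constructors validate positivity only.

## The synthetic-data generators

The generators produce every input table with known ground truth, under
a single integer seed each (pure functions of their arguments; the
caller's RNG state is untouched):

* `gen_od_series()` / `gen_diauxic_series()`: exponential and
  piecewise exponential–plateau–exponential curves with unit-mean
  multiplicative lognormal noise (positive-valued measurements).
  Diauxic defaults emulate a glucose-to-acetate shift:
  $\lambda_1 = 0.9$ /h, $\lambda_2 = 0.3$ /h, exhaustion at OD 0.25
  from OD 0.02, sampled every 0.05 h for 14 h (plate-reader cadence).
* `gen_proteomics()`: the cost–growth relation is generated
  *phenomenologically* as $\log N = a - b\lambda + \varepsilon$ with
  lognormal $\varepsilon$, not derived from the growth-law model —
  the measured anticorrelation was observed for substrates absent from
  the growth medium, so the mechanistic link is the hypothesis under
  test, not an assumption the generator should hard-code. Defaults
  $a = 10$, $b = 6$ span roughly two orders of magnitude in copy number
  across growth rates 0.2–1.0 /h, the spread such transporter data
  show; noise CV defaults to 20%. Decoy genes present in exactly one
  table exercise the join bookkeeping.
* `gen_cfu()`: Poisson counts with mean
  $density \times volume / dilution$ (counts are counts); plates with
  expected counts above $10^6$ are refused as uncountable.
* `gen_titration_data()`: the model curve plus additive Gaussian noise
  truncated at zero.

What the generators do **not** emulate: instrument drift and
plate-reader saturation, biological replicate-to-replicate variation
beyond measurement noise, growth-curve curvature at very low OD,
non-lognormal proteomics error structure, and colony-count clumping
(over-dispersion). Passing the recovery studies therefore demonstrates
estimator correctness under the stated noise model, not robustness to
every artefact of real data.

## Numerical choices

* The independent flux-balance cross-check (`flux_balance_allocation()`)
  uses derivative-free bisection on $\phi_R \in [\phi_0, \phi_R^{max}]$,
  tolerance $10^{-14}$ with a machine-resolution stall guard; tight
  enough that the translated growth rate agrees with the closed form to
  well under $10^{-9}$ relative error over the whole parameter range.
  It shares no algebra with the closed form, which is the point.
* Recipe molarities are compared to printed tables after rounding half
  away from zero to one decimal — the convention printed tables use,
  not R's round-half-to-even.
* Degenerate inputs raise classed errors (`gp_domain_error`,
  `gp_format_error`, `gp_noshift_error`, …) rather than returning NA;
  file readers name the file, line and column of the first offence.

## Problem sizes in the recovery studies

The seeded recovery studies in the test suite and in
`scripts/acceptance.R` use: 1000 random parameter draws for the
closed-form/numeric agreement; 200 replicates each for growth-rate
recovery (10 time points, 2% noise), diauxic-lag recovery (lags 1, 2,
4 h cycled, 2% noise, 0.05 h grid), $\kappa_n$ recovery from 41-point
titration curves (noise 2% of the peak rate), and the proteomics
anticorrelation (20 substrates, 20% noise, plus a $b=0$ null). These
sizes give binomial standard errors of about 2 percentage points on the
reported pass fractions, small against the margins being tested, and
the whole battery runs in well under a minute.

## Known limitations

* Steady state only: no dynamic reallocation ODEs, so nothing here
  predicts the *time course* of a shift — only its lag summary.
* The cAMP–CRP signalling mechanism is not modelled; induction is a
  phenomenological variable.
* `fit_titration()` assumes the growth context is known; fitting it
  jointly from one curve is not identifiable and is deliberately not
  offered.
* The titration optimum identity holds exactly for `hard_min`; under
  `harmonic` the peak sits below the closed form, so mixing modes
  between generation and fitting biases $\kappa_n$.
* Fold changes are taken as given at the slow-growth reference; no
  interpolation across growth rates is attempted.
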