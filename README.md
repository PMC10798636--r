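# growthplast

Steady-state bacterial growth-law modelling in which **nutrient quality is a
plastic, regulation-set parameter**, plus the phenotype quantification that
goes with testing that idea in the lab.

## The problem

*E. coli* grows at very different rates on different carbon sources, and the
classic growth laws compress all of that variability into one parameter, the
nutrient quality κ<sub>n</sub>. The growth laws balance two fluxes over a
constrained proteome: translation by the ribosomal sector,
λ = κ<sub>t</sub>(φ<sub>R</sub> − φ<sub>0</sub>), and nutrient influx by the
catabolic P-sector, λ = κ<sub>n</sub>φ<sub>P</sub>, with
φ<sub>R</sub> + φ<sub>P</sub> = φ<sub>R</sub><sup>max</sup>. Eliminating the
sector fractions gives the Monod-like closed form

λ = λ<sub>max</sub> · κ<sub>n</sub> / (κ<sub>n</sub> + κ<sub>t</sub>),  λ<sub>max</sub> = (1 − φ<sub>fixed</sub>)·κ<sub>t</sub>.

This package implements the plasticity extension of that model: the
substrate-specific transporters and enzymes (the C\*-sector) are only a
fraction *f* of the much larger co-regulated catabolic sector, so the
effective nutrient quality decomposes as

**κ<sub>n</sub> = f · κ<sub>n</sub>\***,

with κ<sub>n</sub>\* the core enzymatic quality. Promoter re-engineering (or
cAMP) moves *f*, so a "poor" substrate can be turned into a "good" one — at
the cost of the adaptability sector φ<sub>AD</sub> = φ<sub>P</sub>(1 − f)
that holds alternative uptake systems, stress and motility proteins. The
package covers:

* **growth-law core** — steady-state allocation, the closed form, its
  inversion (κ<sub>n</sub> from an observed rate), promoter-swap predictions,
  and an independent numeric flux-balance solver for cross-checks;
* **cAMP titration** — growth rate versus imposed catabolic-sector induction
  (hard-minimum and harmonic flux combination), its optimum, and least-squares
  fitting of κ<sub>n</sub> from titration curves;
* **protein-cost integration** — joining copy-number, fold-change and
  substrate growth-rate tables, amino-acid cost, and the Spearman rank
  anticorrelation between transporter investment and growth rate (exact
  permutation p-values for n ≤ 8);
* **phenotype metrics** — semi-log exponential fits with automatic window
  selection, diauxic-shift detection and lag time by back-extrapolation,
  CFU-based starvation survival percentages, and soft-agar colony-area /
  swarming summaries;
* **synthetic data** — seeded generators for every input table with known
  ground truth, so parameter recovery is testable end to end;
* **IO & CLI** — validated TSV/CSV readers and writers, a YAML model
  configuration, a media-recipe molarity calculator, and a `growthplast`
  command-line tool (`inst/exec/growthplast`) with `simulate`, `fit-growth`,
  `lag`, `survival`, `cost`, `titrate` and `recipe` subcommands.

## Worked example

```r
library(growthplast)

ctx <- growth_context(kappa_t = 4, phi_0 = 0.1, phi_R_max = 0.6)  # illustrative units
mannose <- substrate_params("mannose", kappa_n_star = 10, f = 0.1)
steady_state_allocation(ctx, mannose)
#> <sector_allocation>
#>   phi_R = 0.2  phi_P = 0.4
#>   phi_C* = 0.04  phi_AD = 0.36
#>   lambda = 0.4 /h
predict_promoter_swap(ctx, mannose, f_new = 1)
#> [1] 1.428571
```

Only 4% of the proteome (φ<sub>C*</sub>) actually serves mannose uptake; the
other 36% is adaptability reserve. Pushing the expression fraction to 1
raises the predicted rate from 0.40 to 1.43 /h without touching enzyme
kinetics — nutrient quality is plastic. Across substrates, the optimum
induction level and the peak growth rate trade off perfectly:

```r
inverse_correlation_summary(ctx, c(glucose = 8, glycerol = 3, mannose = 1))
#>   name     kappa_n x_star lambda_star
#> 1 glucose        8  0.167       1.33
#> 2 glycerol       3  0.286       0.857
#> 3 mannose        1  0.4         0.4
```

Poor substrates need high induction (high cAMP) yet still grow slowest. The
phenotype side, on a simulated diauxic shift with 2% OD noise and a true lag
of 2 h:

```r
s <- gen_diauxic_series(lambda1 = 0.9, od_shift = 0.25, lag = 2, lambda2 = 0.3,
                        t_grid = seq(0, 14, by = 0.05), noise_cv = 0.02, seed = 42)
analyze_diauxie(s)
#> <diauxic_result> shift at 2.8 h, lambda1 = 0.898, lambda2 = 0.301 /h, lag = 2.05 h

pct <- survival_percent(cfu_observation(c(200, 210, 190), 1e5, 0.1),
                        cfu_observation(c(40, 38, 45), 2e4, 0.1))
round(as.numeric(pct), 1)
#> [1] 4.1
```

And the protein-cost anticorrelation on generated proteomics tables
(20 substrates, 20% abundance noise):

```r
d <- gen_proteomics(n_substrates = 20, noise_cv = 0.2, seed = 42)
res <- cost_growth_analysis(join_datasets(d$abundance, d$foldchange, d$substrates))
c(rho_copies = res$rho_copies, rho_cost = res$rho_cost)
#> rho_copies   rho_cost
#> -0.982       -0.973
```

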