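# dlgrowth

Bayesian growth modeling for linear skeletal traits, and a resampling
framework for a practical design question: **how well do cross-sectional
samples (one radiograph per individual) recover the growth standards and
milestones that dense longitudinal data would give?**

Longitudinal growth studies — the same children imaged repeatedly for a
decade or more — are the gold standard for craniofacial growth modeling,
but repeated radiographic imaging is rarely feasible. Cross-sectional
samples are cheap and ethical, yet a single measurement per individual
cannot separate measurement error from true between-individual variation.
dlgrowth quantifies what that costs, for whoever needs growth standards:
orthodontists and craniofacial surgeons timing treatment around the
pubertal growth spurt, and growth researchers building percentile charts
from whatever data they can ethically collect.

## The model

Trait size (mm) as a function of age (years) follows a double-logistic
curve — two additive logistic phases, prepubertal and adolescent:

```
y(age) = a1 / (1 + exp(-b1 (age - c1))) + (f - a1) / (1 + exp(-b2 (age - c2)))
```

with `f` the asymptotic size at growth cessation, `a1` the prepubertal
asymptote, `b1`, `b2` phase rates (truncated positive, so growth is
monotone), and `c1`, `c2` the ages of maximal phase growth. Observations
are Normal around the curve; longitudinal data add an individual-level
intercept `a_ID ~ Normal(0, sigma_ID)`, so residual measurement error
(`sigma`) and between-individual variation (`sigma_ID`) are separately
estimated. Priors are Normal with genetic-algorithm-elicited means and
fixed scales, plus `Exponential(0.25)` priors on both SDs. Growth velocity
is the closed-form first derivative of the curve; `find_milestones()`
extracts peak growth velocity (PGV, mm/y) and the age at which it occurs
(aPGV, y).

The pipeline stages map to exported functions:

| stage | functions |
|---|---|
| synthetic population | `population_config()`, `generate_population()` |
| prior elicitation & checks | `elicit_prior_means()`, `prior_predictive_curves()` |
| model fitting | `fit_longitudinal()`, `fit_cross_sectional()` (MCMC or MAP), `check_convergence()` |
| growth standards | `posterior_predict()` (50/80/98% intervals) |
| resampling experiment | `draw_cross_section()`, `run_experiment()`, `aggregate_replicates()` |
| agreement metrics | `mean_abs_difference()`, `milestone_errors()`, `rate_rmsd()`, `percentile_comparison()`, `compare_to_longitudinal()` |
| one-call study | `run_study()` |
| I/O and CLI | `read_dataset()`, `write_dataset()`, `cli_run()` (wrapper script in `inst/scripts/dlgrowth.R`) |

## Worked example

Simulate a 300-individual longitudinal population, elicit priors, fit the
longitudinal reference, and test cross-sectional subsamples of 50 and 200
individuals (10 replicates each):

```r
library(dlgrowth)

cfg <- population_config(n_individuals = 300, seed = 11)
study <- run_study(config = cfg, sizes = c(50, 200), reps = 10,
                   master_seed = 7)
print(study)
#> Longitudinal dataset: 2913 observations of 300 individuals (visits: median 10, range 2-18)
#>   traits: synthetic_trait | sexes: F | ages 4.02-21.98 y
#>   provenance: synthetic (truth config attached)
#> Cross-sectional vs longitudinal agreement by subsample size:
#>  size_label size n_replicates    mad pgv_mae pgv_bias apgv_mae apgv_bias
#>          50   50           10 0.4605  0.1875   0.0298   0.3550    0.0281
#>         200  200           10 0.2516  0.1274  -0.0299   0.2009    0.0482
#>  rate_rmsd
#>     0.0301
#>     0.0650
#> Reference milestones: PGV = 1.809 mm/y at aPGV = 11.450 y

find_milestones(median_growth_params(study$reference))
#> Growth milestones: PGV = 1.809 mm/y at aPGV = 11.450 y (adolescent phase); asymptote f = 100.99 mm
```

Reading the output: `mad` is the mean absolute difference (mm) between
each cross-sectional replicate's median growth curve and the longitudinal
reference curve, averaged over replicates and over the 5–20 y comparison
grid — 0.25 mm at n = 200, i.e. repeated cross-sections of 200 individuals
reproduce the longitudinal curve to a quarter millimeter on average.
`pgv_mae` / `apgv_mae` are the mean absolute errors of the growth
milestones: at n = 200 the peak growth velocity is recovered to ~0.13 mm/y
and its age to ~0.2 y. The synthetic population here grows to ~101 mm with
an adolescent spurt of ~1.8 mm/y at ~11.5 y, a plausible mid-sized
craniofacial distance.

For full posterior inference, fit by MCMC (adaptive Metropolis on the
marginalized multilevel posterior; 4 chains, 10,000 iterations, 50%
warmup by default) and extract growth-percentile standards:

```r
d <- generate_population(population_config(n_individuals = 100, seed = 1))
pr <- elicit_prior_means(d, ga_control(seed = 1))
fit <- fit_longitudinal(d, pr, mcmc_control(seed = 1))
check_convergence(fit)              # rank-normalized split R-hat, bulk ESS
posterior_predict(fit, levels = c(50, 80, 98), target = "new-observation")
```

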