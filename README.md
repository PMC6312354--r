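# saxsemble

Bayesian inference of protein conformational ensembles from small-angle
X-ray scattering (SAXS), optionally fused with NMR chemical shifts and
per-conformer structural energies.

Multi-domain proteins with flexible linkers exist in solution as
ensembles of conformations. A SAXS curve of such a protein is the
population-weighted average of its conformers' scattering,
*m(q) = λ Σᵢ wᵢ Iᵢ(q) + noise*, so given a library of candidate
conformers with precomputed profiles the task is to infer which
conformers are present and with what weights *w*. Because a SAXS curve
carries only ~10 independent parameters, the central danger is fitting
noise with an over-large ensemble. saxsemble follows a two-stage
Bayesian design:

1. **Model selection by variational Bayes.** The posterior over weights
   is approximated by a Dirichlet(α); maximizing the evidence lower
   bound (ELBO) in closed form selects ensembles by (approximate) model
   evidence, which penalizes complexity automatically. Conformers whose
   variational weight *wᵢ = αᵢ/α₀* falls below a cutoff are culled
   iteratively until the objective stops improving.
2. **Complete Bayesian inference.** On the selected subset, the weights,
   the intensity scale factor λ, and (with an energy prior) the
   reference shift U_ref are sampled by MCMC, yielding posterior
   distributions, credible intervals, convergence diagnostics
   (split-R̂, effective sample size), a Jensen–Shannon ensemble
   uncertainty in [0, 1], and posterior predictive checks.

Priors over weights are the non-informative Jeffreys Dirichlet(½, …, ½)
or an energy-biased Dirichlet with Boltzmann-factor concentrations
βᵢ = exp(−(U_ref + Uᵢ)/kT), which centers the prior on the Boltzmann
populations of the conformer energies while the data control its
strength. Exact model evidence by Monte-Carlo integration, Bayes
factors, exhaustive ensemble-size scans, goodness-of-fit tools
(reduced χ², error-weighted residuals, an exact longest-run
correlation-map test) and a fully seeded synthetic two-domain benchmark
generator are included, so every stage is testable without external
data.

## Worked example

Simulate a benchmark data set (100-conformer library, measurement
generated from 5 members with weights 0.1/0.15/0.2/0.25/0.3 at the
reference noise level), select the ensemble, and sample the posterior:

```r
library(saxsemble)

bench <- synthetic_benchmark("recovery100", seed = 1)
model <- select_ensemble(bench$curve, bench$library,
                         config = selection_config(seed = 42))
tidy(model)
#> # A tibble: 5 × 3
#>   member_id weight alpha
#>   <chr>      <dbl> <dbl>
#> 1 conf_012  0.0978 2305.
#> 2 conf_052  0.152  3585.
#> 3 conf_055  0.199  4678.
#> 4 conf_079  0.255  6001.
#> 5 conf_096  0.297  6994.
bench$truth$ids
#> [1] "conf_012" "conf_052" "conf_055" "conf_079" "conf_096"
```

The selection recovered exactly the five generating conformers, with
weights within ~0.003 of the generating values; `alpha` are the final
Dirichlet concentrations (their total reflects how sharply the data pin
the weights). Complete inference on the selected subset then quantifies
the uncertainty:

```r
sub   <- subset_library(bench$library, model$member_ids)
draws <- sample_posterior(bench$curve, sub, config = mcmc_config(seed = 7),
                          init = list(weights = model$weights,
                                      lambda = model$lambda_hat))
glance(draws)
#> # A tibble: 6 × 7
#>   parameter     mean       sd   q2.5 q97.5  rhat   ess
#>   <chr>        <dbl>    <dbl>  <dbl> <dbl> <dbl> <dbl>
#> 1 w[conf_012] 0.0981 0.00429  0.0893 0.106  1.03 109.
#> 2 w[conf_052] 0.153  0.00272  0.147  0.158  1.03 112.
#> 3 w[conf_055] 0.199  0.00219  0.194  0.203  1.02 168.
#> 4 w[conf_079] 0.254  0.00482  0.245  0.264  1.04 108.
#> 5 w[conf_096] 0.296  0.00311  0.290  0.302  1.05  92.8
#> 6 lambda      0.999  0.000698 0.998  1.00   1.02 128.
ensemble_uncertainty(draws)   # expected JSD vs the posterior mean, in [0,1]
#> [1] 6.93192e-05
fit_quality(model)            # chi2, CorMap longest-run test
#> # A tibble: 1 × 5
#>   chi2_raw chi2_reduced n_free cormap_C cormap_p
#>      <dbl>        <dbl>  <int>    <int>    <dbl>
#> 1     1.13         1.14      5        8    0.908
```

A posterior mean within a fraction of a percent of each generating
weight, a tiny ensemble uncertainty (the posterior is essentially a
point on the weight simplex), reduced χ² ≈ 1.1 and a CorMap run-test
P ≈ 0.9 together say the 5-member model explains the curve to within
its errors. `autoplot()` methods display curves, fits, posterior weight
densities and predictive envelopes; `run_pipeline()` executes the whole
workflow from a YAML config, and `inst/cli/saxsemble` exposes
`simulate | select | infer | evidence | fitqc | pipeline` subcommands
for shell use.

Real data enter through plain-text formats: 3-column `.dat` SAXS curves
(`read_saxs_curve()`), per-conformer profile matrices evaluated on the
experimental grid (`read_profile_matrix()`; FoXS-style, pre-descaled),
chemical-shift tables keyed by residue/atom label (`read_cs_table()`,
`read_cs_predictions()`, `align_cs()`), and one-energy-per-conformer
lists (`read_energies()`).

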