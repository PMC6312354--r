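---
title: "Bayesian conformational-ensemble inference from scattering, shifts and energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian conformational-ensemble inference from scattering, shifts and energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Multi-domain proteins with flexible linkers populate ensembles of
conformations in solution. A small-angle X-ray scattering (SAXS) curve of
such a protein is the population-weighted average of its conformers'
curves, so, given a library of candidate conformers with precomputed
scattering profiles, the inference problem is: which conformers are
present, and with what population weights? Because a SAXS curve carries
only on the order of ten independent parameters, the central danger is
overfitting — an ensemble with too many members will happily absorb
noise. saxsemble addresses this with a two-stage Bayesian treatment:
model selection by variational inference that maximizes a bound on the
model evidence, followed by complete Markov chain Monte Carlo inference
of the weights on the selected subset.

## The probabilistic model

The measured intensities are modelled per point as independent Gaussians,

$$ m_j \sim N\!\Big(\lambda \sum_{i} w_i I_{ij},\ \varepsilon_j\Big), $$

where $I_{ij}$ is conformer $i$'s profile on the experimental q-grid,
$w$ lies on the probability simplex, and $\lambda$ is the single scale
factor between the measured and computed intensity scales. At fixed
weights, $\lambda$ has the closed-form weighted-least-squares optimum
$\lambda = \sum_j \varepsilon_j^{-2} m_j \bar I_j \,/\,
\sum_j \varepsilon_j^{-2} \bar I_j^2$ with
$\bar I_j = \sum_i w_i I_{ij}$, and the code profiles it analytically
wherever it appears. NMR chemical shifts enter as a second Gaussian
block with the prediction uncertainty and the experimental error summed
in quadrature, $\varepsilon_{CS}^2 + \varepsilon_{pre}^2$; shifts live
on an absolute ppm scale, so no scale factor is applied there. The two
likelihoods multiply.

The prior over weights is a Dirichlet. Two variants are supported: the
non-informative Jeffreys prior (all concentrations 1/2), and the
energy-biased prior with Boltzmann-factor concentrations
$\beta_i = e^{-(U_{ref}+U_i)/kT}$ built from per-conformer structural
energies. The mean of the energy prior equals the Boltzmann populations
for any $U_{ref}$; $U_{ref}$ only sets the total concentration
$\beta_0$, i.e. how sharply the prior insists on those populations. It
carries a uniform hyperprior and is co-optimized (selection stage) or
sampled (MCMC stage), so the data decide how much weight the energies
deserve.

A note on $kT$: structural energies from empirical force fields are on
an arbitrary scale, and the function default `kT = 1` treats them
literally. For score-function energies spanning tens of units (the
benchmark quintet spans 16), `kT = 1` collapses the Boltzmann
populations onto the single lowest-energy conformer; an effective
thermal scale of order 10–15 energy units yields moderately informative
populations, which is the regime in which an energy prior carries
information about a whole ensemble rather than one member. The energy
benchmark presets therefore carry `kT = 15`.

## Stage 1: variational model selection

The posterior over weights is approximated by a Dirichlet with free
concentrations $\alpha$. Maximizing the evidence lower bound (ELBO) is
equivalent to minimizing a closed-form objective $L(\alpha)$ consisting
of: the KL-type divergence from the approximation to the prior
(log-gamma and digamma terms, zero when $\alpha$ equals the prior); the
data misfit at the Dirichlet-mean weights $w_i=\alpha_i/\alpha_0$ with
$\lambda$ profiled; and a covariance correction
$\tfrac{1}{2}\lambda^2\sum_{il} G_{il}\,\mathrm{Cov}(w_i,w_l)$ with
$G$ the error-weighted profile Gram matrix, which charges the
approximation for its remaining uncertainty. Together the misfit and
covariance terms are the exact Dirichlet expectation of the quadratic
misfit at fixed scale — a property the test suite verifies against
brute-force Monte Carlo. The Gaussian normalization constants are kept,
so $-L$ is a true lower bound on the log evidence (Jensen's
inequality), also verified against Monte-Carlo integration. Chemical
shifts contribute analogous misfit and covariance terms with combined
variances; their exact form follows the SAXS structure, a
derivation-by-analogy validated by the same expectation oracle.

$L$ is minimized by simulated annealing over $\log\alpha$ (single
coordinate Gaussian proposals, geometric cooling), followed by a
quasi-Newton polish (BFGS with the analytic gradient) that sharpens the
point estimate; the annealer finds the basin, the polish the point.
Annealing temperatures are set from the locally probed objective
variability — the median $|\Delta L|$ of proposal-sized steps around the
start — rather than from $|L|$ itself, whose large constant terms say
nothing about the move scale. The first iteration starts at the prior
($\alpha_i = 1/2$, or $\beta_i$); later iterations warm-start from the
previous optimum, which matches the smooth weight trajectories this
kind of selection shows across iterations.

Selection then iterates: optimize, read off weights, cull members with
$w_i < w_{cut}$ (default 0.01; ties retained; at most half the set per
iteration, which guards against premature pruning), and stop when $L$
has not improved for `patience` (default 10) iterations. Two details
matter in the flat-likelihood regime. First, when every refined weight
sits above the cut but $L$ has stalled, the raw annealed weights are
consulted — near-redundant members fluctuate below the cut there, which
is how an annealing-only implementation prunes naturally. Second, if
that also yields nothing, the weakest member is removed on trial; the
stopping rule arbitrates, and because the best state ever seen is what
is returned, a detrimental trial cull can never corrupt the result.
Without an energy prior the whole pass restarts from the surviving set
until no further improvement; with one, a single pass converges.

## Exact evidence and Bayes factors

For small libraries the evidence $\int f(m|w)f(w)\,dw$ is integrated
directly: the likelihood is averaged over draws from the prior
Dirichlet, with $\lambda$ profiled per draw, stabilized log-mean-exp
accumulation, and a batch-jackknife standard error. Because the
likelihood reduces to quadratic forms in the Gram matrix, the per-draw
cost is independent of the number of data points. Within an exhaustive
size scan the best subset of each size is re-estimated on fresh draws:
the within-size maximum of noisy estimates is biased upward, and more
so for sizes with more subsets. This estimator is reliable when the
posterior is not dramatically tighter than the prior; for very
informative data its log-mean-exp is biased downward — the classic
failure mode of prior sampling — which is why the evidence benchmarks
run at moderate information content and report standard errors.

## Stage 2: complete Bayesian inference

On the selected subset (typically 3–10 members), the weights, the scale
factor and, with an energy prior, $U_{ref}$ are sampled by MCMC.
Weights are parameterized by a multinomial-logit (softmax) transform
with the last coordinate pinned and log-Jacobian $\sum_i \log w_i$;
$\lambda$ is sampled on the log scale under a broad half-normal prior
scaled to five times its analytic point estimate; $U_{ref}$ is uniform
on its configured interval. The sampler is a mixture kernel: (a)
random-walk Metropolis with per-coordinate scales adapted to the
posterior spread during warmup (first half of each chain, per the usual
convention), efficient once the posterior is concentrated; and (b)
independence proposals of the whole weight block drawn from the prior
Dirichlet, whose Hastings ratio reduces to the likelihood ratio and
which therefore mix essentially perfectly when the data constrain the
weights weakly. The contract is the posterior, not the algorithm: the
suite checks the sampler against exact limits on both ends —
prior-dominated (posterior means must match the Dirichlet/Boltzmann
means within Monte-Carlo error) and data-dominated (means must match
the variational point estimates within 0.05). Convergence is monitored
with split-$\hat R$ and an autocorrelation-based effective sample size
per parameter; any weight with split-$\hat R$ > 1.05 triggers a
warning. Defaults are 2000 iterations and 4 chains.

Ensemble uncertainty is summarized by the expected base-2
Jensen–Shannon divergence between posterior draws and a reference
weight vector, a number in [0, 1] with 0 meaning a delta posterior.
Which reference — the posterior mean or the variational point estimate —
is a genuine ambiguity; the default is the posterior mean and the
pipeline reports both. Posterior predictive checks resimulate noisy
curves from posterior draws and report the central 95% envelope and its
empirical coverage of the data.

## Goodness of fit

Reduced $\chi^2$ (with a configurable degrees-of-freedom convention,
default ensemble size − 1 weights + 1 scale; both raw and reduced are
reported since conventions differ), error-weighted residual plots, and
a correlation-map test: the longest run of same-sign residuals, with
the probability of a run at least that long among $N$ fair coin flips
computed exactly by dynamic programming over run-length-bounded sign
sequences (compositions with bounded parts, accumulated on the
probability scale). The exact computation replaces the usual asymptotic
approximation — identical intent, no approximation error at the small
and moderate $N$ of scattering curves; the suite checks it against
exhaustive enumeration up to $N = 16$. Zero residuals break runs.

## The synthetic benchmark generator

Every stage is testable without downloads through a generator that
emulates a two-domain protein benchmark. Each conformer is a coarse
multi-sphere body — two core domains (radii ~14–18 and ~10–14 Å) at a
linker-controlled separation (15–65 Å) plus a few satellite spheres for
loops and termini — evaluated with the Debye formula, normalized to
I(0) = 1, with the analytic radius of gyration recorded. On top of this
envelope each conformer carries private fine structure: a random-phase
sum of cosine components over the molecule's internal distance range
(5–120 Å), suppressed below q ≈ 0.15 so the Guinier region is untouched,
reaching a relative amplitude of 6% at wide angles. This layer stands in
for the all-atom pair-distance detail that distinguishes real conformers
of similar overall shape; without it a coarse-grained library is so
mutually redundant (effective rank far below the member count) that no
method could single out individual members, and the recovery benchmark
would be meaningless. The default grid (600 points to 0.9 1/Å) reaches
into the wide-angle region where that detail lives, as profile
calculators do.

Synthetic noise follows the standard counting-statistics recipe: errors
proportional to the intensity with relative error growing linearly in
q, $\varepsilon_{ref}(q) = c\,I(q)(q+q_{off})$, calibrated to a stated
mean signal-to-noise (default 50 at the reference level). The noise
ladder multiplies this template by `sigma_scale`, so "noise level 3"
means three times the reference errors. Ground truth (members, weights,
seeds, the error template) is returned with every data set, and the
noise-free limit returns the exact weighted average.

The named presets pin the benchmark conditions: `recovery100`
(100-member library, 5-member truth with weights 0.1/0.15/0.2/0.25/0.3,
reference noise), `lownoise100` (the same at `sigma_scale = 0.01`),
`energy100` (equal truth weights 0.2 and the energy quintet −135.2,
−140.0, −126.7, −125.5, −124.0 on the truth members, `kT = 15`),
`refined101` (adds a 101st conformer at −178.9 duplicating the
lowest-energy member's profile, for checking that a single deep-energy
structure does not hijack the prior), and `evidence10` (10 members,
3-member truth with weights 0.2/0.3/0.5, an experimental-length
150-point grid to 0.35 1/Å, mean signal-to-noise 200, and no fine
structure — ten conformers of one protein on a short grid are mutually
correlated, and that correlation is what lets the evidence's complexity
penalty separate ensemble sizes cleanly).

What passing these benchmarks does and does not show: the generator
reproduces the statistical structure of the inference problem —
ensemble-averaged smooth curves, realistic signal-to-noise anisotropy,
member distinguishability, energy-population coupling — but not
atomistic realism. Real libraries have conformers with genuinely
near-identical profiles, where the identity (though not the quality) of
the selected ensemble becomes non-unique; real data have correlated
errors and background-subtraction artifacts that the Gaussian
independent-error model does not capture (the posterior predictive
check is the tool that exposes such mismatches).

## Problem sizes and numerical choices

The shipped benchmarks use a 100-member library with 600-point curves
for recovery experiments, a 10-member library with 150-point curves for
exhaustive evidence scans (375 subsets at 1e5 prior draws each), 5
replicate seeds for majority statistics, and MCMC runs of 2000–6000
iterations over 4 chains; on one CPU the full suite runs in roughly a
quarter of an hour. Degenerate inputs are handled explicitly: duplicate
profiles are permitted (likelihoods remain well-defined, selection
resolves ties); an all-culled selection returns the best single member
with a warning rather than an empty ensemble; a vanishing ensemble
average is a degenerate-profile error; zero experimental CS errors are
accepted (the prediction uncertainty then carries the variance) but a
zero combined variance is an error. Members exactly at `w_cut` are
retained. All randomness flows through explicit seeds; no global state
is consumed silently.

## Known limitations

Evidence by prior sampling degrades for very informative data (use the
reported standard error); the variational stage's greedy pruning can in
principle lock in a suboptimal subset when many members are
near-collinear — the stochastic and trial culling channels plus
restarts mitigate but cannot eliminate this, which mirrors the known
premature-pruning caveat of this algorithm family; and the random-walk
stage of the sampler, while adequate for the post-selection subsets it
is meant for, is not a gradient-based sampler and will be slow beyond a
few tens of members.
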