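---
title: "Estimating stabilizing CNDD in tree mortality: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating stabilizing CNDD in tree mortality: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cnddtools)
```

## What is being estimated

Conspecific negative density dependence (CNDD) is the reduction in a tree's
performance caused by nearby members of its own species. Only the part of
this effect that *exceeds* the effect of neighbours in general (heterospecific
density dependence, HNDD) stabilizes species' abundances, so the estimand
here is **stabilizing CNDD**: the effect of conspecific density on sapling
mortality *adjusted for total neighbour density* in a multiple regression,
equivalent to CNDD − HNDD. The package quantifies it as the change in annual
mortality probability when one conspecific neighbour (DBH 2 cm, 1 m away) is
added while total density stays fixed — on the probability scale, so that
species and sites with different baseline mortality remain comparable.

## The model stack and its assumptions

**Neighborhood densities.** `conD` and `totD` are kernel-weighted sums of
neighbour basal area (cm², or counts for the `N` estimator) within a 30 m
radius, taken at the census that opens the interval. Two kernel families are
supported, exponential `exp(-d/mu)` and exponential-normal `exp(-d^2/mu^2)`;
`mu` is selected by a grid search (1–25 m in 2 m steps, jointly over all
species, separately for `conD` and `totD`, by summed model log likelihood
over the species that converge in every cell). Assumptions: neighbour
effects are isotropic, additive in (weighted) basal area, and only live
trees at the interval's start exert them. Focal trees within 30 m of a plot
edge are excluded from modelling (their neighborhoods are truncated) but
still act as neighbours.

**Mortality models.** Status over an interval is binomial with a
complementary log-log link, so the offset `log(dt)` makes the model a
constant-hazard discrete-time survival model that handles unequal census
intervals: halving the interval exactly halves the fitted hazard.
Flexibility in `conD`, `totD` and DBH comes from penalized thin-plate
smooths (`k = 10`; `k = nvals - 2` when a predictor has fewer than 10 unique
values, a linear term below 5), with REML smoothness selection; a census
random intercept absorbs interval-level mortality shocks when more than one
interval is observed. The smooth basis is not byte-identical to any
particular legacy software; equivalence is enforced at the level of the
marginal effects against closed-form oracles on linear-truth data.

**Eligibility and pooling.** A species-site gets its own model with ≥ 20
alive and ≥ 20 dead observations, ≥ 4 unique `conD` values, and a `conD`
range at least as wide as the perturbation (so the counterfactual never
extrapolates by more than one perturbation). All other species are pooled
into rare-tree and rare-shrub group models (growth form: a species is a
tree if the mean DBH of its six largest individuals exceeds 10 cm in some
census — all individuals if fewer than six, a choice the source rules leave
open). Each rare group enters the meta-analysis as *one* record per site,
with abundance equal to the mean of its members' abundances. Member-level
effects (group coefficients + a member's own covariates) are available via
`estimate_cndd(pooled_level = "member")` but are not the default: pooling
eligibility conditions on realized death counts, and near the threshold
this selects chance-low-mortality species into the pool; replicating that
selection bias once per group with a large sampling variance is harmless,
replicating it once per member species is not (we measured roughly a
−0.05 shift on the log(rAME+1) scale for member-level pooled records on
synthetic data with truth +0.048).

**Marginal effects.** For each observation, the fitted annual probabilities
at the observed covariates and at `conD + delta` give `aME` and `rME`
(`delta` = kernel weight at 1 m × basal area of a 2 cm stem ≈ 2.2514 cm²
under the default kernel); species-level `aAME`/`rAME` are their unweighted
means over all observations and censuses. Variants: *equilibrium* (observed
`conD`), *invasion* (`conD = 0`), *interquantile* (Q1 → Q3 of the species'
observed `conD`; not comparable across species and used only for a global
average). Uncertainty is simulation-based: 500 coefficient vectors from the
multivariate normal with the fit's unconditional covariance (including
smoothing-parameter uncertainty where available); the sampling variance is
the variance of `log(rAME + 1)` across draws, the two-sided p-value is
`2 * min(share ≤ 0, share ≥ 0)` floored at `2/n_draws`. The census random
effect is set to its population mean for all predictions — a divergence
risk, as the original procedure does not state its convention.

## Meta-regression

Records `y = log(rAME + 1)` with sampling variances `v` enter
`y_lm = b0 + f(predictors) + r_l + s_lm + e_lm`, with site and
species-in-site random intercepts and `e_lm ~ N(0, v_lm)` known. Because
each record is one species-site, the species effect contributes one latent
variance per record, and the covariance is block-compound-symmetric by
site; the REML criterion is evaluated with a per-site Woodbury identity and
profiled over `(sigma_r^2, sigma_s^2)` on the log scale by bounded
quasi-Newton (three starts, Nelder-Mead polish, tolerance ~1e-8); a dense
brute-force path of the same criterion exists purely as a test oracle.
Covariates are centred at 11.75° absolute latitude and 1 tree/ha so main
effects describe rare tropical species; inference at another point is
obtained by recentring and refitting (the fitted surface is invariant).
Predictions back-transform as `100 * (exp(lp) - 1)` percent.

Fixed-effect tests use a Student-t reference with `df = n - p` rather than
the normal: at production scale (thousands of records) the two coincide,
but desk-scale suites fit meta-regressions to as few as 6 records, where
normal-reference Wald intervals measurably undercover. This is the one
deliberate deviation from the "plain Wald z" convention of standard
meta-regression software.

Per-site summaries use intercept-only species-random-intercept fits: the
intercept is the site mean, the species variance component the latent
interspecific s.d.; their ratio is the CV of CNDD, computed only for sites
with positive mean CNDD (positive density dependence is destabilizing
regardless of interspecific variation) and compared with the
stable-coexistence threshold CV > 0.4 from simulation studies. Sites with
fewer than two estimates are skipped.

## The synthetic world

The generator exists so that every stage can be validated against known
truth without restricted census data. One site = a log-series community
(`n_species`, Fisher's alpha; expected size `alpha * (exp(S/alpha) - 1)`),
per-species Thomas cluster processes (Poisson parents at 2/ha, Gaussian
offspring, sd 10 m; out-of-bounds offspring are resampled, no toroidal
wrap), truncated-lognormal DBH (median 2.5 cm, sdlog 0.6, 1–80 cm). Deaths
follow a cloglog model *linear* in `conD`, `totD` and DBH — linear truth so
that the smooth fits must recover a known closed form (`true_rAME()`), a
stronger test than self-consistent smooth truth. Defaults: annual baseline
mortality 0.02, total-density coefficient 1e-4 per cm², DBH coefficient
−0.05 per cm, deterministic growth 0.15 cm/yr, censuses 5 years apart, two
censuses, 9 ha plots (~20,000 stems). Species' conspecific coefficients are
derived from target relative effects as `beta_con = log(1 + rAME)/delta`
(exact in the small-probability limit; the stored truth is always the exact
`true_rAME()` average, not the target). A scenario adds a latitude trend,
an interspecific s.d., and a target correlation between log abundance and
the conspecific coefficient. Seeds split hierarchically
(ensemble → site → census) so adding sites never perturbs earlier ones.

What the generator does *not* emulate: recruitment (off by default, so
communities shrink), habitat heterogeneity, spatially correlated mortality
agents, multi-stem individuals, measurement error in DBH or coordinates,
and interval-censored status codes. A green recovery test therefore
establishes calibration of the estimator chain under a correctly specified
world, not robustness to those field realities — the robustness module's
randomizations and screens address parts of that gap.

## Numerical choices and degenerate inputs

- Mortality-model convergence = optimizer success, finite coefficients and
  covariance; failures are flagged (and re-routed to pooling), not raised.
- Relative effects are undefined below a 1e-12 baseline-probability floor;
  such observations are excluded with a count, and an estimate is flagged
  unstable (and excluded from meta-regression) when > 10% of draws contain
  an undefined relative effect.
- Q1/Q3 are type-7 empirical quantiles.
- A non-positive-semidefinite draw covariance is repaired by clamping
  negative eigenvalues to zero, with a warning.
- Variance components below 1e-12 are reported as exactly zero.
- Cook's distances hold variance components at full-data estimates
  (leave-one-out GLS); the brute-force refit oracle is used on toys.
- The grid search's "distinct optimum" for per-species decay-range audits
  means a strict interior argmax whose log likelihood exceeds both grid
  ends by ≥ 2 units.
- Interval length uses per-tree measurement dates when present, census-level
  dates otherwise; non-positive intervals are dropped with a warning.
- "Missing" status at follow-up censors the observation (dropped), and a
  tree recorded dead but later alive is corrected to alive throughout.

## Desk-scale testing policy

Acceptance simulations run at documented reduced scale — fewer replicates
(10 instead of 20 for recovery and null calibration, 5 for kernel recovery)
and, where stated, smaller communities — with unchanged pass thresholds.
The kernel-recovery scenario deliberately concentrates signal (stronger
CNDD, mean rAME 0.15; total-density coefficient 3e-4) because family
discrimination that a 23-site, 2,500-species analysis achieves jointly must
here come from a single synthetic site. One spec-level expectation was
corrected during development: the score-equation invariant "sum of fitted
probabilities equals the number of deaths" holds for canonical links only;
for the cloglog link the tests verify the actual intercept score equation
(zero derivative of the unpenalized log likelihood along the intercept).

## Known limitations

- The random-intercept convention for predictions (population mean) may
  differ from the original software's behaviour.
- Group-level pooling inherits the eligibility selection bias described
  above, attenuated but not removed.
- The meta-regression assumes normal sampling errors of `log(rAME + 1)`
  with *known* variances; with 500 draws those variances are themselves
  estimates, and very uncertain species can carry understated `v`.
- The spatial screen is a Moran's-I permutation stand-in calibrated on
  null data, not a re-implementation of any specific residual-diagnostic
  suite; the demographic trade-off axes are principal-component
  approximations of the published construction, with sapling influx as a
  recruitment proxy.
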