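---
title: "Predicting evolutionary responses to selection on female extra-pair reproduction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting evolutionary responses to selection on female extra-pair reproduction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Whether extra-pair reproduction (EPR) by socially monogamous females is
under selection, and whether it will evolve, cannot be answered from
phenotypic associations alone: covariances between a female's EPR and her
fitness components can be environmental rather than genetic, and selection
may act through individuals that die before the trait is expressed.  The
secondary theorem of selection sidesteps both problems: the predicted
per-generation change in mean breeding value of a trait z equals its
additive genetic covariance with relative fitness,

    delta A_z = cov_A(w, z).

`eprqg` implements the full quantitative-genetic pathway for this
prediction in a wild passerine system: pedigree algebra, Bayesian animal
models for mixed Gaussian / threshold traits, posterior summaries,
selection-response post-processing, and a synthetic island-population
generator so that every stage is testable without access to restricted
field data.

## Traits and codings

Three traits are analysed, in the codings produced by
`build_trait_table()`:

* **EPR_L** — a female's liability to produce an extra-pair rather than a
  within-pair offspring.  Binomial threshold trait on a logit scale, with
  the yearly extra-pair offspring count as numerator and the yearly number
  of ringed offspring (ARS) as denominator.  Female-years with ARS = 0
  carry no information about the extra-pair/within-pair split and
  contribute no EPR_L record.
* **ARS_w** — relative annual reproductive success: ringed offspring per
  female-year divided by the across-year population mean (so the mean is
  exactly 1).  Gaussian; emitted for *all* female-years including
  failures.
* **SR_wB / SR_wG** — survival to recruitment at age 1, either as a binary
  threshold trait (for interpretable statistical confidence) or as
  relative fitness on the observed scale, 0 or 1/mean(recruitment)
  (for a quantitatively interpretable evolutionary prediction).

Relative fitness is computed against across-year means by default;
year-specific means are available via `relative_fitness(mode =
"year-specific")`.  The reference set excludes immigrant females, whose
inbreeding coefficient is undefined; the across-year mean is computed
after that exclusion.

## Pedigree algebra

`pedigree()` validates and canonically sorts records (generation depth,
then id), accepting `NA`, `0` and empty-string encodings of unknown
parents.  `additive_relationship()` implements the tabular method with
inbreeding, so `diag(A) = 1 + f` and `A = 2K`; `ainverse()` builds the
inverse directly from Henderson's rules with the inbreeding-adjusted
Mendelian-sampling variances; `prune_pedigree()` restricts to phenotyped
individuals and their ancestors without changing any retained
relationship.  Individuals with one known parent are treated as having an
unrelated, non-inbred unknown parent; immigrants are founders with
kinship zero to all natives, so offspring of immigrant-native pairs have
f = 0.  All matrices are dense: the target scale (hundreds to a few
thousand individuals) makes exactness cheap.

A deliberately simple corollary of unmodelled paternity is exposed as
`expected_link_correctness(e)` = (1 + (1 − e))/2: with maternal links
always correct and paternal links wrong with probability equal to the
extra-pair rate e, about 86% of social-pedigree links are correct at
e = 0.29.

## The animal model and its sampler

`fit_animal_model()` fits univariate and bivariate animal models by a
Gibbs sampler on the latent-Gaussian representation.  Every record
carries a value on the model scale: the observed response for Gaussian
traits, a latent logit liability for binomial/binary traits, an imputed
draw for missing responses.  Conditional on those values the model is a
Gaussian mixed model

    l = X b + Z_a a + Z_y u_y + Z_pi u_pi + e,

with a ~ N(0, G_A ⊗ A), year effects keyed on calendar year (breeding
year for EPR_L/ARS_w, natal year for SR, shared across traits of a
bivariate model so year covariances are estimable), permanent-individual
effects for repeated female-year traits, and residuals correlated across
traits within an observational unit (the female-year for EPR_L/ARS_w;
the offspring for SR).

Sampler updates per iteration:

1. **Location effects** (fixed effects and all random effects) jointly
   from their multivariate normal full conditional via the dense
   mixed-model equations, using the exact A-inverse.  Fixed effects have
   N(0, 1e8) priors.
2. **Free (co)variance blocks** from conditional inverse-Wisharts (scale
   `nu V + S`, degrees of freedom `nu + n`).  Constraint masks support
   fully free blocks, diagonal blocks (covariances fixed at 0) and fully
   fixed blocks — the three patterns the models require.  Fixed elements
   (the binary-trait residual variance of 1, structural zero residual
   covariances) are never updated.
3. **Latent liabilities** by per-record random-walk Metropolis-Hastings
   against the binomial/Bernoulli likelihood and the conditional normal
   prior implied by the residual structure, with proposal scales adapted
   to roughly 20-50% acceptance during burn-in.  Missing responses are
   drawn directly from their conditional normal (imputation inside the
   sampler, never row deletion), so ARS = 0 female-years stay informative
   for ARS_w while uninformative for EPR_L.
4. **Joint scale moves**: a Metropolis step that rescales one
   component-trait's effect vector and the corresponding (co)variance
   row/column together (`eff' = s·eff`, `G'_tt = s²G_tt`).  The Gaussian
   effect-prior normalisation cancels against the Jacobian, leaving the
   likelihood change, `−nu log s`, and the inverse-Wishart trace term, so
   the move targets the exact posterior under the exact prior.  It breaks
   the strong autocorrelation between variance components and their
   effect vectors that otherwise dominates thinned-chain autocorrelation.

Imputed cells are created only where a missing response is coupled to an
observed one through a *free* residual covariance.  Where the residual
covariance is structurally zero (between EPR_L and recruitment, whose
records never share an observational unit; or with any binary trait), the
likelihood factorises and imputing cells at foreign units would add
latent noise without information, so none are created.

Binomial (multi-trial) liability traits carry an estimated per-record
overdispersion residual on the liability scale; binary traits have their
residual variance fixed to 1 by convention and never declare
permanent-individual effects (not identifiable from single records).

### Priors, chain lengths, reproducibility

Default priors are inverse-Wishart with limit variance 1 and degree of
belief nu = 0.002 per free block (scale matrix `nu V`, df `nu`), prior
covariances zero — only weakly informative.  `prior_spec()` allows
per-component overrides, e.g. for prior-sensitivity runs.

`mcmc_config()` requires an explicit seed; identical data, priors,
configuration and seed give bit-identical draws.  The `"desk"` preset
(55,000 iterations, burn-in 5,000, thin 50 → 1,000 draws) keeps a fit of
a few hundred individuals at a few minutes on one core and achieves
lag-1 autocorrelation of thinned variance chains well under 0.05; the
`"paper"` preset (3,005,000 / 5,000 / 3,000) reproduces full-length
chains where compute time does not matter.

### Summaries

`summarize_posterior()` reports posterior means, equal-tailed 95%
credible intervals (HPD intervals are deliberately not the default: the
equal-tailed quantiles are the simplest reproducible reading of a
credible interval), kernel-density modes (with reflection at zero for
variance parameters, so boundary mass is not smeared negative), lag-1
autocorrelation of the thinned chain, and a density-near-zero diagnostic
for variances: the ratio of posterior density at zero to density at the
mode, flagged when it exceeds 0.5.  Variances are bounded below by zero,
so credible intervals alone cannot show whether a variance differs from
zero; the mode and the density ratio carry that information, and
null-trait simulations (V_A = 0) provide the calibration check.

`heritability()` computes per-draw ratios h² = V_A/(V_A + V_PI + V_Y +
V_R), adding the logistic link variance π²/3 to the denominator for
logit-family traits and omitting absent components; the posterior
summary is the mean of per-draw ratios, which is not the plug-in ratio
of posterior means.

## Selection responses

`secondary_theorem()` is, by construction, the identity on the additive
covariance chain: its summaries equal the model's own summaries of
cov_A(w, z).  `sum_components()` adds predictions over fitness
components; per-draw sums (with credible intervals) are only formed when
the covariances come from a single model's chain — across separate
bivariate fits the means are summed and the interval is reported as
unavailable, because draws from independent chains cannot be aligned.

`backtransform(delta, p0)` maps a liability-scale change to the observed
scale as `plogis(qlogis(p0) + delta) − p0`; it is strictly increasing and
bounded in (−p0, 1 − p0).  The baseline is a required argument (the
observed mean extra-pair proportion, 0.29 in the motivating system) and
no attenuation correction for liability-scale variance is applied.  Note
a documented discrepancy: applying this transformation to a summed
liability response of 0.18 at baseline 0.29 gives ≈ 0.038, while the
motivating analysis reports ≈ 0.03 for the combined prediction; the
exact procedure behind that printed value cannot be reconstructed, and
the package does not attempt to match it.

`selection_differential()` estimates the phenotypic covariance cov_P
between extra-pair liability and a Gaussian fitness component as the
residual covariance of a bivariate mixed model with year random effects
and fixed age and inbreeding effects but *no* additive genetic term,
restricted to female-years where both traits are observed.
`breeders_equation(h2, S)` completes the comparison R = h²S.

## The synthetic island population

`simulate_population()` emulates the kind of small, intensively monitored
island population the method was developed for: overlapping generations,
yearly random social pairing, extra-pair paternity through a maternal
logit liability, annual reproductive success as a latent Gaussian on the
relative scale rounded to a non-negative count (a Poisson-free choice
reflecting the only slightly skewed ARS distributions of such systems),
binary recruitment, inbreeding depression on all three traits, and
unrelated immigrants (Poisson, 1.1/year).  Kinship is tracked exactly
among potential parents, so offspring inbreeding coefficients equal the
pedigree-derived values and Mendelian-sampling deviations have variance
`0.5 G_A (1 − (f_dam + f_sire)/2)` (verified by `mendelian_check()`).

Default generating values are the study conditions: mean ARS 4.7,
extra-pair offspring proportion 0.29, recruitment 0.195, and 3×3 G
matrices assembled from the posterior means of the motivating bivariate
analyses (V_A = 1.198/0.016/0.405 for EPR_L/ARS_w/SR liability, cov_A =
0.087/0.160/0.025, year, permanent-individual and residual blocks
likewise; inbreeding-depression slopes −0.17/−1.07/−8.04).  Values the
motivating study does not state were chosen once on biological grounds:
adult survival 0.6 per year and a carrying capacity of 45 breeding pairs
(the upper end of the island system's observed 15-45 pairs) make the
default population roughly stationary; 20 founder pairs and 10 years
give analysis-sized data; `calibration_f = 0.05` approximates the
long-run mean inbreeding coefficient.

Two calibration mechanisms deserve explanation:

* **Intercept calibration.**  The EPR and recruitment intercepts are
  found by a one-dimensional root find so that `E[plogis(mu + offset +
  sigma Z)]` equals the target rate given the total liability variance —
  the configuration expresses rates on the observed scale, the model
  lives on the liability scale.
* **Stabilising regulation.**  Fitness components are heritable and under
  selection inside the simulation, so without compensation their means —
  and through the positive genetic covariances, the extra-pair rate —
  would evolve directionally across generations and leave the configured
  rates within a few generations.  The per-year intercepts therefore
  track the mean genetic, permanent-individual and inbreeding load of
  the current breeder pool (and, for recruitment, of the realised
  cohort).  This is a year-level re-centring only: within-year variation,
  all individual-level (co)variances and the year effects themselves are
  untouched, so animal-model estimation on generator output is
  unaffected, while marginal rates stay at their configured targets as a
  stationary wild population's would under density-dependent
  regulation.

`simulate_traits()` is the controlled counterpart for calibration
studies: given a fixed pedigree and generating (co)variance matrices it
draws breeding values down the pedigree and emits records for any trait
family, with no demography in the way.  Parameter-recovery suites fit
models to its output and count how often generating values fall inside
95% credible intervals.

The recovery design deserves its own notes, because interval calibration
at desk scale is only meaningful when the experiment can actually
resolve the parameters:

* **Repeated records.**  With a single record per individual the
  additive and residual (co)variances of a bivariate model are barely
  separable at a few hundred individuals: the posterior sits on a
  cov_A/cov_R ridge and can legitimately place the generating value
  outside its marginal interval.  Three records per individual — echoing
  the repeated female-year measurements of the motivating design —
  restores identification.
* **Many year levels.**  With few year levels the posterior tracks the
  realised variance of those few effects, which wanders far from the
  generating hypervariance; the suites use 15 levels (25 for the binary
  family, whose records carry the least information).
* **Founder-rich pedigrees.**  Immigration keeps the base population —
  the entity whose variance the animal model estimates — well sampled.
* **HPD intervals.**  Variance posteriors are bounded at zero and
  right-skewed; equal-tailed quantile intervals are poorly calibrated
  there, so the recovery suites use highest-posterior-density intervals
  (`summarize_posterior(interval = "hpd")`).
* **A weakly-informative additive prior for binary traits.**  A binary
  trait leaves its liability-scale additive variance so weakly
  identified that the default near-scale-invariant prior piles posterior
  mass on the zero boundary; the binary fits use the standard
  weakly-informative choice of a limit variance of order half the
  liability variance with one degree of belief.
* **Replicate seeds from one master seed.**  Consecutive integer seeds
  with identical consumption patterns produce noticeably correlated
  streams in R's Mersenne-Twister (an empirical observation reproduced
  with plain `rnorm()`); replicate seeds are therefore drawn with
  `sample.int()` from a single master seed.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: paternity-assignment error and its pedigree
consequences (only the expected-link-correctness formula addresses it),
mate fidelity and non-random pairing, spatial structure, observation
error in ARS or recruitment, age-dependent survival, and any
environment-driven trend in rates.  Recovery of generating values from
synthetic data demonstrates the estimator is consistent with its own
model family, not that the model family is right for any particular
field system.

## Numerical choices and problem sizes

Dense linear algebra throughout (pedigrees to ~2,000 individuals);
mixed-model equations refactorised by Cholesky each iteration; latent
updates vectorised per residual-pattern group.  Chains in the test suite
are scaled to the information in the data: unit tests use hundreds of
iterations (structure, determinism, constraints), calibration suites use
a ~260-individual pedigree with 1,200-iteration chains (2,400 for the
latent-liability families) across 20 replicates per trait family, the
chain-quality check uses the full desk preset on a ~350-individual
pedigree, and the large-sample generator check uses a ~45-year
population with >5,000 offspring.  Degenerate
inputs fail fast with informative errors: duplicate ids, pedigree
cycles, phenotyped individuals missing from the pedigree, epo > ars,
zero relative-fitness reference means, burn-in ≥ iterations, non-PSD
generating matrices, extinction of the simulated population.

## Known limitations

* At most two traits per model; the full trivariate model is out of
  scope (its residual structure cannot be specified correctly in this
  model family, which is also why the motivating analysis used pairwise
  bivariate fits).
* Constraint masks cover free / diagonal / fixed patterns only; a fixed
  non-zero covariance with free variances is rejected.
* The breeder pool's kinship matrix is dense, so extremely long
  simulations (tens of thousands of recruits) are memory-bound.
* Liability-scale covariances involving SR_wB have, as in the motivating
  study, no direct quantitative interpretation as observed-scale change;
  the Gaussian coding SR_wG exists for that purpose.
* Nonlinear (stabilising/disruptive) selection responses,
  cov_A(w, (z − mean)²), are not estimable for liabilities and are not
  implemented.
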