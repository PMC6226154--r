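---
title: "Spatial zero-inflated count models for disease mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial zero-inflated count models for disease mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`zimap` fits Bayesian zero-inflated count models with district-level random
intercepts and conditional autoregressive (CAR) spatial structure, for
mapping rare-event rates — facility-based maternal mortality being the
motivating application — on areal data. This vignette documents the model,
the priors and their interpretation, the sampler, the synthetic-data
generator, and the design decisions taken where reasonable alternatives
existed.

```{r setup}
library(zimap)
```

## The model family

Counts `y_ij` (facility *j* in district *i*) with exposure `N_ij` follow a
zero-inflated mixture: with probability `pi_ij` the observation is a
structural zero; otherwise it is Poisson or negative binomial with mean
`nu_ij = N_ij * lambda_ij`. The negative binomial arises by Poisson–Gamma
mixing with `u ~ Gamma(r, r)`, giving the closed-form marginal with
dispersion `phi = 1/r` and variance `nu (1 + phi nu)`; the sampler uses this
marginal directly rather than sampling per-observation mixing latents (the
two parameterisations have the same likelihood, which the test suite checks
against numerical quadrature of the mixture integral). `phi -> 0` recovers
the Poisson.

Canonical links connect both components to covariates and district effects:

* `logit(pi_ij) = z_ij' alpha + vartheta_i + u_1i`
* `log(nu_ij) = x_ij' beta + log(N_ij) + theta_i + u_2i`

Three non-spatial intercept structures are supported — `independent`,
`correlated` (bivariate normal with correlation `rho` between the propensity
for structural zeros and the count level), and `shared`
(`vartheta_i = zeta * theta_i`) — and three spatial structures: intrinsic
CAR (`icar`, count component), proper CAR (`proper`, count component, with
autocorrelation `psi`), and the bivariate intrinsic CAR (`bicar`) that puts
one field in each component with a 2x2 conditional cross-covariance
`Sigma_u`; its off-diagonal carries the spatial association between the two
model components. Plain `poisson` and `nb` families (no zero component) are
included as baselines.

Assumptions worth stating: districts' non-spatial intercepts are
exchangeable; the spatial fields' dependence is fixed by the binary
adjacency structure (`omega_ii' = 1` for neighbours); within a district all
facilities share the same pair of intercepts (equal within-district
correlation regardless of facility size); and missing covariate values are
handled by complete-case analysis, which is unbiased only under
missing-completely-at-random.

## Priors

The default prior block (`prior_spec()`), in shape/rate convention:

| block                       | prior                                   |
|-----------------------------|-----------------------------------------|
| fixed effects (each comp.)  | `N(0, sigma2)`, `sigma^-2 ~ Gamma(1e-5, 1e-5)` shared within the component |
| district intercept prec.    | `Gamma(1e-3, 1e-3)` (univariate structures) |
| CAR field precisions        | `Gamma(5e-3, 5e-3)`                     |
| NB order parameter `r`      | `Gamma(1e-3, 1e-3)`, `phi = 1/r`        |
| shared-model `zeta`         | normal with precision `1e-4` (variance `1e4`) |
| bivariate precision matrices| `Wishart(I2, 2)`                        |
| proper-CAR `psi`            | uniform on its admissible interval      |

Two readings deserve comment.

**Scope of the fixed-effect hyperprior.** A `Gamma(eps, eps)` precision
hyperprior can be attached to each coefficient individually or shared by all
coefficients of a component. The per-coefficient version, marginalised,
is a scaled t kernel with `2 eps` degrees of freedom — effectively
`p(beta) ~ 1/|beta|` — a scale-invariant spike at zero with essentially
improper tails. Along weakly identified posterior directions this is
destructive in both directions: it shrinks poorly informed contrasts hard
toward zero, and it leaves near-flat ridges (for example the zero-component
intercept versus the outside-capital effect, whose sum is well identified
but whose difference is informed only by the handful of large
inside-capital facilities) essentially unbounded. The default is therefore
`coef_prec_scope = "shared"`: one precision hyperprior per component, so the
coefficient scale is learned jointly from all of that component's
coefficients, keeping the prior vague (the hyperprior is still
`Gamma(1e-5, 1e-5)`) while bounding the ridge. The per-coefficient reading
remains available (`coef_prec_scope = "per_coefficient"`, implemented by
collapsing the precision analytically into the coefficient update so the
sampler does not inherit the spike's notorious stickiness).

**`zeta`'s normal prior.** A "`N(0, 1e-4)`"-style specification is read in
the precision convention of the graphical-model software tradition this
model family comes from, i.e. variance `1e4`. The literal variance reading
would pin `zeta` at zero and make the shared structure vacuous.

The Wishart prior is placed on precision matrices with scale `I2` ("a prior
guess of the order of the covariance matrix"); sampled covariances are its
inverse. The proper-CAR `psi` is restricted to
`(1/lambda_min, 1/lambda_max)` of the eigenvalues of `D^-1/2 W D^-1/2`
(`psi_bounds()`), the exact condition for a positive-definite joint
precision.

## Sampler

`fit_zi()` runs Metropolis-within-Gibbs with the inner loop in C++:

* fixed effects and latent district effects move by per-parameter adaptive
  random walks (proposal scales tuned toward 0.44 acceptance during burn-in
  and frozen afterwards, so retained draws come from a fixed kernel);
* variance components are conjugate: Gamma updates for univariate
  precisions (the ICAR precision uses rank `n - 1` for a connected graph)
  and Wishart updates for the bivariate blocks (`df = 2 + n` for the
  intercepts, `2 + n - 1` for the bivariate ICAR);
* the proper-CAR `psi` moves by a bounded random walk whose acceptance uses
  the exact determinant term via the precomputed adjacency eigenvalues;
* the NB order parameter moves on the log scale with the Jacobian included.

Two classes of *ridge moves* supplement the componentwise updates, both
ordinary Metropolis proposals that leave the posterior unchanged: a joint
shift between an intercept and a dummy block whose reference cell is rare
(the facility-type block; the zero-component location dummy), and a
likelihood-invariant level swap between an intercept and the common level of
its district intercepts. Without them, componentwise samplers effectively
never traverse these directions; with them, the reported credible intervals
reflect the actual posterior geometry.

**Identifiability of intrinsic fields.** The ICAR prior is improper along
the constant direction, so after every sweep each intrinsic field is
re-centred to mean zero with the level transferred into the corresponding
component intercept. Because the shift moves along the prior's flat
direction and the likelihood depends only on the sum, this is a
likelihood-preserving reparameterisation rather than the uncompensated
re-centring some implementations use.

**Numerical choices.** Zero-inflation probabilities are clipped to
`[1e-12, 1 - 1e-12]` inside log computations only; the `y = 0` mixture mass
is evaluated by log-sum-exp; logistic terms clamp linear predictors at
`|eta| = 35`; NB terms use `lgamma` throughout. Initial values are fixed
effects at zero except the count intercept (crude log-rate), variance
components at 1, and latent effects at `N(0, 0.01)` jitter — components a
model does not use are initialised at exactly zero so they never leak into
the linear predictor. A non-finite initial likelihood triggers
re-initialisation with a bounded number of retries. All randomness flows
from R's RNG: a `(seed, chains)` pair reproduces draws bitwise.

**Islands.** The CAR full conditional is undefined for a district with no
neighbours; the default is an error, and `island = "zero"` pins island
effects at zero (they are excluded from re-centring and from the rank
correction).

## Model assessment

`dic()` computes `DIC = 2 * mean(D) - D(at posterior means)` with the
conditional deviance (given random effects) and the plug-in evaluated at the
posterior means of *all* sampled quantities, district effects included. This
convention is comparable across the model family but, like every plug-in
DIC, is not invariant to reparameterisation — a caveat inherited from the
estimator itself.

`ppo()` estimates posterior predictive ordinates
`P(y_ij = s | Y) = (1/J) sum_k P(y_ij = s | Theta_k)` over the support
`s = 0..smax`; `brier_score()` turns them into the count-outcome Brier score
`-(1/n) sum_ij sum_s (p_ijs - 1{y_ij = s})^2`, a proper score maximised (at
0) by the degenerate perfect predictor; higher is better. The support is
truncated at `max(y) + 20` by default; for typical facilities this captures
essentially all predictive mass, though the very largest hospitals can carry
mass beyond any fixed buffer — the truncation is a documented approximation,
and `support_max` is user-settable. A per-draw-averaged squared-error
variant of the score would differ by a predictive-variance term; the
posterior-mean-probability version implemented here is the standard one for
this family of comparisons.

`morans_i()` computes global Moran's I with binary weights by default
(row-standardised optionally) and reports both a permutation p-value
(seeded) and the analytic normal approximation under the randomisation
assumption, since published analyses rarely state which was used.

## The synthetic survey generator

`simulate_dataset()` draws a complete survey-like dataset with known truth:
a rook-lattice district map (default 10 x 12 = 120 districts, close to the
124 districts of the motivating survey); per-district facility counts from a
truncated-geometric law on 1..10 (mean about 3 facilities per district, the
survey's density; a uniform option exists); facility covariates matched to
the survey's published marginals (64.1% type-II/III/post facilities, 65%
outside the district capital, region thirds as contiguous lattice bands so
that region and spatial structure are confounded the way national geography
confounds them, Beta-distributed proportion covariates matched to printed
means by method of moments with a default concentration); and log-normal
admission volumes with strongly type-dependent scale. True parameters
default to the published posterior means of the selected spatial model
(terms absent from that model are zero) and its variance components
(`sigma2_theta = 1.09`, `sigma2_vartheta = 0.26`,
`Sigma_u = diag(0.84, 2.05)`).

The admission scales were calibrated once, a priori, so that the generated
regime matches the survey's published shape — a zero share in the
neighbourhood of the observed ~63% (the defaults land in the low 70s),
around 5 deaths per facility on average, and district admission totals in
the hundreds to thousands — and were not revisited afterwards. Referral
proportions, for which no marginal is printed, default to mean 0.10.

What the generator deliberately does *not* emulate: the joint covariate
distribution beyond printed marginals (in reality facility type, location
and staffing are strongly associated), non-lattice adjacency of real
districts, any missingness mechanism other than optional MCAR cellwise
missingness, and reporting artefacts. Passing simulate-and-recover tests
therefore demonstrates the correctness of the fitting machinery under the
model, not robustness to the misspecifications real surveys carry.

`recovery_experiment()` wraps the simulate-fit-check loop and reports
per-parameter bias, RMSE and credible-interval coverage across seeded
replicates.

## Problem sizes used in the tests and the acceptance script

The package's own test suite validates each operation against independent
oracles (40-digit arithmetic for pmfs, quadrature for the Poisson–Gamma
mixture, dense matrix algebra for CAR kernels and conditionals, a conjugate
Gamma posterior, an external Gibbs implementation on a ZIP toy, and the
pseudoinverse covariance of the constrained ICAR sampler). Sampler-based
checks run at reduced sizes chosen to keep Monte-Carlo error well below the
asserted tolerances: toy fits with 6,000–30,000 iterations, a 20,000-sweep
Gibbs-invariance check on a 3 x 3 lattice, and a ten-replicate recovery
experiment on the full 10 x 12 lattice at 6,000 iterations per fit, which is
past the point where the fixed-effect posteriors stabilise for this data
density. `scripts/acceptance.R` fits the two headline models at 15,000
iterations (5,000 burn-in). Full-length analyses of real data should use the
50,000 / 20,000 defaults of `mcmc_config()` and at least two chains for
`convergence_report()`.

## Known limitations

* The zero component is weakly identified at survey-like data densities
  (a few facilities per district, most of them small): structural and
  sampling zeros can only be separated where facilities are large enough
  that a sampling zero would be surprising. Zero-side district effects are
  correspondingly noisy, and their maps should be read with that in mind.
* Region fixed effects and the ICAR fields are partially confounded when
  regions are contiguous blocks of the map; the data inform their sum much
  better than the split.
* DIC uses a plug-in at posterior means and inherits its parameterisation
  sensitivity; Brier-score support truncation is an approximation for
  facilities with very large expected counts.
* Only the intrinsic bivariate CAR is implemented (no proper multivariate
  CAR), matching the scope of the model family it implements.
* Hurdle models are out of scope by design: when both structural and
  sampling zeros are plausible, the zero-inflated formulation is the
  appropriate one.
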