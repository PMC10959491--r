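---
title: "Quantitative genetics of thermoregulatory capacity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of thermoregulatory capacity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoqg)
```

# The scientific problem

Large endotherms in strongly fluctuating climates must keep critical organs
— above all the brain — inside a narrow thermal zone. The motivating system
is the ostrich (*Struthio camelus*): pedigreed captive populations of
several subspecies (South African Black, Zimbabwean Blue, Kenyan Red)
breeding in a semi-desert where air temperatures range from −5 to 45 °C.
Thermal imaging makes
it possible to phenotype this noninvasively at scale: the difference between
head and neck surface temperature from one image (`head_t - neck_t`) is a
measure of how strongly an individual regulates its head temperature *for a
given thermal load*, because both body parts share the same recent
microclimate and behavioural history while the neck tracks that load. Lower
head-neck deviations under heat indicate stronger head cooling.

`thermoqg` implements the full analysis chain for such data in pedigreed
populations: preprocessing raw image and weather records into model-ready
observations, Bayesian animal models for the deviation across air-temperature
regimes, heritability / repeatability / evolvability estimation from the
posterior variance components, a threshold (binary-liability) model linking
thermoregulation to daily egg laying, and a seeded synthetic-data generator
so that every stage can be validated against known truth.

# Preprocessing

* **Air temperature at image time.** Hourly weather-station records are
  interpolated per day with a *natural cubic interpolating spline*
  (`interpolate_air_temperature()`), evaluated at the image timestamp. An
  interpolating spline through 24 hourly knots was chosen over a penalized
  smoother: it is fully reproducible without a smoothing-parameter
  convention, passes through every knot exactly, and at hourly density the
  two differ by well under 0.1 degrees C. No extrapolation outside a day's
  covered hour range is allowed.
* **Temperature-change reaction-norm covariates.** 20 degrees C is treated
  as the thermal optimum (reproductive performance peaks there). Air
  temperature becomes an absolute deviation from 20, split by a direction
  factor (decrease / increase) and divided by the dataset's maximum absolute
  deviation so the covariate lies in [0, 1]. At exactly 20 the change is 0;
  the direction label there is an arbitrary convention (`decrease`) and is
  inert because the covariate is zero. The normalizer is computed over
  increases and decreases jointly.
* **Temperature categories.** cold: air temperature at or below 20; benign:
  between 20 and 30; hot: 30 or above. The boundary values follow the
  methods definition (cold includes 20.0 exactly).
* **Validation.** Surface temperatures outside [-10, 60] degrees C, images
  outside the 05:00-18:00 window, and non-positive pixel counts are dropped
  with logged reasons. Repeated images of an individual within a day are
  retained. No outlier removal is performed on analysis data.

# The mixed-model engine

All models are Gaussian or threshold generalized linear mixed models fitted
by Gibbs sampling (`qgfit()`), written for this package (compiled C++ core):

$$y = X\beta + \sum_k Z_k u_k + e$$

Each random term $k$ has $q_k$ effect columns per grouping level and an
unstructured $q_k \times q_k$ covariance $\Sigma_k$; a *pedigree-linked*
(animal) term has prior covariance $\Sigma_k \otimes A$, with $A$ the
additive relationship matrix from the tabular method and its sparse inverse
from Henderson's rules with inbreeding. Residual variances may be
homogeneous or estimated separately per temperature category.

**Sampling scheme.** All full conditionals are conjugate:

* fixed effects in one dense multivariate-normal block (flat prior, full
  rank enforced at design time);
* random effects level by level; terms sharing a grouping factor (the
  permanent-environment and additive-genetic effects of the same
  individual) are updated *jointly* per individual, which removes their
  dominant posterior correlation, while the relationship structure enters
  through the sparse rows of $A^{-1}$ (Gauss-Seidel over relatives);
* covariances from inverse-Wishart conditionals, residual variances from
  inverse-gamma conditionals;
* threshold family: latent liabilities from truncated normals with the
  liability residual variance fixed at 1 for identifiability.

A joint all-location update via the mixed-model equations would mix
slightly faster per iteration but requires a sparse Cholesky refactorization
every iteration; per-individual joint blocks in compiled code are an order
of magnitude faster at this study scale and leave the stationary
distribution unchanged. Levels of a non-pedigree term that have no
observations (pedigree ancestors without images) are integrated out exactly
rather than sampled.

Determinism: identical data, model, priors and seed give bit-identical
retained draws. The bulk normal draws use a fast deterministic stream
seeded from R's RNG, so `set.seed()` governs everything.

**Priors.** The default for every random term is the weakly informative
inverse Wishart with $V = \mathrm{diag}(q)$ and $\nu = q - 1 + 0.002$,
which for $q = 1$ is the inverse-gamma with shape and scale 0.001; the
residual prior is that same inverse gamma. Default schedules mirror the
production analyses (5,100,000 iterations, 100,000 burn-in, thinning 4,000;
the threshold selection model 31,500,000 / 1,500,000 / 10,000); all tests
and examples pass reduced schedules explicitly.

**A caution on the q > 1 prior at small variances.** For a $3 \times 3$
term the marginal prior on each variance is IG(0.001, $\approx$1.0), not
IG(0.001, 0.001): the exponential factor $e^{-1/\sigma^2}$ imposes a soft
floor near 0.1 (trait units squared). Variance components far below that
floor cannot be recovered under this prior regardless of chain length — we
verified on simulated data that shrinking $V$ restores recovery. On the
degrees-Celsius scale of the head-neck deviation (component variances of
order 0.1-1.5 C^2) the floor is immaterial, but users applying the category
or reaction-norm models to traits with much smaller variances should supply
a prior `V` on the scale of their data.

**Posterior summaries.** Point summaries are kernel-density modes (Gaussian
kernel, Silverman bandwidth, dense grid); intervals are 95% highest
posterior density (shortest interval); `pMCMC` is the floored two-sided
sign probability $\max(2\min(n_+, n_-)/N,\ 2/N)$. Convergence is assessed
across replicate chains by the potential scale reduction factor (floored at
1) and lag-1 autocorrelation of retained draws
(`convergence_check()`; flags at 1.1 and 0.1).

# The four analyses

* **Body-part model** (`recipe_body_part_model()`): each image stacked into
  a head and a neck row; a body-part factor interacts with every fixed
  effect, so the head-vs-neck difference in warming and cooling rates is an
  explicit contrast; an image-level random effect ties the two rows of one
  image together.
* **Category model** (`recipe_headneck_category_model()`): head-neck
  deviation with fixed category, within-category standardized
  air-temperature deviation, time of day (linear + quadratic), subspecies
  and subspecies-by-category (the interaction is included only when every
  category-by-class cell is observed); random year, enclosure, date, a
  3x3 individual-by-category permanent-environment covariance and an
  optional pedigree-linked 3x3 additive covariance; heterogeneous residuals
  by category.
* **Selection model** (`recipe_selection_model()`): threshold model of
  whether at least one egg was laid 2-4 days after imaging (the oviduct
  transit lag), on the standardized deviation, period category (benign vs
  hot moment of a hot day) and their interaction, subspecies and an age
  factor (2 vs older). Filters (computed as independent masks, so order
  cannot matter): only days whose daily maximum exceeds 20 C; the first 45
  days of each breeding season removed; females with fewer than 10 eggs
  that year removed; events at or below 20 C at image time dropped.
  "Season start" is operationalized as the first laying date in the
  female's enclosure-year (falling back to the year), since no explicit
  definition is available; a lagged window of days +2, +3, +4 with
  "at least one egg" as the success definition.
* **Subspecies reaction norm** (`recipe_subspecies_reaction_norm()`):
  random regression of the deviation on (intercept, decrease slope,
  increase slope) per individual, with a pedigree-linked counterpart; the
  genetic slope-intercept correlation comes from the additive covariance
  draws via `genetic_correlation()`.

# Quantitative-genetic estimators

With per-category permanent-environment variance $\sigma^2_{pe}$, additive
variance $\sigma^2_a$, and year / enclosure / residual components, the
package computes per retained draw

$$R = \frac{\sigma^2_{pe}}{\sigma^2_{pe} + \sigma^2_{year} +
\sigma^2_{enclosure} + \sigma^2_{res}}, \qquad
h^2 = \frac{\sigma^2_a}{\sigma^2_{pe} + \sigma^2_a + \sigma^2_{year} +
\sigma^2_{enclosure} + \sigma^2_{res}}, \qquad
I_A = \frac{\sigma^2_a}{\bar{z}^2} \times 100.$$

The date variance is estimated but *excluded* from both denominators —
that is the published definition of these ratios, replicated exactly;
`include_date = TRUE` exposes the variant with it. Whether its omission was
intentional cannot be decided from the source, so the printed formula is
the default. Ratio quantities are computed draw-wise and then summarized,
never as ratios of summaries. Evolvability uses the *posterior mode* of the
trait mean in the denominator so that only the additive-variance
uncertainty propagates; it diverges as the trait mean approaches zero, so a
zero mean is an error rather than a number.

# The synthetic-data generator

`simulate_study()` emulates the study regime with known truth: a pedigree
founded by 139 individuals (non-overlapping generations, random mate
pairing, re-mating when pairs exceed candidates — simpler than the study's
overlapping generations, which does not affect recovery properties);
founder subspecies labels and expected-fraction-based hybrid
classification (85% threshold); hourly weather as an AR(1) daily mean plus
a diurnal sinusoid peaking mid-afternoon, clamped to [-5, 45] C; ~423
measured females averaging ~6.5 images each across 48 study days in six
seasons; and daily egg laying with a probit link whose linear predictor
adds `beta_hn` times the standardized hot-period deviation lagged 2-4 days.

Default variance components are anchored to the degrees-Celsius scale the
trait actually has (within-category residual SD above 1 C, total
phenotypic variance near 2 C^2), giving true per-category heritabilities
of 0.07-0.08 and repeatabilities of 0.14-0.16 — the study's regime. Head
and neck absolute temperatures are generated only to exercise
preprocessing (a linear neck baseline in air temperature, head = neck +
deviation), so `build_observations()` reconstructs the generated deviation
exactly; they do not model radiative physics. Other simplifications: one
enclosure per female, image days drawn uniformly across seasons, constant
age class per female. Passing recovery tests on these data therefore
demonstrates correctness of the estimation machinery under the assumed
variance structure, not robustness to confounding structures absent from
the generator (e.g. spatial microclimate gradients, measurement error
correlated with distance).

# Validation strategy and problem sizes

The test suite validates each stage against independent oracles: the
tabular-method relationship matrix against a recursive kinship oracle
(20 random pedigrees, agreement to 1e-12); the spline against an
independent tridiagonal natural-spline solver; the sampler against ordinary
least squares (fixed effects), the analytic inverse-gamma posterior
(Kolmogorov-Smirnov distance below 0.05 at 1,000 exact draws), a probit
closed form (threshold intercept), and `glm` (threshold slope). Recovery
runs use 600 measured females with 6 images each on a ~1,340-individual
pedigree at a reduced schedule (51,000 iterations, thinning 40): 20
replicates at h2 = 0.3 / R = 0.45 (modes within 0.1, 95% HPD coverage at
least 80%), and the low-heritability study regime h2 = 0.07 / R = 0.15
(modes within 0.05 on average). The threshold model is checked for null
calibration (rejection rate at the nominal 5% over 40 refits) and for sign
detection of a -0.16 SD liability effect at ~2,000 events (negative
posterior mode in at least 90% of 20 replicates). These sizes were chosen
as the smallest at which the regimes are statistically identifiable;
`scripts/acceptance.R` re-derives the same quantities end to end with
fewer replicates.

# Known limitations

* The per-individual block sampler mixes more slowly than a joint location
  update for very small or pathologically confounded designs; the
  convergence diagnostics are there to catch this.
* The threshold model fixes the liability residual variance at 1; odds- or
  probability-scale effects must be derived from the liability scale.
* Heritabilities near the inverse-Wishart prior floor (see the prior
  caution above) require a rescaled prior `V` or a rescaled response.
* The event-level "at least one egg in three days" response aggregates the
  daily probit process, so liability-scale event coefficients are larger in
  magnitude than the daily-scale generating coefficient; sign and
  calibration are preserved.
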