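---
title: "Measurement models and design choices for slider and interval responses"
author: "drsirt maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models and design choices for slider and interval responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drsirt)
```

## The measurement problem

Personality questionnaires increasingly use continuous bounded response
formats: the visual analog scale (VAS), where a respondent places a single
slider on a 0–100 line, and the dual-range slider (DRS), where a respondent
places a *lower* and an *upper* bound, reporting an interval. The interval's
midpoint is read as the location (central tendency) of the respondent's
state distribution, and its width as the intra-individual variability of
states across situations. The psychometric question this package addresses
is whether those widths behave like a reliable, valid measure: does the
latent width score correlate with itself across occasions (test–retest
reliability), does the DRS location agree with the VAS (convergent
validity), and are widths distinct between traits (discriminant validity)?

## Compositional likelihoods: BRM and DDRM

Bounded slider responses are naturally compositional. A VAS response $v$ on
$[0, M]$ splits the line into two segments $(v/M,\, 1 - v/M)$; a DRS
response $(l, u)$ splits it into three: $(l/M,\, (u-l)/M,\, (M-u)/M)$.
The package models the two-part composition with a beta distribution (beta
response model, BRM) and the three-part composition with a Dirichlet
distribution (Dirichlet dual-response model, DDRM).

For person $p$ and item $i$ answered with the VAS:
$$\mu_{pi} = \operatorname{logit}^{-1}\!\big(\alpha_i(\theta^V_p - \delta_i)\big),
\qquad x_{pi} \sim \mathrm{Beta}(\mu_{pi}\tau_i,\ (1-\mu_{pi})\tau_i),$$
with item scaling $\alpha_i > 0$ (discrimination/loading), difficulty
$\delta_i$ (intercept), and precision $\tau_i > 0$ (inverse residual
dispersion).

For the DRS, two logistic submodels drive the expected composition:
$$\mu_{pi} = \operatorname{logit}^{-1}\!\big(\alpha^{loc}_i(\theta^D_p - \delta^{loc}_i)\big),
\qquad \omega_{pi} = \operatorname{logit}^{-1}\!\big(\alpha^{wid}_i(\eta^D_p - \delta^{wid}_i)\big),$$
$$\mathbf m_{pi} = \big(\mu_{pi}(1-\omega_{pi}),\ \omega_{pi},\ (1-\mu_{pi})(1-\omega_{pi})\big),
\qquad \mathbf x_{pi} \sim \mathrm{Dirichlet}(\mathbf m_{pi}\,\tau_i).$$
This construction reproduces the structural dependency of interval
responses: the expected width $\omega$ increases in the width parameter
$\eta^D$, the expected midpoint $\mu(1-\omega) + \omega/2$ increases in
$\theta^D$, and as $\omega \to 1$ the midpoint is squeezed to the scale
center — wide intervals cannot sit at the extremes. One precision $\tau_i$
is shared across the three components; the exact published appendix forms of
these models were not available to this implementation, so the
parameterization above (logistic links; shapes proportional to the mean
composition) is the package's committed choice. It satisfies every property
the surrounding literature states for these models, and both the simulator
and the fitter use the *same* density code, so generation and inference
cannot drift apart.

### Boundary responses

Beta/Dirichlet densities are undefined at the simplex boundary, but sliders
do get pushed to the scale ends, and zero-width intervals occur. The
standard compression $x' = (x(n-1) + 1/K)/n$ (with $n$ the number of
response records and $K$ the number of components) pulls every composition
into the interior by an amount that vanishes as the data grow. It is applied
once, at model-assembly time.

## The joint hierarchical model

With two traits, two formats, and two occasions, each person carries a
12-vector $(\theta^V, \theta^D, \eta^D) \times (\mathrm E, \mathrm C)
\times (t_1, t_2) \sim \mathcal{MVN}(\boldsymbol\mu, \boldsymbol\Sigma)$,
$\boldsymbol\Sigma = \mathbf D \mathbf R \mathbf D$. Identification fixes
the first-occasion means to 0 and SDs to 1; second-occasion means and SDs
are free. The 12×12 correlation matrix $\mathbf R$ is the scientific
payload: its cells are the test–retest, convergent, and discriminant
correlations.

Item parameters are shared across occasions under strict measurement
invariance (the default). Because each scale is randomly split per person
into a VAS half and a DRS half (held fixed across occasions), every item
accumulates both BRM and DDRM parameters across respondents, and each
person×item cell not assigned to a format is simply missing by design: it
contributes no likelihood term.

Priors (all overridable via `model_config()`): $\alpha \sim
\mathrm{LogNormal}(0, 0.5)$, $\delta \sim \mathrm N(0,1)$, $\tau \sim
\mathrm{LogNormal}(\log 10, 1)$, free means $\mathrm N(0,1)$, free SDs
half-$\mathrm N(1)$, and an LKJ(1) prior — uniform over correlation
matrices — on $\mathbf R$.

## Estimation

No Stan-family backend is available in this environment, so the package
ships its own sampler: a multinomial no-U-turn Hamiltonian Monte Carlo
sampler with dual-averaged step size and windowed diagonal mass-matrix
adaptation, over an unconstrained parameterization (non-centered person
vectors $P = \boldsymbol\mu + \boldsymbol\sigma \odot L z$; the correlation
Cholesky factor via tanh-transformed canonical partial correlations;
log-transformed positive parameters). Gradients are analytic (verified
against numerical differentiation to ~1e-9 in the test suite); the tiny
Jacobian of the per-row Cholesky transform is obtained by finite
differences of an algebraic function, which is exact to the tolerances that
matter for HMC. Chains are seeded deterministically from the user seed, so
fixed data plus a fixed seed reproduce draws bit for bit on one machine.

Convergence is assessed with rank-normalized split-$\hat R$ and bulk/tail
effective sample sizes (thresholds $\hat R < 1.01$, ESS ≥ 400), implemented
from the published algorithm. Model comparison uses PSIS-LOO: importance
ratios smoothed by a generalized Pareto fit (profile-likelihood method with
the usual weak shape prior), yielding `elpd_loo`, `p_loo`, and per-observation
Pareto-$k$ diagnostics. Differences between models are computed from
pointwise elpd vectors, never from marginal standard errors.

Default sampler settings follow the source study's spirit (4 chains, high
acceptance target 0.95) with reduced iteration counts; analyses in the test
suite use explicitly reduced settings, documented below.

## The invariance ladder

`invariance_ladder()` fits, per trait × format sub-model, the four nested
levels — configural (item parameters occasion-specific), metric ($\alpha$
shared), scalar ($\alpha, \delta$ shared), strict ($\alpha, \delta, \tau$
shared) — and compares adjacent levels by $\Delta$elpd_loo. The winner is
the level with the highest elpd_loo, with a practical-equivalence note when
its lead is within 2 SE of the runner-up. The ladder is fit on sub-models
rather than by toggling constraints inside the joint model: each fit stays
small, mirroring how such comparisons are typically run.

## The synthetic-data generator

The generator is first-class, tested code, emulating the study design: 224
respondents, two 42-item scales, per-person random half-splits into formats
(fixed across occasions), randomized block order per person-occasion, two
occasions — 37,632 response slots at full scale.

* **Population correlations.** `reference_population()` inserts the
  published posterior-median correlations into the 12×12 matrix (test–retest
  .89/.90/.92/.87/.81/.73; convergent .93/.96/.88/.90; location–width
  .00/−.01/−.11/−.05; cross-trait .38/.34/.30/.31/.94/.96). Unspecified
  cells default, per the original plan, to zero before positive-definite
  projection — but a zero fill is severely indefinite here (a .94 cross-trait
  width correlation plus .81/.73 test–retest correlations force substantial
  cross-occasion cross-trait correlations), and eigenvalue clipping would
  drag the *specified* cells far from their printed values. The package
  therefore defaults to a transitive completion: each unknown cell is filled
  with the largest-magnitude product $r_{ik} r_{kj}$ over known chains,
  iterated to closure. The result is positive definite and reproduces every
  specified cell to machine precision, giving recovery tests exact truths.
  The zero fill remains available (`fill = "zero"`).
* **Item priors.** Scalings log-normal around 1 (sdlog 0.3); difficulties
  normal with mean −0.4 (locations) and +0.8 (widths), SD 0.75; precisions
  log-normal around 10 (sdlog 0.3). These were chosen once so that simulated
  response distributions land where the published descriptives do — VAS and
  DRS-location means in the upper-middle of the 0–100 scale, mean widths
  near 30 — and are not tuned thereafter.
* **Second-occasion moments.** Free means default to 0 and SDs to 1 (the
  published descriptives show near-identical moments across occasions).
* **Rounding** to integer slider values is off by default: the likelihood is
  continuous, and recovery tests should not carry discretization
  misspecification. A flag enables it for realism studies.
* **Not emulated:** response styles beyond the model, item-specific wording
  effects, attrition mechanisms, realistic response-time or seriousness
  structure (only simple contamination hooks for exclusion tests). A green
  recovery test therefore establishes that *the pipeline recovers the model's
  own truth at study-like scale* — not that the model is true of human data.

## Preprocessing rules

Exclusions run in a fixed order: duplicate records (first-in-file kept;
the record schema has no timestamps, so file order stands in for
chronology), non-serious respondents (flagged at any occasion), completion
times, response outliers (robust $z$ on per-person means and SDs of
interval midpoints, median/MAD, threshold 3.5), and finally an optional
completeness requirement across occasions with the attrition percentage
$100 \cdot t_1\text{-only}/(t_1\text{-only} + \text{both})$.

The published speed criteria live in footnotes unavailable here, so the
time rules are quantile-based and configurable (defaults 1%/99% on
per-entry total response time). Pure rank-based trimming removes its tail
fraction on *every* application, which would contradict the pipeline
invariant that preprocessing is idempotent; the rule therefore additionally
requires genuine separation from the bulk (robust $|z| > 3.5$ on log
times). On clean data the operation is then a fixed point, while a
constructed extreme-fast respondent is still caught, and the quantile
threshold itself is reported verbatim in the exclusion report.

## Numerical choices

* HDI: exact shortest window over sorted draws (ties → leftmost window).
* Cumulative interval densities: the density at $x$ counts intervals
  containing $x$; quantiles of the accumulated mass are computed exactly
  from the piecewise-linear CDF (not on a grid; the grid only renders the
  density trace, default step 0.1). Zero-width intervals count for the
  density but carry no mass; if all widths are zero, quantiles fall back to
  weighted point quantiles.
* CLPM: computed in closed form per posterior draw of the 4×4 width
  correlation matrix — standardized, intercept-free ($\beta = R_{xx}^{-1}
  r_{xy}$), with $R^2_{\text{full}}$, the other-trait-only simple $R^2$,
  their difference $\Delta R^2$ (the unique same-trait increment), and the
  T2 residual correlation. Singular draws are skipped and counted.
* Positive-definite projection: eigenvalue clipping at 1e-8 with diagonal
  rescaling; deterministic.

## Reduced-scale testing and its limits

The published analysis ran hours of MCMC on a 3,548-parameter model; the
test suite must finish in minutes. The recovery test (the package's primary
correctness surface) therefore runs at a reduced scale — 100 persons
instead of 150, keeping the stated 12 items per trait per format and
4 chains × 500 post-warmup draws, with a capped tree depth — and the
invariance-ladder tests run many small fits (50 persons, 12 items of one
trait, short chains). The acceptance thresholds themselves (±0.15 recovery
error, ≥90% HDI coverage, 8-of-10 seed wins) are unchanged from the build
contract. At reduced scale two effects work against HDI coverage of the
*population* correlations: posterior medians of very high correlations
shrink slightly toward zero under the uniform LKJ prior, and the realized
sample of latent person vectors has its own sampling error around the
population matrix (about ±0.03 for a correlation of .8 at n = 100), which
the fit cannot see past. The ±0.15 band absorbs both comfortably; the
coverage clause is tighter, and its outcome at reduced scale is reported
honestly by the test rather than adjusted.

## Known limitations

* Tree depth is capped in test configurations; extreme posteriors would be
  flagged by $\hat R$/ESS rather than explored exhaustively.
* The invariance ladder does not implement partial invariance (item-level
  freeing), and only two occasions are exercised although the design types
  support more.
* `p_loo`'s match to the parameter-count heuristics is approximate at small
  draw counts; the LOO contract is tested against exact leave-one-out in a
  conjugate model instead.
* Reverse-coded DRS items are assumed to reflect both bounds (preserving
  width); the alternative readings are not implemented.
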