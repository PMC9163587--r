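---
title: "Estimating apparent magnetic susceptibility anisotropy from single-orientation QSM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating apparent magnetic susceptibility anisotropy from single-orientation QSM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative susceptibility mapping (QSM) assigns every brain voxel an
apparent magnetic susceptibility (AMS, here written $\chi_{app}$, in
ppb). In white matter this value is not a pure tissue property: the
myelin sheath around axons is magnetically anisotropic, so the
recovered scalar depends on the angle $\theta$ between the dominant
fibre direction and the main field $B_0$. For a radially symmetric
fibre susceptibility tensor with components $\chi_\parallel$ and
$\chi_\perp$,

$$\chi_{app}(\theta) = (\chi_\parallel - \chi_\perp)\cos^2\theta + \chi_0 ,$$

where $\chi_0$ collects all orientation-independent contributions
(tissue iron, isotropic myelin effects). Measuring the anisotropy
$\chi_\parallel - \chi_\perp$ directly requires scanning the head at
several orientations, which is clinically impractical. The idea this
package implements is to exploit the natural spread of fibre
orientations *within a tract*: treating the tract's voxels as
observations of the line above turns the anisotropic and isotropic
components into regression coefficients,

$$\chi_{app}(\theta) = \delta\chi \cos^2\theta + \chi_{iso},$$

estimable from a single acquisition. $\delta\chi$ is the *apparent*
magnetic susceptibility anisotropy (aMSA) of the tract, a candidate
marker of myelin integrity; $\chi_{iso}$ is the tract's isotropic
component. The motivating application is normal-appearing white
matter in relapsing-remitting multiple sclerosis (MS), where diffuse
demyelination is expected to lower $\delta\chi$, in three tract ROIs:
the optic radiation (OR), the splenium of the corpus callosum (SCC)
and the superior longitudinal fascicle (SLF).

## The multilevel cohort model

Comparing a patient cohort with controls voxel tables are modelled
jointly in one Bayesian multilevel linear model per ROI:

$$\chi_{app}^{voxel} = \left(\chi_{iso}^{subj} + \beta_{iso} AO +
\tau_{iso} DD + \lambda_{iso} LL\right) + \left(\delta\chi^{subj} +
\beta_{\delta\chi} AO + \tau_{\delta\chi} DD + \lambda_{\delta\chi}
LL\right)\cos^2\theta^{voxel} + \varepsilon$$

with $\varepsilon$ i.i.d. Gaussian voxel noise. The covariates are:

* $AO$ — age at examination (controls) or age at disease onset
  (patients), referenced to 30 years and scaled by 10 years, so the
  ageing effects $\beta$ are in ppb per decade and are shared between
  cohorts;
* $DD$ — disease duration in decades, 0 for controls by definition,
  so $\tau$ is a patient-cohort effect;
* $LL$ — lesion-load fraction of the ROI in $[0,1]$, 0 for controls,
  so $\lambda$ is a patient-cohort effect. (Coefficients are per unit
  fraction internally; divide by 10 for "per 10% lesion load".)

Subject levels $\chi_{iso}^{subj}, \delta\chi^{subj}$ are drawn from
cohort-specific normal distributions,
$N(\mu^{coh}_{iso/\delta\chi}, \sigma^{coh}_{iso/\delta\chi})$.
Because controls have $DD = LL = 0$ structurally, duration and lesion
effects for the control cohort are not identifiable and are simply
not parameters of the model. Cohorts are compared through the
standardized effect size computed per joint posterior draw,

$$\eta = \frac{\mu^{MS} - \mu^{HC}}
{\sqrt{(\sigma^{MS\,2} + \sigma^{HC\,2})/2}},$$

whose marginal posterior (MAP, 95% highest-density interval,
probability above zero) summarizes the evidence.

### Priors

The response is standardized (demeaned, scaled by the pooled SD)
within each ROI before sampling, and all reported coefficients are
rescaled back to ppb. On that standardized scale the priors are
weakly informative: $N(0, 1)$ for cohort means, $N(0, 2.5)$ for the
covariate effects, and Half-Normal(1) for the cohort SDs and the
noise SD (all scales configurable in `model_spec()`). The covariate
effects get the wider scale because they are coded per unit of
low-spread predictors — most extremely the lesion-load *fraction*,
where a plausible effect of a few ppb per 10% lesion load is one to
two standardized units per unit fraction; a unit-scale prior
measurably shrinks such an effect and, through the covariate
adjustment, biases the patient cohort mean at its reference point
(observed as a ~3 ppb distortion of the cohort difference in
simulation before the scale was widened). All priors on anisotropy
quantities are deliberately symmetric about zero: negative
$\delta\chi$, although hard to justify biophysically, is an important
empirical signature (the SLF shows it robustly), and the model must
be able to express it rather than suppress it.

### Sampling

The model is a Gaussian hierarchy, so everything below the population
level can be handled in closed form; sampling uses JAGS (via rjags).
Defaults: 4 chains, 1000 warmup iterations (half adaptation, half
burn-in) and 1000 retained draws per chain, all seeded and exactly
reproducible.

Three implementation choices matter for speed and mixing:

1. **Exact likelihood collapse.** For one subject the Gaussian voxel
   likelihood depends on the data only through the OLS estimate
   $(\hat\chi_{iso}, \hat{\delta\chi})$, the matrix $X^TX$ and the
   residual sum of squares: $\hat\beta_s \sim
   N_2(\beta_s, \sigma_v^2 (X^TX)^{-1})$ and $RSS_s \sim \sigma_v^2
   \chi^2_{n_s-2}$ independently. The sampler therefore sees two
   likelihood nodes per subject instead of hundreds of voxels —
   an exact factorization, not an approximation. (A test verifies the
   collapsed and voxel-level log densities differ by a
   parameter-free constant; `log_joint_density()` exposes the
   voxel-level form.)
2. **Marginalized subject effects.** The subject-level components are
   integrated out analytically — marginally $\hat\beta_s \sim
   N_2(\text{population mean}_s,\; \sigma_v^2 (X^TX)^{-1} +
   \mathrm{diag}(\sigma_{iso}^2, \sigma_{\delta\chi}^2))$ — so MCMC
   runs only on the population-level parameters. This matters most
   where the tract angle range is narrow (SCC): there the per-subject
   slopes are weakly identified, and sampling them as latent
   variables couples them so strongly to $\sigma_{\delta\chi}$ that
   single-site Gibbs stalls (split-R-hat above 4 in early
   experiments); on the marginal, the same fits reach split-R-hat
   below 1.01. Subject-level draws are then reconstructed exactly,
   per retained population draw, from their closed-form bivariate
   normal conditionals.
3. **Within-cohort covariate centering.** Cohort means and covariate
   slopes are strongly correlated when $DD$ and $LL$ have non-zero
   cohort means. The sampler works in a within-cohort
   covariate-centered parameterization and maps draws back to the
   reference scale (age 30, at onset, lesion-free) afterwards — an
   exact, invertible reparameterization. As in other
   centered-intercept samplers, the $N(0,1)$ prior on each cohort
   mean is placed at the cohort's covariate centre.

Convergence is monitored with split-R-hat (BDA3 form) and effective
sample sizes (capped at the total draw count); a fit whose
population-level split-R-hat exceeds 1.01 is flagged with a warning
and `converged = FALSE`.

## The synthetic cohort generator

No patient data are distributable, so the package ships a generator
whose defaults encode the study conditions: 64 healthy controls
(ages ~24-66, median near 30 years, SD near 10) and 89
relapsing-remitting MS patients (disease duration 1-32 years, median
near 9; age = age at onset + duration), three tract ROIs, 500 voxels
per tract and subject, and i.i.d. Gaussian voxel noise.

Fibre-to-field angles are drawn from a Watson axial distribution
around a mean tract direction — one concentration parameter per
tract, which reproduces the qualitative tract profiles: nearly
perpendicular and narrow in SCC (mean 90°, $\kappa = 25$, central 95%
of $\theta$ spanning about 19° — a third of the angular range),
moderate in OR (75°, $\kappa = 12$), broad in SLF (40°, $\kappa = 5$).
The SLF profile was calibrated once so that $E[\cos^2\theta] \approx
1/2$, making the tract's mean AMS $\approx \chi_{iso} +
\delta\chi/2$, the relation expected for an orientationally
homogeneous tract; with the default $\chi_{iso} = -15$,
$\delta\chi = -30$ ppb this gives a mean AMS near $-30$ ppb.

Default generating values sit in the reported ranges for this
analysis: control-cohort anisotropy means of 27 (OR), 21 (SCC) and
$-30$ (SLF) ppb; a patient OR mean of 21 ppb so that the true OR
effect size is $-0.6$ with cohort SDs of 10 ppb; the widest subject
spread in SCC ($\sigma_{\delta\chi} = 30$ ppb); ageing effect
$\beta_{\delta\chi} = -2$ ppb/decade in OR; a disease-duration effect
concentrated in SCC ($\tau_{\delta\chi} = -10$ ppb/decade) and a
lesion-load effect concentrated in OR ($\lambda_{\delta\chi} = -3$
ppb per 10% lesion load). Quantities the source analysis does not
report numerically — the voxel noise SD (15 ppb), cohort SDs other
than the ones above, isotropic-component means beyond their ranking
OR < SCC < SLF, and the zero-inflated-Beta lesion-load distributions
(heaviest involvement in OR) — are fixed arbitrarily at plausible
values and are fully configurable; tests depending on them are
parameter-recovery tests, not comparisons to reported numbers.

What the generator deliberately does *not* emulate: spatial voxel
structure and correlated reconstruction artefacts (only a
$\theta$-correlated artefact probe is provided via
`inject_orientation_artifact()`), heteroscedastic or heavy-tailed
noise, errors in the fibre-orientation estimates, and any genuine
within-tract variation of the underlying tensor anisotropy. Passing
recovery tests therefore demonstrates correctness of the estimation
chain under the model's own assumptions — not robustness of aMSA to
the dipole-inversion biases that real single-orientation QSM is known
to suffer (the robustly negative SLF anisotropy being the prime
suspect).

## Mask construction

The voxel-selection rules are implemented as metric morphology on
binary grids: white-matter masks are eroded with a 2 mm sphere;
lesion masks are dilated by 1 mm and subtracted to form
normal-appearing white matter; crossing-fibre voxels are excluded by
retaining only FA $\ge$ 0.6 and peak quotient $\le$ 0.3. The
exclusion wording is read as "exclude if FA < 0.6 *or* PQ > 0.3" —
the only reading that removes both low-anisotropy and crossing-fibre
voxels — with a closed (boundary-inclusive) acceptance region.
Structuring elements are metric (mm-aware), so anisotropic grids are
handled; voxels beyond the volume count as background, making edge
erosion conservative. Per-ROI lesion load is the lesioned fraction of
the ROI volume. Whether the FA/PQ filter is applied before or after
ROI intersection is not prescribed; the functions operate on whatever
table they are given, and the generator emulates filter-passing
voxels directly.

## Numerical choices

* **OLS stage**: `lm.fit` on $(1, \cos^2\theta)$; at least two
  distinct angles are required, otherwise the anisotropy is flagged
  non-estimable. Angle-decile bins assign remainder voxels to the
  lowest bins with stable tie order. No outlier rejection anywhere.
* **HDI**: sorted sliding-window (narrowest window containing
  $\lceil 0.95\,n \rceil$ draws); width ties resolve to the lowest
  start, which is the documented convention for flat stretches.
* **MAP from draws**: argmax of a Gaussian-kernel density
  (Silverman bandwidth, 4096-point grid) refined by the vertex of a
  quadratic fitted to the contiguous top 4% of the curve. The
  refinement suppresses argmax jitter on flat-topped marginals while
  keeping the kernel narrow enough not to bias skewed ones (worst
  error ~0.03 at $10^6$ draws for both a unit normal and a standard
  lognormal).
* **Probability above zero** uses strict inequality; zeros count as
  not-above.
* **Watson angle sampling** inverts the axial cosine CDF numerically
  on a 4097-point grid (restricted to the mass-bearing interval for
  large concentrations); concentration 0 and $\infty$ are handled
  exactly.
* **Problem sizes**: the packaged recovery study uses 20 replicates
  of the full cohort at 200 voxels per tract, which leaves the
  population-level posterior essentially unchanged relative to 500
  voxels (per-subject fits enter the model only through their
  sufficient statistics) while keeping the suite quick.

## Known limitations

* The exact priors of the original analysis are not public; the
  weakly informative choices here are defensible but not identical,
  so posterior summaries on real data would differ in detail.
* Gibbs sampling relies on the collapsed conjugate structure; the
  model cannot be extended to non-Gaussian likelihoods without
  changing the sampler.
* Effect sizes and covariate effects are only as interpretable as the
  model: with narrow tract angle distributions (SCC-like), per-subject
  anisotropy is weakly identified and cohort conclusions lean on the
  hierarchy.
* Point estimates of the cohort effect size inherit the full posterior
  width: because the patient cohort mean is defined at the covariate
  reference point (onset, lesion-free), uncertainty in the
  disease-duration and lesion-load effects propagates into it, and the
  MAP of the effect-size posterior scatters around the generating
  value noticeably more than the cohort-mean difference alone would
  suggest. Interval summaries (the 95% HDI) represent that
  uncertainty honestly; single-number effect sizes should be read
  with it in mind.
* `lesion_load` here is a scalar covariate; lesion geometry beyond
  the mask operations is out of scope, as are all image-reconstruction
  stages (phase unwrapping, background-field removal, dipole
  inversion) and segmentation/registration.

## A worked example

```{r example}
library(amsa)

cfg <- generator_config(n_hc = 16, n_ms = 20, voxels_per_roi = 150,
                        seed = 7)
ds <- generate_cohort_dataset(cfg)

## per-subject orientation curves and fits
fits <- fit_all_subjects(ds$voxels)
curves <- binned_curves_table(ds$voxels)

## multilevel model, OR only
spec <- model_spec(seed = 8)
posts <- fit_cohort_model(ds$voxels, ds$subjects, spec, rois = "OR")
summarize_posterior(posts$OR)

## report bundle (TSV + JSON + figures)
render_report(fits, curves, posts, "report")
```
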