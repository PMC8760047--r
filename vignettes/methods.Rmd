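---
title: "Methods: joint group/BMI modeling and gated bootstrap mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint group/BMI modeling and gated bootstrap mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bdbmi)
```

## The model

`bdbmi` analyses long-format cohort tables — one row per subject ×
hemisphere × region — from multi-site case-control studies. For a region's
volume $y_{ijh}$ (site $i$, subject $j$, hemisphere $h$, in mm³) the
working model is

$$y_{ijh} = \beta_0 + \beta_g\,\mathrm{case}_j + \beta_b\,\mathrm{BMI}_j +
\beta_a\,\mathrm{age}_j + \beta_s\,\mathrm{female}_j +
\beta_h\,\mathrm{right}_{h} + \beta_v\,\mathrm{ICV}_j + u_i + v_{ij} +
\varepsilon_{ijh},$$

with independent normal random intercepts for site
($u_i \sim N(0,\sigma^2_{\text{site}})$) and subject
($v_{ij} \sim N(0,\sigma^2_{\text{subj}})$) and hemisphere-level residuals
$\varepsilon_{ijh}$. The subject intercept plus hemisphere-level residual
is what "hemisphere nested within subject" means operationally: the two
hemispheres of one subject share $v_{ij}$ and differ by a fixed left/right
offset plus independent noise. Estimation is REML through `lme4` (ML for
likelihood comparisons); group is coded case-positive with the control
group as reference, so a positive $\beta_g$ means larger volumes in cases.

Assumptions worth keeping in mind: volumes are treated as conditionally
normal (lateral ventricles are right-skewed in real data; the pipeline,
like the studies it follows, models them linearly); covariate effects are
shared across sites except for what the random intercept absorbs; and QC
missingness is ignorable given the covariates.

### Degrees of freedom

`lme4` deliberately reports no denominator df. Following the containment
logic of the classical nested-model packages, `fit_lmm()` uses

$$\mathrm{DF} = n_{\text{obs}} - p - (\text{number of random grouping
levels consumed}),$$

with $p$ the number of fixed coefficients. For a complete two-hemisphere
cohort this is roughly the number of subjects minus the number of sites
and coefficients, which reproduces the df magnitudes reported for studies
of this design (≈2280–2420 at 2735 subjects with ~10% region-level QC
loss). A `residual` convention ($n_{\text{obs}} - p$) is available via
`df_method`; at these sample sizes the choice moves p-values in the fourth
decimal.

### Effect sizes

Group contrasts are converted to Cohen's $d$ with the unequal-group-size
form $d = t\,(n_1+n_2)/(\sqrt{\mathrm{DF}}\sqrt{n_1 n_2})$ — the
convention used by the large imaging consortia, and the one that
reproduces published worked examples; the symmetric $2t/\sqrt{DF}$ variant
does not. Its CI uses $\mathrm{SE}_d = \sqrt{(n_1+n_2)/(n_1 n_2) +
d^2/(2(n_1+n_2))}$. BMI associations become partial
$r = t/\sqrt{t^2+\mathrm{DF}}$ with a Fisher-z CI at effective
$n = \mathrm{DF}+2$. Published $d$/$r$ point values and partial-$r$ CIs
reproduce at two decimals from printed coefficients; published $d$ CI
bounds occasionally differ by 0.01 at the second decimal (the source
reports state no CI formula), which is why tests pin the point values.

### Multiplicity and screens

FDR control is Benjamini-Hochberg across the eight regions *within each
model family × term* — the family a reader of a results table implicitly
assumes — not globally across all analyses; α defaults to 0.05 and gating
decisions use adjusted p-values. Interaction screens test (a) a fixed
group × BMI term by its coefficient and (b) BMI × site as an ML
likelihood-ratio test of a random (mean-centred) BMI slope by site. The
null of the slope-variance test lies on the parameter boundary, so its
p-value uses the $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture; a zero LRT
statistic maps to p = 1.

## Mediation

The mediation model asks how much of the total group effect $c$ on a
region travels through BMI: mediator model $\mathrm{BMI} \sim
\mathrm{group} + \mathrm{age} + \mathrm{sex}$ (site intercept) gives path
$a$; the joint outcome model gives path $b$ (BMI → volume) and the direct
effect $c'$; the group-only outcome model gives $c$. Analysis is *gated*
by four criteria — group predicts the volume, group predicts BMI, BMI
stays significant jointly, and the group coefficient is attenuated — so
mediation is never reported where the causal ordering it presumes has no
statistical footing. Suppression (adjustment strengthening the group
effect, the amygdala pattern) fails the fourth criterion by construction.

The indirect effect $a\,b$ gets a percentile bootstrap CI: participants
are resampled with replacement *within sites at the original per-site
counts* (plain resampling can empty a small site and silently drop its
random effect), both hemispheres travel with their subject, and each
replicate refits the three models. The proportion mediated is
$100\,|a b|/|c|$ — magnitudes, so the value is invariant to the group
coding, with an explicit inconsistency flag when signs disagree — and
carries its own percentile interval. A Sobel test
($Z = ab/\sqrt{a^2\mathrm{SE}_b^2 + b^2\mathrm{SE}_a^2}$) is reported as
the conservative analytic cross-check.

Two bootstrap engines are provided. The default `full` engine refits the
hemisphere-level mixed models every replicate — faithful, but thousands of
replicates of three `lmer` fits are expensive. The `collapsed` engine
averages hemispheres to one row per subject and refits OLS with site as a
fixed factor; conditioning on site this estimates the same paths (the
package's tests check the two engines agree within fractions of a
standard error), and it is the engine used for simulation-scale
calibration. Replicates that fail to converge are dropped and counted;
more than 5% dropped aborts the run. One master seed spawns per-replicate
sub-seeds, so enlarging `n_boot` extends rather than reshuffles the
replicate stream and results are bit-reproducible under a seed.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes — not images, not segmentation. Defaults mirror a 17-site cohort
of 2735 individuals: per-group age (35.47 ± 12.63 vs 41.72 ± 12.66 years)
and sex (57.2% vs 60.3% female) distributions, BMI 24.43 ± 4.12 kg/m² in
controls with a +2.37 kg/m² case shift (`path_a`, equal by construction to
the difference of the published group means, so the per-group means and
the explicit mediation path coincide), ICV 1.5 ± 0.15 × 10⁶ mm³
independent of group, and per-region fixed effects whose group/BMI entries
are published *direct* (jointly adjusted) coefficients in case-positive
coding — hence each generated cohort carries a known indirect effect
`path_a * b_bmi`, recorded in its provenance attribute. Age, sex,
hemisphere and ICV coefficients are plausible magnitudes for adult
subcortical anatomy (ventricular expansion with age, near-proportionality
to ICV, small lateral asymmetries) chosen once to shape the covariate
structure; they are not study estimates. Subject-level SDs are scaled so
group-contrast standard errors at full size match published magnitudes,
with site SD ≈ 35% and hemisphere-residual SD ≈ 30% of the subject SD
(site ICC ≈ 10%).

Pragmatic truncations keep draws physical: age in [18, 90], BMI ≥ 14
kg/m², ICV ≥ 8 × 10⁵ mm³, volumes ≥ 1 mm³. The volume floor touches only
the lateral ventricles (≈1–2% of draws under defaults), which biases the
ventricular BMI slope downward by a few percent at most — visible in, and
tolerated by, the recovery simulations. QC missingness removes both
hemispheres of a subject × region jointly (volumes set `NA`), emulating
region-level quality-control withholding; the 10% default reproduces
published df magnitudes. Per-site sample sizes are configurable rather
than guessed (real per-site dispersion is not public); the case/control
split is applied deterministically per site so configured fractions are
exact.

An optional medication model equips cases with 0–3 medication classes and
a lithium flag, either independent (null post-hoc checks) or loaded on a
shared latent driver of medication count, BMI and ventricular volume —
the construction that reproduces the "overlapping R²" phenomenon where
jointly modeling BMI and medications adds almost nothing over either
alone despite both being individually associated.

What the generator does *not* emulate: skewed/heteroscedastic volume
distributions, site differences in covariate effects (unless a random
slope is injected), scanner/protocol effects beyond the site intercept,
non-ignorable QC missingness, and longitudinal structure. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to real-data pathologies.

## Numerical choices and degenerate inputs

* **Exact-fit data.** When the outcome is an exact linear function of the
  fixed design (all variance components zero), REML is ill-posed;
  `fit_lmm()` detects this (residual SD < 1e-10 of the outcome scale),
  returns the OLS solution with zero variance components, and marks the
  fit `degenerate`.
* **Zero-variance columns.** The collapsed mediation engine drops constant
  design columns (e.g. a constant ICV) instead of failing; group and BMI
  must survive or the analysis is undefined.
* **Boundary variance estimates.** Site/subject variances estimated at
  zero are legitimate boundary solutions, reported as zero with the
  singular flag, never perturbed; with a zero site-variance estimate the
  fixed effects coincide with OLS (the standing oracle test).
* **Convergence.** `lmer` convergence warnings set `converged = FALSE` on
  the fit object and propagate; they are never swallowed.
* **R².** Marginal R² is var(fixed predictions) over total variance;
  conditional adds the random-intercept variance to the numerator. Zero
  total variance is reported as `NA` with a warning.
* **Rounding.** Report output rounds half away from zero at two decimals,
  matching the print convention of results tables.
* **WHO BMI categories** use inclusive lower bounds (normal < 25 ≤
  overweight < 30 ≤ obese), underweight folded into "normal" to match the
  three-category convention.

## Problem sizes used by the test suite

Simulation-based checks run at deliberately chosen scales: indirect-effect
recovery and CI coverage at 10 sites × 60 subjects, 200 cohorts,
500-replicate collapsed bootstrap; bootstrap size control under a null
indirect path at 500 cohorts; the FDR global-null check at 5 sites × 30
subjects, 200 cohorts; gate-pattern checks at the full 17 × 161 default.
These sizes give Monte-Carlo error comfortably inside the asserted bands
while keeping the suite runnable in minutes; the acceptance script uses
the same scales with seeds derived from its `--seed` argument.

## Known limitations

Mediation here is associational: with cross-sectional observational data
the $a$ and $b$ paths are not causally identified, and no
sensitivity-to-confounding analysis is included. The df convention is a
documented choice, not an inference about any particular legacy engine.
The collapsed engine conditions on site as a fixed factor, which is not
identical to integrating over a site random effect when sites are tiny.
Cortical measures, shape analysis, and scanner-level moderators are out of
scope.
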