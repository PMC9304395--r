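---
title: "Methods: from force curves to tissue stiffness statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from force curves to tissue stiffness statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechamap)
```

`mechamap` turns raw AFM force–distance curves acquired over a grid on a
tissue section into per-pixel Young's moduli, vets the resulting stiffness
maps, and compares stiffness across tissue types and clinical covariates
with hierarchical gamma models. This vignette records the models, the
tunable parameters, and the numerical and design choices, so that every
number the package produces can be traced to an explicit assumption.

## The contact-mechanics model

A rigid sphere of radius $R$ pressed a depth $\delta$ into an isotropic
elastic half-space experiences the Hertz force

$$F(\delta) = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

with Young's modulus $E$ and Poisson ratio $\nu$. Two assumptions matter in
practice. First, the half-space assumption fails near a rigid substrate;
the fit therefore only uses indentations up to 10% of the section
thickness (2 µm for the default 20 µm sections), where the substrate
contribution is negligible. Second, the model is purely elastic: soft
tissue is also viscoelastic and poroelastic, so the fitted $E$ is an
*apparent* modulus at the acquisition loading rate (2 µm/s by default) and
is comparable only across curves acquired under the same protocol. Only the
approach segment is fitted; the retract segment carries adhesion hysteresis
and is deliberately ignored.

The measured variables are piezo position $z$ and cantilever force $F$; the
indentation depth is not observed directly. With cantilever spring constant
$k$, the piezo travel past the contact point $z_0$ splits into indentation
and cantilever deflection:

$$\delta = (z - z_0) - F/k.$$

$\nu$ is set to 0.5 (incompressible, hydrated soft tissue) and is
configurable; any value used is recorded in the acquisition configuration.

## Per-curve processing

1. **Baseline correction.** A straight line fitted to the pre-contact
   window is subtracted, so the pre-contact force has zero mean; the window
   is located on a noise-adaptively smoothed trace, with the noise level
   estimated robustly from first differences. Curves with less than 0.5 µm
   of identifiable pre-contact travel are declared to be in permanent
   contact — a quality-control verdict, not an error.
2. **Contact-point detection.** The corrected approach force is scanned for
   the first run of at least 5 samples exceeding $3\sigma$ of the baseline
   noise; the contact estimate is the last sample before that run. On very
   noisy curves, where that threshold is never persistently crossed, the
   smoothed rough contact from the baseline stage is used instead.
3. **Joint refinement and fit.** For fixed $z_0$ the Hertz model is linear
   in $(F_0, E)$ after the basis transform $x = \delta^{3/2}$, so the
   profile objective over $z_0$ is cheap. Because the set of samples inside
   the fit window changes discretely as $z_0$ crosses samples, the profile
   is jagged at the sample scale and a blind golden-section search can
   stall; the package scans candidate contact points one sample apart
   across a ±1 µm window and then refines continuously within the winning
   sample (tolerance $10^{-12}$ m). The profile objective is the residual
   *variance* $\mathrm{rss}/(n-2)$, not the raw residual sum: candidate
   contact points admit different numbers of samples, and a late contact
   point with only five points would otherwise win by fitting its own
   noise.
4. **Quality control.** Three exclusion rules, each configurable:
   permanent contact (no pre-contact window); ill-defined contact point
   (less than 2 µm of flat baseline before contact, where "flat" means an
   absolute local slope below $2\sigma_{\text{noise}}$ per µm of the
   corrected force); and excessive noise (pre-contact force SD at least
   $c$ times the trigger force, with $c = 0.25$ operationalizing "noise
   comparable to the trigger"). The rules are deliberately orthogonal: the
   flatness threshold scales with the curve's own noise estimate, so a
   noisy-but-flat baseline trips only the noise rule.

Fits with fewer than five usable depth–force pairs are reported as
non-converged rather than excluded — they fall outside the three exclusion
rules and are tallied separately. A negative unconstrained modulus is
clipped to zero and flagged.

## Map coverage

Quality filtering perforates maps. The coverage index of a map is the mean,
over valid pixels, of the distance to the nearest other valid pixel, on
pixel-centre coordinates $(i + 0.5)\,p$ with pitch $p = 50/10 = 5$ µm
(endpoint-inclusive spacing $50/9$ µm is available by argument). A full
regular grid scores exactly the pitch; higher is sparser. Maps with index
above 8 µm are discarded. Because one description of this rule in the
source protocol reads as "retain index $\le 8$" and another as the
opposite inequality, the package adopts the first (the only one consistent
with "high index = poor coverage"); the threshold and direction are
explicit arguments. A weighted one-way ANOVA (weights = valid-pixel
counts) checks that coverage does not differ by tissue type before maps
are pooled. For display, stiffness maps use a square-root colour scale,
which keeps the many sub-0.1 kPa pixels readable.

## The hierarchical gamma model

Per-pixel moduli are positive, right-skewed, and clustered: pixels within
maps, maps within tissue regions of a patient, patients within a cohort. A
gamma GLMM with log link captures this:

$$E_{ijk\ell} \sim \mathrm{Gamma},\quad
\log \mu = \beta_0 + \beta_{\text{tissue}} + x_i^\top\gamma
           + b_i + b_{it} + b_{m},$$

with independent Gaussian random intercepts for patient ($b_i$),
patient-by-tissue ($b_{it}$, the cross-effect between maps and tissue
types), and map ($b_m$). The model is fitted by penalized
quasi-likelihood: iterate the gamma/log working response
$\zeta = \eta + (y - \mu)/\mu$ against a linear mixed model until the
fixed effects change by less than $10^{-6}$ (relative), capped at 100
iterations. For the gamma/log pair the IRLS weights are identically one,
so the working response is homoscedastic and the inner solve is an
ordinary REML linear mixed model, delegated to `nlme::lme()`. Dispersion
is the moment estimator from Pearson residuals. Fixed effects are tested
with Wald F statistics,
$F = (C\beta)^\top (CVC^\top)^{-1} (C\beta)/q$, preferred over likelihood
ratios because the quasi-likelihood fit has no true likelihood and the
data are overdispersed; denominator degrees of freedom follow the
containment rule of the inner mixed-model solve.

Degenerate random structures are handled explicitly rather than left to
the optimizer: grouping factors with a single level are dropped, as are
nesting levels that add no grouping resolution (for example a map level
when every patient-by-tissue cell holds exactly one map — its variance is
then confounded with the parent level). With no random structure left, the
model collapses to an ordinary gamma GLM, which is also the exact limit of
PQL at zero random-effect variance; the test suite checks both this
collapse and the agreement of the full fitter with an independent PQL
implementation.

Three table-shaped analyses sit on top of the fitter:

* **Variability** (per tissue type): the *Map* row fits map identity as a
  fixed effect with a patient random intercept, the *Patient* row patient
  identity with a map random intercept. The source protocol describes the
  fixed/random roles for these analyses in two conflicting ways; both
  presets exist and the two-row layout reports one of each.
* **Tissue contrasts**: tissue fixed, patient / patient-by-tissue / map
  random; distal and proximal normal epithelium may be pooled into
  "normal", and tumor epithelium plus stroma into "T+S".
* **Clinical associations**: tumor-compartment observations (tumor
  epithelium, stroma, mixed zones) against one covariate at a time, with
  patient and map random intercepts. Reference levels: female, left colon,
  stage I+II, MSI. The one-at-a-time layout follows the per-covariate
  sample sizes of the original analysis; no multiplicity correction is
  applied, matching it.

## What the generator emulates — and what it does not

The synthetic-data generator is the package's test bed and defines the
study conditions:

* **Acquisition:** 10.2 µm bead, spring constant 0.2 N/m (within the
  calibrated 0.15–0.24 N/m range), 2 nN trigger, up to 50 µm ramps,
  10 × 10 pixels over 50 × 50 µm, 20 µm sections, 10 nm piezo sampling.
* **Stiffness scale:** normal mucosa mean 0.07 kPa (soft tissue, below
  0.1 kPa); log-scale tissue effects tumor epithelium +0.192, stroma
  +2.18, mixed +1.75; clinical effects left location +0.564, stage III+IV
  +0.90, RAS +0.498, perinervous infiltration +0.625.
* **Random structure:** patient SD 0.6, patient-by-tissue SD 0.1, map SD
  0.2 on the log scale, gamma shape 2. The two smaller SDs were set, before
  any acceptance run, so that a study-sized design (20 patients, one map
  per tissue, ~56 values per map) yields a tumor-vs-normal contrast
  standard error near 0.08 — the uncertainty scale of the original
  contrast estimates.
* **Filtered-map sizes:** per-map value counts drawn around a median of
  56, truncated to 21–93.
* **Noise and artifacts:** 20 pN Gaussian force noise (a plausible floor
  for soft cantilevers in liquid; no measured figure exists), a single
  negative adhesion well on retract, and three artifact kinds that each
  violate exactly one QC rule.

Deliberately *not* modelled: viscoelastic or rate-dependent response,
piezo drift, tip contamination dynamics, spatial autocorrelation of the
true stiffness field (independent pixels by default; a smoothed-field
switch exists for robustness experiments), and probe-to-probe offsets
(exposed, default zero, as no quantification exists). Passing tests
therefore demonstrate correctness of the *computational* chain under an
idealized elastic, artifact-injected instrument — they do not validate the
elastic model itself against real viscoelastic tissue.

## Simulation suite sizes and calibration checks

The statistical machinery is checked by simulation, with sizes chosen to
give informative Monte-Carlo precision at desk scale:

* **Type-I error:** 500 null datasets (all fixed effects zero, random SDs
  at defaults) at the package's default design — 20 patients × 4 maps with
  study-sized per-map value counts; the Wald F rejection rate at
  $\alpha = 0.05$ must lie in $[0.03, 0.08]$. At this size the test is
  essentially nominal; at much smaller designs (8 patients) the containment
  Wald F becomes conservative, with a true size near 0.03.
* **Sign recovery:** 200 datasets of 20 patients × 4 maps at study-sized
  value counts, generated with the default (study-scale) effects; the
  stroma, tumor-epithelium and stage contrasts must recover the true sign
  in at least 95% of runs. The tumor-epithelium effect (+0.192 at SE
  ≈ 0.08) is the binding case; the stage effect, identified only between
  patients, sits nearest the threshold.
* **Oracle equivalence:** on 20 noiseless fixtures the full fit must agree
  with a brute-force $(E, z_0)$ grid search (0.2% modulus steps, 0.1 nm
  contact steps) within the grid's own resolution, and never achieve a
  worse residual sum than the exhaustive search.

## Known limitations

* PQL is approximate; its fixed-effect estimates carry small-sample bias
  for strongly non-normal responses, which is why parameter recovery is
  asserted on signs and calibrated coverage rather than exact values.
* The containment degrees of freedom are one defensible convention among
  several (Satterthwaite and Kenward–Roger are not available for PQL
  fits); p-values near a decision boundary should be read accordingly.
* The coverage-index monotonicity (removing pixels never improves
  coverage) is checked empirically on regular-grid fixtures; it is not a
  theorem for arbitrary point patterns.
* Vendor binary force-curve formats are out of scope; ingestion is a
  documented TSV dialect (`curve_id, segment, z_nm, force_pN`), and
  converters from vendor formats must be supplied externally.
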