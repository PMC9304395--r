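# mechamap

Micromechanical stiffness mapping of soft tissue from AFM force spectroscopy.

Colon tissue — like most soft tissue — is mechanically heterogeneous, and its
stiffness changes with disease: tumors are stiffer than normal mucosa, and
the stromal compartment is stiffer still. Atomic force microscopy (AFM)
measures this directly: a colloidal bead glued to a soft cantilever indents
the tissue at each pixel of a grid, and the recorded force–distance curve is
converted into a local Young's modulus. `mechamap` implements the full
computational chain for such experiments, for biophysicists and
biostatisticians who need a tested, reproducible pipeline:

1. **Synthetic cohorts and raw force curves.** Virtual patients with
   clinical covariates, per-map gamma-distributed ground-truth stiffness
   fields with patient / patient×tissue / map random structure, and
   simulated indentation cycles (flat baseline, Hertzian loading with
   cantilever-deflection coupling, force trigger, retract with adhesion),
   including deliberately corrupted curves for testing the quality filters.
2. **Curve processing.** Baseline correction, contact-point detection, the
   piezo-to-indentation conversion `δ = (z − z₀) − F/k`, and a least-squares
   fit of the Hertz spherical-indenter model
   `F = (4/3)·E/(1−ν²)·√R·δ^{3/2}` with the contact point refined jointly
   with the modulus. Three quality-control rules exclude curves in permanent
   contact, with an ill-defined contact point (less than 2 µm of flat
   baseline), or with force noise comparable to the trigger.
3. **Map quality control.** A nearest-neighbour *coverage index* (mean
   distance from each valid pixel to its nearest valid neighbour, µm);
   maps with index above 8 µm are discarded. A square-root display
   transform and heatmaps for visualisation, and a weighted ANOVA checking
   that coverage does not differ between tissue types.
4. **Hierarchical statistics.** A gamma generalized linear mixed model
   (log link) fitted by penalized quasi-likelihood (PQL), with Wald F tests
   for fixed effects: intra-/inter-patient variability per tissue, tissue
   contrasts (stroma vs tumor epithelium vs normal), and one-at-a-time
   clinical covariate associations (location, stage, RAS status, ...), plus
   a clinical baseline descriptive table.

Everything is tibble-in/tibble-out and pipe-friendly; model objects have
`tidy()` and `glance()` methods.

## Worked example

```r
library(mechamap)
cfg <- afm_config()   # 10.2 µm bead, k = 0.2 N/m, 2 nN trigger, 10x10 grid

# one synthetic indentation cycle on 1.2 kPa tissue, and its Hertz fit
fc  <- simulate_force_curve(E_true = 1200, cfg, seed = 42)
fit <- fit_hertz_curve(fc, cfg)
fit
#> <hertz_fit>
#>   E = 1192 Pa (1.192 kPa), F0 = 5.72e-12 N
#>   contact point z0 = 24.9999 um
#>   rss = 2.89e-20 N^2 on 58 samples (delta <= 2 um)
```

The fitted modulus (1.192 kPa) recovers the simulated truth to within the
20 pN force noise, and the contact point lands on the simulated 25 µm mark.

```r
# a full force map with 10 deliberately noisy curves
field <- simulate_stiffness_field(log(0.8), gamma_shape = 2, seed = 42)
fm <- simulate_force_map(field, cfg,
                         artifact_kinds = c(rep("clean", 90),
                                            rep("high_noise", 10)),
                         seed = 42)
px <- process_map(fm$curves, fm$manifest, cfg)
attr(px, "exclusions")
#> permanent_contact ill_defined_contact     too_noisy  non_converged  passed
#>                 0                   0            10              0      90
coverage_index(px, pitch_um = cfg$pitch_um)
#> # A tibble: 1 × 8
#>   map_id n_valid index_um retained ...
#> 1 M1          90        5 TRUE     ...
```

All ten corrupted curves are rejected by exactly the noise criterion; with
90 of 100 pixels left the coverage index is still 5 µm (every valid pixel
has a neighbour one pitch away), comfortably under the 8 µm retention
threshold.

```r
# tissue contrasts on a simulated 12-patient cohort
obs <- simulate_observations(n_patients = 12, maps_per_patient = 4, seed = 42)
tissue_contrasts(obs, reference = "normal")
#> # A tibble: 3 × 5
#>   contrast                    beta     sd t_value  p_value
#> 1 mixed vs normal            1.76  0.0963   18.3  7.57e-19
#> 2 stroma vs normal           2.16  0.0973   22.2  2.01e-21
#> 3 tumor_epithelium vs normal 0.170 0.0965    1.76 8.71e- 2
```

The recovered log-scale contrasts sit close to the generator's truths
(mixed +1.75, stroma +2.18, tumor epithelium +0.192): stroma is roughly
`exp(2.16) ≈ 9` times stiffer than normal epithelium, while the tumor
epithelium effect is small and, at 12 patients, borderline.

`run_pipeline()` chains all stages (simulate → process → map QC → statistics)
and writes curves (TSV), result tables (CSV) and a JSON run summary.

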