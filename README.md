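# annulusEKF

Fully automatic measurement of the **aortic annulus diameter** in 3D
transoesophageal echocardiography (TEE) volume sequences.

Sizing the annulus — the virtual ring at the base of the aortic valve — is
the critical measurement before transcatheter aortic valve implantation
(TAVI): an implant chosen from a wrong diameter risks paravalvular
regurgitation. This package measures it with no user interaction beyond a
rough initialization (an estimated LVOT long axis, an annulus centre guess
and an initial diameter), and is aimed at researchers in cardiac image
analysis who need a reproducible, scriptable annulus measurement or a
reference implementation of Kalman-filtered deformable-surface tracking.

## Method

The left ventricular outflow tract (LVOT) and aortic root are modelled as a
cylindrical **Doo-Sabin subdivision surface** (5 rings × 6 control points)
deformed by

* 30 local states `x_l` — signed radial offsets of the control points — and
* 7 global states `x_g = [t_x, t_y, t_z, s, θ_x, θ_y, θ_z]` of a similarity
  transform `T_g(p) = s R_x R_y R_z p + t`,

with the annulus represented by a rigid disc in the model mid-plane. An
**extended Kalman filter** estimates `x = [x_g; x_l]` over the cardiac
cycle: a motion model `x̂_{k|k-1} = A x̂_{k-1|k-1} + (I − A) x_{0,k}`,
`P_{k|k-1} = A P A' + Q_{0,k}` predicts each frame; edge displacements
`v_i` detected along surface normals (least-squares step/peak profile fits,
outlier rejection, variances normalized to `Σ r_i = r_edge`) update it in
information form,

    P_{k|k}^-1 = P_{k|k-1}^-1 + Σ_i h_i r_i^-1 h_i',     h_i = J_i' n_i
    x̂_{k|k}   = x̂_{k|k-1} + P_{k|k} Σ_i h_i r_i^-1 v_i.

Segmentation is two-phase — a **stiff** pass (pose only, ±14 mm edge
capture range) followed by a **deformable** pass with bidirectional
tracking, forward and backward estimates fused per frame by precision
weighting `P_k = (P_f^-1 + P_b^-1)^-1`. The annulus is quantified by
intersecting the fitted surface with the disc plane and fitting an ellipse
(direct conic fit + Sampson refinement); the **perimeter-derived diameter**
(perimeter/π) at mid-systole (the maximum-area frame) is the main output.

A seeded synthetic TEE phantom generator with exact ground truth (bright
tube wall with annulus waist and sinus bulge, rigid motion, pulsation,
Rayleigh speckle, optional dropout and stitching artifacts) stands in for
patient data in all tests.

## Worked example

```r
library(annulusEKF)

# a noiseless static phantom: 25 mm annulus, 5% pulsation peaking at frame 4
ph  <- generate_phantom(phantom_config(speckle_level = 0, translation_amp = 0,
                                       rotation_amp_deg = 0), seed = 1)
fit <- fit_annulus(ph$sequence, annulus_init(center = c(0, 0, 0)))
summary(fit)
```

```
Mid-systolic annulus measures (frame 4 ):
  major diameter      25.81 mm
  minor diameter      25.74 mm
  area                521.7 mm^2
  perimeter            81.0 mm
  area-derived D      25.77 mm
  perimeter-derived D 25.77 mm  (main output)

Per-frame measurements:
 frame valid  area perimeter area_derived_d perimeter_derived_d
     1  TRUE 483.9     77.98          24.82               24.82
     2  TRUE 495.1     78.88          25.11               25.11
     3  TRUE 512.7     80.26          25.55               25.55
     4  TRUE 521.7     80.97          25.77               25.77
     ...
```

The fit found mid-systole at the programmed pulsation peak (frame 4) and
measured a perimeter-derived diameter of 25.77 mm against a ground truth of
26.25 mm (−1.8%). `coef(fit)` returns the per-frame state estimates,
`plot(fit)` the diameter curve over the cycle, `predict(fit)` the fitted
surfaces, and `write_results(fit, "out/")` a CSV/JSON/VTK result set.

A command-line front-end is included:

```sh
Rscript inst/cli/annulus-tool.R phantom --out seq.nii.gz --seed 1
Rscript inst/cli/annulus-tool.R segment --input seq.nii.gz --out results/
Rscript inst/cli/annulus-tool.R sensitivity --input seq.nii.gz --protocol rotation --reps 50 --seed 42 --out sens.json
```

## Package layout

| Area | Files |
| --- | --- |
| Surface model (Doo-Sabin mesh, sampling, Jacobians) | `R/mesh.R` |
| Global similarity transform | `R/transform.R` |
| Volumes and trilinear interpolation | `R/volume.R` |
| Edge detection | `R/edges.R` |
| Kalman engine (predict/update/assimilate) | `R/kalman.R` |
| Two-phase pipeline, `fit_annulus()`, sensitivity | `R/pipeline.R` |
| Annulus extraction and ellipse measures | `R/annulus.R` |
| Synthetic phantom generator | `R/phantom.R` |
| I/O (NIfTI, VTK/OBJ, JSON/YAML), CLI | `R/io.R`, `inst/cli/` |
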