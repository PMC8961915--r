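# kneelkin

Tibiofemoral kinematics and contact-point analysis of deep kneeling
(Seiza) from single-plane lateral fluoroscopy, with a fully synthetic
test bed.

## What it does, and for whom

Knee biomechanics groups study deep flexion by matching CT-derived 3D
bone models to lateral fluoroscopic silhouettes (2D/3D registration),
expressing the recovered femur-relative-to-tibia motion in the
Grood–Suntay joint coordinate system (JCS), and locating the medial and
lateral tibiofemoral contact points (CPs) from bone-surface proximity.
`kneelkin` is an R implementation of that chain for the kneeling motion
(flexion 90° → maximum flexion ≈ 161° → 90°), aimed at researchers who
want a reproducible, testable reference for each stage:

* **Synthetic knee generator** — parametric bone meshes with analytic
  landmarks, ground-truth six-DOF trajectories shaped by published
  per-angle kneeling means, and perspective silhouette renderings
  (1024×1024 px, 0.42 mm pitch, 5 Hz).
* **Silhouette registration** — recovers each bone's six-DOF pose per
  frame by derivative-free minimization of
  `w1·(1 − IoU) + w2·(mean symmetric contour distance)`.
* **JCS kinematics** — exact compose/decompose of the six degrees of
  freedom (flexion, varus–valgus, internal–external rotation; AP, ML,
  IS translation), B-spline smoothing, and resampling on the 5° flexion
  grid from 100° to per-subject maximum flexion, interpolation only.
* **Contact points** — per-frame tibial-face proximity maps, the
  subject-specific contact threshold (smallest distance giving contact
  in every frame, in vivo 5.5–7.0 mm), area-weighted CP centroids on
  the tibial X–Y plane.
* **Phase statistics** — per-angle paired t-tests between the flexion
  and extension phases and an overall mixed-model difference
  (random subject intercept, REML, Wald-type 95% CI).

The JCS convention: rotations about the femoral X axis (e1, flexion),
the tibial Z axis (e3, axial rotation), and varus–valgus as
∠(e1,e3) − 90°; translations are the components of the origin offset in
the (e1, e2, e3) basis with e2 = e3 × e1. Signs: plus = posterior /
medial / superior translation, plus = varus / external rotation.

## Worked example

Simulate a small cohort with table-shaped ground truth, run the
analysis from ground-truth poses, and summarize:

```r
library(kneelkin)
study <- run_pipeline(pipeline_config(n_subjects = 3, seed = 1,
                                      registration = "truth"))
study
```

```
<kneel_study> 3 subjects, poses from truth 
  contact thresholds (mm): 6.4 6.2 6.0 
  posterior  range: flexion   37.5  extension  -36.4
  external   range: flexion   19.8  extension   -7.4
  superior   range: flexion   -4.7  extension    4.1
  varus      range: flexion   -5.9  extension    4.8
  medial     range: flexion    5.8  extension   -7.6
  medial_cp  range: flexion  -21.2  extension   26.2
  lateral_cp range: flexion  -37.7  extension   28.5
```

Reading this: over the flexion phase (100° to maximum flexion) the
simulated femur translates 37.5 mm posteriorly and rotates 19.8°
externally relative to the tibia, and returns 36.4 mm / 7.4° in the
extension phase — exactly the ranges of the cohort-mean curves used as
ground truth. Contact thresholds land inside the in vivo 5.5–7.0 mm
band. The CP ranges come from the synthetic primitive geometry: with
spherical condyles centred on the flexion axis the contact point tracks
the femoral origin's AP travel, so CP excursions are several times the
in vivo ones, while the qualitative pattern (the lateral CP travels
farther posteriorly than the medial CP in flexion) is preserved.
Per-angle tables with n, means, SDs, p-values and significance stars
are in `study$tables`; overall mixed-model phase differences with 95%
CIs are in `study$overall`.

To run the same cohort through actual image-based registration instead
of ground-truth poses:

```r
study <- run_pipeline(pipeline_config(n_subjects = 3, seed = 1,
                                      registration = "silhouette"))
```

(several seconds of simplex optimization per tracked frame).

## Documentation

The methods vignette (`vignettes/kneeling-analysis.Rmd`) documents the
models, conventions, default parameters and their rationale, numerical
choices, and known limitations of the synthetic test bed.
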