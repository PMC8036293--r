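# kerato3d

Automated keratoconus screening and staging from two ordinary eye
photographs — one frontal, one lateral — for vision researchers and
image-analysis developers who want corneal-shape severity grading without
topography hardware.

Keratoconus thins the cornea and bulges it into a cone. This package
reconstructs the corneal surface in 3D from the two orthogonal views and
grades severity from its geometry:

1. **Iris detection** — circular Hough transform on the frontal view.
   For a circle of radius $r$ centred at $(m, n)$,
   $(x - m)^2 + (y - n)^2 = r^2$; the accumulator over $(m, n, r)$ counts
   supporting edge pixels and its arg-max is the iris.
2. **Cross-view features** — difference-of-Gaussian keypoints with
   128-dimensional gradient descriptors, matched by the nearest-neighbour
   distance-ratio test.
3. **Corneal depth** — from the lateral profile's apex $p_1$ and limbus
   chord endpoints $p_2, p_3$ with midpoint $C$:
   $d = \sqrt{|p_1 p_2|^2 - |p_2 C|^2}$ (Pythagoras on the apex
   triangle).
4. **3D fusion** — a translational transform aligns the orthogonal views
   (frontal supplies $x, y$; the lateral abscissa supplies depth $z$) and
   the corneal surface is rasterised into a volume.
5. **Curvature staging** — the apex angle
   $\theta = \arccos\big((d_2^2 + d_3^2 - d_1^2)/(2 d_2 d_3)\big)$, the
   angle of curvature $180^\circ - \theta$, and the steepest tangent
   slope against the limbus plane; the slope is graded
   **mild** $< 45^\circ \le$ **moderate** $\le 52^\circ <$ **severe**,
   with **normal** when no cone is detected at all.
6. **Volumetric CNN** (optional) — a 3D convolutional network
   (4 conv 3×3×3 blocks of 96/128/256/512 kernels + 2×2×2 max pools, two
   1000-wide fully connected layers, softmax over the four stages; SGD,
   batch 32, learning rate 0.01, ≤ 30 epochs) classifying reconstructed
   corneal volumes.

A parametric **eye-phantom generator** renders frontal/lateral views and
3D volumes with analytically known iris circle, corneal depth and
steepest slope, so the whole chain is testable end to end without any
clinical data. An **evaluation module** provides confusion matrices,
accuracy/sensitivity/specificity, stratified k-fold cross-validation,
Pearson correlation and Bland–Altman limits of agreement.

## Worked example

```r
library(kerato3d)

spec <- eye_phantom_spec(stage = "moderate", steepness_angle_deg = 48)
res  <- run_case(render_frontal(spec), render_lateral(spec), case_id = "demo")
res
#> case demo: stage moderate (steepness 48.3 deg, depth 37.6 px) [low_matches,geometric_alignment]
res$iris
#> iris circle: centre (row n=128, col m=128), r=34 px, votes=0.964
res$staging$triangle
#> curvature triangle: d1=67.81 d2=50.64 d3=50.64 -> theta=84.07 deg, angle of curvature=95.93 deg
```

The phantom was built with a true steepest slope of 48°; the pipeline
detects the iris (34 px, matching the spec), measures a corneal depth of
37.6 px from the lateral profile, reads the steepest slope back as 48.3°
and therefore grades the case moderate (45–52° band). The `qc_flags`
record that too few cross-view keypoint matches survived the ratio test
on this texture-less synthetic eye, so the view alignment fell back to
the iris/chord geometry. `res$volume` holds the reconstructed 64³
corneal volume, ready for `cnn_predict()` after `preprocess_volume()`.

Batch runs work from a manifest:

```r
coh <- generate_cohort(10, seed = 42)   # 40 phantoms, 10 per stage
run <- run_cohort(coh)
run$accuracy
#> [1] 100
run$confusion$counts                    # 4x4 actual x predicted
```

A thin command-line front end with the same operations lives at
`inst/cli/kerato3d.R` (`simulate`, `detect-iris`, `depth`, `stage`,
`run`).

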