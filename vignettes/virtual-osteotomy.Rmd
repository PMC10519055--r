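---
title: "Methods: virtual opening-wedge osteotomy and TT-TG metrology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual opening-wedge osteotomy and TT-TG metrology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owosim)
```

## The procedure being simulated

A lateral opening-wedge distal femoral osteotomy (LDF-OWO) corrects genu
valgum by opening a wedge on the lateral cortex of the distal femur and
rotating the distal fragment into varus about a medial hinge. The package
simulates this as pure rigid-body geometry on landmark models:

1. **Plan construction.** The osteotomy trajectory runs from an entry point
   2 cm proximal to the lateral epicondyle toward the medial cortex at the
   adductor-tubercle level (the apex/hinge). The osteotomy plane contains
   both points and is parallel to the anteroposterior axis. The rotation
   pivot sits 1 cm from the medial cortex at the apex, on the plane.
2. **Fragment classification.** Landmarks below the plane belong to the
   distal fragment; the tibia is merged with it (it moves simultaneously),
   so tibial landmarks are distal unconditionally.
3. **Varus rotation.** The distal fragment rotates by θ about the
   anteroposterior (+y) axis through the pivot — an exact coronal-plane
   rotation with no out-of-plane component, applied to the *native* model
   at every scheduled angle (0–12° in 2° steps by default).
4. **Measurement.** At each angle the posterior condylar line (PCL) is
   re-derived from the rotated condylar landmarks, projected into the fixed
   axial (xy) plane, and the TT-TG distance is the component of the axial
   TT−TG offset along the PCL direction.

Wedge-gap mechanics, hinge deformation and bone contact are deliberately
not modelled: the transformation is a pure rotation, which is exactly what
an interactive rotation in a 3D planning program does.

## Coordinate conventions and signs

The canonical frame is that of a **right knee**: +x lateral, +y anterior,
+z proximal, millimetres, knee centre near the trochlear groove. Left knees
are mirrored (x → −x) at ingest, processed in the canonical frame, and
re-mirrored on output; the test suite proves the two paths agree in
magnitude at every angle.

A **positive varus angle displaces points distal to the pivot medially**
(−x), which is the correction sense for a valgus knee. The measured TT-TG
distance is signed, positive when the tuberosity lies lateral to the
groove; report layers round to 0.1 mm for display while all computation
keeps full precision.

## The crux: measurement in the fixed axial plane

The measurement plane is the **fixed scanner axial plane**, and the PCL
direction is re-derived from the *rotated* condylar landmarks at each
angle. This convention is what produces the pendulum effect: both TT and
TG ride on the distal rigid body, so a coronal tilt changes their apparent
mediolateral separation in a fixed viewing plane even though their true 3D
distance is invariant. The alternative convention — re-anchoring the
measurement plane perpendicular to the rotated femoral axis — would undo
the tilt and null the effect entirely. Since the per-angle decrease is the
phenomenon of interest, the fixed-plane convention is the decision the
whole result hinges on, and it is recorded here explicitly.

Measuring along the PCL direction is mathematically identical to the
common construction of two parallel planes perpendicular to the posterior
plane through TG and TT; the projection form needs fewer constructions and
yields the same number.

With `m` the PCL vector and `v` the TT−TG vector, the closed form is

$$\mathrm{TTTG}(\theta) = \langle P_{xy} R_\theta v,\;
\widehat{P_{xy} R_\theta m} \rangle$$

which for a purely mediolateral `m` and `v = (a, v_y, -b)` reduces to
`a·cosθ − b·sinθ`. The full 3D pipeline agrees with this closed form to
1e−6 mm on noise-free knees (an invariant in the test suite), and the
measured value is provably independent of the pivot location — only
absolute positions, not the TT−TG and PCL *vectors*, depend on the pivot —
which the tests confirm to 1e−9 mm under randomized pivots.

## Generator calibration

`generator_params()` defaults define the study conditions:

| parameter | default | units | why |
|---|---|---|---|
| `n_subjects` | 6 | — | cohort size of the reference study population |
| `tttg_mean`, `tttg_sd` | 21.0, 2.1 | mm | reference cohort native TT-TG |
| `tttg_range` | [18, 24] | mm | printed min–max; enforced by truncation |
| `groove_tuberosity_dz_mean` | 47.0 | mm | solved from `21·cos12° − b·sin12° = 10.8` so a noise-free knee lands on the reference 12° mean |
| `groove_tuberosity_dz_sd`, range | 3.0, [40, 58] | mm | plausible anatomical spread of the longitudinal TG–TT offset |
| `condylar_halfwidth` | 22 | mm | posterior condyles at x = ±22 |
| `posterior_offset` | −35 | mm | condylar posterior landmarks' y |
| `hka_mean`, `hka_sd`, `hka_range` | 3.2, 1.1, [1.5, 6] | ° | valgus alignment of the reference cohort; sd chosen as ≈ quarter-range since only mean and range are reported |
| `ldfa_mean`, `mpta_mean` | 82.2, 87.7 | ° | deformity descriptors, carried as metadata |
| `condyle_dz_jitter_sd` | 1.0 | mm | longitudinal jitter of condylar landmarks, so the PCL is not artificially exact |

Sampling is truncated-normal by rejection, so every draw honours the
printed ranges; a configuration whose range excludes the mean by more than
6 sd is rejected as a generator error. One seed governs a cohort, and each
subject draws from a deterministic substream indexed by subject id, so
reproducibility does not depend on draw order; the caller's RNG state is
saved and restored.

Two calibration facts worth stating plainly:

* Symmetric truncation leaves the **mean** at 21.0 mm (the acceptance
  quantity), but shrinks the realized **sd** below the nominal 2.1 mm
  parent value (analytically ≈ 1.5 mm at the default ±1.43 sd window). No
  symmetric unimodal distribution on [18, 24] can have sd 2.1; a printed
  sample sd of 2.1 at n = 6 is compatible with sampling variability. The
  tests therefore assert the mean against 21.0 and the sd against the
  analytic truncated-normal value, not the parent value.
* HKA is a cohort descriptor, not an input to the TT-TG computation. It
  tilts the tibial shaft landmark (`lat_tibial_condyle_posterior`) about
  the knee centre; the tuberosity itself is placed directly at
  `(TT-TG, y, −dz)` because the sampled TT-TG *is* the net transverse
  lateralization, and the oracle equivalence requires the longitudinal
  offset to equal `dz` exactly. Tilting the tuberosity too would make the
  sampled target and the measured native value disagree.

### What the generator emulates, and what it does not

It reproduces the landmark geometry that the per-angle TT-TG trajectory
depends on: native TT-TG, the longitudinal TG–TT offset, condylar width
and posterior position, and cohort-level alignment statistics. It does
**not** emulate real bone surfaces, trochlear dysplasia, torsional
deformity, patellar geometry, or correlations between TT-TG and alignment
within a subject (draws are independent). Passing tests demonstrate the
rotation/measurement machinery and the statistical pipeline are correct
under these conditions; they do not validate the generator against any
individual patient anatomy, and the condylar dimensions are
literature-plausible constants, not fitted values. The parametric mesh
layer (ellipsoid condyles, cylindrical shaft, slab tibia) exists to
exercise the mesh-mode landmark-extraction path, not for visual realism.

## Statistical dialects

* **Wilcoxon signed-rank, exact (default).** Full enumeration of the
  `2^n` sign assignments of the ranked absolute differences (subset-sum
  dynamic programming over doubled ranks, so average ranks under ties are
  handled); two-sided p = `2·min(P(T⁺≤t), P(T⁺≥t))` capped at 1. For six
  uniform-sign pairs this gives the floor p = 2/64 = 0.03125.
* **Wilcoxon signed-rank, normal.** Large-sample z with tie-corrected
  variance and *no* continuity correction — the dialect of common
  commercial packages, which for six uniform-sign pairs prints ≈ 0.0277.
  Both dialects are provided because published tables produced with such
  software show 0.026–0.027 where exact enumeration gives 0.03125; the
  package is transparent about that reproducibility gap rather than
  resolving it silently. Zero differences are dropped before ranking in
  both dialects.
* **Headline correlation.** Pearson r is computed on the seven per-angle
  *means* (angle vs mean TT-TG), the reading under which direct
  recomputation from the reference per-angle means reproduces the printed
  −0.991; the per-2° slope is the mean successive difference of those
  means, algebraically `(last − first)/6`.
* **No multiple-testing correction** is applied, matching the source
  analysis; the summary reports the number of uncorrected comparisons.
* **Fisher-z sample size.** `n = ⌈((z_α + z_β)/C)² + 3⌉` with
  `C = atanh(r)`. For r = 0.9, α = 0.05, power 0.8 this yields 6
  one-tailed but 7 two-tailed. Published calculations sometimes quote
  "two-tailed" alongside n = 6, which only the one-tailed formula
  produces; the discrepancy is surfaced here rather than hidden, and the
  package default is one-tailed.

## Numerical choices

* Geometric identity tolerance 1e−9 mm; degeneracy thresholds 1e−6 mm²
  (triangle area) and 1e−6 mm (coincident axial projections) — double
  precision leaves ~6 orders of headroom at anatomical scale.
* Rotations are applied to the native model at each scheduled angle rather
  than compounding rotated models; the two are equivalent by the
  composition property (tested to 1e−9 mm) and the former avoids error
  accumulation.
* The pivot is placed 10 mm from the apex along the entry→apex direction
  projected into the coronal (xz) plane. Only the offset magnitude is
  anatomically specified; the direction is a free choice that the
  pivot-invariance property makes immaterial to the measured TT-TG, which
  the tests prove by randomizing the pivot.
* The hinge landmark (`medial_cortex_apex`) lies on the osteotomy plane by
  construction and is labelled *proximal*: the hinge cortex stays attached
  and undisplaced in an opening wedge. Any other landmark within 1e−9 mm
  of the plane raises an ambiguity error instead of being silently
  assigned.
* Mesh landmark extraction breaks posterior-extremum ties (within 1e−9 mm)
  by lowest vertex index, so extraction is deterministic; condylar
  ellipsoids are oriented with a mesh vertex exactly at their posterior
  pole, so extraction is exact at any resolution.
* A single observation's sd is reported as 0 with a warning; single-subject
  cohorts emit descriptives with tests marked not applicable.

## Problem sizes

The test suite exercises 4,000-draw calibration checks and 200-cohort
(1,200-knee) significance/calibration sweeps; property tests loop over
10–25 randomized cases under fixed seeds. The acceptance script simulates
200 six-knee cohorts through the full seven-angle schedule. These sizes
give Monte-Carlo standard errors well inside the asserted tolerances
(≈ 0.04 mm for the 1,200-knee mean) while keeping a full run in seconds.

## Known limitations

* Individual-level reproduction of the reference cohort is impossible — no
  per-patient values are published — so validation rests on summary
  statistics plus exact structural properties.
* The 47 mm longitudinal offset default is calibrated from the reference
  12° endpoint; the 12°-mean agreement therefore validates the
  rotation/measurement machinery, not an independent anatomical
  prediction.
* The osteotomy is modelled as a pure rotation of a half-space of
  landmarks; there is no wedge gap, hinge compliance, or soft-tissue
  constraint.
* Landmarks are points, not surfaces: "deepest groove point" and
  "tuberosity midpoint" identification error, a real source of variance in
  imaging studies, is outside the model (the condylar z-jitter parameter
  is the only observer-noise surrogate).
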