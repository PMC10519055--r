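# owosim — virtual distal femoral osteotomy simulation and TT-TG metrology

`owosim` is an R package for surgeons and musculoskeletal researchers who
want to quantify how a **lateral opening-wedge distal femoral osteotomy
(LDF-OWO)** — the standard varus-producing correction for genu valgum —
changes the **tibial tuberosity–trochlear groove (TT-TG) distance**, the
axial-plane measurement that drives decisions about tibial tuberosity
medialization in patellar instability.

## The model

The TT-TG distance is the mediolateral component of the offset between the
tibial tuberosity midpoint (TT) and the deepest point of the trochlear
groove (TG), measured in the fixed axial plane along the posterior condylar
line (PCL). After an LDF-OWO, the distal femoral fragment and the tibia
move as one rigid body: both TT and TG sit distal to the osteotomy, so
their true 3D separation never changes. What changes is the *projection*:
tilting the rigid body by a varus angle θ in the coronal plane swings the
TT–TG offset vector like a pendulum relative to the fixed axial measurement
plane. With native TT-TG distance *a* (mm) and longitudinal
groove-to-tuberosity offset *b* = z(TG) − z(TT) (mm),

```
TT-TG(θ) = a·cos θ − b·sin θ
```

Because *b* ≈ 45–50 mm dwarfs *a* ≈ 21 mm, the sin θ term dominates and the
TT-TG distance falls steeply — about 1.7 mm per 2° of varus for a typical
valgus knee — even though no bone was moved mediolaterally.

The package provides:

* an exact 3D simulation: synthetic knee landmark models, osteotomy plane
  and hinge-pivot construction, rigid Rodrigues rotation of the distal
  fragment about an anteroposterior axis, and PCL-referenced axial
  measurement (`sample_knee`, `build_osteotomy_plan`, `apply_varus`,
  `measure_tttg`, `run_schedule`);
* the closed-form pendulum model (`closed_form_tttg`) and a least-squares
  estimator of (*a*, *b*) from a measured series (`pendulum_fit`), with the
  usual `coef`/`predict`/`residuals`/`plot` methods;
* a calibrated synthetic cohort generator (native TT-TG 21.0 mm truncated
  to 18–24 mm, HKA 3.2° valgus in 1.5–6°) so the whole pipeline is testable
  without patient imaging (`generator_params`, `sample_cohort`);
* cohort statistics mirroring the standard repeated-measures table: per-angle
  descriptives, paired Wilcoxon signed-rank tests (exact enumeration and
  SPSS-style normal dialects), Pearson correlation of angle vs mean TT-TG,
  per-2° slope, and a Fisher-z sample-size calculator
  (`summarize_cohort`, `wilcoxon_signed_rank`, `sample_size_correlation`);
* an optional parametric triangle-mesh layer with STL I/O and
  posterior-condyle landmark extraction (`build_parametric_mesh`,
  `extract_posterior_landmarks`, `write_stl`).

## Worked example

Generate a seeded six-knee valgus cohort, simulate the 0–12° schedule in 2°
steps, and summarise:

```r
library(owosim)
dir <- tempfile(); dir.create(dir)
cli_generate(dir, generator_params(seed = 42))
cli_simulate(dir, file.path(dir, "results.csv"))
cli_analyze(file.path(dir, "results.csv"))
```

```
Cohort of 6 knee(s), 7 angles, Wilcoxon dialect: exact

  angle   min-max median    mean+/-sd p vs baseline p vs previous
  0 deg 19.4-23.3   21.6 21.5 +/- 1.6
  2 deg 17.7-21.8   20.0 19.9 +/- 1.6         0.031         0.031
  4 deg 16.0-20.2   18.4 18.3 +/- 1.6         0.031         0.031
  6 deg 14.3-18.5   16.8 16.6 +/- 1.6         0.031         0.031
  8 deg 12.6-16.9   15.2 14.9 +/- 1.6         0.031         0.031
 10 deg 10.9-15.2   13.6 13.3 +/- 1.6         0.031         0.031
 12 deg  9.2-13.6   11.9 11.5 +/- 1.7         0.031         0.031

slope: -1.66 mm per 2 deg step; Pearson r(angle, mean) = -1.000
(12 uncorrected pairwise comparisons)
```

Every subject's TT-TG decreases at every angle (the pendulum effect is
monotone), so each six-pair exact Wilcoxon test reaches its uniform-sign
floor p = 2/2⁶ = 0.031; the mean decrease is ~1.7 mm per 2° step and the
angle–mean relationship is almost perfectly linear over 0–12°.

A single noise-free knee shows the machinery is exact — the 3D simulation
reproduces the closed form to machine precision, and the estimator recovers
the generator's true parameters:

```r
p <- generator_params(tttg_sd = 0, groove_tuberosity_dz_sd = 0,
                      hka_sd = 0, condyle_dz_jitter_sd = 0)
s <- run_schedule(sample_knee(p, 1))
s
#>   angle_deg tttg_mm
#> 1         0  21.000
#> 2         2  19.347
#> ...
#> 7        12  10.769
pendulum_fit(s)
#> Pendulum model fit: tttg = a*cos(theta) - b*sin(theta)
#>   native TT-TG (a): 21.000 mm
#>   offset dz    (b): 47.000 mm
#>   rms residual    : 3.08e-15 mm over 7 angles
```

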