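---
title: "Measuring knee alignment from landmarks and quantifying rater agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring knee alignment from landmarks and quantifying rater agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneemetry)
```

## The measurement problem

On a full-leg anteroposterior (AP) weight-bearing radiograph, lower-limb
alignment is summarised by a handful of angles between mechanical axes and
joint lines: the hip–knee–ankle angle (HKA, reported as a signed deviation
from 180°, negative for varus), the mechanical lateral distal femoral angle
(mLDFA) and the mechanical medial proximal tibial angle (mMPTA). A more
recent landmark, relevant to kinematically aligned knee arthroplasty, is the
**trochlear groove bisector** (TGB): two tangent lines are drawn from the
apical midpoint of the intercondylar groove to the medial and lateral
trochlear facets; the angle they subtend is the trochlear groove angle (TGA),
and the TGB bisects it. The **bisector angle** (BA) is the medial angle
between the TGB and the distal femoral joint line — close to 90° in healthy
knees, which is what makes the TGB a candidate reference for the distal
femoral cut when arthritis has erased the native joint line.

All of these are functions of a small set of named 2D landmark coordinates
digitised by a human observer. `kneemetry` implements (a) the landmark
geometry, (b) the reliability statistics appropriate to a fully crossed
subjects × observers (× occasions) study of such measurements, and (c)
synthetic data generators so that both layers can be validated end-to-end
without access to radiographs.

## Geometry conventions

Coordinates arrive in an arbitrary image frame (pixel origins and axis
directions vary between PACS exports), so the package resolves anatomy from
landmark *names* plus the annotation's `side` field, never from coordinate
signs:

* **Unsigned angles** (mLDFA, mMPTA, TGA, BA) are computed between vectors
  whose anatomical direction is fixed by named landmark pairs
  (`condyle_medial − condyle_lateral` is lateral→medial by construction).
  They are therefore invariant under any rigid motion, uniform scaling and
  mirroring of the image.
* **BA sign convention.** The TGB direction is the negation of the internal
  bisector of the two apex→tangent rays (i.e. oriented proximally, up the
  femoral shaft), measured against the lateral→medial joint-line vector.
  Perpendicularity reads exactly 90°, and BA < 90° means the proximal tip of
  the bisector leans medially. Whether sub-90 values *clinically* correspond
  to a medial or lateral lean is not settled usage; this package's convention
  is a documented choice, not an anatomical claim.
* **HKA sign.** The only place a mirror (handedness) convention is
  unavoidable: varus must come out negative on both left and right limbs.
  When the joint-line landmarks are present the handedness of the frame is
  derived from them (cross product of the proximal axis and the medial
  direction); a pure four-point axis annotation falls back to the standard
  AP display frame assumption (y proximal, medial at +x on a right limb).
  Mirror-plus-side-flip invariance holds in both paths.
* **Tangent points.** Observers usually digitise the tangent contact points
  directly (that is what drawing a tangent line on a workstation produces).
  When only facet contours are digitised, `tangent_from_point()` finds the
  supporting point: the contour point whose ray from the apex leaves every
  other contour point on one side. Ties in polar angle go to the point
  farthest from the apex — the drawn line touches the outermost point.

Angles are kept at full precision internally; printing rounds to 0.1°
(angles) and three decimals (ICC), matching how such tables are reported.

## The agreement model

A crossed measurement study gives `y_ijk = μ + a_i + b_j + (ab)_ij + e_ijk`
for subject *i*, observer *j*, occasion *k*, with independent zero-mean
normal components. `mean_squares()` computes the two-way crossed ANOVA mean
squares (with `r = 1` the interaction and error strata merge), and
`variance_components()` applies the method-of-moments equations, truncating
negative estimates at zero while preserving the raw values.

From these:

* **ICC, absolute agreement.** ICC(A,1) `= (MS_R − MS_E) / (MS_R + (m−1)MS_E
  + (m/n)(MS_C − MS_E))` and ICC(A,k) `= (MS_R − MS_E) / (MS_R + (MS_C −
  MS_E)/n)`, with F-based confidence intervals using Satterthwaite degrees of
  freedom, the standard construction for this family. Both forms are always
  reported; `average` is the default because crossed reliability studies
  with several raters typically quote the averaged form, but published ICCs
  frequently omit which form was used, so the single form is kept alongside.
* **LOAM.** The limits of agreement with the mean generalise Bland–Altman to
  more than two raters: the half-width is `z·sqrt(((m−1)/m)(σ²_observer +
  σ²_interaction) + (1 − 1/(mr))σ²_residual)`, i.e. the SD of one
  measurement's deviation from its subject's mean, times `z = 1.96` (the
  normal multiplier both source methods use; configurable).
* **Extended Bland–Altman plot.** One point per measurement, difference from
  the subject mean against the subject mean, with reference lines at 0 and
  ±LOAM. Per-subject differences sum to zero by construction.
* **Repeatability coefficient.** `RC = 1.96·√2·s_w` with `s_w²` the pooled
  within-subject variance across occasions. Because "inter-subject
  repeatability" is sometimes used loosely for the between-subject spread,
  the analogous `1.96·√2·s_b` (SD of subject means) is also exposed; which
  of the two a given publication means is often undecidable from its text.
* **Intra-rater data** (one observer, `r` occasions) are analysed by the same
  two-way machinery with occasions in the observer slot. This reproduces the
  common practice of quoting a two-way random-effects ICC "across time
  points" and keeps one code path.

Missing cells are an error, never imputed: the supported design is fully
crossed, and silently unbalanced reliability statistics are a known trap.

## The synthetic world

Two generators exist because measurement error arises at the landmark level
but the statistics operate on angles:

* `simulate_angle_table()` draws directly from the two-way model above.
  Population defaults are the healthy-cohort values: HKA 0° (SD 2.48°),
  mLDFA 87.6° (SD 1.88°), mMPTA 88° (SD 2.2°), BA 89.4°. No subject-level SD
  for BA is published; the default 1.1° sits inside the published
  per-observer SD range (0.96–1.25°) and is a package choice. The angle-level
  noise defaults (`sigma_observer` 0.15°, `sigma_residual` 0.65°) were set
  once so that the implied BA LOAM, `1.96·sqrt((2/3)(0.15² + 0.65²)) ≈
  1.07°`, and per-observer SDs land near published reliability figures for
  this measurement.
* `build_subject_geometry()` inverts the five angle definitions into a
  stylised limb (femur 430 mm, tibia 370 mm, condylar width 80 mm) in a
  canonical frame, such that `measure_all()` returns the requested angles to
  1e-9°; this round-trip identity is the backbone of the geometry test
  suite. `simulate_annotations()` then perturbs each observer's digitisation
  with a fixed per-landmark observer bias (SD 0.3 mm) plus isotropic
  per-reading jitter. The jitter default (0.33 mm) was calibrated once so the
  end-to-end pipeline at 110 limbs and 3 observers yields a BA LOAM near
  1.3°, the reliability regime this measurement lives in.

What the generator deliberately does **not** emulate: anisotropic or
correlated landmark errors (real raters err along bone contours, not
isotropically), osteoarthritic deformation and osteophytes, rater drift over
time, within-patient correlation of bilateral limbs (contralateral limbs are
treated as independent, mirroring how such cohorts are commonly analysed),
and any image-level effect (rotation malposition, magnification). A green
end-to-end test therefore establishes internal consistency of geometry plus
statistics under an idealised error model — not agreement with any clinical
dataset. Notably, isotropic jitter calibrated to the published LOAM produces
a *higher* ICC (~0.87) than the published 0.677, i.e. real rater
disagreement contains structure (likely shared landmark ambiguity) that
white jitter does not capture.

## Numerical choices and edge cases

* Degenerate geometry (coincident points, opposite rays, apex inside a
  contour's hull) raises classed errors, never silent NaNs; a zero-opening
  groove (`tga = 0`) is the one legal degenerate reading, with the bisector
  along the single ray.
* A constant measurement table has zero total variance: every dispersion
  statistic is exactly 0 and the ICC is flagged `undefined`, not reported as
  1 or 0.
* When `MS_E = 0` (perfect agreement) the Satterthwaite ratio is 0/0; any
  finite df gives the same degenerate closed-form CI, so `n − 1` is used.
* Negative method-of-moments components are truncated to zero for derived
  statistics (keeping LOAM real-valued), raw values retained for inspection.
* All simulation is seeded explicitly; the same seed yields byte-identical
  CSV/JSON outputs. Config files are JSON; flags override file values.

## Known limitations

* With three observers the observer variance component rests on 2 degrees of
  freedom; its estimate carries ~100% relative sampling SD per dataset. The
  parameter-recovery check at 20 replicate seeds still shows ~22% relative
  SD on the mean, so the 10%-recovery property fails for this component by
  design of the world, not by an implementation defect (the subject and
  residual components recover to well under 1%). A reliability study that
  needs a trustworthy observer variance needs more observers, not more
  subjects.
* The mMPTA plateau line requires explicit `plateau_medial` /
  `plateau_lateral` landmarks; the package does not guess a tibial joint
  line from femoral condyles.
* Which condyle points are "most prominent" under deformity is the
  observer's call; the package trusts the digitisation.
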