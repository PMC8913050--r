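---
title: "Methods: a passive ACL graft element over synthetic gait, swept across tibial insertion sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a passive ACL graft element over synthetic gait, swept across tibial insertion sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acltis)
```

## What the package computes

`acltis` evaluates the force in a single-bundle ACL graft, modelled as a
passive straight-line elastic element between one femoral and one tibial
insertion point, over a normalized 101-point gait cycle, and quantifies the
sensitivity of that force to the placement of the tibial insertion site
(TIS). Because the element is passive, its force is fully determined by its
length — no muscle-force resolution, inverse kinematics or contact model is
needed, which is what makes a desk-scale reimplementation of this analysis
possible. The trade-off is discussed under *Limitations*.

## The knee model

Femur and tibia frames both use x anterior, y proximal, z lateral. The femur
frame sits at the femoral head center; the tibia frame origin coincides, at
the default pose, with the midpoint between the femoral epicondyles,
`origin_offset = c(0, -40, 0)` cm from the femoral head. (Anchoring a
"tibial" frame to a femoral landmark is deliberate: it mirrors the source
model convention this package follows; the frame moves with the tibia once
the joint rotates.)

The knee pose has three independent rotations applied as successive
body-fixed rotations in the fixed order flexion (about z, with a sign such
that positive flexion carries the tibia posteriorly), adduction (about x),
internal rotation (about y). The source convention names the three degrees
of freedom but not their sequence; this order approximates the standard knee
joint-coordinate-system convention (flexion on the femoral z axis first,
long-axis rotation last). Superimposed on the rotations is a
flexion-coupled translation of the tibia origin, tabulated as `(flexion,
tx, ty)` knots and interpolated piecewise-linearly (a cubic option exists;
the functional form of the source coupling is not published, and a linear
table of six knots is the least-committal representation). Out-of-domain
flexion values are clamped to the table boundary with a warning rather than
extrapolated: the coupling is a bounded anatomical function and polynomial
extrapolation beyond 120° would be pure invention.

### The coupling table and its calibration

The shipped coupling is a generic stand-in (whole-body musculoskeletal
models inherit their knee coupling from source knee rigs and rarely print
it): anteroposterior roll-back from 0 to −0.52 cm over 0–120° flexion, and a
constant superoinferior offset `ty = 0.80` cm. The `ty` value is the one
deliberately calibrated constant in the package. It was chosen once so that
the default center-placed graft is taut through stance with a peak strain
near 0.08 — comfortably above slack, below the linear-region strains that
would imply several hundred newtons at center. Every qualitative behaviour
of the insertion-site sweep (anterior force growth, medial/lateral
asymmetry, posterior slackness beyond 2.5 mm) then follows from geometry
alone; no per-direction tuning exists anywhere in the package.

## The ligament element

Length is the Euclidean distance between the femoral insertion mapped
through the femur→tibia transform and the tibial insertion; strain is
`(L - L0)/L0`; force follows the standard toe-then-linear ligament law

- `f = 0` for `e <= 0` (slack),
- `f = 0.25 k e^2 / e_l` for `0 <= e <= 2 e_l` (quadratic toe region),
- `f = k (e - e_l)` for `e >= 2 e_l` (linear region),

which is continuous at both breakpoints (both middle/upper branches give
`k e_l` at `e = 2 e_l`) and has asymptotic stiffness `k`. Defaults:
`L0 = 2.8` cm, `k = 3100` N, `e_l = 0.03`, insertions `(-1.1, -40.5, 0.7)`
and `(1.2, -3.2, -0.1)` cm. Units are cm, N and dimensionless strain
throughout; TIS offsets are entered in mm and converted at the API boundary.

**Subject scaling.** Insertion coordinates scale with the subject's uniform
scale factor (`height / 1.70` m by default); the resting length scales by
the ratio of default-pose path lengths after/before scaling (exactly the
scale factor when the whole geometry scales uniformly); stiffness is never
scaled. Because the sweep also scales the origin offset and the coupling
translations by the same factor, the entire strain trace — and therefore the
force trace — is invariant under uniform subject scaling. This is an exact
property, tested to 1e-12, and it means inter-subject force variation in the
default cohort comes entirely from kinematic variability, not from body
size. A model in which stiffness stayed fixed while geometry scaled *non*-
uniformly would break this; uniform scaling is the stated assumption.

## The synthetic gait generator

The generator stands in for motion-capture data. Each angle trace (flexion,
adduction, internal rotation) is a shape-preserving piecewise cubic Hermite
spline (PCHIP, via `pracma::pchip`) through a knot table; PCHIP zeroes the
slope at extremum knots, so a knot is never overshot and a landmark placed
on a knot is attained *exactly* at a sampled cycle point. The landmark knots
carry the calibrated values:

| Landmark | Default | Where |
|---|---|---|
| stance flexion max | 14° | 15% cycle |
| swing flexion max | 64° | 72% cycle |
| adduction peak | 10° | 85% cycle |
| swing internal rotation max | 7° | 88% cycle |
| swing external rotation max | 12° (magnitude) | 68% cycle |
| stance fraction | 0.60 | — |

The remaining knots (heel-strike flexion ≈ 5°, mid-stance minimum ≈ 3° at
40%, toe-off ≈ 12°, small stance adduction/rotation values) are generator
shape defaults chosen to give normal-gait-looking curves; they are
configurable and carry no claim beyond plausibility. The stance fraction of
0.60 is the standard level-walking convention.

**Variability.** With `variability > 0`, interior knots receive
multiplicative amplitude jitter (Gaussian, SD `0.08 × variability`) and
additive phase jitter (SD `0.02 × variability` cycle, order-preserving);
the two cycle endpoints share one amplitude draw so every realization still
closes. Each subject's jitter is driven by a seed derived deterministically
from the master seed, so any subject is reproducible in isolation and the
whole pipeline is bit-reproducible end to end.

**Cohort anthropometrics.** Heights and masses are drawn from normal
distributions, default 1.63 ± 0.098 m and 72.04 ± 15.22 kg for seven
subjects. The height SD deserves a flag: the cohort summary this emulates
prints "1.63 ± 0.98 m", an SD that would be physically implausible for
adult stature; the package treats it as a misprint for 0.098 m. The value
is configurable for anyone who disagrees.

**What the generator does not emulate.** Real post-reconstruction gait has
asymmetries, within-subject stride-to-stride variance, correlated errors
between angle channels, and soft-tissue/marker artefact none of which the
knot-jitter model reproduces. Passing tests on synthetic cohorts therefore
demonstrate the correctness and sensitivity structure of the *model
pipeline*, not claims about any clinical population.

## The insertion-site sweep

The grid is center + {2.5, 5.0, 7.5} mm × {anterior, posterior, medial,
lateral} = 13 sites. Anteroposterior offsets move the tibial x coordinate;
mediolateral offsets move z with the medial sign resolved from the side
(right knee: medial = −z; left inputs are handled by mirroring). The femoral
insertion is never moved. Offsets are applied on the unscaled generic
geometry *before* subject scaling, consistent with a tunnel placed on the
anatomical footprint, which scales with the subject. The sweep stores the
full 101-point force curves (the correlation analysis needs whole curves,
not just peaks) in stable subject-major order with per-curve provenance
(seed, scale, site).

## The statistics layer

- **Peaks.** Two stance-phase force peaks are extracted: the maximum over
  [0, 30%] (initial contact) and over (30%, 60%] (terminal stance). The 30%
  split is a package choice; the two named regions have no published
  boundary. All-slack curves yield invalid (NA) peaks, never zeros.
- **Correlation.** Sample Pearson r of each offset curve against the same
  subject's center curve over all 101 points, two-sided p from the exact t
  transform with n − 2 df (`stats::cor.test`). Constant curves give N/A.
- **Paired t-tests.** Per-condition peaks versus center
  (`stats::t.test(paired = TRUE)`), pairs with a slack side excluded
  pairwise; fewer than two remaining pairs reports N/A rather than erroring,
  and zero-variance differences are flagged explicitly (`t = 0, p = 1` when
  all differences are zero; `p = 0` with a zero-variance flag otherwise)
  because `t.test` itself refuses constant data.
- **No multiple-testing correction** is applied across the 12 comparisons;
  raw p-values are reported with a note, reproducing the analysis style this
  package emulates. Significance stars are derived from the stored p-values
  at 0.05/0.01 at render time — there is no second thresholding path to
  drift out of sync.
- The report annotates any condition whose mean stance peak exceeds a
  configurable literature threshold (default 600 N, the low end of the
  cadaveric ACL ultimate-force range 600–2300 N). This is an annotation
  only; no failure model is implemented.

## Numerical and design choices

- **PCHIP, not a generic cubic spline**, for gait traces: a C² spline
  overshoots non-monotone knot sequences by ~2% of the swing amplitude,
  silently violating the landmark contract; shape preservation is the
  requirement, smoothness of second derivatives is not.
- **Degenerate inputs**: empty coupling tables, non-increasing knots,
  non-positive `L0`/`k`, out-of-range `e_l`, infeasible landmark
  combinations (swing flexion ≤ stance flexion) and zero-length default-pose
  paths all raise explicit validation errors; out-of-domain flexion clamps
  with a warning.
- **Seed flow**: one master seed → per-subject seeds via a seeded
  `sample.int` draw → per-subject trace jitter; anthropometrics are drawn
  under the master seed. Two runs with one master seed are byte-identical
  through to the written CSVs.
- **Problem sizes**: the shipped defaults (7 subjects × 13 sites × 101
  samples) run the full generate→sweep→report pipeline in a few seconds; the
  test suite's property loops use 20–1000 random cases per invariant.

## Limitations

- The element is passive: force comes from kinematics and geometry only.
  The terminal-swing knee extension therefore loads the graft much like
  initial contact does, whereas an analysis driven by measured dynamics and
  muscle forces would differentiate them. Stance-window peak statistics are
  unaffected, but swing-phase force values should be read as geometric
  tautness, not physiological load.
- The coupling table, default-pose offset and generic insertions are
  stand-ins for an unpublished source model; absolute force magnitudes
  depend on them. The sweep's *orderings* are robust to this (they follow
  from the insertion geometry), which is why the package's guarantees are
  stated qualitatively.
- Resting length is constant per subject (then scaled); no per-subject
  reference-strain adjustment is modelled.
- No ligament wrapping, multi-bundle structure, viscoelasticity or failure
  mechanics.
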