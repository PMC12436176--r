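---
title: "A functional multi-segment foot model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A functional multi-segment foot model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hffm)
```

## The model

`hffm` computes clinical foot kinematics from a 17-marker set on the shank
and foot. The foot is treated as four segments — shank (Sh), hindfoot (Hf),
forefoot (Ff) and a single-axis hallux (Hal) — whose coordinate systems are
anchored on *functionally* motivated joint parameters rather than on a
static calibration posture:

* **KJC / AJC** — knee and ankle joint centers, midpoints of the femoral
  epicondyle (LEP/MEP) and malleolar (LML/MML) markers; the knee joint axis
  (KJA) runs from the medial to the lateral epicondyle.
* **HRC** — the heel rotation center, the pivot of heel rolling just after
  initial contact ("first rocker"). It is regressed linearly from the three
  calcaneus markers:
  `HRC = (0.54 CCLx − 0.15 LCLx + 0.15 MCLx, 0.28 CCLy + 0.43 LCLy + 0.42 MCLy, 0.29 CCLz + 0.025 LCLz + 1.74 MCLz)`.
* **MFJC** — the midfoot joint center, the functional center of angular
  motion between hindfoot and forefoot (no single anatomical joint), from
  `MFJC = (0.16 NAVx + 0.25 PMT1x + 0.30 PMT5x, 0.52 NAVy − 0.17 PMT1y + 0.26 PMT5y, 0.5 NAVz + 0.5 PMT5z)`.
* **MRA** — the metatarsal rotation axis under the metatarsal heads, about
  which the foot rolls in late stance ("third rocker"): the line through the
  first and fifth metatarsal head markers (DMT1, DMT5), shifted 11 mm down
  along gravity — 8 mm for the metatarsal head radius plus 3 mm for the
  marker radius.
* **FFC** — the forefoot center: the orthogonal projection of the second
  metatarsal head marker (DMT2) onto the MRA; also the origin of the hallux
  axis (FFC to HLX).

Segment frames follow the cross-product constructions of the model
definition: the shank from KJC, AJC and the KJA; the hindfoot with its
x-axis from HRC to MFJC and its y-axis normal to the plane spanned with the
HRC-to-AJC direction; the forefoot with its x-axis from MFJC to FFC and its
z-axis normal to the MRA. Two construction details are worth spelling out
because the published axis table is ambiguous about them:

* Read literally, the forefoot rules (`z = x × MRA`, `y = x × z`) produce a
  left-handed triad. We use `z = MRA × x`, `y = z × x`, which is proper,
  parallel to the stated axes, and — unlike the sign-fix "z upward" — agrees
  with the hindfoot and shank frames in a neutral posture (their z-axes
  point distally, along KJC→AJC).
* All frames therefore coincide for a neutral foot, which makes neutral
  joint angles zero without any static-offset correction — the central
  selling point of a functional model.

## The local frame behind the regressions

The regression coefficients above only have meaning in the (unpublished)
foot-anchored frame they were fitted in; their sums differ from 1, so the
result depends on that frame's origin and scale. Two constraints pin our
choice:

1. the regressed points must move **rigidly** with their segment (otherwise
   midfoot motion and foot pitch leak into the joint centers, and recovered
   angles are distorted by several degrees), so the frame may use only
   markers rigid with that segment, and
2. the three calcaneus markers alone span a plane; any frame built only from
   them confines the regressed HRC to that plane (every local z coordinate
   is zero, so the 1.74·MCLz term can never act).

We therefore evaluate the HRC regression in a hindfoot technical frame whose
vertical sense is anchored by the malleolar midpoint — the ankle pivot,
which is rigid with respect to the hindfoot — with origin CCL and the
heel-to-midheel direction as its anterior axis. The MFJC regression uses a
forefoot technical frame (origin NAV, anterior axis toward the mid
metatarsal heads, normal of the forefoot marker plane). Both frames are
marker-only and rigid-transform equivariant; on plausible synthetic feet the
HRC lands low inside the calcaneus, posterior to the mid heel markers, and
the MFJC at midfoot height. The coarse whole-foot frame (origin CCL, x =
horizontal heel-to-forefoot direction, z = lab vertical) is retained for the
phenomenological channels only.

## Angles

Nine rigid-segment channels are Euler–Cardan angles of the relative
rotation `R = t(R_prox) %*% R_dist` for the pairs shank/hindfoot,
hindfoot/forefoot and shank/forefoot, decomposed in the intrinsic X–Y–Z
(sagittal, frontal, transverse) sequence. The decomposition is evaluated in
a permuted orthonormal basis per segment — X′ = mediolateral, Y′ = anterior,
Z′ = vertical — so that the first rotation is about the flexion axis as the
sequence name implies, while the stored frames keep the published axis
labels (x anterior). With this basis all channels carry clinical signs
without per-channel flips: dorsiflexion, varus/supination/inversion,
internal rotation and adduction are positive. Left feet are mirrored across
a vertical lab plane before analysis, which is equivalent to flipping the
mediolateral axis per frame but keeps every rotation matrix proper.

Hallux flexion and abduction are projected angles of the FFC→HLX axis in
the forefoot frame (sagittal and transverse projections). Four
phenomenological channels complete the set:

* **medial arch** — apex angle of the MCL–NAV–DMT1 triangle (180° = flat,
  smaller = more cavus);
* **medial arch inclination** — sagittal inclination of the MCL→DMT1 line
  against the horizontal;
* **metatarsal I–V** — splay angle between the first and fifth metatarsal
  directions (PMT→DMT), projected onto the horizontal plane;
* **subtalar eversion** — frontal-plane angle from the malleolar line
  (MML→LML) to the calcaneal line (MCL→LCL), projected onto the plane
  normal to the foot's anterior axis, eversion positive.

The latter three were historically defined by the predecessor measurement
method whose original formulas are not printed in full anywhere we can
reach; the constructions above are geometrically faithful readings of the
named marker triads and are validated by behaviour (sign conventions,
mirror symmetry, monotone response to deformity) rather than by legacy
numerical equivalence.

## Pipeline parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff_hz` | 4.5 Hz | zero-lag low-pass (4th-order Butterworth, forward–backward) applied per marker component |
| `max_gap` | 10 samples | longest marker dropout filled by spline interpolation |
| `classify_window` | 5 % cycle | least-squares slope window for the equinovarus rule |
| `vertical` | `c(0, 0, 1)` | lab vertical (gravity reference of the MRA shift) |
| `n_points` | 101 | samples per normalized gait cycle (every 1 %) |

The cutoff deserves a note. 6 Hz is the habitual figure for gait marker
smoothing, but a zero-lag filter with a 6 Hz passband mathematically cannot
attenuate a 10 mm single-sample artifact below ~1.2 mm at 100 Hz sampling,
whatever its order or family; and cubic smoothing splines cannot
simultaneously keep walking-frequency content distortion-free. We chose
4.5 Hz with a sharp (effective 8th-order) rolloff: pure sinusoids at gait
frequencies pass with < 0.01 mm error, a 10 mm spike is suppressed below
1 mm, and with 1 mm isotropic marker noise the recovered angle curves show
about 0.6° RMSE on the synthetic bed.

Gait events: initial contact is detected at local minima of the dorsal heel
marker's height (gated near the global minimum, so shallow mid-swing dips
are ignored); toe-off at the first sustained rise of the second metatarsal
head marker's forward velocity above 2 % of the cycle's peak. Events
supplied with the trial override detection. Cycles are resampled to 101
points by cubic interpolation; a foot is called equinovarus (EV) when the
least-squares slope of hindfoot/shank flexion over the first 5 % of the
cycle is positive (flexion rising right after contact indicates
forefoot-first contact). The paper-level rule says only "at initial
contact"; a one-sample derivative would be noise-dominated, hence the 5 %
window.

Group statistics use the foot as the unit: per foot, each angle's
cycle-averaged curve is reduced to mean, maximum and range of motion; groups
are compared per angle and outcome by classic one-way ANOVA with a
Bonferroni factor of 3 (the three outcomes tested per angle — never across
angles), plus pooled-SD pairwise t-tests with the same factor. The
Shapiro–Wilk screen is advisory only; the comparison proceeds regardless of
its outcome.

## The synthetic test bed

There is no public reference dataset for this marker set, so validation
rests on a built-in rigid-body generator (`make_template_foot()`,
`generate_trial()`). The template is a deterministic adult-sized foot
(~245 mm) with all 17 markers; five coordinates (medial calcaneus y, heel
marker height, fifth metatarsal base y and height, second metatarsal head
y) are solved by Newton iteration so that in the neutral pose all segment
frames coincide *exactly*. Prescribed joint waveforms (sums of up to three
sinusoids per channel, composed in the same Cardan basis the analysis
decomposes) are then exactly recoverable, which turns the generator into a
ground-truth oracle: noiseless recovery is accurate to < 0.5° (the residual
comes from the gravity-referenced MRA shift, which is deliberately not
rigid with the pitching forefoot, and from cycle interpolation).

The generator emulates: forward progression during swing (quintic
smoothstep), vertical body bob with its minimum at initial contact, swing
foot lift, rigid marker attachment, exact event times, seeded isotropic
Gaussian marker noise, and left feet as exact mirror images. Deformity
presets shift waveform constants: cavovarus (CV) adds +4° dorsiflexion and
+5° hindfoot varus offsets, −4° forefoot/hindfoot flexion and an 8 mm
navicular raise; equinovarus (EV) swaps in a plantarflexed hindfoot flexion
waveform with positive early slope, +7° varus, +6° forefoot adduction and a
14 mm navicular raise. These are generator constants chosen to reproduce
the *direction* of the published group contrasts, not their magnitudes.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: soft-tissue artifact (markers move with skin,
not bone), non-rigid intra-segment foot deformation, marker misplacement
between sessions, occlusions beyond simple gaps, and pathological gait
timing beyond the preset offsets. Known idealizations: the malleolar markers
ride on the shank while the ankle pivot is shared with the hindfoot (true
only approximately in vivo); NAV and the proximal metatarsal markers are
assigned to the rigid forefoot; under large navicular raises (> ~10 mm) the
solved fifth-metatarsal-base height becomes unrealistically low; the
template's neutral arch (~154°) is flatter than clinical means, so arch
*contrasts*, not absolute values, are the meaningful output.

## Numerical choices and degenerate inputs

* Rotations are validated to orthonormality and determinant +1 within 1e−9;
  compose/decompose round-trips are exact to 1e−8 degrees away from gimbal
  lock. At |frontal| ≥ 89° the transverse angle is set to zero, the sagittal
  angle carries the combined rotation, and a warning is emitted. The
  generator refuses waveforms that could exceed 80°.
* Coincident markers, collinear construction points and near-parallel frame
  axes (< 1° separation) raise named degenerate-geometry errors rather than
  producing unstable frames.
* Missing optional markers (TTU, SH1, SH2 — placement aids) never affect
  output; a missing HLX nulls only the hallux channels.
* The template alignment solve iterates Newton steps on exact residuals to
  1e−10 mm and aborts loudly if it cannot converge.
* C3D input is not supported (no reader available in the R stack this
  package builds on); the wide CSV dialect
  (`time,<LABEL>_x,<LABEL>_y,<LABEL>_z,...`, mm) is the interchange format.

## Validation workloads

The shipped test suite runs the model end to end at desk scale: five-cycle
trials at 100 Hz for waveform recovery (noiseless and at 1 mm noise),
twenty seeds per preset for the classification rule, and 2000 replicates of
a three-group null (20 feet per group, white 5° curves) for the type-I
calibration of the ANOVA + Bonferroni family, which lands within
[0.03, 0.07] at the nominal 5 % level.
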