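---
title: "Methods: rigid-body strain simulation of the elbow medial ligament complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rigid-body strain simulation of the elbow medial ligament complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uclstrain)
```

## The model

The ulnar collateral ligament (UCL) of the elbow — its anterior bundle (AB)
and posterior bundle (PB) — together with the anterior and posterior common
tendons of the flexor-pronator muscles (ACT, PCT) restrain elbow valgus, the
loading direction implicated in throwing injury.  This package models each
of these structures as straight line segments between a humerus-fixed
origin and an ulna-fixed insertion, digitized at a single joint posture,
and asks how each segment's length changes when the forearm is rigidly
rotated through a flexion-by-valgus grid.

Nine fibers are modeled from 18 digitized attachment points:

* **ACT, PCT** — one origin/insertion pair each (2 points each);
* **AB1–AB3** — anterior, central and posterior bands of the anterior
  bundle, from 6 points: the anterior and posterior edges are digitized,
  and the central band joins the midpoints of the edge origins and edge
  insertions (it can also be digitized explicitly);
* **PB1–PB4** — anterior, anterior-central, posterior-central and
  posterior bands of the posterior bundle, from 8 points.

The anatomical frame is built from three humeral landmarks:

* **Y-axis**: from the midpoint of the medial and lateral epicondyle tips
  (the frame origin) toward the glenohumeral rotation center, itself the
  center of a least-squares sphere fitted to a cloud of points digitized on
  the humeral head (about 40 by convention);
* **X-axis**: the unit normal of the plane through the two epicondyle tips
  and the glenohumeral center — rotation about it is varus/valgus;
* **Z-axis**: completes the right-handed frame — rotation about it is
  flexion/extension.

A pose `(flexion, valgus)` is reached from the digitized posture by rotating
every ulna-fixed point by `flexion − 90°` about the Z-axis and then by
`valgus` about the X-axis (Rodrigues rotations about humerus-fixed axes
through the frame origin).  Strain is the percent length change relative to
the reference pose of 90° flexion and 0° valgus:

$$\mathrm{strain\ \%} = \frac{L_T - L_{ST}}{L_{ST}} \times 100,$$

where $L_{ST}$ is the fiber length at the reference pose and $L_T$ its
length at the target pose.  Positive strain means the fiber is taut
relative to the reference, negative that it is slackened.  The reference
length is always computed from the digitized geometry, never read from a
file, so strain at the reference pose is exactly zero by construction.

## Morphology groups

Dissection classifies specimens into three groups, which are metadata here
(never inferred from coordinates): Group I — AB, PB, ACT and PCT all
separable as independent structures; Group II — PB continuous with the
joint capsule ("unclear"); Group III — all four structures continuous and
unclear.  The groups differ in *where* the band endpoints are digitized.
In Groups II and III the PB central bands cannot be followed as discrete
bundles, so their origins are digitized on the capsule 2 mm anterior and
2 mm posterior of the medial epicondyle tip — a 4 mm spread matching the
typical width of the PB origin.  In Group III the AB edges are taken at
the adjacent tendon margins (posterior edge of the ACT, anterior edge of
the PCT), and the digitized PCT fibers sit anterior of their Group I/II
position.

## Sphere fit

The glenohumeral center is fitted two ways. The default algebraic fit
solves the linear least-squares system obtained by expanding
$|p - c|^2 = r^2$; points are centered and scaled first so the degeneracy
test (condition number of the normal equations above `1e8` flags
coplanar/collinear clouds) is independent of units and placement. The
optional geometric fit refines the algebraic center by BFGS on the sum of
squared radial residuals, profiling out the radius (the optimal radius for
a given center is the mean distance). At the digitizer noise level the two
centers agree within about 0.1 mm; the reported `rms_residual` is the RMS
of (distance-to-center − radius).

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `flexion_grid` | 0, 30, 60, 90, 120 | deg | must contain 90 (reference) |
| `valgus_grid` | 0, 10 | deg | must contain 0 (reference) |
| `order` | flexion first | — | humerus-fixed rotation order |
| `sphere_method` | algebraic | — | or geometric refinement |
| `humeral_head_radius` | 22.5 | mm | synthetic head sphere |
| `head_cloud_size` | 40 | points | digitized head cloud |
| `digitizer_noise_sd` | 0.23 | mm | digitizer precision, applied to the cloud |
| `epicondyle_width` | 55 | mm | epicondyle tip separation |
| `humerus_length` | 290 | mm | elbow origin to glenohumeral center |
| `pb_central_offset` | 2.0 | mm | capsule-site offset from the medial epicondyle tip |
| `attachment_jitter_sd` | 0.3 | mm | per-seed variation of attachments |
| `decimals` | 1 | — | display rounding of wide tables |

The 10° valgus default reflects that ultimate valgus failure of the UCL
occurs near 16°, so 10° probes substantial but sub-failure load.

## The synthetic specimen generator

Raw cadaver coordinates for this kind of study are rarely published, so
the generator produces anatomically plausible landmark sets that make
every pipeline stage testable.  It emulates: representative adult
dimensions (head radius 22.5 mm, epicondyle width 55 mm, humerus length
290 mm — configurable, not asserted as any cadaver's true dimensions); a
40-point humeral-head cloud on the proximal hemisphere with isotropic
Gaussian noise at the digitizer's stated 0.23 mm precision; and a
group-conditional attachment layout.  Every specimen is finally mapped by
a seeded random rigid transform into an arbitrary digitizer space, as a
real digitizing session would record it — nothing downstream may assume
axis-aligned input.

The canonical attachment coordinates were placed analytically and frozen.
Two closed-form conditions guided placement.  With the flexion axis through
the epicondyle tips, a fiber is taut in extension when its origin leads its
insertion by 30°–90° in angle about that axis (and taut in flexion for the
mirrored range); and a fiber lengthens under valgus exactly when
$u_y h_x - u_x h_y > 0$, where $h$ is the origin and $u$ the posed
insertion in frame coordinates.  The frozen layout therefore reproduces the
published qualitative behavior: the ACT taut in extension in every group;
the PCT taut in flexion in Groups I/II but reversed in Group III; the ACT
and all AB bands strictly tauter at 10° valgus than at 0° at every flexion
angle; the Group II/III capsule bands near-isometric, slackening slightly
at full extension under valgus; and the cohort-mean average strain at 10°
valgus non-increasing from 0° to 90° flexion in all groups.

What the generator does **not** emulate: real bone surface geometry and
soft-tissue wrapping (fibers are chords, so deep flexion strains of long
fibers are mildly underestimated); inter-specimen correlation of
dimensions; digitization error structure beyond isotropic Gaussian noise;
and any specimen's true coordinates — passing tests demonstrate internal
consistency and correct qualitative mechanics, not numerical reproduction
of any particular cadaver's strain values, which depend on unpublished
coordinates.

Determinism: all randomness (cloud sampling, noise, jitter, rigid
placement) derives from the single integer seed; identical parameters give
byte-identical landmark files.  The Group II/III capsule-site origins are
placed exactly at `pb_central_offset` (no jitter) because they encode a
dissection *rule* rather than an anatomical measurement.

## Numerical choices

* Rotations use the Rodrigues formula; a zero angle short-circuits to the
  exact identity so reference-pose strains are exactly 0, not round-off.
* Degeneracy thresholds: condition number `1e8` on the (centered, scaled)
  sphere normal equations; collinearity of frame landmarks via the cross
  product norm relative to the landmark scale.
* The rotation order (flexion then valgus, both humerus-fixed through the
  epicondyle midpoint) is a convention: the two rotations do not commute,
  and `order = "valgus_first"` is provided for sensitivity checks.  At 0°
  valgus the orders coincide bitwise.
* Sides: a right-handed frame cannot keep both flexion and valgus signs
  anatomical on both sides.  The X-axis (valgus) follows the
  medial-to-lateral ordering of the epicondyle arguments, which mirrors
  between sides, and the flexion delta is sign-flipped for right elbows in
  `pose_points()`; mirrored specimens therefore yield identical strains.
* Axis origin: anatomical-frame conventions fix the axis directions but
  not where the rotation axes pass through; both axes here pass through
  the epicondyle midpoint, the conventional elbow center (configurable in
  principle via the frame origin).  Valgus strains in particular are origin-dependent, which is a
  known comparability caveat, not an implementation degree of freedom.
* Wide tables round to 0.1 % for display; the long table keeps full
  precision, so no test or downstream computation depends on rounding.
* File precision is 0.001 mm, one order finer than the digitizer, making
  write/read a fixed point (bit-exact round trips).

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
specimens: grids of 5 flexion x 2 valgus poses, 9 fibers, 40-point clouds;
Monte-Carlo checks use 1000 sphere-fit replicates, 100 seeds per group for
the reference-pose identity, and 20-seed cohorts for group-level pattern
checks.  These sizes were chosen to estimate each property stably; the
whole suite completes in well under a minute.

## A worked run

```{r example}
params <- generator_params(seed = 1, group = "I")
specimen <- generate_specimen(params)
validate_specimen(specimen)

table <- run_strain_study(specimen)
widen_strain_table(table, valgus_deg = 0)
widen_strain_table(table, valgus_deg = 10)
average_strain(table)
```

## Known limitations

Fibers are straight chords between endpoint pairs: no wrapping, no
material properties, no forces or torques, no muscle activity, and no
in-vivo variation of the joint axis with flexion.  Group membership is an
input label.  The simulation compares *geometric* strain patterns between
morphologies under a shared axis convention; it does not predict tissue
load.
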