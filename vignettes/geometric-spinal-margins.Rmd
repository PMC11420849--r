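---
title: "Geometric spinal target margins: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric spinal target margins: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemargin)
```

## The problem and the model

Pediatric craniospinal irradiation with a posterior proton field must cover
each vertebral body uniformly: a dose gradient across a growing vertebra can
unbalance bone growth. The spinal target is therefore built by expanding the
spinal canal ventrally (towards the vertebral limbus) and dorsally (towards
the spinous process). `spinemargin` replaces the hand-drawn expansion with a
measured, per-level geometric rule.

The measurement primitive is the water-equivalent length (WEL): geometric
path length weighted by relative proton stopping power (RSP), the natural
depth coordinate of proton range. On the canal-midline ray of each vertebra,
four depths from the posterior skin surface are taken (`d1` anterior canal
wall, `d2` anterior vertebral wall, `d3` posterior canal wall, `d4` spinous
tip), averaged over the upper, middle and lower slices of the level. The
ventral and dorsal expansions are the differences `x_d = d2 - d1` and
`x_p = d3 - d4` (mmWEL). Although the clinical definitions only name the four
depths, the beam-depth compositions `L_d = d1 + x_d` and `L_p = d3 - x_p`
force exactly these differences: `L_d` must reach the anterior vertebral wall
and `L_p` the spinous tip.

Expansions are converted to real thickness by dividing by a per-region RSP
constant (1.34 cervical; 1.27 thoracic, lumbar, sacral) and regressed on the
vertebral index `N` (1..26, C1..S2) by ordinary least squares, per segment:

* ventral `X_d`: constant over C2–C7 (the cervical ventral expansion shows no
  trend in `N`), linear over T1–L5;
* dorsal `X_p`: linear over C2–C7 and linear over T1–L5.

C1 is excluded from the cervical fit — the skull sits in its beam path and
perturbs the range — and the two sacral levels provide too few measurements
for a fitted line; all three keep their cohort mean expansions as constants.
Refitting the packaged cohort table reproduces the published coefficients at
display precision (`0.6 N + 5.2` ventral T/L with r = 0.99; `-0.2 N + 12.6`
dorsal T/L; `1.3 N + 1.2` cervical dorsal; 8.2 mm cervical ventral constant).
Two display-precision details are worth noting as recomputation effects: the
cervical dorsal intercept recomputes to 1.29 mm (displayed 1.3) against the
published 1.2, and the lumbar dorsal correlation recomputes with a negative
sign at the published magnitude 0.19. Neither affects the model actually
used, which retains full precision internally.

### Growth factor

Body size, and with it every margin, grows with age. Because individual
growth varies, the scaling is anchored to body surface area (Du Bois:
`BSA = W^0.425 H^0.725 x 0.007184`), whose regression on age in the cohort
gives `f(g) = 0.052 g + 0.51`. The factor multiplies the *real-thickness*
margins (`X_d(N, g) = X_d(N) f(g)`), never the WEL quantities — the
conversion to thickness happens first, the anatomical scaling second. `f` is
used exactly as fitted, not renormalized to 1 at any reference age (it is
0.978 at the cohort median age of 9); whether it should be read as a raw
BSA-on-age regression or a rescaling is genuinely open, and the package takes
the fitted line at face value. A soft warning is emitted outside ages 3–15,
the range over which the pediatric rationale holds.

### Beam range margins

The beam-specific PTV adds proton range uncertainty margins to the stCTV:
`DM = 3.5% x L_d + 1` mmWEL distally and `PM = 3.5% x L_p + 1` mmWEL
proximally, where the depths include the couch (7.8 mmWEL) and, only when
flagged present, a nozzle-mounted (5 mmWEL) and/or couch-mounted (32 mmWEL)
range shifter. Both WEL margins are converted to geometric mm with the same
region RSP constants (matching the region-constant conversion practice used
for the expansions, rather than voxel-wise ray tracing), and a 7.0 mm lateral
setup margin is applied in-plane.

## Key parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| region RSP | C 1.34; T/L/S 1.27 | – | WEL-to-thickness conversion |
| growth model | slope 0.052, intercept 0.51 | 1/yr, – | BSA-on-age line |
| couch / nozzle RS / couch RS | 7.8 / 5 / 32 | mmWEL | shifters off by default |
| range margin | 3.5% + 1 | mmWEL | distal and proximal alike |
| lateral margin | 7.0 | mm | bsPTV only |
| surface threshold | −300 | HU | body/air separation on the ray |
| slice thickness (phantom) | 2.5 | mm | planning-CT resolution |

## Numerical choices

* **Ray geometry.** Parallel posterior rays along the y axis only; the entry
  point is the posterior face of the most-posterior voxel above the surface
  threshold, and RSP is integrated in native-voxel steps with fractional end
  segments. No supersampling: results are then exactly reproducible on the
  planning grid.
* **Midline column.** The measurement ray sits at the canal centroid's x on
  each slice (half-up rounded), the sagittal-midline choice implied by the
  anatomy; upper/middle/lower slices are the first, floor-middle and last
  slices of the label extent, middle ties breaking towards inferior.
* **Voxelization of margins.** mm margins become voxel counts by half-up
  rounding of margin/spacing — deterministic, and never under-covering by
  more than half a voxel.
* **Expansion.** Per-column 1-D interval extension along y (ventral-dorsal
  only), not isotropic dilation; the result is clipped to the body mask so
  margins cannot exit the patient, and unioned with the canal. The stCTV
  covers C1–S2; the intracranial target is out of scope.
* **Slice-level assignment.** Each axial slice takes the majority vertebra
  label; canal-only slices inherit the nearest labeled slice (inferior wins
  ties, keeping the assignment total and single-valued).
* **Agreement metrics.** The Hausdorff distance here is deliberately the
  *slice-averaged* symmetric Hausdorff — per axial slice the larger directed
  max–min boundary distance, averaged over slices where both contours exist —
  and MDA mirrors the same slicing symmetrically. Boundaries are voxels with
  a 4-neighborhood background neighbor in-plane, distances between voxel
  centers in physical mm. Slices where exactly one structure is empty are
  excluded rather than penalized. Dice and Jaccard are the plain 3-D set
  coefficients, so `J = DSC/(2 − DSC)` holds identically — note that
  published per-patient tables pairing DSC 0.84 with J 0.50 cannot satisfy
  this identity and must involve a different (undocumented) aggregation;
  such values are therefore not comparison targets for these definitions.
* **Degenerate inputs.** Empty-vs-empty overlap, no common slice, and
  single-patient confidence intervals are reported as missing (`NA`) with a
  warning, not as 0.

## The synthetic phantom

Real planning CTs and physician contours are not distributable, so validation
uses a generated phantom: a soft-tissue body (HU 40) holding, per level, a
square low-density canal (HU 10) inside a high-density vertebra (HU 700)
with a ventral shell, lateral pedicles and a dorsal spinous process, over 26
three-slice blocks at 2 × 2 × 2.5 mm spacing. The construction margins — the
shell thickness and spinous length — are taken from the published margin
model, so the measurement and fitting stages have exactly the signal shape
the model assumes (linear in `N` over T/L). All in-plane dimensions scale
affinely with age through the growth factor, normalized to the cohort median
age of 9. A "physician" reference contour is the canal expanded by the truth
margins after per-level Gaussian jitter (seeded), emulating intra-observer
contouring variability.

This closes the loop: with zero jitter, measuring a noiseless phantom,
refitting, expanding and evaluating returns Dice 1 and zero boundary
distances in every region, and the refitted margins match the construction
within one voxel at every level. What the phantom does **not** emulate:
spinal curvature (lordosis/scoliosis), irregular vertebral shapes, cortical
vs. trabecular bone, CT noise and beam hardening, and genuinely independent
per-patient anatomical variation. Passing the closed loop therefore
demonstrates the internal consistency of measurement, fitting and expansion
on the stated geometry — not clinical accuracy on real anatomy, which
requires patient data the package does not ship.

## Problem sizes

The test suite and the acceptance script run the phantom at 26 levels × 3
slices (about 32 × 41 × 78 voxels), the metric identity checks on 100+
random 12 × 12 × 4 mask pairs, and the brute-force distance oracles on masks
up to 20 × 20 × 5 — sizes chosen so the whole validation is a desk-scale
computation while still exercising every code path.

## Limitations

* The margin model is fitted to a nine-patient, single-institution pediatric
  cohort; the sacral constants rest on 18 measurements and carry the largest
  disagreement in the source evaluation.
* Only the posterior parallel-beam geometry is modeled; oblique or divergent
  beams, and lateral expansion rules for the stCTV itself, are out of scope.
* Dose calculation, robust optimization and DICOM-RT handling are out of
  scope; volumes are exchanged as NIfTI masks.
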