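# spinemargin

Geometric spinal target margins for proton craniospinal irradiation (CSI) of
skeletally immature children.

In pediatric CSI the whole vertebral body must be irradiated uniformly —
asymmetric dose across a growing vertebra risks scoliosis — so the clinical
target volume over the spine (the "technical" CTV, tCTV) is expanded from the
spinal canal to cover each vertebral body. In practice that expansion is drawn
by hand and varies between and within physicians. `spinemargin` implements a
geometric alternative: measure, per vertebral level, how far the vertebral
body actually extends ventrally and dorsally of the canal in water-equivalent
depth, fit a simple piecewise-linear model in the vertebral index, and let the
model expand the canal mechanically into a *simulated* tCTV (stCTV) plus a
beam-specific PTV (bsPTV).

It is intended for medical physicists and treatment-planning researchers who
want a reproducible, physician-independent spinal target, or who want to
benchmark automatic contouring against one.

## The model

Vertebrae are indexed `N` = 1..26 (C1..S2). For a posterior beam, four
water-equivalent lengths (WEL) are measured per vertebra on the canal midline:
skin to anterior canal wall (`d1`), anterior vertebral-body wall (`d2`),
posterior canal wall (`d3`) and spinous-process tip (`d4`), averaged over the
upper/middle/lower slices. The technical expansions are `x_d = d2 − d1`
(ventral) and `x_p = d3 − d4` (dorsal), converted from mmWEL to real thickness
by the region stopping power (1.34 cervical, 1.27 thoracic/lumbar/sacral).
Ordinary least squares in `N` gives the piecewise model (mm):

    X_d(N) = 8.2                (C2–C7, constant)
    X_d(N) = 0.6 N + 5.2        (T1–L5)
    X_p(N) = 1.3 N + 1.2        (C2–C7)
    X_p(N) = −0.2 N + 12.6      (T1–L5)

C1 and the sacral levels keep their cohort mean expansions. Margins may be
scaled by a growth factor `f(g) = 0.052 g + 0.51` (`g` = age in years),
the regression of Du Bois body surface area on age in the cohort. The bsPTV
adds beam range margins `DM = 0.035 L_d + 1` and `PM = 0.035 L_p + 1` mmWEL —
where `L_d = d1 + x_d + devices` and `L_p = d3 − x_p + devices` include the
couch and any range shifters — plus a 7 mm lateral setup margin.

Agreement with a reference contour is scored with the slice-averaged
symmetric Hausdorff distance, mean distance-to-agreement, Dice and Jaccard
coefficients, reported per spine region.

## Worked example

Refit the packaged per-vertebra cohort table and validate the expansion on a
synthetic phantom with a jittered "physician" reference contour:

```r
library(spinemargin)

fit <- fit_margin_model(load_table3_fixture())
fit
#> Refitted per-vertebra margin model
#>   X_d (T/L): 0.6 N + 5.2, r 0.99
#>   X_d (C2-C7): constant 8.2 mm
#>   X_p (C2-C7): 1.3 N + 1.3
#>   X_p (T/L): -0.2 N + 12.6

ph <- generate_phantom(phantom_spec(age = 9, seed = 42, jitter_sd = 1.5))
stctv <- expand_canal_to_stctv(ph$canal, ph$spine, age = 9, use_growth = TRUE)
evaluate_regions(stctv, ph$reference, ph$spine)
#>            region n_slices dH_mm MDA_mm   DSC     J volume_A_ml volume_B_ml
#> 1     whole spine       78  2.00  0.423 0.964 0.930      135.81       138.2
#> 2 C-spine (C1-C7)       21  1.71  0.335 0.970 0.942       30.78        32.1
#> 3 C-spine (C2-C7)       18  1.67  0.334 0.970 0.942       26.46        27.5
#> 4         T-spine       36  2.33  0.517 0.957 0.917       65.61        64.8
#> 5         L-spine       15  1.60  0.324 0.973 0.948       29.70        30.8
#> 6         S-spine        6  2.00  0.418 0.960 0.923        9.72        10.5
```

The refit reproduces the published piecewise coefficients from the packaged
WEL table (the slight `X_p` cervical intercept difference is the model's full
recomputation at display precision). On the phantom, 1.5 mm of per-level
contour jitter still leaves Dice above 0.95 in every region, with sub-voxel
mean boundary distances — the geometric expansion tracks the constructed
anatomy closely.

A shell interface mirrors the R API:

```sh
spinemargin phantom --age 9 --seed 42 --out phantom/
spinemargin pipeline --config run.yaml
```

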