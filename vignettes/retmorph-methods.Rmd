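---
title: "Regional morphometry of retinal microvascular networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional morphometry of retinal microvascular networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retmorph)
```

## The scientific problem

Retinal fundus photography shows the microvascular tree non-invasively, and
its geometry changes in systemic and ocular disease: diabetic retinopathy
prunes and re-grows vessels, glaucoma thins the network. Global summaries
of the whole retina can average these changes away, because the optic-disc
neighbourhood (large trunks entering the eye, a dense peripapillary halo)
and the macular neighbourhood (fine arterioles and venules around an
avascular centre) are structurally different and remodel differently.

`retmorph` quantifies that regional structure from binary
vessel-segmentation masks. For a whole mask and for square or circular
regions of interest (ROIs) centred on the optic disc and the macula, it
computes three skeleton-based metrics:

* **Box-counting fractal dimension** `Db` — the slope of
  `log N(eps)` against `log(1/eps)`, where `N(eps)` counts occupied boxes
  of side `eps`; 1 for a curve, 2 for a plane-filling set. Higher `Db`
  means a more complex, space-filling network.
* **Lacunarity** `Lambda` — the squared coefficient of variation
  `(sigma/mu)^2` of per-box foreground mass, averaged over grid origins
  and box sizes. 0 when every box carries equal mass; large when the
  pattern is gappy.
* **Skeleton vessel density** — the percentage of window pixels on the
  skeletonized (unit-width) network, so caliber does not bias coverage.

All three are computed on the skeleton of the analysis window: the window
is cropped first, then thinned, then measured.

## The analysis pipeline

`run_pipeline()` drives manifest → ROI crops → skeletons → metrics →
statistics. The manifest is a plain CSV (`image,mask,group,od_x,od_y,
mac_x,mac_y`) with expert-supplied centre coordinates; the package does
not localize the disc or fovea. Defaults follow the standard regional
protocol: 1000-px square ROIs, 12 grid origins, box sides up to 45% of
the shorter window side. The statistical battery mirrors the standard
design for a three-group (healthy / glaucoma / diabetic retinopathy)
study:

* macula vs optic-disc t-tests within the healthy group (Student form by
  default; the literature rarely states the variant, so Welch is a flag);
* one-way ANOVA with Tukey HSD across groups on whole-retina metrics;
* two-way region × group ANOVA with Tukey HSD over the six cell means,
  with compact letter displays (groups sharing a letter are not
  significantly different).

Degenerate layouts are resolved explicitly: all-constant responses give
F = 0, p = 1 (no effect), and distinct constants with zero within-cell
variance give perfect separation, rather than the `NaN` that a naive
ANOVA produces. Compact letters are built by the deterministic
insert-and-absorb construction, ordered by descending means.

## Numerical design of the box-counting estimator

Two choices keep the estimator unbiased on finite rasters; both were made
after the naive version underestimated a filled square's dimension by
~0.1 under these settings (box sides to 45% of the window):

1. **Divisor-preferred box sizes.** Integer box sides that divide the
   shorter window side tile it exactly, so an aligned grid over a
   space-filling set counts exactly `(side/eps)^2` boxes and the log-log
   relation is exactly linear. Non-divisor sides truncate boxes at the
   boundary and distort counts by up to `(1 + eps/side)^2`, which
   flattens the fitted slope most at the largest sizes. Windows with too
   few divisors fall back to near-divisors (remainder at most 8% of the
   side), then to plain linear sampling.
2. **Cyclic grid offsets.** The 12 origins are deterministic phase
   offsets, evenly spaced along the diagonal of the `[0, eps)^2` offset
   lattice and recomputed per size; they are applied modulo the window.
   A non-cyclic shifted grid needs up to one extra boundary box per
   dimension — an additive distortion that grows with `eps` — whereas the
   cyclic shift keeps the relative grid phase constant across scales and
   preserves the scaling law of self-similar sets. The first origin is
   always the aligned grid, so single-origin results are plain anchored
   box counts.

With these choices the estimator recovers a line at 1.000, a filled
square at 2.000, the order-5 Sierpinski carpet at 1.902 (theory 1.893)
and the order-5 Koch curve at 1.235 (theory 1.262, wider tolerance
because finite-order 1-px rasterization biases the slope); the test suite
asserts these, and the smallest box side is 2 px (a 1-px box makes
`N(eps)` the foreground count and flattens the regression).

Lacunarity uses the same sizes and origins but non-cyclic grids with
edge-truncated boxes discarded: partial boxes bias mass statistics, while
presence/absence counts tolerate them. Empty boxes count in the mass
distribution (a single foreground pixel among 100 boxes gives
`lambda = 99`), the variance is the population form, and the scalar
summary is the unweighted mean over origins and sizes — one
heterogeneity number per image across all grid placements. Sizes whose
partition has no foreground are dropped. Under this definition the small
box sizes contribute a term close to the inverse foreground density, so
sparse skeletons have `Lambda` well above 1; comparisons between regions
or groups are meaningful, absolute magnitudes depend strongly on
density.

## Skeletonization

Thinning is a sequential Zhang–Suen-family algorithm (compiled code):
candidates for each of two directional sub-passes are marked on a frozen
copy of the image, so erosion advances symmetrically from opposite
boundaries and the skeleton settles on the centreline; deletions are then
applied in fixed raster order with the simplicity conditions re-checked
on the current image, which makes every deletion topology-preserving. A
fully parallel Zhang–Suen pass can delete a 2 × 2 blob outright, which
would break the component-preservation contract. A final clean-up
dissolves residual fully-foreground 2 × 2 blocks one 8-simple pixel at a
time (simplicity judged by the Yokoi connectivity number).

One honest caveat: a 2 × 2 block whose four pixels each carry a diagonal
arm — the hub of two crossing vessels whose crossing falls between pixel
centres — is topologically irreducible: deleting any pixel disconnects an
arm. Reference implementations leave the same block. Such hubs are rare
(none arise in the 50-tree contract suite) and `is_unit_width()` flags
them; `vessel_density()` warns when its input is substantially
non-unit-width.

## Calibration and branching generations

Pixel scale follows the optic-disc convention: the user supplies
population reference disc dimensions in micrometers, and the scale is the
mean of the horizontal and vertical ratios (e.g. a 200-px disc with
972-μm references gives 4.86 μm/px). Caliber at a point is derived from
the Euclidean distance transform: at a centreline pixel the
centre-to-centre distance `d` to the nearest background pixel gives a
width of `2d − 1` px, which returns exactly 1 for a 1-px line and the
nominal width for straight bars (within 1 px at 0°–90° orientations, as
the test oracle checks). On binary masks the external-wall versus lumen
distinction of photographic calibers collapses; this caliber is the
segmented width.

Branching generations follow the diameter rules used for retinal trees:
root segments are generation 1; at a bifurcation the daughters' caliber
ratio decides whether the larger daughter continues the parent's
generation (ratio below `symmetry_ratio`) or both daughters advance
(ratio at or above it). The threshold operationalizes "relatively equal
diameters"; the field states no canonical value, so 0.8 is the exposed
default. Calibers attach to segments, sampled at midpoints, because
diameters change at bifurcations and the rules compare daughter
segments.

## The synthetic-data module

The generator exists so that every pipeline stage is testable without any
image download, and its defaults encode the study conditions the package
targets: vessels as seen by a 45° fundus camera at ≈4.86 μm/px, with
first-generation trunks near 99 μm tapering by ≈0.7 per generation to
≈21 μm — the smallest caliber such a camera resolves — over about five
generations, and a foveal avascular zone at the macular centre. A
1024-px cohort window stands for a ≈3500-px fundus image, and calibers,
the avascular radius and the visibility floor (`min_caliber`) scale
accordingly. Trees grow segment by segment: tips bifurcate with
probability `branch_prob` (asymmetry drawn uniformly; ground-truth
generations are recorded by the same diameter rules the assignment
operation implements), continue with slight caliber decay and direction
jitter, or stop at the window edge, the avascular zone, or the
visibility floor. Proposed segments are clipped to those boundaries
rather than discarded, so every committed daughter materializes and the
recorded generations remain recoverable from the realized tree.

A whole retina (`simulate_retina()`) composes three systems: the arcade
tree from the optic-disc root, a short stubby radial peripapillary net
around the disc, and a quasi-regular wavy lattice mesh around the
macular centre. The mesh deserves a note: for thin-line masks, mean
lacunarity is dominated by an inverse-density term at small box sizes,
so branching trees alone cannot reproduce the healthy eye's joint
regional pattern (macula lower than disc in both density *and*
lacunarity). A near-regular mesh with a characteristic strand spacing is
the structure that decouples the two — and it is also what the
perifoveal microvasculature actually looks like. The diabetic preset
prunes macula-side terminal branches, drops half the mesh strands
(capillary drop-out) and enlarges the avascular zone; the glaucoma
preset mildly reduces branching.

What the generator does **not** emulate: vessel tortuosity beyond mild
jitter, arteriole/venule distinction, crossing artifacts of the two real
vascular systems, image noise, illumination or segmentation errors, and
absolute densities of real gold-standard masks (synthetic skeleton
coverage sits near 5–10% versus ≈11–12% in 1000-px fundus ROIs). Passing
direction-of-effect tests on these synthetics therefore shows that the
metrics order structured patterns correctly, not that the pipeline
reproduces any particular dataset's absolute values.

## Problem sizes and determinism

The test suite and the acceptance script regenerate everything from code:
known-dimension fixtures at 729–1024 px, 50-tree skeleton and
generation-recovery contracts at 512-px windows, 20-seed regional
archetype comparisons, a 30-image synthetic cohort at 512 px, and 2000
simulated null cohorts for the two-way ANOVA's type-I error
(rejection rate asserted within 5% ± 2%). Every stochastic step takes an
explicit integer seed; identical inputs and configuration give
bit-identical metrics. Single-origin box counts are checked exactly
against an exhaustive pixel-scan oracle, lacunarity against closed
forms, the t and F statistics against hand-computed decompositions, and
caliber against a brute-force nearest-background search.

## Known limitations

* The lacunarity magnitude convention (empty boxes included, equal
  weighting over sizes from 2 px) makes `Lambda` density-dominated on
  sparse skeletons; published fundus studies using other tools report
  values well below 1 on comparable images, so only within-convention
  comparisons are meaningful.
* ROI windows that overrun the image edge are rejected by default; the
  opt-in clamp shifts them inside and logs it, which changes the
  window's content and is the user's explicit choice.
* Whole-retina skeleton density on full fundus masks is a strict
  percent-of-window quantity; tools with field-of-view-restricted
  denominators report substantially higher values for the same images.
* Essential 2 × 2 crossing hubs (above) are retained rather than broken.
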