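---
title: "Methods behind phenoscreen: fitness, growth and shape readouts of a CRISPRi screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind phenoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscreen)
```

phenoscreen implements the quantitative readouts of an arrayed CRISPRi
essential-gene library in *E. coli*: pooled relative fitness measured by
spacer sequencing, cross-contamination QC, plate-reader growth features,
single-cell morphometrics from cell contours, and the robust screen-level
classification that turns those measurements into phenotype calls. Every
stage has a matched synthetic-data generator, so the whole pipeline is
validated by parameter recovery without any external data. This vignette
explains the models, the parameters that matter, and the numerical and
design choices.

## Pooled relative fitness

In a pooled competition, each knockdown strain carries a unique 20-nt
sgRNA spacer that doubles as a sequencing barcode. Spacer counts are taken
before and after the pool undergoes $D$ doublings of the control strains
($D = 15$ by default). With per-sample frequencies
$f_i = (c_i + p) / \sum_j (c_j + p)$ (pseudocount $p = 0.5$ by default),
the log2 fold change is $L_i = \log_2(f_{\mathrm{end},i} / f_{t_0,i})$ and
the relative fitness is

$$ RF_i \;=\; 1 + \frac{L_i - \operatorname{median}_{\mathrm{ctrl}}(L)}{D}, $$

the number of doublings of strain $i$ per control doubling. The median
nontargeting control has $RF = 1$ exactly, by construction; $RF$ is not
clamped, so a strain depleted faster than dilution can go negative.

Design notes:

* **Counting is exact substring matching** of each library spacer against
  each read (no mismatch tolerance, no fixed read layout assumed). Reads
  hitting zero or two or more distinct spacers are tallied separately as
  unmapped and ambiguous. Matching uses Biostrings preprocessed
  dictionaries, so counting is linear in the number of reads.
* **Pseudocount.** $p = 0.5$ keeps $L_i$ finite for strains that drop to
  zero reads. $p = 0$ is allowed and makes $RF$ exactly invariant to
  per-sample depth rescaling; with $p > 0$ the invariance is approximate
  (exact in the deep-sequencing limit), which is why the exactness tests
  run at $p = 0$.
* **Replicates** are analyzed separately and combined by the mean of $RF$
  per strain and condition (`combine_fitness_replicates()`).
* **Contamination QC.** For an arrayed well, the contamination fraction is
  the share of *mapped* reads carried by the most abundant spacer other
  than the expected one; a well is called cross-contaminated when that
  fraction strictly exceeds $10^{-4}$. Unmapped reads are excluded from
  the denominator (the sensible choice when sequencing error, not
  cross-contamination, dominates unmapped reads).

## Growth-curve features

Wells are sampled at a fixed interval ($\Delta t = 8.5$ min). The
instantaneous growth rate is the slope of $\ln \mathrm{OD}$: the log
series is smoothed with a centered moving average of window 5 and
differentiated by central differences (one-sided at the ends). The maximum
growth rate $\mu_{\max}$ is the largest instantaneous rate, and the lag
time is the first time the rate reaches $\mu_{\max}/2$, linearly
interpolated between samples. Both features are normalized per strain
against the median of the $k = 10$ wild-type replicate wells with the
closest starting OD (ratio by default; a difference mode is available).

Choices worth knowing:

* Smoothing is applied to $\ln \mathrm{OD}$, not OD (a flag switches
  this); OD is floored at $10^{-4}$ before the log so that additive noise
  cannot produce nonpositive arguments, and an optional blank can be
  subtracted first.
* The saturation phase is not excluded when locating $\mu_{\max}$: the
  maximum rate naturally precedes saturation.
* Window edges use symmetrically shrinking windows, so the feature series
  has the same length as the input.

## Single-cell morphometrics

Cell outlines (from any segmentation tool, or from the bundled mask
segmenter) are measured with a midline mesh in the MicrobeTracker
tradition:

1. **Poles.** Start from the two contour points of maximal separation;
   refine by moving each pole to the boundary support point along the
   midline end tangent (this matters for bent cells, where the farthest
   point pair sits on the cap corners).
2. **Ribs.** Split the boundary into two pole-to-pole arcs and join
   arc-length-matched point pairs. For straight or constant-curvature
   rods this initial pairing is already nearly perpendicular.
3. **Relaxation.** Iteratively move each interior midline point along its
   normal toward the midpoint of the boundary chord perpendicular to the
   local midline tangent, with damping (0.7) and light smoothing per
   iteration. This is a Jacobi-style update; the damping and smoothing
   suppress the zigzag instability the naive point-by-point update
   develops on curved cells. Iteration stops when every body rib is
   within 5 degrees of perpendicular and the midline has stopped moving
   (ribs inside the polar caps wobble by construction and are excluded
   from the convergence test, as they are from the width).
4. **Failure = information.** If relaxation does not converge, the
   midline self-intersects, or the midline length does not exceed 1.1
   times the largest rib width (a circle scores 1.0), the cell is not a
   rod and the mesh raises a `rod_shape_error`. `cell_dimensions()` then
   falls back to the extents along the principal axes of the contour —
   the appropriate measure for round cells — and records the method used.
   A flag can force the principal-axis path for whole datasets of
   non-rod cells, in which case no width filtering should be applied.

**Length** is the pole-to-pole midline arc length (it includes the polar
caps). **Width** is the mean rib width after excluding ribs within half
the median width of either pole (one refinement pass) and ribs flagged as
septation sites: contiguous local-minimum runs below 75% of the median
rib width, extended by one rib on each side (threshold configurable).
This keeps the width of a deeply constricted dividing cell at the lobe
width rather than averaging in the neck. **Volume** revolves the mesh
about the midline: conical frustums between adjacent ribs, tapering to
zero radius at the poles, which converges to the spherocylinder closed
form $\pi r^2 (L - W) + \tfrac{4}{3}\pi r^3$ as contour resolution grows
(about $-2.8\%$ at 64 vertices, $-0.1\%$ at 512 on an ideal
$4 \times 1\ \mu m$ cell; the bias is monotone in resolution). The
principal-axis fallback uses an ellipsoid of revolution,
$\tfrac{\pi}{6} L W^2$.

**Strain aggregation** eliminates cells with widths outside
$[0.6, 2.0]\ \mu m$, requires at least 100 surviving cells per strain
(strains below that are flagged and excluded from medians), and reports
median length/width plus robust CVs ($1.4826 \times \mathrm{MAD}$ over
the median). **Plate correction** subtracts each plate's median length
and width and adds back the global median, independently per dimension —
this equalizes plate medians exactly and leaves the global median
unchanged. Note it is only translation-invariant against a shifted plate
when that plate does not straddle the global median; with many plates and
moderate offsets (the regime it is meant for) that condition holds.

**Time lapse.** The single-cell instantaneous growth rate is
$\frac{1}{V}\frac{dV}{dt}$, computed from per-frame mesh volumes smoothed
with a 3-frame moving average and differentiated centrally. Reporter
fluorescence is summed over pixels whose centers fall inside the contour,
background-subtracted, and divided by the projected (pixel-count) area.

**Mask segmentation** extracts iso-0.5 boundaries from binary masks by
marching squares with linear interpolation (subpixel). Components touching
the image border yield open boundary lines and are discarded — the border
rule falls out of the topology.

## Robust screen statistics

All screen-level calls use robust statistics: location is the median and
scale is $1.4826 \times \mathrm{MAD}$. A strain is called when its robust
z-score strictly exceeds $k = 3$; the reference distribution is the
nontargeting controls for fitness (one-sided low) and all strains for lag
(one-sided high) and shape (one-sided per dimension), matching how each
readout defines "abnormal". Enrichment of a gene category among flagged
strains is an exact upper-tail hypergeometric probability. No
multiple-testing correction is applied to the 3-SD calls; enrichment
p-values are reported raw.

Robust regression (`fit_robust()`) is an MM-type estimator written for
determinism: a repeated-median start (50% breakdown, no random
subsampling) refined by iteratively reweighted least squares with the
Tukey bisquare loss ($c = 4.685$, fixed robust residual scale). The
package's tests cross-check it against an established MM implementation
on contaminated data. Pearson's $r$ and its two-sided p-value accompany
every fit because the two are conventionally reported together.

## What the synthetic data emulates — and what it does not

* **Pooled screen:** lognormal initial abundances, deterministic
  amplification $a_i 2^{d_i}$, multinomial read sampling (optional
  Dirichlet-multinomial overdispersion, off by default — the read-count
  noise model of a real screen is unknown). Controls have $d_i = D$
  exactly; real controls carry biological noise, so simulated control
  spreads are narrower than real ones.
* **Growth curves:** the rate ramps logistically from 0 to
  $\mu_{\max}$ with the half-maximum crossing exactly at the target lag,
  and OD follows the closed form
  $\mathrm{OD}(t) = \mathrm{OD}_0 e^{M(t)} / (1 + \mathrm{OD}_0(e^{M(t)}-1)/K)$
  with $M(t) = \int_0^t \mu$, plus additive Gaussian noise. Defaults:
  inoculum OD 0.02 (a 1:100 overnight dilution), carrying capacity
  $K = 2.0$ (saturating OD of a shaken LB microplate), ramp time constant
  $\Delta t / 2$ (sharp lag exit, keeping the half-max definition crisp).
  Real curves have multiplicative noise components, diauxie, and
  condensation artifacts that are not modeled.
* **Cells:** spherocylinders with truncated-normal length and width
  (defaults 3.0/0.6 and 1.0/0.06 μm, the scale of exponentially growing
  *E. coli* in rich medium), random pose, optional per-plate additive
  offsets, and optional rasterization at 0.065 μm/px (a typical 100x
  camera scale). Nonpositive or non-rod draws are resampled. Real
  segmentations add boundary noise, curvature, and touching cells; the
  bent-rod and constricted-cell fixtures in the tests probe the first
  two, but passing tests on ideal contours does not certify performance
  on noisy masks.
* **Time lapse:** width-constant elongation with exponential (or linear)
  volume growth; no division events.

Truth tables accompany every simulation, which is what makes the
parameter-recovery test design possible.

## Problem sizes and budgets

The test suite validates recovery at the scales the methods are meant
for: a 96-well plate for growth features, 500 cells for population
morphology (64-vertex contours), 100 replicate screens at depth $10^6$
for RF bias, and a 469-strain table for the classifier — chosen to
exercise full-scale behaviour while keeping the whole suite in tens of
seconds. `scripts/acceptance.R` re-runs the same computations from
scratch at any seed.

## Known limitations

* The revolved-mesh volume treats bent cells as locally straight tubes;
  strong curvature biases volume slightly high on the outer side.
* The septum detector is a width-minimum heuristic; shallow constrictions
  (< 25% of the median width) are not excluded.
* `fit_robust()` fixes the residual scale from the repeated-median start
  rather than re-estimating it as a full S-estimator would; its tuning
  constants are documented, not fitted.
* The classifier inherits the 3-SD convention's lack of multiplicity
  control; with hundreds of strains a handful of false calls per metric
  is expected (that is the convention's operating point, quantified by
  the Gaussian-null false-positive tests).
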