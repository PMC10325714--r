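---
title: "Meibomian gland morphometry: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meibomian gland morphometry: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meibomorph)
```

## The problem

Infrared meibography images the meibomian (tarsal) glands of the everted
eyelid as bright, near-vertical bands. Gland *morphology* — in particular
tortuosity and width irregularity — changes under mechanical stress such as
long-term overnight orthokeratology lens wear, often before any gland
dropout is visible. meibomorph quantifies this with a per-gland
**deformation coefficient** built on the classical arc–chord (arc–string)
tortuosity ratio, and reproduces the cohort statistics used to compare a
treated eye against the untreated contralateral eye of the same subject.

The package is organized as an analysis workflow: every computation lives in
package functions (so it is testable and reusable), and the numbered scripts
under `analysis/` narrate the study-scale runs that write `results/`.

## The deformation coefficient

For one gland, sample the mask row by row along the gland axis. Row $i$
contributes a width $w_i$ (distance between the leftmost and rightmost
foreground columns, inclusive), a left and a right boundary point, and their
midpoint. With $n$ sampled rows:

* $p_a$, $p_b$ — polyline arc lengths of the left and right boundary point
  sequences;
* $L_\mathrm{central}$ — the length of the central line;
* $\bar w = \tfrac1n\sum_i w_i$ and
  $\sigma_w = \sqrt{\sum_i (w_i - \bar w)^2 / (n + 1)}$ — the width mean and
  the width-variation term. The $n+1$ denominator is retained exactly as
  published (it is neither the $n$ nor the $n-1$ estimator; a faithful
  reproduction keeps it).

The default coefficient is

$$D \;=\; \frac{p_a\,p_b}{L_\mathrm{central}^2}\,
  \Bigl(1 + \frac{\sigma_w}{\bar w}\Bigr).$$

Three combiner variants are selectable in `deformation_coefficient()`:

| variant | formula | dimensionless | minimum |
|---|---|---|---|
| `as_printed` | $(p_a p_b / L^2)\,\sigma_w$ | no (pixels) | 0 |
| `normalized` | $(p_a p_b / L^2)\,(\sigma_w/\bar w)$ | yes | 0 |
| `normalized_plus_one` (default) | $(p_a p_b / L^2)\,(1 + \sigma_w/\bar w)$ | yes | 1 |

The literal published expression (`as_printed`) multiplies the arc–chord
factor by the raw width SD, which carries pixel units and vanishes on a
straight uniform gland — contradicting the published statements that the
coefficient is dimensionless with minimum 1. Only the default variant
satisfies both statements, so it is the default; the others remain available
and the variant is recorded in all per-gland output.

### What "central line length" means

The published description calls $L_\mathrm{central}$ the length of the
central line. Two readings are possible: the arc length of the midpoint
polyline, or the straight (chord) length of the central line. The arc-length
reading makes $p_a p_b / L^2 \approx 1$ for *every* band-like shape —
boundary curves of a ribbon have essentially the centerline's arc length —
so the coefficient could not discriminate tortuosity at all, and the
published per-site means (up to ≈ 7.4) would be unreachable. The chord
reading makes $p_a p_b / L^2$ a squared arc–chord ratio, which is exactly
the "arc–string ratio model" the coefficient is described as extending, has
minimum 1 on a straight gland, and grows with sinuosity. meibomorph
therefore defines $L_\mathrm{central}$ as the straight-line distance between
the first and last centerline points. The arc–chord inequality
$p_a p_b / L^2 \ge 1$ then holds up to a discretization slack of 2%, and is
asserted property-style in the tests.

## Geometry extraction from a binary mask

`extract_geometry()` samples one connected component every `step_px` (default
1 px) along its axis:

* **Axis choice.** Upper-eyelid glands are anatomically near-vertical, so
  image rows are the natural sampling axis. A genuinely tilted component
  (e.g. a rotated acquisition) should instead be realigned to its principal
  axis. These two goals conflict for strongly sinuous vertical glands: the
  sinuosity itself tilts the second-moment axis by 10–17°, and realigning to
  it samples widths obliquely. The default `align = "auto"` resolves this
  empirically: it extracts in both frames and keeps the one with the smaller
  $\bar w + \sigma_w$, since sampling a band obliquely to its true axis both
  inflates and destabilizes the measured widths. `align = "principal"` and
  `align = "none"` force either frame.
* **Boundary smoothing.** Boundary columns read off a binary mask are
  integer-quantized; the arc length of the raw staircase polyline
  overestimates the true boundary length by up to ~7% at slope 0.6. A
  centred moving average (window 5 px, shrinking symmetrically at the ends)
  removes the staircase almost completely while attenuating genuine
  sinusoidal structure at the generator's wavelength scale (~100 px) by
  under 1%. Widths are taken from the *raw* extremes so that integer-width
  glands keep $\sigma_w = 0$ exactly.
* **Failure modes.** Components with fewer than two sample rows error
  ("gland too short"); an empty row strictly inside the span errors
  ("fragmented gland") rather than silently bridging a broken gland.

Against dense numeric integration of the generating curves, extracted
$p_a$, $p_b$, $L_\mathrm{central}$ agree within 2% for widths ≥ 6 px across
the tested amplitude/wavelength grid, and $D$ is scale-invariant within 2%
across 1×/2×/3× rasterizations of the same shape.

## Central-gland selection and numbering

Following the published protocol, the analysis uses the ten glands nearest
the midline of the overall gland area: the midline is the area-weighted
centroid column of all gland pixels (robust to a stray peripheral gland;
the midpoint-of-extremes is available as an alternative reading), five
glands are taken on each side, and the selected ten are numbered 1 (most
temporal) to 10 (most nasal). A centroid exactly on the midline joins the
side with fewer glands, ties to the temporal side — the published protocol
does not state this case, so the rule is a declared convention. For a right
eye (OD) the temporal side is image-left in standard en-face meibography;
for OS image-right. Because acquisition mirroring is device-dependent,
`temporal_side` is always overridable per image. Glands touching the image
border are excluded before selection (their geometry is incomplete).
Mirroring an image and flipping laterality yields identical
(index, D) pairs — asserted end-to-end in the tests.

## The synthetic generator

No patient images are distributed with the study, so the package ships a
generator that provides ground truth at three levels.

**Single gland.** A gland is a vertical sinusoidal centerline
$x(y) = A\sin(2\pi y/\lambda + \phi)$ with linearly tapered width; the
boundaries are the *horizontal* offsets of the centerline by half the local
width, and rasterization fills `round(w(r))` pixels per row centred on the
centerline column. Horizontal (rather than perpendicular) offsets were
chosen deliberately: the extractor samples widths along fixed rows, so this
family makes generator and extractor conventions identical, a constant-width
gland keeps exactly zero raster width variation, and the truth-vs-raster
comparison isolates pure discretization error. This family controls the
arc–chord factor (through $A$, $\lambda$) and the width term (through the
taper) independently, which is what the coefficient's two factors measure.

**Scene.** `generate_eyelid_scene()` packs non-overlapping glands on an
evenly spaced grid; the image is the Gaussian-smoothed mask plus additive
Gaussian noise, clipped to $[0,1]$. Scenes are pure functions of the seed.

**Cohort.** `generate_cohort()` emulates the paired design: for subject $s$
and gland $g$, the control eye's deformation is
$\mu_g + b_s + \varepsilon$, the treated eye's
$\mu_g + \delta_g + b_s + \varepsilon'$, with $b_s$ a shared subject-level
Gaussian inducing the between-eye correlation and $\varepsilon$ independent
per eye and gland. Defaults are the study conditions: $n = 36$ subjects
(recovered from the published SD/SE ratios, e.g. $(3.536/0.589)^2 = 36.04$;
the headline "68 eyes" count is inconsistent with the published tables'
internal arithmetic, so the summary utilities take $n$ explicitly),
$\mu_g$ = the published control-eye site means, $\delta_g$ = the published
per-gland paired differences, per-eye noise SD $3.536/\sqrt2$ so the
paired-difference SD matches the published pair-5 row, and between-eye
correlation 0.5 (not published; a moderate within-subject correlation is
typical of paired ocular-surface measures). With `render = TRUE` each eye
becomes a 12-gland scene whose central ten glands realize the subject's
deformation targets — the sinusoidal amplitude is solved per gland by 1-D
root finding on the analytic ground-truth coefficient, and targets below the
variant minimum raise an error rather than being clamped.

**What the generator does not emulate.** Real meibography has uneven
illumination, specular highlights, eyelash shadows, partial gland dropout,
and glands that branch or merge; deformation values are right-skewed and
bounded below by 1, whereas the value-level cohort model is Gaussian (so
zero-effect calibration and power checks are exact, but extreme-tail
behavior of real coefficients is not represented). Passing tests therefore
demonstrate correctness of the measurement and statistics machinery on
controlled geometry, not segmentation robustness on clinical images.

## Augmentation policy

The training-time augmentation scheme samples `N` of 11 registered
transforms (uniformly, without replacement) with an integer magnitude
`M` in 1–10 per operation; the working configuration is `N = 2`. The
published description names eight transforms; the registry completes the
stated count of 11 with shear and sharpness adjustments, following common
automatic-augmentation practice. Each transform's magnitude map is linear
with documented maxima (e.g. rotation ±30°, so M = 10 ↦ 30° and M = 1 ↦ 3°).
Geometric transforms apply identically to image and mask (nearest-neighbour
for the mask, background fill outside the canvas); photometric transforms
leave the mask byte-identical. Whether magnitudes were drawn per operation
or once per policy is not stated in the published description; meibomorph
draws per operation.

## Segmentation stage

The learned segmentation network is out of scope here; the stage contract is
"grayscale image in, binary mask out", and any predictor honouring it can be
plugged in upstream of the morphometry. The bundled classical baseline
(Gaussian smoothing → local-mean adaptive threshold → morphological opening
→ small-component removal) exists to exercise the pipeline end-to-end; its
defaults (`blur_sigma` 1, window 15, offset 0.15, opening radius 2,
min area 30) were calibrated on the synthetic generator, where it reaches
IoU ≥ 0.9 on noise-free scenes. Evaluation metrics follow the standard
pixel confusion matrix; "average IoU" is read as the mean of per-image IoU
(the pooled-confusion-matrix alternative is provided via
`evaluate_segmentation_set(method = "pooled")`). Empty-denominator
conventions: sensitivity 1 when the truth has no foreground, specificity 1
when no background, IoU 1 when both masks are empty. Manual corrections are
modelled by `apply_manual_edits()` with removal precedence on overlap.

## Cohort statistics

Per-gland paired t-tests (two-sided, α = 0.05, no multiple-testing
correction, matching the emulated analysis; Benjamini–Hochberg is available
but off by default), one-way ANOVA across the ten gland sites within each
group, and Fisher LSD post-hoc comparisons. The summary-level utilities
(`t_from_summary()`, `ci_from_summary()`, `anova_from_summary()`,
`infer_n_from_summary()`) recompute printed table internals from printed
rows alone; `anova_from_summary()` agrees with the raw-data decomposition to
1e−9 on moment-matched data (`groups_from_summary()` constructs such data by
affine transformation).

The LSD *ordering string* compresses the pairwise results: groups are
ordered by descending mean and split into blocks whose members are mutually
non-significant, with `>` between adjacent blocks; a group that is
non-significantly different from members of more than one block has no
strict rank and is listed as unplaced rather than forced into the chain. On
the published treatment-site profile this yields
`6, 5 > 7, 4 > 2, 1, 10, 9` with glands 3 and 8 unplaced — consistent with
the published `5, 6 > 3, 4 > 1, 2, 8, 9, 10` up to the published string's
silent omission of gland 7 (whose mean, 4.176, lies between the blocks it
separates) and its forcing of the bridging glands 3 and 8 into blocks.

## Numerical and design notes

* Coordinates are 1-based pixel centres (R convention); rows run down the
  image; the gland axis is the row direction. Scale is arbitrary pixels —
  no acquisition geometry is published — which is justified by the
  coefficient's scale invariance.
* Component labeling is 8-connected (row-run union-find); components are
  ordered left-to-right by centroid column, ties broken by topmost row.
* Monte-Carlo problem sizes in the tests (1000 zero-effect cohorts for
  type-I calibration, 500 cohorts for the pair-5 power check, 100 LSD
  simulations) give binomial standard errors comfortably inside the asserted
  bands while keeping the suite fast.
* The paired-difference SD implied by the cohort model is
  $\sqrt2\,\cdot$ `noise_sd` regardless of the between-eye correlation (the
  shared subject term cancels in the difference); the correlation parameter
  shapes the per-eye covariance, not the paired tests.
* Known limitations: no gland-dropout/atrophy scoring (meiboscore), no
  lower-eyelid scenes, no automatic laterality detection from image content,
  and the published clinical endpoints that depend on raw patient data
  (tear-film break-up time, axial length, spherical equivalent, and the
  between-group tables whose printed t values are not reconstructible from
  their printed summaries) are intentionally out of computational scope.
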