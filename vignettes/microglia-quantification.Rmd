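---
title: "Quantifying microglial surveillance, chemotaxis, morphology and amyloid engulfment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial surveillance, chemotaxis, morphology and amyloid engulfment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgliaQuant)
```

## Scope and scientific background

Microglia are the resident immune cells of the CNS. In the homeostatic state
their ramified processes continuously extend and retract, surveying the
parenchyma; after a focal insult (an ATP source, an amyloid-beta deposit) the
processes chemotax toward the site. `microgliaQuant` implements the standard
ex-vivo image-quantification battery for these behaviours:

* **surveillance** — a pixel-overlap *motility index* on binarized
  time-lapses;
* **chemotaxis** — directed process *velocity* from tracked tip positions,
  with arrival truncation at the target;
* **morphology** — per-field cell counts/density and per-cell skeleton
  metrics (endpoint count, total branch length);
* **engulfment** — two-channel *percent coverage* of an amyloid-beta deposit
  over time;
* **molecular readouts** — soma/process intensity partitioning of receptor
  staining (e.g. P2RY12) and double-delta-Ct qPCR fold changes;
* **statistics** — two-tailed t-tests, one-/two-way ANOVA, Sidak or Tukey
  post-hoc contrasts, mean ± SEM summaries.

Because manual imaging data of this kind are rarely deposited, the package
ships a first-class synthetic generator that renders calibrated image stacks
with **exact ground truth** for every stage, so the full pipeline can be
validated pixel-for-pixel.

## The motility index

Each frame of a single-cell ROI is binarized; consecutive binary frames are
color-merged. Pixels present only at `t+1` are *extending* (green), only at
`t` *retracting* (red), in both *stable* (yellow). The per-pair index is

$$ MI_t = \frac{\#\text{green} + \#\text{red}}{\#\text{yellow}} $$

and the time-lapse value is the arithmetic mean over pairs. Two conventions
required a decision:

* **Formula grouping.** The index is read as (green + red) / yellow — the
  change area normalized by the persistent area — rather than the literal
  left-to-right reading green + (red / yellow); the color semantics and
  standard usage in the surveillance literature imply the former.
* **Undefined pairs.** When a pair has no stable pixels the ratio is
  undefined. Such pairs are excluded from the mean and counted
  (`excluded_pairs`) instead of propagating infinity; a lapse in which every
  pair is undefined is flagged invalid.

The pipeline order is register → crop to ROI → binarize → classify. The
default threshold is a **single Otsu threshold computed on the temporal mean
image** and applied to all frames: per-frame thresholds flicker with noise,
and threshold flicker converts directly into spurious extend/retract pixels
that inflate the index. Fixed and per-frame Otsu thresholds remain available.

## Registration

Stabilization is translation-only phase correlation. The cross-power
spectrum of two frames related by a pure shift is a complex exponential;
its inverse transform peaks at the displacement. The integer peak is refined
by evaluating the inverse DFT on an upsampled local grid (a direct
matrix-multiply kernel, 0.1 px resolution at the default `upsample = 10`).

Two numerical choices matter:

* **Progressive estimation.** By default each frame is registered against
  its *predecessor* and the shifts are accumulated. A remodeling cell
  imaged over many frames genuinely changes shape; registering frame 15
  directly against frame 1 can lock onto a spurious sub-pixel offset that
  rounds to a 1-px shift and contaminates the change counts. Consecutive
  frames differ only by one turnover step, for which the zero-shift peak is
  unambiguous. `mode = "fixed"` restores direct-to-reference estimation.
* **Border fill.** Pixels shifted in from outside the field are filled with
  the stack's modal intensity (the background mode), not zero, so the
  border does not binarize into a false "extension" band.

Applied corrections are rounded to whole pixels; the returned shift table
keeps the sub-pixel estimates.

## Chemotaxis velocity

Velocity is **total path length over elapsed time** (the per-step distance
semantics of manual tip tracking), not net displacement; the two are equal
for a straight approach and diverge under jitter, and the path-length
definition matches what the tracking plugin this workflow emulates reports.
When a pipette position is attached, a track is truncated at the first point
within the capture radius — **2 µm by default**, a choice we had to make
because arrival is described only qualitatively in this literature — and
elapsed time ends at the truncation point. Tracks with fewer than two usable
points report an undefined velocity; per-cell aggregation averages the
defined process velocities (3–5 per cell is typical) and logs exclusions.

The automated tracker (for synthetic stacks) binarizes each frame, reduces
foreground blobs to centroids, seeds the `n` blobs nearest the pipette at
the first frame, and links each track to the nearest centroid within a
search radius per frame. It is deliberately minimal: no gap closing, no
multi-hypothesis linking — the synthetic tips are well separated, and manual
tracking remains the interface for real data (CSV input).

## Skeleton morphometry

Cells are binarized, labelled as 8-connected components, filtered by a
minimum area (default 50 px, which also removes isolated pixels from cell
statistics), and thinned to a topological skeleton with the Zhang–Suen
algorithm. Metrics follow the ImageJ-style skeleton-analysis conventions:

* **Endpoints** are skeleton pixels with exactly one 8-neighbour; an
  isolated skeleton pixel counts as one endpoint. Endpoint count per cell is
  the "number of processes".
* **Total branch length** sums adjacency steps at 1 px (orthogonal) and
  √2 px (diagonal), converted through the pixel size. The step weights are
  applied on the **minimum spanning tree** of the skeleton adjacency graph,
  which removes the redundant diagonal edge that corner configurations
  otherwise double-count — a straight n-px line measures exactly n − 1 px.

Two numerical caveats are documented rather than hidden. The (1, √2) chamfer
estimator overestimates the Euclidean length of a straight digital line by
up to 8.2 % at 22.5° orientation (it is exact along the axes and the
diagonals); the simulator therefore records as ground truth the chamfer
length of the pixel chains it renders, which is the quantity the skeleton
measures. And Zhang–Suen's two sub-iterations are directionally asymmetric,
so skeleton lengths under 90° rotation or mirroring agree to a fraction of a
percent, not exactly; endpoint counts are invariant.

The skeleton is computed on the whole cell mask, soma included (no soma
subtraction), matching the cited workflow. Touching cells are split by
watershed on the distance transform only when supplied soma markers indicate
more than one soma in a component.

Cell counting uses bright-component detection with a size **and** intensity
criterion: components must exceed the minimum area and a minimum mean
intensity (default: modal background + 6 robust deviations). The intensity
guard exists because Otsu on a field containing only background noise will
happily split the noise in two; the guard rejects those components. Density
is reported per mm³ from the field area times the imaged depth (default
20 µm); both the per-field count and the density are emitted because the
literature is not always explicit about which unit it prints.

## Percent coverage of amyloid-beta

Per time point and channel, frames are z-projected (when 3-D) and binarized
independently — the channels are acquired separately precisely to avoid
bleed-through, so no spectral unmixing is attempted. With deposit mask A and
microglia mask M:

$$ \text{coverage} = 100 \cdot \frac{|M \cap A|}{|A|} $$

(yellow over yellow + red; the denominator is the deposit area). The deposit
mask is re-binarized per time point by default, since a deposit can diffuse
or compact; `freeze_abeta = TRUE` reuses the first-frame mask, under which a
monotonically growing microglia mask provably yields a non-decreasing
series. An empty deposit at the first time point is an error; an empty
deposit at a later (per-frame) time point yields an undefined, flagged
point.

## Intensity partition and ΔΔCt

The receptor-staining partition sums all pixel intensities (total), the
intensities inside the union of the outlined soma masks (soma), and reports
the remainder as process signal with
`percent_in_processes = 100 · process / (process + soma)`. No background
subtraction is applied by default (field totals are reported in raw
arbitrary units); optional constant subtraction clamps at zero.

qPCR fold changes follow the Livak double-delta-Ct construction: replicate
Cq values average per (sample, gene); ΔCt = Cq(target) − Cq(reference gene)
per sample; ΔΔCt = group mean ΔCt − reference-group mean ΔCt; fold change
= 2^(−ΔΔCt), so the reference group is exactly 1.0. Group means of
per-sample ΔCt are used (not means of per-sample fold changes): that is the
standard Livak formulation. Samples lacking the reference gene are excluded
with a warning.

## Statistics

`compare_groups` wraps the designs used for these readouts: pooled-variance
two-tailed t-test, one-way ANOVA, and two-way ANOVA with interaction.
Post-hoc families: Sidak (`1 − (1 − p)^m` over raw pairwise pooled-variance
contrasts) and Tukey HSD — both are offered because methods sections and
figure legends in this literature alternate between them; Sidak is the
default in the pipeline configuration. Degenerate inputs are handled rather
than thrown: identical groups give statistic 0 and p = 1; zero within-group
variance with differing means is flagged degenerate with an infinite
statistic. SEM is computed over the stated unit of analysis (per cell for
motility/velocity, per animal or field for density, morphology and
intensity), which the pipeline config controls by what it treats as a
replicate.

## The synthetic generator: what it emulates, and what it does not

Defaults mirror the acquisition geometry of the study conditions this
package models: 1024 × 1024 px fields at 284/1024 ≈ 0.277 µm/px every 20 s
for surveillance and chemotaxis (a 20-min lapse is 61 frames / 60 pairs);
2048 × 2048 px at 284/2048 ≈ 0.139 µm/px every 15 min, 9 time points, for
engulfment; single 284 × 284 µm fields with a 20-µm depth for
density/morphology. The pixel pitch is inferred from the stated field width
and pixel counts — microscope pitch is rarely printed — and is configurable.

* **Baseline mode** plants one ramified cell and flips, per frame pair,
  `turnover_rate · A` of its `A` pixels: half additions on the outer margin,
  half removals from the boundary, with the exact extend/retract/stable
  counts recorded. At zero noise the analysis pipeline reproduces these
  counts exactly; this is the package's core oracle.
* **Chemotaxis mode** advances tips toward the pipette at the programmed
  µm/min (converted through pixel size and frame interval), with optional
  Gaussian positional jitter, arrival capture, and continuous-coordinate
  tracks as truth. Tips are rasterized at their continuous centres: rounding
  the centre first biases the recovered path length upward by several
  percent, because path length sums absolute step lengths.
* **Engulfment mode** renders a fixed circular deposit and covers exactly
  the scheduled percent of its pixels at each time point (linear
  interpolation between schedule knots), growing contiguously from an
  approach side.
* **Field mode** plants non-overlapping cells with bright somas and
  1-px-wide branches, recording the planted count, per-cell tip counts and
  chamfer branch lengths.
* **Intensity mode** chooses soma and process levels so the soma masks
  contain exactly the programmed fraction of total signal (to 8-bit
  quantization).

One seed in the config governs all draws (via an RNG-preserving scope; the
session's global RNG state is untouched), and identical config + seed gives
bit-identical stacks. Intensities are quantized to an 8-bit-like 0–255
integer grid, which also makes TIFF round-trips bit-exact; calibration and
axis layout travel in a JSON sidecar because plain TIFF tags cannot carry
them portably.

What the generator does **not** emulate — and therefore what passing tests
do not demonstrate about real data: photon (Poisson) noise and detector
characteristics, out-of-focus light and the z-blur of real 11-plane stacks
(a single 2-D plane stands in for the volume; analysis of real data runs on
z-max projections anyway), ATP diffusion physics, biomechanically realistic
process shapes, bleaching, and drift other than pure translation. Truth
recovery at zero noise validates the *bookkeeping* of every stage — set
algebra, calibration arithmetic, truncation, formula implementations — not
robustness to real microscope artefacts.

## Problem sizes and runtimes

The test suite and the acceptance script run the same pipelines at reduced
field sizes (128–512 px fields, 5–25 frames, 1024 px for the morphology
field) chosen so each stage still exercises its full code path — the
calibration, not the pixel count, carries the science — while the whole
suite completes in well under a minute per module. The full-size presets
remain the generator defaults.

## Known limitations

* Registration is translation-only; rotational drift is out of scope.
* The tip tracker is nearest-neighbour with no gap closing; it is a
  validation instrument for synthetic data, not a general tracker.
* ΔΔCt assumes ideal amplification efficiency (no Pfaffl correction) and no
  melt-curve QC.
* Mixed-effects nesting (cells within animals) is not modelled; the unit of
  analysis is whatever the pipeline config treats as a replicate.
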