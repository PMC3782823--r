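---
title: "Methods: graph-cut breast segmentation and density quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-cut breast segmentation and density quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammogc)
```

## Scope and model

`mammogc` segments a mediolateral-oblique (MLO) mammogram into its
anatomical regions — background, skin-air interface, uncompressed fat,
compressed fat, glandular tissue, and optionally a hyperdense mass — and
quantifies breast density as the glandular fraction of the breast area.
The central tool is a seeded multi-label graph cut: the user (or a test
fixture) marks a handful of pixels per region, and the labeling `L`
minimizes

$$E(L) = \lambda \sum_{p \in P} D_p(L_p)
       + \mu \sum_{\{p,q\} \in N} V_{p,q}\,\delta(L_p \neq L_q),$$

a Potts energy with a per-pixel data term and a contrast-modulated
boundary term. The assumptions are those of any intensity-driven
segmentation of film mammograms: regions are characterized by their gray
levels, radiodensity orders them (background darkest, mass brightest),
and spatial coherence is a reasonable prior. Texture is deliberately not
modeled.

## Data term

`D_p(l) = -\ln \Pr(I_p \mid l)`, where the likelihood is the 256-bin
histogram of the intensities of label `l`'s seed pixels. Histograms make
no parametric assumption and are exactly reproducible. Two numerical
choices matter:

- **Likelihood floor.** Seed sets are tiny, so most bins are empty. Bins
  are floored at `epsilon` (default `1e-6`) and renormalized, keeping
  every data cost finite (at most `-ln(epsilon) ≈ 13.8`).
- **Hard constraints.** A seeded pixel costs 0 for its own label and
  `hard_cost` (default `1e9`, i.e. `1e10` after the `lambda` weight) for
  any other. This exceeds any achievable finite energy by four orders of
  magnitude, so no cut ever violates a seed, while all arithmetic stays
  finite. `gc_params()` rejects values that could not dominate.

## Boundary term

`V_{p,q} = \exp(-(I_p - I_q)^2 / 2\sigma^2) / \mathrm{dist}(p,q)` over an
8-neighborhood by default (4 available). `sigma` (default 10 gray levels)
sets which intensity steps count as "an edge": discontinuities across
steps much larger than `sigma` are nearly free, those inside homogeneous
tissue cost the full Potts penalty. Diagonal pairs are attenuated by
their `sqrt(2)` spacing. The weights `lambda = 10` and `mu = 20` are the
defaults throughout; scaling both by a common factor provably leaves the
argmin unchanged (asserted in the tests), so only their ratio matters.

## Optimization

The energy is minimized by α-expansion. Labels are expanded in ascending
id order; each move solves one *exact* min-cut on the standard binary
expansion graph. Because the Potts interaction is a metric, each pairwise
term is submodular, and the move graph folds the linear parts of each
pairwise term into the terminal links (the classic decomposition of a
submodular binary function), which reaches the same exact minimum as the
auxiliary-node construction with a smaller graph. The min-cut itself is
delegated to igraph's max-flow; the test suite verifies move optimality
against exhaustive enumeration over all `2^n` labelings on small grids,
so the solver is treated as a black box with a checked contract.

Deterministic tie-breaking: the initial labeling is the per-pixel
data-cost argmin with ties to the smallest label id; a move is accepted
only if it strictly lowers the energy (beyond a `1e-7` relative
tolerance), so plateaus never churn the labeling; sweeps stop when a full
sweep accepts nothing or after `max_sweeps` (default 10; phantoms
converge in 2–3). Identical inputs therefore give identical labelings,
and the per-move energy trace (returned as `trace`) is non-increasing by
construction — both are asserted property-style in the tests.

## Preprocessing choices

- **Breast binarization.** A global threshold by Otsu's criterion
  computed on the log-intensity histogram `log(1 + I)`. On a linear
  histogram the maximum between-class variance can fall *between tissue
  classes inside the breast* — mammographic foregrounds are strongly
  multimodal (fat vs. glandular vs. pectoral), and with a bright, large
  glandular area the interior split wins. The log transform compresses
  the bright modes so the dominant gap, dark background versus tissue,
  prevails; the returned threshold still operates on raw intensities, and
  a fixed threshold can be supplied instead. A morphological opening
  (disk, radius 2; image replicate-padded so the breast is not eroded
  where it touches the frame) then removes thin debris, and only the
  largest 8-connected component is kept — film labels and opaque markers
  are bright but disconnected from the breast, which is what deletes
  them.
- **Order of stages.** binarize → background blanking → crop →
  downsample → median filter → orient → pectoral removal → graph cut.
  Cropping before downsampling keeps the offset bookkeeping in source
  pixels; filtering after downsampling filters the raster the cut will
  actually see.
- **Downsampling** is block averaging (factor 4 by default, the usual
  choice for digitized film) with half-up rounding; partial edge blocks
  average over the available pixels, so dimensions are `ceiling(dim/f)`.
- **Median filter** (3×3 by default) with edge replication at borders;
  written in-package because the border contract is part of the tested
  behavior.
- **Pectoral removal.** After orienting the chest wall to the left (an
  exact, invertible column reversal, side auto-detected from the border
  columns with ties to left), a region grows from the foreground pixel
  nearest the top-left corner inset by 3 px. Growth is 4-connected BFS —
  8-connectivity leaks across thin diagonal boundaries — admitting a
  pixel when it differs from the running region mean by at most
  `tolerance` (default 16 gray levels, roughly half the typical
  pectoral/glandular gap). Removed pectoral and background pixels are
  pinned to the background label during segmentation and never enter the
  density denominator.

## Density and BIRADS

`density % = 100 · glandular / breast`, where the breast is every
non-background, non-pectoral pixel — the skin-air band and both fat
layers are inside the denominator, because preserving the skin line is
diagnostically useful and discarding it biases the area. Mass pixels
count as dense by default (`include_mass`): a mass is hyperdense tissue
embedded in the glandular region; the flag exposes the alternative.
Categories: ≤25 → 1, ≤50 → 2, ≤75 → 3, >75 → 4. The printed category
table has a gap between 25 and 26; boundaries here are half-open upward,
so exactly 25.0 is category 1. Because a skin-inclusive breast area
deflates the percentage relative to categorical readings, the affine
calibration `y = 1.327 + 0.040x` is also evaluated; its raw value is
reported as-is, with a clearly-flagged convenience rounding (nearest
integer clipped to 1..4) available separately.

## Evaluation metrics

Completeness `TP/(TP+FN)`, correctness `TP/(TP+FP)`, quality
`TP/(TP+FP+FN)`, with the dense positive class being glandular ∪ mass.
Degenerate conventions (not derivable from the formulas): if both
prediction and truth are empty all three metrics are 1; if exactly one is
empty, the metric whose denominator vanishes is 0. For `TP > 0` the
algebraic identity `ρ = CM·CR/(CM + CR − CM·CR)` holds and is asserted to
`1e-12`. Group summaries are unweighted means over images. Evaluation
runs over the full provided raster (not a cropped sub-frame), which is
the simplest convention to state and reproduce.

## The phantom: what it does and does not emulate

`generate_phantom()` builds a geometric MLO stand-in: a half-ellipse
breast on the chest wall with a 3 px skin-air band and a 6 px
uncompressed-fat band, a compressed-fat interior, a central glandular
ellipse, an optional mass disk strictly inside it, an optional pectoral
right-triangle at the top chest-wall corner, and an optional bright
background rectangle emulating a film label. Pixels belong to a region
when their centre lies inside the analytic shape; inner shapes override
outer ones. Default mean intensities (5, 40, 80, 120, 180, 220; pectoral
200; artifact 230) follow the radiodensity ordering the generator
enforces, and `noise_sd = 5` additive Gaussian noise (clipped to 0..255,
rounded) reflects a mildly noisy digitization; `noise_sd = 8` is used as
the stress condition. Same spec and seed ⇒ bit-identical output.

What passing on phantoms shows: the geometry plumbing, the optimizer, the
hard constraints, the density arithmetic and the determinism contracts
are correct. What it does not show: performance on real parenchymal
texture, fuzzy fat–glandular transitions, overlapping structures or
scanner artifacts other than uniform bright labels — flat-intensity
regions plus i.i.d. noise are exactly the easy case for an
intensity-likelihood model, so phantom accuracy is an upper bound, not a
clinical claim.

## Problem sizes

The test and acceptance workloads are sized for a desk run: enumeration
oracles on grids up to 4×4 (binary, 100 random instances),
energy-monotonicity sweeps on fifty 16×16 4-label instances, twenty
noiseless and eight `noise_sd = 8` 64×64 phantoms for recovery checks
(≥99% pixel agreement; density within ±5 points; mass centroid inside
the truth disk), and 96×96 phantoms for the pipeline examples. Full-scale
mammograms (~1024² before the factor-4 downsample) run through the same
code path; only the fixtures are small.

## Known limitations

- Intensity histograms ignore texture; on real dense/fatty interdigitation
  the glandular boundary will be noisier than on phantoms.
- α-expansion guarantees a strong local optimum, not the global one, for
  3+ labels (binary sub-problems are exact).
- The region-growing pectoral extractor assumes a reasonably homogeneous
  muscle wedge reachable from the corner; curved or low-contrast pectoral
  edges would need a model-based boundary (out of scope here).
- The BIRADS calibration line is evaluated, never refitted; it is only as
  good as the density definition it was derived under.
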