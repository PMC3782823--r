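# mammogc

Computer-aided detection for mediolateral-oblique (MLO) mammograms:
seed-constrained multi-label **graph-cut segmentation** of breast anatomical
regions, **breast-density quantification** with BIRADS categorization, and
the standard region-overlap **evaluation metrics** — plus a synthetic
phantom generator with pixel-exact ground truth, so the entire pipeline is
testable without clinical data.

It is aimed at medical-image-analysis researchers who want a reproducible,
fully scriptable baseline for mammographic density segmentation: radiology
groups prototyping density measurement, and methodologists who need a
seeded multi-label graph-cut reference implementation with an
enumeration-verified optimizer.

## The model

A mammogram is partitioned into 3–6 anatomical labels (background, skin-air
interface, uncompressed fat, compressed fat, glandular tissue, and
optionally a hyperdense mass) by minimizing the Potts energy

```
E(L) = λ · Σ_{p∈P} D_p(L_p)  +  μ · Σ_{{p,q}∈N} V_{p,q} · δ(L_p ≠ L_q)
```

- `D_p(l) = −ln Pr(I_p | l)` is the data cost, from a 256-bin histogram of
  the user's seed pixels for label `l` (floored at `ε` and renormalized);
  seeded pixels are hard constraints (cost 0 for their label, a dominating
  finite cost otherwise).
- `V_{p,q} = exp(−(I_p−I_q)² / 2σ²) / dist(p,q)` is a contrast-sensitive
  boundary weight over a 4- or 8-neighborhood.
- Defaults `λ = 10`, `μ = 20`, `σ = 10`, 8-neighborhood.

The energy is minimized by **α-expansion**, each move being one exact
min-cut (igraph max-flow); for binary problems the result is verified in
the test suite against exhaustive enumeration over all `2^n` labelings.

Upstream of the cut, the pipeline binarizes the breast profile (Otsu
criterion on a log-intensity histogram, morphological opening, largest
8-connected component), blanks the background, crops, downsamples (block
mean, factor 4 by default), median-filters, orients the chest wall to the
left, and removes the pectoral muscle by seeded region growing.
Downstream, breast density is

```
density % = 100 · glandular pixels / breast pixels
```

with the breast defined as every non-background, non-pectoral pixel
(skin-air band included), mapped to a BIRADS category
(≤25 → 1, ≤50 → 2, ≤75 → 3, >75 → 4) and to the linear calibration
`y = 1.327 + 0.040·x`. Segmentations are scored by completeness
`TP/(TP+FN)`, correctness `TP/(TP+FP)` and quality `TP/(TP+FP+FN)`.

## Worked example

```r
library(mammogc)

spec  <- phantom_spec(height = 96, width = 96, noise_sd = 5, rng_seed = 7)
ph    <- generate_phantom(spec)      # image + pixel-exact truth labels
seeds <- sample_seeds(ph$truth, per_label = 4, rng_seed = 7)
res   <- run_pipeline(ph$image, seeds, pipeline_config(factor = 1))
res
#> mammogram pipeline run (side: left )
#> breast density: 43.28% (1886 / 4358 pixels)
#> BIRADS category: 2 (threshold table); 3.058 (linear model)

density_percentage(ph$truth)$percentage   # ground-truth density
#> [1] 43.30275
```

The pipeline binarized the phantom, removed the bright film-label
artifact, cropped, grew and removed the pectoral triangle, segmented the
remaining breast with 6 seed labels, and recovered the ground-truth
density (43.30%) to within 0.03 percentage points. `res$labels` holds the
per-pixel label map; `run_pipeline(..., out_dir = "out")` additionally
writes every intermediate image, a color label map, a JSON report and an
md5 `MANIFEST.json` (reruns are byte-identical).

A command-line front end with `phantom | preprocess | pectoral | segment |
density | run` subcommands is installed at
`system.file("cli", "mammogc", package = "mammogc")`.

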