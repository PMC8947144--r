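# sxtcell

Post-processing and mesoscale spatial analysis of organelle segmentations
in single-cell soft X-ray tomograms (SXT).

SXT images whole cells in a near-native state at ~25 nm resolution; each
voxel carries a linear absorption coefficient (LAC, 1/µm) proportional to
local molecular density, which is what makes organelles (nucleus,
mitochondria, dense-core insulin vesicles) visible. Deep networks that
segment such tomograms work on 2D slices and patches; turning their
per-slice output into biology takes a chain of well-defined 3D
post-processing steps and spatial statistics. `sxtcell` implements that
chain for people studying subcellular organization — e.g. insulin-vesicle
trafficking in pancreatic β-cells — without shipping or requiring any
network weights:

* **I/O and preprocessing** — MRC / multi-page TIFF volume readers and
  writers, cropping, resampling to the canonical 280 × 480 × 320 shape,
  slicing along X/Y/Z, and overlapping 150 × 50 patch tiling (≥30 %
  overlap) with score-based patch merging.
* **Fusion** — the three algorithms that assemble 3D masks:
  1. *multi-view voting*: a voxel is foreground when ≥2 of the three
     per-axis reconstructions agree, `v = 1 iff vX + vY + vZ ≥ 2`;
  2. *2D→3D instance linking*: 2D instances on adjacent slices merge into
     one 3D instance when the IoU of their footprints exceeds 0.5,
     chained transitively along the slicing axis;
  3. *priority merging* into one cell scene with
     vesicle > nucleus > mitochondria > cell.
* **Metrics** — Dice `2|P∩G|/(|P|+|G|)`; instance recall with the
  normalized center distance `d = d_u/(r_pred + r_gt)` (a pair matches
  when `d < 1`); AP50 (average precision at mask IoU ≥ 0.5); slice-wise
  normalized intensity and organelle/cytoplasm contrast ratios.
* **Mesoscale analysis** — Euclidean distance fields to the nucleus and
  plasma membranes; the 8-shell partition of the cytosol by normalized
  depth `λ = d_nuc/(d_nuc + d_pm)`; radial distribution functions
  `g_k = (count_k/V_k)/(N/V)` for vesicle centers, mitochondria voxels
  and vesicle–mitochondria contacts (vesicle voxels within 1.5 voxels of
  the mitochondria surface); per-vesicle radial LAC profiles that expose
  the dense-core signature.
* **Synthetic phantoms** — a seeded generator for an INS-1E-like cell
  (ellipsoidal cell and nucleus, tubular mitochondria at contrast ≈1.1,
  dense-core vesicles with LAC rising 0.35 → 0.55 toward the center),
  prediction-degradation simulation, and a simple threshold segmentation
  backend, so every stage runs end-to-end without tomograms.

## Worked example

```r
library(sxtcell)

# a full phantom at half canonical resolution, deterministic by seed
ph <- generate_phantom(phantom_spec(seed = 7))
ph
#> <sxt_phantom> 140x240x160 voxels; cell 1383175, nucleus 293180,
#>               mito 5287 voxels; 40 vesicles

# segment it with the threshold backend, fuse into scenes, evaluate
seg <- threshold_segment(ph$volume, default_thresholds(ph$spec))
scene_pred <- fuse_priority(seg$cell, seg$nucleus, seg$mito, seg$vesicles)
scene_gt   <- fuse_priority(ph$cell, ph$nucleus, ph$mito, ph$vesicles)
evaluate_segmentation(scene_pred, scene_gt, seg$vesicles, ph$vesicles)
#> <sxt_eval>
#>   Dice: cell 0.988, mitochondria 0.431, nucleus 0.997, vesicle 0.159
#>   Recall 0.950, AP50 0.000, instances pred/gt 38/40
```

The pattern is instructive: the large smooth classes (cell, nucleus)
segment almost perfectly, low-contrast mitochondria poorly, and vesicles
show the characteristic split between high *instance recall* (0.95 — the
right objects are found, centers within the matching distance) and low
*voxel overlap* (Dice 0.16, AP50 0) because the crude threshold backend
only captures the dense cores. Distance-based recall is exactly the
metric that stays meaningful when mask boundaries are unreliable.

```r
# where do the vesicles sit between nucleus and plasma membrane?
fields <- distance_fields(ph$cell, ph$nucleus)
shells <- shell_partition(fields$d_nuc, fields$d_pm, n_shells = 8)
rec <- extract_instances(ph$vesicles, ph$volume)
rdf <- rdf_points(as.matrix(rec[, c("cx", "cy", "cz")]), shells)
rdf
#> # A tibble: 8 × 4
#>   shell count shell_volume     g
#>   <int> <int>        <int> <dbl>
#> 1     1     0        65652 0
#> 2     2     3        88615 0.923
#> 3     3     1       104856 0.260
#> 4     4    10       122344 2.23
#> 5     5     8       144663 1.51
#> 6     6     9       167338 1.47
#> 7     7     9       194410 1.26
#> 8     8     0       202117 0

autoplot(rdf)   # g vs shell with functional regions shaded
```

`g = 1` is the uniform-random baseline; `g > 1` marks enrichment. Here
the finite-size vesicles are excluded from the thinnest shells (1 and 8)
because a sphere cannot be packed there — a geometric effect the
shell-volume normalization makes visible. Shell 1 is the perinuclear
space, shells 2–3 the vesicle-maturation region, 4–6 transportation, 7–8
secretion (`functional_regions()`).

```r
# dense-core check: LAC rises from the vesicle boundary to its center
autoplot(lac_radial_profile(ph$volume, ph$vesicles == 1L))

# mitochondria contrast over the surrounding cytoplasm
cyto <- ph$cell & !ph$nucleus & !ph$mito & !(ph$vesicles > 0)
contrast_ratio(ph$volume, ph$mito, cyto)
#> [1] 1.1124
```

A shell entry point wrapping the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/sxt simulate phantom --out run1 --seed 7
Rscript inst/cli/sxt analyze rdf --cell run1/cell.tif \
    --nucleus run1/nucleus.tif --vesicles run1/vesicles.tif \
    --population vesicles --out run1/rdf.csv
```

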