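# condensatr

Quantification of biomolecular (RNA) condensates in fluorescence microscopy
images, for researchers measuring phase-separated droplets in vitro and
bright intracellular foci in rod-shaped bacteria.

Repeat-expansion RNAs tagged with fluorogenic aptamers form condensates that
appear as bright near-circular objects. The biology is read out through a
small set of image statistics, all implemented here as a reproducible,
tested pipeline:

* **Droplet detection** by the classic threshold recipe: background
  F<sub>B</sub> estimated by iterative exclusion, objects at
  F<sub>B</sub> + 3·SD, minimum equivalent diameter 0.5 µm
  (2·√(area/π)), densities per 4430 µm² imaging view.
* **Partition ratio** of each condensate: mean intensity inside the object
  divided by the condensate-free background mean (solution in vitro;
  foci-subtracted cytoplasm in cells).
* **Bacterial cell recipe**: smooth → segment cells at whole-image
  background + 3·SD → flag rod-shaped single cells (aspect ≥ 2, solidity
  ≥ 0.9, area bounds; audit flag, not deletion) → bright-spot foci at
  cellular background + 3·SD with contrast/diameter filters →
  child-in-parent assignment → foci-subtracted cellular background →
  per-focus partition ratios, per-cell foci counts, cell lengths.
* **Colocalization**: Pearson correlation of two channels over cell masks.
* **Ring vs filled classification** from core/shell radial intensity
  (core < 0.7 × shell ⇒ ring), and ring percentages.
* **FRAP fitting**: I(t) = A − B·exp(−t/τ) on post-bleach frames; mobile
  fraction (plateau − post)/(pre − post), t½ = τ·ln 2.
* **Summary statistics**: pooled-variance Student's t-test, condensation
  kinetics plateaus and t90, aggregation by repeat-content ratio
  (N<sub>CAG</sub>/N<sub>total</sub>), fluorescence-to-concentration
  calibration.
* **Synthetic microscopy generator** with ground-truth manifests (droplet
  fields, spherocylindrical cells with polar foci, two-channel images with
  a target PCC, FRAP traces, nucleation-and-growth time series), used to
  validate every stage by seeded parameter recovery.

Everything is tidyverse-shaped: record-producing functions return tibbles,
fitted objects support `tidy()`/`glance()`/`autoplot()`, and the pipeline
driver writes plain CSV/JSON/YAML run directories.

## Worked example

```r
library(condensatr)

fs <- field_spec(seed = 42)                        # 256x256 px, 0.065 um/px
dr <- random_droplets(fs, 15, diameter_um = c(1.4, 1.8), partition_ratio = 7.7)
sf <- render_droplet_field(fs, dr)                 # image + ground truth

q <- quant_droplets(sf$image)
glance(q)
#> # A tibble: 1 x 6
#>   n_condensates density_per_view bg_mean bg_sd median_partition_ratio median_diameter_um
#>           <int>            <dbl>   <dbl> <dbl>                  <dbl>              <dbl>
#> 1            15             240.    100.  9.97                   7.68               1.66
```

All 15 rendered droplets are recovered; the background estimate matches the
generator's 100 ± 10 ADU noise model; the median partition ratio (7.68) and
equivalent diameter (1.66 µm) match the generator's truth (7.7; diameters
uniform in 1.4–1.8 µm). `tidy(q)` returns the per-droplet table and
`autoplot(q)` overlays detections on the field.

The cellular recipe is one call as well:

```r
cells <- random_cells(fs <- field_spec(512, 512, seed = 7), 30)
foci  <- place_foci(cells, n_foci = rep(0:3, length.out = 30))
img   <- render_cell_field(fs, cells, foci)$image
qc    <- quant_cells(img)
glance(qc)        # cells, single rods, foci, fraction with 1-2 foci, ...
tidy(qc, "foci")  # per-focus records with partition ratios
```

A thin CLI over these functions lives in `inst/cli/condensatr.R`
(`simulate`, `quant-droplets`, `quant-cells`, `frap`, `coloc`).

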