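# micromorph

Quantitative microglial morphometry for DAB-stained, haematoxylin
counterstained brightfield sections, written for neuropathology studies
that compare microglial **burden**, **activation** and **dystrophy**
across brain regions and diagnostic groups (frontotemporal lobar
degeneration subtypes, Alzheimer's disease, controls).

The package implements the full measurement protocol as composable R
functions:

* **Sampling** — `sample_squares()` places random analysis squares
  (default ten, 1000 px = 500 µm a side at 0.5 µm/px) uniformly inside a
  region-of-interest polygon, disjoint by default.
* **Segmentation** — `dab_mask()` thresholds each square in HSV on the
  0–255 scale (defaults: hue 0–30, saturation 60–80, the band selecting
  brown DAB over blue haematoxylin); `extract_cells()` labels 8-connected
  components and excludes objects below a 5 µm (ten-pixel)
  equivalent-circle diameter.
* **Morphometry** — burden is the areal fraction
  (`areal_fraction()`, % of pixels stained); per cell,
  circularity `4·pi·A/P²` (1 = amoeboid/activated, low = ramified) and
  perimeter in µm (larger = more ramified) via a corner-corrected
  boundary-chain estimator; `aggregate_region()` forms means of square
  means.
* **Dystrophy** — Iba1 cells are linked into cell clusters across ≤ 3 µm
  gaps, skeletonised (`skeletonize_cell()`), classified into ramified /
  amoeboid / hypertrophic / rod-shaped / dystrophic archetypes
  (`classify_cell()`), and the region receives an ordinal 1–5 score
  (`score_dystrophy()`) driven by the dystrophic fraction, the
  intact-soma fraction and a punctate-staining index, with rod-shaped and
  hypertrophic presence calls (`morphology_presence()`).
* **Statistics** — `run_level()` runs the six-level hierarchical group
  comparison (Kruskal–Wallis + Dunn's post hoc, rank-sum, paired
  grey-vs-white Wilcoxon signed-rank, Fisher's exact for sex) with exact
  small-sample modes, and emits p-value heat-map matrices with a
  three-band significance class.
* **Synthetic histology** — `make_cell_stamp()`, `render_region()` and
  `make_synthetic_cohort()` generate stained-section images with planted
  cells of known class, areal fraction and dystrophy severity, so the
  whole pipeline is testable against ground truth without any slide data.

`run_pipeline()` orchestrates generator → sampling → segmentation →
morphometry → dystrophy → statistics from one configuration with
deterministic seeding; identical configurations reproduce byte-identical
output tables. A thin command-line wrapper lives in
`inst/cli/micromorph.R`.

## Worked example

Render a synthetic CD68 white-matter region at a 6% target burden,
analyse it with ten 200-px squares, then score a planted severity-3 Iba1
region and run the paired grey-vs-white statistics on a 20-case synthetic
cohort:

```r
library(micromorph)

spec <- region_spec(region_label = "FW", image_shape = c(1000, 1000),
                    target_burden = 6, seed = 42)
rr <- render_region(spec)
rr$image$marker <- "CD68"
an <- analyze_region_image(rr$image, n_squares = 10, side = 200, seed = 1)
an$square_metrics[1:3, ]
#>  square burden mean_circularity mean_perimeter n_cells
#>       0 8.0175       0.09690832      192.42831       3
#>       1 7.9050       0.14510685      134.02152       5
#>       2 2.0300       0.46766151       65.69272       3
an$region[, c("burden", "circularity", "perimeter", "n_cells")]
#>  burden circularity perimeter n_cells
#>  6.0265   0.3364136  113.1788      43
rr$truth$planted_burden
#> [1] 5.44
```

The region mean (6.03%) sits near the planted ground truth (5.44%); the
gap is spatial sampling error from covering 40% of the region with ten
squares — per-square burdens here range from 2.0% to 11.7%, which is why
the protocol averages ten squares per region.

```r
sp2 <- region_spec(image_shape = c(560, 560), layout = "spaced",
                   n_cells = 25, dystrophy_severity = 3, seed = 7)
rr2 <- render_region(sp2); rr2$image$marker <- "Iba1"
an2 <- analyze_region_image(rr2$image, n_squares = 1, side = 560, seed = 1)
table(an2$classified$morph_class)
#>     amoeboid   dystrophic hypertrophic     ramified
#>            2           18            4            1
an2$dystrophy[c("score", "dystrophic_fraction", "punctate_index")]
#> $score: 3    $dystrophic_fraction: 0.72    $punctate_index: 0
```

18 of 25 cell clusters are read as dystrophic (fraction 0.72 — "most,
but not all"), so the region scores 3, exactly the planted severity.

```r
cfg <- cohort_config_contrast(n = 20, seed = 1)
study <- run_synthetic_study(cfg)
lv <- run_level(study$metrics, study$cases, level = 1)
lv$results[lv$results$test == "wilcoxon_paired" &
           lv$results$metric %in% c("burden", "dystrophy_score"),
           c("metric", "marker", "region", "statistic", "p_value")]
#>           metric marker   region statistic      p_value
#>           burden   CD68 FG vs FW         8 4.768372e-05
#>           burden   CD68 TG vs TW        15 2.613068e-04
#>           burden   Iba1 FG vs FW         2 5.722046e-06
#>           burden   Iba1 TG vs TW         1 3.814697e-06
#>  dystrophy_score   Iba1 FG vs FW         0 1.525879e-05
#>  dystrophy_score   Iba1 TG vs TW         0 1.525879e-05
```

The cohort is configured with the qualitative contrasts seen in diseased
tissue — higher white-matter burden and more severe white-matter
dystrophy — and the paired signed-rank tests recover both directions
(small W = grey below white) at p ≪ 0.05 in both lobes.

The methods vignette (`vignettes/microglial-morphometry.Rmd`) documents
the model, every threshold and its default, the generator's scope, and
the numerical choices.

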