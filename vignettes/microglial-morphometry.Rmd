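---
title: "Quantifying microglial burden, activation and dystrophy in stained sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial burden, activation and dystrophy in stained sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromorph)
```

## The measurement problem

Post-mortem studies of neurodegenerative disease stain microglia with
3,3'-diaminobenzidine (DAB, brown) against a haematoxylin (blue) counterstain,
using markers such as CD68 (phagocytic microglia), CR3/43 (antigen-presenting
microglia) and Iba1 (all microglia). Three questions are asked of every
region of tissue (frontal and temporal grey and white matter, FG/FW/TG/TW):

* **Burden** — what percentage of tissue area is marker-positive?
* **Activation** — are the cells rounded and amoeboid (activated) or
  branched and ramified (surveillant)? Circularity
  $C = 4\pi A / P^2$ and cell perimeter $P$ summarise this: $C \to 1$ for
  amoeboid cells; a larger perimeter indicates more ramified cells.
* **Dystrophy** — do the Iba1-stained cells show senescence-associated
  degeneration (deramification; thin, shortened, beaded, tortuous or
  fragmented processes), graded on an ordinal 1–5 scale?

micromorph implements this protocol as composable stages — random-square
sampling, HSV colour thresholding, minimum-diameter exclusion, per-cell
morphometry, skeleton-based dystrophy scoring, and hierarchical
nonparametric group statistics — together with a synthetic histology
generator that plants cells of known class, areal fraction and severity so
that every stage can be tested against ground truth. No real slides ship
with the package; the generator is the test bed.

## Sampling and segmentation

`sample_squares()` draws analysis squares (default ten, 1000 px = 500 µm a
side at 0.5 µm/px) uniformly over the admissible top-left positions inside
the region-of-interest polygon. Containment is tested on the four corners
plus the centre by default; exact rasterised containment is available via
`containment = "raster"`. Squares are pairwise disjoint by default
(rejection sampling with a retry cap) so that cells are never counted
twice in a region mean; near the random-packing limit (roughly 55–60%
coverage) the sampler stops with an error that suggests overlap mode
rather than silently degrading.

`dab_mask()` thresholds each square in HSV on the 0–255 scale used by
common raster tools: hue 0–30 and saturation 60–80 by default, the band
that selects brown DAB over blue-violet haematoxylin (hue ≈ 150) and
near-white background (saturation < 40). The saturation band is a bracket
for specific staining: the lower edge rejects weak nonspecific staining
and is the knob a user would adjust per slide for background level. The
synthetic generator renders DAB pixels at hue ≈ 15, saturation ≈ 70 —
inside the default band with enough margin that 8-bit quantisation cannot
move a pixel across a threshold, which is why planted and detected masks
agree exactly on synthetic sections. Passing tests therefore demonstrate
the correctness of the machinery downstream of colour segmentation; they
do not demonstrate robustness to the staining variability of real slides,
which has no counterpart in the generator beyond a bounded jitter knob
(`stain_noise`).

`extract_cells()` labels 8-connected components and removes those whose
equivalent-circle diameter $2\sqrt{A/\pi}$ falls below 5 µm (ten pixels),
excluding out-of-plane cell parts. "Diameter" of an irregular object is
deliberately the equivalent-circle diameter — a size criterion, not a
shape criterion. Burden is computed from the *raw* thresholded mask by
default (`burden_basis = "raw"`), because the size filter is a rule about
which objects count as cells for morphometry, not about how much stain is
present; `burden_basis = "filtered"` is available.

## Morphometry

Perimeter uses a corner-corrected boundary chain on the outer contour:
axial steps count 1, diagonal steps $\sqrt2$, each direction change
contributes $-0.15$, and the closed contour receives $+\pi$ for the
half-pixel offset between pixel centres and the true object boundary.
Holes are not counted. On rasterised references this estimator is accurate
to about 1% for both axis-aligned squares and discs (a plain
$1/\sqrt2$-weighted chain overestimates a digitised circle by ≈ 5%, enough
to push disc circularity to 0.91). A one-pixel object is defined to have
perimeter $\pi$ px and circularity 1. Circularity is clipped to $[0,1]$
and uses the object's own contour, not its convex hull.

Region summaries are means of square means ("averaged across all cells
present … then averaged across the ten squares"): burden averages over all
squares; circularity and perimeter average over squares containing at
least one cell, with `n_squares_used` recording the denominator, and are
`NA` — not 0 — when no square has a cell, since 0 would be a shape
statement about cells that do not exist. The pooled-cell alternative is
deliberately not the default; with unequal cells per square it weights
squares unequally.

## The dystrophy score

The ordinal rubric is verbal ("some … at least half … most … all … only
generalised punctate staining"); micromorph operationalises it with three
measured quantities per region:

* $f$ — the fraction of cell clusters classified dystrophic,
* $s$ — the fraction of dystrophic clusters with an intact soma
  (maximal inscribed disc ≥ 7 µm, a typical microglial soma scale),
* $q$ — the punctate index: the fraction of stained area in components
  below the 5 µm exclusion diameter (sub-cellular debris).

Score 1 if $f \le 0.05$; 2 if $f \le 0.5$; 3 if $f < 0.95$; 4 if
$f \ge 0.95$ and $s \ge 0.25$; 5 if $f \ge 0.95$ and $s < 0.25$, or
whenever $q \ge 0.5$. A region with no cells at all is scored 5 when
staining is punctate and is otherwise flagged undefined — absence of
staining is not evidence of very severe dystrophy. All cut points are
named entries of `dystrophy_thresholds()`. The score is computed only for
Iba1 (the pan-microglial marker used for dystrophy assessment); requesting
it for CD68 or CR3/43 is an error, not a silent zero.

Because fragments of one degenerating cell appear as separate connected
components, components lying within 3 µm of one another (Euclidean
dilation linkage) are attributed to a single *cell cluster* before
classification; $f$ counts clusters, not fragments. Cells are pooled
across a region's squares for scoring (the rubric describes a per-region
impression); a per-square-median variant would be a reasonable alternative
but is not the default.

### The morphology classifier

Each cluster is thinned to a Zhang–Suen skeleton and summarised: endpoints
(ring crossing number 1), junctions (crossing number ≥ 3 — raw neighbour
counts misread the corner pixels of diagonal runs as junctions), total
process length (weighted adjacency chain), process width (twice the
distance transform along the skeleton, minus one pixel, median taken
outside the widest — soma — zone), branch tortuosity (arc/chord over
simple-path branches cut at the soma zone), and beads (isolated width
maxima on thin processes). The decision tree, in priority order:

1. **dystrophic** — fragmented ($\ge 2$ components per cluster), or beaded
   ($\ge 3$ beads), or tortuous (mean arc/chord > 1.8), or deramified
   (≤ 2 endpoints, processes < 15 µm total, soma present *and*
   circularity < 0.6 — the circularity guard separates a deramified stump
   from a plain amoeboid cell, which matches the other three conditions
   yet is normal morphology);
2. **rod** — axis ratio ≥ 3 with at most one skeleton junction;
3. **hypertrophic** — process width ≥ 2 µm and ≥ 4 endpoints (bushy,
   short, thickened processes);
4. **amoeboid** — circularity ≥ 0.6;
5. **ramified** otherwise.

Bead detection is the numerically delicate part: the distance transform
oscillates by half a pixel along rasterised branches, and junction and
soma neighbourhoods are legitimate width maxima. Beads are therefore
sought only on thin branches (median width ≤ 2.8 µm), outside soma and
junction zones, on a 3-tap smoothed profile, and must be resolvable
swellings: at least 1.8× the branch median, at least 1.7 µm and at most
3.2 µm wide, with 0.8 µm prominence. These values are geometric statements
about what a bead is at 0.5 µm/px, not fitted constants.

## The synthetic generator

`make_cell_stamp()` draws one cell of a named archetype with its class
invariants enforced at construction (rod axis ratio ≥ 3, amoeboid < 1.5,
dystrophic stamps fragmented into ≥ 2 components). `render_region()`
supports two layouts:

* **random** — cells placed uniformly with overlap allowed (merged cells
  occur in tissue and are counted once in burden), rejection-sampled until
  the realised areal fraction is within 10% relative of the target.
  Targets above 60% are refused: beyond that, overlapping stamps stop
  resembling stained tissue. Ground truth stores the realised burden,
  which equals the rendered foreground fraction by construction.
* **spaced** — exactly `n_cells` cells on a jittered 55 µm grid, far
  enough apart that distinct cells can never be linked into one cluster.
  The planted dystrophic fraction follows the severity preset
  (0, 0.32, 0.72, 1, 1 for severities 1–5): severities 2–4 use
  soma-bearing fragmented cells, severity 5 uses soma-less fragments plus
  punctate debris planted to ≈ 55–60% of stained area. These are the
  clear-cut parameterisations of the rubric's verbal grades; the exact
  counts (e.g. 8 of 25 cells at severity 2) remove binomial noise from
  what is meant to be a test of the measurement chain, not of sampling
  error.

Nuclei are blue-violet discs, the background near-white with bounded
noise. What the generator does **not** emulate: stain intensity gradients
across a slide, section thickness and focus effects, touching-cell
declumping (the pipeline, like the protocol it implements, does not split
touching cells), and real morphological continua between archetypes.
Passing recovery tests on synthetic sections shows the chain of
sampling → thresholding → measurement → classification → scoring is
correct and deterministic; transfer to real slides rests on the colour
thresholds and classifier cut points, which are all exposed configuration.

## Cohorts and the six comparison levels

`make_synthetic_cohort()` emits case records mirroring the study design
this pipeline supports: 60 cases (50 FTLD — 20 FTLD-tau with CBD, MAPT,
Picks and PSP subtypes; 26 FTLD-TDP with subtypes A (sporadic, *GRN*,
*C9orf72*, *TBK1*), B and C; 4 FTLD-FUS — plus five AD and five controls),
with labels at six comparison levels: (1) overall groups, (2) main FTLD
subtypes and AD, (3) FTLD-tau subtypes, (4) FTLD-TDP subtypes,
(5) sporadic versus genetic FTLD-TDPA, (6) genetic subtypes, where the
FTLD-*C9orf72* group contains only FTLD-TDPA cases so that the comparison
isolates the mutation rather than the pathological subtype.
`validate_case_records()` enforces the hierarchy (an FTLD-*GRN* label
implies FTLD-TDPA implies FTLD-TDP implies FTLD; FTLD-TDPC cannot be
genetic; controls carry no onset age). Demographics are drawn uniformly
from the per-group ranges — they exist to exercise the statistics, not to
model covariance between age and pathology.

`run_level()` compares every metric × marker × region across a level's
groups with Kruskal–Wallis plus Dunn's post hoc pairs (rank-sum for two
groups), compares grey versus white matter within each lobe and group with
paired Wilcoxon signed-rank tests, handles demographics with the same
machinery (sex by Fisher's exact test, missing values excluded listwise),
and emits p-value matrices with a three-band significance class
(p < 0.01, 0.01–0.05, ≥ 0.05). P values are unadjusted by default,
matching a fixed p < 0.05 threshold; Holm and Benjamini–Hochberg
adjustments are flags, as is Dunn–Bonferroni.

### Numerical choices in the tests

* Kruskal–Wallis H is tie-corrected; all-equal input gives H = 0, p = 1 by
  convention. Exact permutation p-values are available for any sample
  via `method = "exact"` (practical to total n ≈ 12, enumerating distinct
  group assignments); the automatic switch uses them below total n = 10,
  where the multinomial enumeration is instant.
* Rank-sum: exact subset enumeration (ties handled by midranks) below
  total n = 13; otherwise a tie-corrected normal approximation without
  continuity correction.
* Signed-rank: zero differences are dropped (Pratt handling is a flag);
  the exact distribution is built by convolution over doubled midranks up
  to n = 25, exact in the presence of ties; beyond that a normal
  approximation with $\mathrm{Var}(W) = \sum r_i^2/4$, which is exact
  under random signs whatever the tie structure. Two-sided p-values for
  the discrete statistics are the doubled smaller tail, capped at 1.
* Fisher's exact test delegates to `stats::fisher.test` (2 × k); the test
  suite checks it against an independent hypergeometric enumeration.

The null-calibration simulations use sample sizes at which each test's
attainable size is close to nominal: three groups of 10 (Kruskal–Wallis),
12 versus 12 (rank-sum), n = 15 exact (signed-rank), and two groups of
250 for Fisher — at small n Fisher's discreteness makes its true size
fall below 3%, so size calibration is only informative at larger counts.

## Problem sizes used in the shipped tests

Synthetic canvases in the tests are deliberately desk-scale: 500 px
squares-free canvases for burden recovery, 560 px spaced canvases with 25
cells for severity recovery (100 seeded regions per severity), 100 stamps
per class for the classifier confusion matrix, and a 20-case cohort on
440 px canvases with four 110 px squares per region for the paired
grey/white contrasts. All sizes scale through `region_spec()` and
`cohort_config()`; the defaults of `sample_squares()` (ten 1000-px
squares) reflect the full-size protocol.

## Known limitations

* Colour segmentation is a global band; there is no per-slide automatic
  saturation tuning, because no defensible tuning rule is available —
  the band edges are configuration.
* Touching cells are not split; in dense regions merged cells bias
  per-cell shape statistics toward lower circularity. The burden readout
  is unaffected.
* The classifier's cut points are calibrated in micrometres at
  0.5 µm/px-scale morphology; very different magnifications deserve a
  review of `dystrophy_thresholds()`.
* The ordinal score is a deterministic mapping; it reproduces a single
  consistent rater, not inter-rater variability.
* Exact-permutation modes for Kruskal–Wallis and Dunn grow multinomially
  and are intended for small groups only.
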