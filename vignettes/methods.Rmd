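---
title: "Methods: spatial TME graphs for NAC response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial TME graphs for NAC response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The two-step model

`tmegraph` implements a two-step analysis of H&E-stained tissue for
predicting response to neoadjuvant chemotherapy (pCR vs RD, with pCR
the positive class).

**Step one** turns annotated slides into histology classification maps.
A non-overlapping 224-pixel grid (stride = tile size, anchored at the
image origin) is laid over the slide; a tile is kept only when its
exact polygon-intersection area with an annotated region reaches 90% of
the tile area, and it inherits the class of the region with the largest
overlap (ties break to the lower class id, for determinism). Tiles are
stain-normalized by SVD-based stain-vector estimation in optical
density (OD) space: tissue pixels (OD norm ≥ 0.15) are projected onto
their top two singular directions and the stain vectors are read off at
the 1st/99th angle percentiles; concentrations are rescaled to the
reference's 99th-percentile maxima and remixed. When estimation
degenerates (near-white tiles, single-stain fields) the standard H&E OD
vectors serve as fallback. Texture features are computed on the
deconvolved hematoxylin channel — the nuclear stain carries most of the
discriminative morphology — with a catalog of exactly 80 features:
GLCM 20 (contrast, correlation, energy, homogeneity, entropy × 4
offsets at distance 1 over 32 gray levels), Gabor 32 (mean and sd of
response magnitude, 4 frequencies × 4 orientations), uniform LBP 18
(P = 16, R = 2), Tamura 3, and 7 histogram moments. Features that are
all-zero, contain NA, or exactly duplicate an earlier feature are
excluded (keep-first); the retained count is data-dependent and is
reported, not asserted. Four classifiers — 1NN, linear SVM, RBF SVM and
RUSBoost ensemble trees — are compared under stratified eightfold
cross-validation (train on seven folds, test on one), with
standardization fit on training folds only. Predicted classes are
assembled into a per-patient class-id grid, with a background sentinel
for unobserved cells.

**Step two** models tissue architecture. For one histology class, the
4-connected components of map cells form *tile clusters*; cluster
centroids of a class pair become the nodes of an undirected, unweighted
geometric graph with an edge whenever two centroids lie within the
radius (default 8 tile widths). Per pair, 20 features are computed in
three blocks: texture averages over cluster-member tiles (GLCM
contrast, GLCM homogeneity, histogram entropy per class, plus the node
count ratio), spectral node statistics (mean degree, degree variance,
mean local clustering, adjacency spectral radius, algebraic
connectivity, normalized-Laplacian energy, cross-class edge fraction),
and global/MST statistics (MST total length over the map diagonal,
mean/sd/max MST edge, component-count fraction, mean cross-class
nearest-neighbor distance). ReliefF (k = 10 neighbors, Manhattan
distance on min–max-normalized features, all instances, hence
deterministic) weights every feature; the top 8 feed the patient-level
classifier under leave-one-out cross-validation. A patient is called
pCR only when p(pCR) strictly exceeds one half, so exact ties go to RD.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `tile_size` | 224 | pixels | the tile granularity of the method |
| `min_overlap` | 0.90 | fraction | annotation-purity threshold for tiles |
| `k_folds` | 8 | — | tile-level CV design |
| `graph_radius` | 8 | tile widths | neighborhood scale of the TME graph |
| `n_top` | 8 | features | selection depth before LOO |
| `relieff_k` | 10 | neighbors | standard ReliefF practice, capped at class size − 1 |
| `beta_od` | 0.15 | OD | tissue mask for stain estimation |
| `effect_size` | 2 | sd units | planted standardized group difference |
| `map_shape` | 80 × 80 | tiles | synthetic map scale (below) |

SVM hyperparameters default to C = 10 with kernel width 1/d for the RBF
kernel (features are standardized first, so the per-feature variance is
1), C = 1 for the linear kernel, and Platt-style probability
calibration; RUSBoost uses 100 depth-3 trees at learning rate 0.1 with
per-round random undersampling of majority classes to the minority
count. None of these were inherited from published settings — they are
ordinary defaults, exposed in the configuration.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage has a test substrate with a
known ground truth. Tiles are rendered as two-stain OD mixtures
(`OD = H·c_H + E·c_E`, exponentiated to RGB with the standard H&E
vectors, so color deconvolution round-trips by construction) of
Gaussian random fields with class-specific correlation lengths and
anisotropy, plus anti-aliased nucleus disks. The four default classes
(stroma, tumor, PGCC, tTIL) differ in correlation length, nucleus
density and stain levels, which gives them distinct second-order
statistics — separable by the texture features, which is the property
the tile-level tests exercise.

Label maps assign each cell the argmax over per-class smoothed Gaussian
noise fields scaled by mixing weights, which yields spatially coherent
patches. The outcome-linked signal is planted by construction: the
tTIL class has zero background weight — tumor-infiltrating lymphocytes
do not form independent tissue regions, they infiltrate tumor — so
every tTIL cell is created by converting an isolated interior tumor
cell (all four neighbors tumor), each conversion adding exactly four
tumor–tTIL adjacencies. Conversions continue until the interface
statistic (adjacent tumor/tTIL cell pairs per map cell) reaches a
per-patient target drawn from N(μ_group, σ), with group means separated
by `effect_size · σ` (σ = 0.01 pairs/cell). The standardized group
difference therefore equals the requested effect size up to rounding
(±4/area) and the truncation of the patient-level noise at ±3σ. Because
per-cell tile features are drawn from class-conditional Gaussians whose
moments come from a small sample of actually generated tiles (six per
class, memoized), the tile-feature stage is statistically linked to the
texture model without rendering thousands of full tiles per patient.

Maps default to 80 × 80 tiles so that the radius-8 geometric graph is a
*local* construct, as it is on whole-slide-scale maps; on much smaller
maps the graph degenerates toward a complete graph and spatial features
lose their meaning. Cohorts default to n = 60 at 50% pCR prevalence.

What passing tests show: the implementation recovers a planted spatial
interaction of known effect size through clustering, graph
construction, ReliefF and LOO classification. What they do not show:
performance on real H&E, where class textures are far richer, maps are
orders of magnitude larger, annotation noise exists, and the
outcome-linked biology is not a single pairwise interface. The
generator makes no attempt at photorealism, scanner artifacts, or
pyramidal slide structure.

## Numerical choices and degenerate inputs

* OD transform: `OD = −log10((I + 1e−6)/I0)`; the epsilon only guards
  zero intensities.
* GLCM correlation is NA when a marginal variance is 0 (constant tile);
  histogram skewness/kurtosis are NA at zero variance; Tamura contrast
  is 0 at zero variance and directionality is 0 when there is no
  gradient (FFT round-off gradients below 1e−9 of the intensity scale
  are suppressed).
* Tamura coarseness only lets a pixel vote for a scale whose displaced
  averaging windows lie fully inside the image; replicated-edge padding
  would otherwise fake large-scale structure on fine textures.
* LBP neighbor comparisons use `neighbor ≥ center − 1e−9` so exact ties
  survive bilinear-interpolation round-off.
* Polygon–tile intersection areas are exact (Sutherland–Hodgman
  clipping + shoelace); class ties at equal area break to the lower
  class id; self-intersecting polygons are rejected.
* Stain estimation falls back to the published H&E OD vectors when the
  two extreme-angle vectors nearly coincide (single-stain images) and
  errors out below 100 tissue pixels.
* Empty node sets yield all-zero pair vectors flagged invalid; a single
  node yields zero MST features; disconnected graphs have algebraic
  connectivity 0.
* ReliefF neighbor ties at equal distance, and selection ties at equal
  weight, resolve by instance/feature index.
* Probability ties at exactly 0.5 predict RD, so a pCR call requires a
  strict majority.
* Classifier fitting runs under a fixed internal RNG scope (the `seed`
  hyperparameter, default 1), so SVM probability calibration and
  RUSBoost undersampling are reproducible irrespective of the caller's
  RNG state; all generator functions are likewise pure functions of
  their (config, seed) arguments.

## Open design choices

* **Edge semantics.** Whether TME-graph edges join only cross-class
  node pairs or all pairs within the radius is ambiguous in the
  method's verbal description; both modes are implemented
  (`cross_only`), with all-pairs as default since the spectral block
  explicitly measures the cross-class edge fraction.
* **Selection leakage.** The default LOO mode reruns ReliefF inside
  every training fold (`nested`), so the held-out patient never
  influences selection; a `global` mode (select once on all patients)
  is provided for replicating select-then-validate orderings. Both are
  reported by the demo.
* **Feature catalog.** The per-family cardinalities (20/32/18/3/4/3)
  and the 20-feature pair catalog are fixed, documented choices that
  hit the published totals; both are config-overridable.
* **Confidence intervals** use a patient-level bootstrap (1000
  resamples, percentile intervals, seeded), as the interval method for
  LOO metrics is otherwise unspecified.
* **Background** is a 17th label at the tile level when present, but
  never becomes a TME-graph node.

## Problem sizes in the test suite

The suite exercises the full pipeline at sizes chosen to keep the
planted-signal statistics meaningful: 8×8 images (100 replicates) for
the GLCM oracle, ≤ 6 nodes for exhaustive MST enumeration, ≤ 50
instances for the ReliefF reference, 40 generated tiles per class for
tile-level separability, and 20 replicate 60-patient cohorts for
ReliefF recovery. These are the package's own demonstration scales;
the statistical design (n = 60, effect size 2, top-8 selection) is the
study condition the generator defaults encode.

## Known limitations

* Real-slide ingestion is an adapter boundary (GeoJSON + tile images);
  pyramidal WSI reading is out of scope.
* The RUSBoost implementation is a SAMME-style reimplementation, not a
  port of any specific toolbox, and tree counts matter for its
  calibration.
* 1NN probability profiles are one-hot, so its ROC curves are step
  functions with few thresholds.
* The exclusion rule treats only exact value duplication as
  "repetitive" by default; |r| = 1 collinearity is available by option.
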