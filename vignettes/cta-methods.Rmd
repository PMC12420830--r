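---
title: "Computational tissue annotation for Visium: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational tissue annotation for Visium: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spotCTA annotates single cells on H&E images of breast tumor sections as
tumor, immune or stroma, aligns them to the Visium spot lattice, and uses
the resulting per-spot composition to benchmark deconvolution methods,
guide copy-number clone calling, and gate downstream analyses. This
vignette documents the science in the package: the models, their
assumptions, every tunable that matters, and the decisions taken where the
design was genuinely open.

## Stain model and optical density

H&E staining is modelled with Beer–Lambert absorption: per channel,
`OD_c = log10(I0_c / I_c)`, where `I0` is the unstained background level.
Stain *amounts* then mix linearly, so a pixel's OD vector is
`a_H * H + a_E * E` for unit stain vectors `H` (hematoxylin) and `E`
(eosin). `rgb_to_od()` floors the intensity at 1 (8-bit scale) and clips
to `od_max` (default 3); a pixel of zero transmittance is assigned
`od_max` directly. Within `(0, od_max)` the transform is exactly
invertible, which is what makes the synthetic scenes a usable oracle for
the stain arithmetic.

`estimate_stain_vectors()` is the automated "stain vector correction"
step. It assumes its input region mixes stained tissue with blank
background (the conventional selection is roughly 60 % tissue / 40 %
background): the background level comes from the brightest pixels (median
of the top decile of brightness), pixels with OD norm below `beta = 0.15`
are discarded as unstained, pixels whose OD direction lies far out of the
dominant two-component plane (residual fraction > 0.3) are discarded as
unrecognized colours, and the stain vectors are the 1st/99th-percentile
extreme angles of the remaining directions in that plane — the standard
automated (Macenko-style) estimator. Hematoxylin is the vector with the
larger red-channel OD (hematoxylin absorbs red strongly; eosin barely).
Failure modes are explicit errors: too few stained pixels, or a collinear
(degenerate) solution.

Per-cell stain *densities* are obtained by inverting the 3×3 basis
`(H, E, residual)` rather than by projection: projection would leak eosin
into the hematoxylin channel wherever the two overlap, whereas the inverse
is exact under the mixing model.

## Segmentation, cell expansion, features

`segment_nuclei()` works on the hematoxylin density: Gaussian smoothing
(`sigma_um = 1.5`), a global Otsu threshold (a numeric OD threshold can be
substituted), then a marker-controlled watershed on the distance transform
to split touching nuclei (tolerance 1 px of distance-map depth). Objects
outside 5–400 µm² are discarded — below lie debris, above lie merged
clumps and vessels. All parameters sit in `segmentation_params()`; when an
image has no pixel size (e.g. a JPEG), every µm parameter is read in
pixels instead, mirroring the pixel-unit mode used for such images.

`expand_cells()` dilates each nucleus by a fixed physical distance
(default 3 µm here) to approximate the cell. Expansions never overlap: a
contested pixel goes to the nucleus with the nearer *centroid* (ties to
the lower id). Any deterministic partition rule would do biologically; the
centroid rule is simple and order-independent.

Features per cell: nuclear and cell area (µm²), circularity `4πA/P²`
capped at 1, and mean/max hematoxylin and eosin densities over nucleus,
cytoplasm (cell minus nucleus) and whole cell. The perimeter uses a
Crofton-corrected boundary-edge count (edge transitions × π/4), which is
exact for rasterized disks — a raw edge count overestimates P by 4/π and
a boundary-pixel count underestimates it, both of which distort
circularity systematically. An empty cytoplasm yields missing cytoplasm
features, not a dropped row.

`smooth_features()` appends neighbourhood-averaged copies of every
feature: Gaussian weights `exp(−d²/2σ²)` with `σ = radius/2`, support
truncated at `2·radius`, self-weight 1, run conventionally at 25 µm and
50 µm. The kernel shape is not prescribed by the upstream tool this
mirrors; a Gaussian was chosen as the least-surprising smooth
distance decay, and the defaults expose it. Smoothing lets the classifier
see context (stroma cells sit among stroma), at the cost of blurring
class boundaries over ~radius.

## The cell classifier

`fit_cell_classifier()` is a random forest (100 trees, `√p` features per
split, unlimited depth) over *all* numeric features, z-scored with
training-set statistics that are stored in the model — "normalized by
mean and variance" is read as per-feature standardization, the only
interpretation that makes the stored statistics reusable at prediction
time. Constant features get unit SD and are flagged rather than dropped,
so a feature that is constant in one training batch but informative later
keeps its column. A seed is mandatory: forests are stochastic and the
model must be refittable bit-for-bit. Prediction re-orders columns by
name (column order must not matter), normalizes the vote fractions to a
simplex and breaks argmax ties alphabetically. The interactive,
iterative annotation loop of the original workflow is modelled as
repeated `fit_cell_classifier()` calls on a growing training set; no
interactivity is in scope. The class set defaults to
tumor/immune/stroma but is configurable — manual pathology annotations
also distinguish DCIS, necrosis and vessels, which this classifier does
not output.

## Spot geometry and alignment

When spot registration was run on a down-sized image, the scaling factor
is `s = h_registered / h_full` and full-resolution coordinates are
`x/s`, `y/s` with an optional y flip `y_full = H_full − y_scaled`
(`registered_to_fullres()`). The flip uses `H`, not `H − 1`: the
convention is stated as subtracting from the image *height*, and the
half-pixel difference is far below the spot radius. The exact inverse is
provided, and the round trip is tested to 1e−9 px. Spots transformed out
of bounds are kept and flagged — silently dropping them would corrupt
barcode joins downstream. Standard Space Ranger geometry
(`tissue_positions_list.csv` + `scalefactors_json.json`, no flip) is read
directly; both dialects of the positions file are supported.

`assign_cells_to_spots()` uses square-window containment —
`|Δx| ≤ r ∧ |Δy| ≤ r` with **closed** inequalities ("± radius" reads as
inclusive). With Visium geometry (radius < pitch/2) windows are disjoint;
should windows overlap (adversarial grids only), the nearest spot centre
wins, ties broken by barcode order. Cells outside every window are
reported as unassigned, never dropped. The implementation is validated
against a literal all-pairs brute-force oracle on random adversarial
geometries.

QC thresholds are strict per their usual phrasing: a spot is removed iff
detected genes < 500 **or** mitochondrial fraction > 0.25 **or**
hemoglobin fraction > 0.20; a spot at exactly a boundary is kept. A
zero-UMI spot is removed with reason "no counts". Gene patterns
(`^MT-`, `^HB[AB]`) and all thresholds are configurable. Manual exclusion
of spots (e.g. under folded tissue) is supported by passing a reduced
barcode set; the package takes no stance on whether such exclusions were
QC-driven.

## Deconvolution benchmarking

Fine-grained fractions (the 29 minor cell states of the public breast
tumor single-cell reference) are summed to tumor/immune/stroma via an
editable TSV map. Mapping normal epithelial states to "tumor" is an open
judgement call: the image classes are morphological, and epithelium reads
as tumor epithelium in these sections; the map ships as data precisely so
users can re-map it.

Per section and class, `correlate_composition()` computes Spearman's ρ
(average-rank ties) over spots shared between the deconvolution and the
annotation, restricted to QC-passing spots with ≥ 1 annotated cell;
records with < 3 spots carry a missing ρ and a note. The grouping unit is
the section, configurable by pooling records. `compare_methods()` runs a
Kruskal–Wallis omnibus per class over the per-section ρ values, then
Dunn's z (tie-corrected pooled-variance rank comparison, normal
approximation) of each method against the chosen reference, with BH
adjustment across that per-class family and stars at 0.05/0.01/0.001.

One calibration note: under a complete null (all methods identical), BH
controls the *family-level* false-discovery probability — by Simes'
identity it equals the nominal α — while the expected *per-test*
rejection fraction in a 6-comparison family is necessarily far below α
(≈ 0.016 measured here). The package's null-calibration check therefore
reports the fraction of simulated families with at least one BH
discovery, the quantity BH actually pins to 0.05; it lands at ≈ 0.046
over 1000 simulations.

## CNV clone calling

Spots with **zero** annotated tumor cells (and ≥ 1 cell of any class —
empty spots carry no evidence of normality and are excluded) form the
normal reference; query spots are those with tumor fraction ≥ τ for
τ ∈ {0.5, 0.7, 0.9}. The boundary is inclusive ("filtering out spots with
*less than* τ"), and the three query sets are nested by construction.

`infer_cnv_profile()` is a deliberately simplified relative-expression
profiler in the moving-average family — the HMM, subclustering and
Bayesian filtering of the full published machinery are **not**
reproduced, and the profile is intended for clone clustering, not
absolute copy-number calls. Steps in order: common-depth library
normalization and `log2(x+1)`; a mean-expression floor (0.1 counts) to
drop noise-dominated genes; subtraction of the per-gene reference mean;
clipping at ±3 (one extreme gene must not dominate a window); a 101-gene
running mean within each chromosome, truncated at the ends (windows
spanning chromosomes would smear alterations across junctions);
per-spot median centring (removes residual depth effects); and denoising
that zeroes values within 1.3 reference-SDs of zero. Window, clip and
denoise factors are conventional for this method family and all sit in
`cnv_params()`. Chromosomes with fewer than two genes are skipped with a
warning.

`call_clones()` z-scores each gene across query spots (the "scaled
output"), clusters with Ward linkage on Euclidean distances, and cuts the
tree. `"ward.D"` — classical Ward updates applied to the supplied
distances without the D2 input-squaring correction — is the default
because that is the linkage name used with this profile type;
`"ward.D2"` is a flag away. Published cut parameters of this kind are
ambiguous between cluster counts and tree heights, so both cut modes are
implemented (`k` or `h`) and neither is asserted as canonical; a height
above the root yields one clone with a warning. Clones are relabelled
A, B, … by decreasing size.

## What the synthetic data emulates — and what it does not

The scene generator (`generate_he_scene()`) places non-overlapping
elliptical nuclei (rejection sampling, 1e5-attempt cap with a
deterministic failure naming the densest class) with class-specific size,
eccentricity and stain intensity: tumor nuclei large (6 ± 0.6 µm radius)
and eosin-rich, immune nuclei small (2.8 ± 0.3 µm), round and eosin-poor,
stroma nuclei elongated (eccentricity 0.75–0.9) and intermediate — the
morphological axes a pathologist actually uses, separated by ≥ 3 SD so
that recovery failures indicate pipeline defects rather than overlapping
classes. Eosin is drawn as a cytoplasmic annulus around each nucleus and
the image is rendered by exact Beer–Lambert mixing at 0.5 µm/px over a
1024² default canvas. The spot generator lays a hexagonal lattice
(100 µm pitch, 55 µm spots). The deconvolution generator perturbs the
true composition with Dirichlet noise of chosen concentration and splits
each class across its fine types; at infinite concentration the split
uses power-of-two weights so aggregation returns the truth *bit-exactly*
(a tie in true fractions must stay a tie, or rank correlations
silently drop below 1). The count generator plants segmental gains and
losses as Poisson (optionally negative-binomial) counts at a target
depth.

Deliberately absent: staining artifacts, folds, out-of-focus regions,
touching/overlapping nuclei beyond the watershed test case,
photorealistic texture, platform-specific noise, and any transcriptional
difference between cell classes other than planted CNV segments. Passing
tests therefore demonstrate the *algorithms* are correct on their stated
models, not that performance transfers to arbitrary clinical H&E — the
standard caveat for simulation-validated pipelines.

## Numerical and evaluation choices

- Coordinates are 0-based, `x` = column, `y` = row, origin top-left;
  physical units are µm via the pixel size, everywhere.
- Centroid matching for segmentation scoring is greedy over
  globally distance-sorted candidate pairs within a 5 µm gate. For
  well-separated nuclei this equals the optimal (Hungarian) assignment;
  an optimal solver was not pulled in for a regime where the two
  coincide.
- The adjusted Rand index is computed in-package (Hubert–Arabie) and
  cross-checked against an independent implementation in the tests.
- Pseudo-bulk uses gene-wise raw sums per group → CPM (columns to 1e6)
  → `log2(x+1)`; base 2 with pseudocount 1 is the transcriptomics
  convention where only "log transformation" is specified. All-zero
  groups are flagged with CPM left missing rather than dividing by zero.
- Group composition percentages are **pooled** (Σ class counts / Σ
  totals), matching a single stacked bar per cluster; mean-of-fractions
  is available behind `pooled = FALSE`. Pooling weights spots by cell
  count, which is the honest reading of "percentage predicted for each
  cluster".
- Test and acceptance problem sizes — 150-nucleus scenes, 100 random
  assignment geometries, 50 deconvolution replicates per concentration,
  1000 null simulations, 200 query + 100 reference CNV spots at depth
  1e4 — were chosen as the smallest sizes at which the checked
  properties are stable, keeping the whole suite around a minute.

## Known limitations

- No pyramidal whole-slide I/O; images must fit in memory as arrays.
- No colour normalization across slides and no deep-learning
  segmentation; heavily overlapping nuclei will undercount.
- The CNV profile is relative and smoothed: breakpoint resolution is
  ~half a window, focal events below the window scale are attenuated,
  and no absolute copy numbers or allele-specific states are produced.
- Deconvolution methods themselves are out of scope: their fraction
  tables are inputs, and the benchmark ranks methods only against the
  morphology-based annotation, which is itself an estimate.
- HDF5 count matrices are not read; use the MTX triplet or CSV.
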