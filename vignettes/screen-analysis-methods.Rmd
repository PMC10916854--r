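---
title: "Methods: analysis of imaging-based arrayed CRISPR screens of dynein cargo localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysis of imaging-based arrayed CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cargoscreen)
```

# The assay and its readouts

Cytoplasmic dynein transports membrane cargoes toward microtubule minus
ends, which concentrate at the microtubule-organizing centre (MTOC) next to
the nucleus. In a high-content screening format, dynein activity is read
out geometrically: when the motor works, cargoes (rapamycin-tethered
peroxisomes carrying GFP/RFP reporters, EEA1-positive early endosomes,
TGN46-positive Golgi membranes, LAMP1-positive lysosomes) pile up in a
perinuclear cluster; when it fails they disperse through the cytoplasm.
`cargoscreen` implements the whole analysis path of such a screen — from
well images or per-cell feature tables to plate-normalized endpoint
scores, SD-threshold hit calls and phenotypic-fingerprint clusters — plus
a synthetic-screen generator with planted ground truth against which every
stage is benchmarked.

# The synthetic-screen generator

No public screening dataset accompanies this kind of assay at the per-cell
level, so the package treats the generator as a first-class module. It
emulates the statistical structure the analysis assumes, not the optics of
any particular microscope:

* **Plate design.** 384-well plates (16 x 24) with 38 neutral-control (NTC)
  wells, 13 positive-control wells (a *LIS1*-disrupting pool: strong cargo
  dispersion, mild viability cost) and 13 editing-control wells (a
  *PLK1*-disrupting pool: near-total proliferation block), scattered across
  each plate; the remaining 320 wells carry library crRNA pools, recycled
  across plates so each pool occupies a configurable number of replicate
  wells.
* **Cells per well.** Poisson with mean `cells_per_well_mean` (default 300,
  the order of analyzed cells per well in a screen of this design after
  gating), scaled down by viability effects.
* **Spot counts.** Per cell and channel, negative binomial with mean
  `spot_mean` (default 30) and size `spot_dispersion` (default 10) —
  overdispersed, as organelle counts are.
* **Radial spot positions.** A two-component mixture of the signed distance
  from the nuclear boundary: with probability `pi_clustered` (default 0.7)
  an exponential decay of length `lambda_um` (default 3 µm, the
  perinuclear cluster), otherwise uniform over the cytoplasm (extent
  30 µm). Dispersion effects multiply `pi_clustered` down; hyperclustering
  pushes it toward 1. These two knobs map directly onto what the assay
  measures, which is why this mixture was chosen over a more literal
  simulation of organelle traffic.
* **Other phenotypes.** Micronucleus counts are Poisson (default rate
  0.05/cell); MTOC counts are multinomial over {0, 1, >1} (defaults 0.05 /
  0.85 / 0.10); 5% of cells carry apoptotic nuclear morphology (small,
  dense, irregular nuclei); 90% of cells are positive for both reporters.
  Effect classes (`lethal`, `micronucleus`, `mtoc_loss`, `mtoc_gain`,
  three dispersion scopes, EEA1 hyperclustering) move the corresponding
  parameter toward its extreme in proportion to a 0-1 effect size.
* **Reproducibility.** Every well draws from its own RNG stream keyed by
  (plate, row, column, global seed) via `well_seed()`, so any single well
  can be regenerated without replaying the screen, and full runs are
  bit-identical under a fixed seed.

Two generation surfaces exist. `simulate_screen()` is the cell-level
generator used end-to-end. `simulate_endpoint_scores()` draws well-level
endpoint values directly (null wells Normal(0, σ_well), planted effects
shifted by a stated number of well-SDs); it exists because SD-threshold
hit-calling benchmarks are only exact when the planted shift is defined on
the same scale the thresholds operate on.

## What the generator does not emulate

Real screens have spatial plate effects (edge wells, dispensing gradients),
cell-cycle structure, guide-level editing heterogeneity, illumination
fields and segmentation-confusing cell contact. None of these are
simulated, and the pipeline deliberately contains no spatial detrending.
Passing the synthetic benchmarks therefore demonstrates the correctness of
the statistical machinery under its own assumptions, not robustness to all
real-data pathologies.

## Rendered images

`render_well_images()` turns a well's cell records into multi-channel
images with pixel-level ground truth: nuclei as smooth discs (Hoechst),
cytoplasm as a diffuse disc (tubulin channel), spots as Gaussian peaks at
radial positions drawn from the cell's generative mixture, micronuclei as
small bright Hoechst discs, MTOC puncta as bright peaks at the nuclear
periphery. Cells sit on a jittered grid of non-overlapping tiles; a
density cap errors out rather than render overlapping cells whose
segmentation would be untestable. Planted spots of one cell and channel
keep a minimum separation of 5 µm (micronuclei 6 µm, placed at least 7 µm
from the nuclear boundary): two point sources below the detector's
resolution are physically one blob, so rendering them as separate ground
truth would make the benchmark unanswerable rather than harder. For the
exact-count image benchmarks the wells are generated with
`viable_frac = 1`; micronuclei adjacent to pyknotic debris are ambiguous
even for a human annotator, and the analysis gates such cells out before
micronucleus scoring in any case.

# Image quantification

* **Nuclei** (`segment_nuclei()`): Gaussian smoothing (σ 1.5 px), Otsu
  threshold, hole filling, watershed on the distance map to split touching
  nuclei, removal of sub-50 µm² debris, then a per-object refinement that
  re-cuts each nucleus at half its own peak intensity — the half-maximum
  contour tracks the true outline much better than one global threshold.
* **Cytoplasm** (`segment_cytoplasm()`): Voronoi-style propagation of the
  nucleus seeds through the cytoplasmic context signal (tubulin stain, or
  the weak Hoechst background when absent), masked at half the bright-signal
  level. Cells touching the image border are flagged and excluded
  downstream; a nucleus with no surrounding signal falls back to a dilated
  nucleus with a logged note.
* **Spots** (`detect_spots()`): scale-normalized Laplacian-of-Gaussian
  filtering over the configured radius range (default 1-3 µm), per-pixel
  maximum across scales, 3x3 local maxima above `detection_sensitivity`
  (default 0.15 in intensity units — a matched Gaussian blob of amplitude
  A gives response ≈ A/2), then greedy merging of peaks closer than the
  splitting distance (default 3 µm), strongest first. These two knobs are
  the direct analogues of the "detection sensitivity" and "splitting
  coefficient" exposed by commercial HCS software. The RFP channel applies
  rolling-window (top-hat) background subtraction first, radius three times
  the maximal spot radius.
* **Ring geometry** (`region_geometry()`, `assign_spots_to_regions()`):
  three bands of signed distance from the nuclear boundary — perinuclear
  [-7, +7] µm (the band reaches *inside* the nuclear outline because the
  MTOC sits at the nuclear periphery and projected cargo overlaps the
  nucleus in 2-D), intermediate (7, 14] µm, outer (14, 35] µm. Upper edges
  are exclusive so assignment at an exact boundary is deterministic; spots
  outside all bands count as out-of-range, so region counts always sum to
  the spot total (an invariant the tests enforce per cell). The two-zone
  scheme for early endosomes takes the inner region (nucleus + perinuclear
  zone) as 50% of cell area by default — the split is a pilot-calibrated
  choice in the assay and is exposed as configuration here.
* **Localization ratio** (`localization_ratio()`): inner/peripheral spot
  count ratio; when the denominator is zero a pseudocount of 1 is added to
  both terms (keeps the ratio finite and monotone; any other policy either
  discards cells or breaks monotonicity). Downstream statistics use the
  natural log of the ratio, which is close to normally distributed.
* **Micronuclei** (`detect_micronuclei()`): connected components of
  supra-background Hoechst signal (≥ 2x the median cytoplasmic intensity)
  inside the cell, at least 4 px outside the nucleus (so the nucleus' own
  intensity skirt is never counted), with area between 1 µm² and 25% of the
  nucleus area — the cap rejects a second full nucleus rather than
  counting it.
* **MTOC puncta** (`count_mtoc_puncta()`): the same LoG detector with a
  tight radius range (0.8-2 µm), higher sensitivity and a 1.5 µm splitting
  distance; per-well summaries are the proportions of cells with 0, 1, >1
  puncta.
* **Texture/morphology** (`extract_texture_morphology()`): Haralick
  co-occurrence statistics, intensity summaries, area, perimeter
  (chain-code with the Vossepoel-Smeulders correction — a raw boundary
  pixel count overestimates a disc's perimeter by several percent, enough
  to visibly bias roundness), roundness 4πA/P², and an axis-symmetry ratio
  from second moments. Undefined entries are imputed as zero and flagged.

# Plate statistics

All normalization is plate-local, because controls are replicated on every
plate:

* `rz_normalize()`: rZ = (x − median_NTC) / (1.4826 · MAD_NTC). The robust
  Z-score with the normal-consistency constant; commercial screening
  software names this score without printing a formula, and the median/MAD
  analogue of the Z-score is the standard definition the name denotes. The
  MAD choice (rather than a robust SD) is recorded in provenance so results
  are auditable.
* `two_point_normalize()`: anchors the NTC median at 0 and the positive
  control at a signed target (−100 for crLIS1-anchored cargo endpoints,
  +100 for crPLK1-anchored lethality).
* `robust_z_prime()`: rZ′ = 1 − 3(1.4826·MAD_pos + 1.4826·MAD_neg) /
  |median_pos − median_neg| — the robust assay-window statistic; 1 is a
  perfect window, and features need rZ′ ≥ 0.1 to enter composite endpoints.
* `fit_lda_endpoint()`: a two-class Fisher discriminant over the features
  passing the rZ′ filter, w ∝ S_w⁻¹(μ_pos − μ_neg) with ridge
  ε = 10⁻⁶·tr(S_w)/p for conditioning (the assay's feature sets are small
  and sometimes collinear; the ridge choice is numerically inert
  otherwise). The projection is affinely rescaled to the two-point
  convention. A single surviving feature passes through with weight one.
* Aggregation: arithmetic means per well over gated cells
  (`aggregate_wells()`, wells under 50 viable cells flagged and kept out of
  control statistics, zero-viable wells excluded as NaN profiles), medians
  per crRNA pool across replicate wells (`aggregate_crRNA()`), and
  replicate concordance as the least-squares R² with endpoints under 0.2
  flagged unusable (`replicate_concordance()`).

`normalize_profiles()` drops a feature (recording it) when a plate's NTC
MAD is exactly zero and the caller opts in; sparse readouts such as
per-cell micronucleus rates genuinely produce all-zero NTC wells on small
synthetic plates, and an error there would be a statement about the
fixture size, not the data.

# Hit calling

Threshold rules are SD envelopes around a named reference control group,
closed at the boundary (a score exactly at k·SD is a hit — the convention
must be fixed somewhere, and closed thresholds make the monotonicity
property exact). Defaults follow the screen design: cargo endpoints
two-sided at ±2.5 SD of NTC (both dispersion and excessive
hyperclustering are genuine phenotypes; the primary-screen legacy values 2
and 3 remain available per rule), lethality and micronucleus calls
one-sided against the crLIS1 envelope, confound exclusion at ±4 SD
(nuclear area) and −3.5 SD (roundness) of the pooled NTC+crLIS1 wells —
pooling is the reading of "SD of NTC and crLIS1" used throughout, recorded
in the audit attributes of every call. Exclusion precedes cargo calling:
an excluded gene never carries a cargo label. MTOC categorization splits
genes that lose the one-punctum class into `mtoc_gain` / `mtoc_loss` by
which abnormal class rises past +2.5 SD, with an auxiliary
stronger-than-crLIS1 flag.

# Phenotypic profiling

Fingerprints are per-gene median rZ vectors over a shared feature
registry. Reduction drops technically variable features (SD ≥ 3 across
crLIS1 replicate profiles scattered over plates) and then redundant ones
(R² ≥ 0.8 with an already-retained feature, greedy in registry order,
first kept wins — the scan order is a free choice and is recorded with
every drop, making the operation idempotent). Hierarchical clustering uses
complete linkage on 1 − Pearson distance after per-feature min-max scaling
across genes; rows are ordered lexicographically before linkage so ties
break deterministically, and zero-variance fingerprints (correlation
undefined) become flagged singletons instead of poisoning the tree.
Cargo-signature grouping uses K-means (Lloyd, seeded restarts, best
inertia) on the three-dimensional mean effect vectors (peroxisome = mean
of GFP and RFP rZ, EEA1, TGN46) with K = 14 by default, the granularity at
which cargo signatures separate into interpretable groups. The 2-D
embedding for visualization (`embed_fingerprints()`) is principal
coordinates on the same correlation distance (deterministic; NMDS via
vegan behind a flag) and is never used for hit calling. Heatmaps export
the dendrogram leaf order and the min-max-scaled matrix alongside the
figure; dendrograms serialize to Newick.

# Pipeline, determinism, and problem sizes

`run_pipeline()` executes simulate → aggregate → normalize → hit call →
profile from a validated `run_config()` (or YAML), writing CSV outputs and
a provenance manifest (package version, seed, parameters, input/output
MD5 hashes — no timestamps, so reruns are byte-identical). One global
seed fans out per stage and per well.

The shipped test and benchmark sizes are chosen so the whole suite runs in
about a minute on one core: screens of one or two 384-well plates at 20-60
cells per well for pipeline behaviour, 1000-4000 cells for distributional
checks, three 8-cell rendered wells for image benchmarks, 160-gene
libraries with 4 wells per pool for hit-recovery benchmarks, and 48-gene
fingerprint sets for clustering recovery. The statistical machinery is
size-free; scaling up changes runtimes, not code paths.

# Known limitations

* The generator's phenotype magnitudes for the built-in controls mirror
  the qualitative control behaviour of this screen family; they are
  configuration defaults, not measured values.
* Segmentation is classical (threshold + watershed + propagation); highly
  confluent or irregular cells would need a learned segmenter, which is out
  of scope.
* No spatial plate-effect modelling or correction (B-scores, median
  polish) — normalization assumes controls are representative of their
  plate.
* The micronucleus detector's area/intensity constants are calibrated on
  synthetic data only; on real images they are the first thing to re-tune.
* 2-D only: maximum projections are assumed done upstream.
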