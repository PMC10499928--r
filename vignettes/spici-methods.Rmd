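---
title: "Methods and design of spici"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of spici}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spici)
```

## The problem

Spot-based spatial transcriptomics (Visium) measures thousands of
transcripts per 55-µm spot, but each spot mixes roughly 1–9 cells and the
assay itself cannot say which cell types they are.  Reference-based spot
deconvolution needs a matched single-cell expression atlas, which is often
unavailable for clinical specimens.  When an adjacent section of the same
tissue has been imaged with multiplexed protein panels (PhenoCycler/CODEX),
the cells on that section can be typed directly from their marker
intensities, registered onto the transcriptomics section's histology image,
and counted into the spots — a reference-free estimate of per-spot cell-type
composition.  `spici` implements this integration end to end, plus a
spot-level ligand–receptor permutation test used to prioritise druggable
interaction pairs.

## Cell typing from marker panels

The built-in registry holds 17 tumor and immune cell types defined over 11
markers (PANCK, CD45, KI67, CD68, CD3e, CD8, CD4, HLA-DR, CD20, CD107a,
CD45RO).  A cell $j$ with log-scaled intensity $x_i$ for marker $i$ is
assigned

$$C_j \;=\; \arg\max_C \prod_{i \in C} x_i ,$$

the type whose required-marker subset maximises the intensity product.  Two
scoring modes are provided because the two natural readings of this rule
disagree when candidate subsets have different sizes: `"product"` (the
default) scores $\prod_{i\in C} x_i$ exactly as written above, while
`"geomean"` scores $(\prod_{i\in C} x_i)^{1/|C|}$.  With raw products, a
two-marker type can outscore a one-marker type whenever the second log
intensity exceeds 1; the geometric mean removes that size advantage but can
then never prefer `Dividing tumor` (KI67, PANCK) over `Tumor` (PANCK) unless
KI67 exceeds PANCK.  Both behaviours are legitimate gating conventions; the
mode flag makes the choice explicit, and the worked example in the test
suite (`PANCK = 5, KI67 = 4`) exercises the disagreement deliberately.

Scoring operates on `log1p`-scaled intensities.  `log(1 + x)` rather than
`log x` keeps zero intensities at zero, so an unstained marker annihilates
every subset containing it and all scores stay non-negative.  A cell whose
best score does not exceed `min_score` (default 0, i.e. no fully positive
subset exists) is left `"Unclassified"` rather than assigned arbitrarily.
Ties between types are broken by registry order, which for the built-in
panel is the order the types are conventionally listed; tie rows are
measure-zero for continuous intensities but matter for all-zero cells and
duplicated subsets.

Whether typing should run on the log or the raw scale is a genuine open
choice; log is the default here because quality control ends with the log
transform and every downstream analysis consumes that matrix.  On the raw
scale the same argmax rule applies, only the scale of `min_score` changes.

## Quality control

Cells are filtered on total intensity: totals strictly below the 0.05
quantile or strictly above the 0.95 quantile of the per-cell total
distribution are discarded as segmentation debris and fused objects.  The
quantile is the linear-interpolation (type-7) definition — the convention
has to be fixed somewhere, and type-7 is R's default and the most common in
practice.  Strict inequalities follow the reading "lower than … or higher
than": a cell exactly at a cutoff stays.  Totals are summed over all
markers; per-channel filtering is deliberately not attempted.

Spots are filtered on detected features: a spot expressing fewer than 200
genes (count > 0) is removed, a standard viability threshold for spot
transcriptomics.  Genes are never removed.

## Image registration

The nuclear-stain channel of the proteomics section (moving image) is
aligned to the histology image of the transcriptomics section (fixed
image).  Both are reduced to grayscale and rescaled to $[0,1]$; the moving
image may first be cropped, rotated and downscaled so its capture area and
resolution match the fixed image (these pre-transforms are recorded and
composed into the final point map).  Because the two modalities have no
intensity correspondence, the similarity is mutual information computed
from the 32-bin joint histogram, in nats.

The affine stage searches rotation, anisotropic scale, shear and
translation, parameterised about the fixed-image centre and initialised at
the centre-of-mass alignment of the two images.  Optimisation is
Nelder–Mead over a three-level block-mean pyramid (4×, 2×, 1×), 500/400/400
iterations per level with relative tolerance $10^{-6}$; the simplex is
derivative-free and robust to the flat, noisy MI landscape at coarse
levels.  These optimizer specifics are declared defaults, not values taken
from anywhere: any monotone MI-maximising scheme is admissible, and all of
them are exposed in `registration_config()`.

An optional deformable stage (`stage = "affine_then_bspline"`) refines
local alignment with a first-order (bilinear) control-point displacement
grid, default spacing 64 px, optimised by L-BFGS-B on MI with a small ridge
penalty on the displacements and box bounds of half a grid spacing.  A
higher-order spline basis would smooth the field further but adds nothing
at the grid resolutions practical here.

Internally the optimiser works with the resampling transform (fixed →
moving, the direction needed to pull pixels); the stored contract is the
*forward point map* (moving → fixed, the direction needed to push cell
centroids).  The affine is inverted analytically.  The deformable
displacement lives on the fixed domain in the resampling direction, so
forward-mapping a point solves $T_{\text{aff}}(x_f) + D(x_f) = x_m$ by
fixed-point iteration ($\le$ 12 iterations, tolerance $10^{-3}$ px;
displacements are bounded well below the contraction limit).  Points whose
solution leaves the fixed-image domain fall back to the affine map and are
flagged `extrapolated`.

Degenerate inputs: a constant image has no structure to register and is
rejected during preparation; non-convergence of the optimiser is reported
via `converged = FALSE`, never as an exception, since a usable transform
may still have been found.

## Spot assignment and composition

Registered cell centroids join the spot whose centre lies within half the
spot diameter (27.5 µm for $d$ = 55 µm).  Spot capture areas do not tile
the section — at the standard 100-µm pitch the discs cover ~27% of the
tissue — and cells in the gaps are deliberately left unassigned: forcing
them to the nearest spot would attribute cells to spots whose transcripts
cannot contain them.  The radius is configurable for non-standard arrays.

Per spot $s$, the composition is $P_s^C = N_C / N_s$ with $N_s$ the number
of assigned cells and $N_C$ of them labelled $C$; proportions over a
non-empty spot sum to one exactly (integer arithmetic).  The spot's
inferred label is the highest-proportion type, optionally after collapsing
types into supergroups.  For a tumor-versus-immune evaluation the natural
collapse uses the registry's lineage column — `Tumor` and `Dividing tumor`
to "Tumor", the 15 leukocyte entries to "Immune" — but the map is explicit
configuration, because any such collapse is an analysis decision, not a
property of the panel.  Accuracy and confusion matrices are computed over
the barcodes present on both sides of the comparison.

## Ligand–receptor permutation ranking

For a pair $(L, R)$ and spot $s$ with neighbourhood $N(s)$ (spots within
150 µm, i.e. the six hex neighbours plus the spot itself), the
co-expression score is the symmetric spot-by-neighbourhood product

$$\text{score}_s = \tfrac12\left( L_s \,\bar R_{N(s)} + R_s \,\bar
L_{N(s)}\right)$$

on library-size-normalised, `log1p`-scaled counts.  The neighbourhood
coupling rewards juxtacrine/paracrine geometry rather than same-spot
coincidence alone.  This exact formula is a declared contract of this
package (isolated behind `lr_spot_scores()` so alternatives can be
swapped); what is fixed by the method is the testing scheme around it.

Significance is by permutation against a *shared* background: `n_background`
(default 1000, configurable upward) random gene–gene pairs drawn uniformly
from all genes of the matrix, scored identically, with the per-spot p-value
$(1 + \#\{\text{background} \ge \text{observed}\})/(1 + n_{\text{background}})$.
The add-one convention forbids $p = 0$.  Because the background depends
only on the matrix and the seed — never on the tested pair list — raw
p-values are bit-identical between a full run and any subset run (e.g.
restricting to druggable pairs), a property the tests assert directly.
Adjustment across pairs within each spot defaults to Bonferroni, whose
adjusted values scale proportionally with the number of pairs tested;
Benjamini–Hochberg is offered.  Pairs are ranked by the number of
significant spots, ties by best raw p-value then name.

## The synthetic-data generator

All four inputs are generated with known ground truth, so every stage is
testable without any external download.

**Marker intensities** follow a log-normal stain model: positive markers
(the cell's type subset) draw from LogNormal(log 30, 0.5), negative markers
from LogNormal(log 0.2, 0.5).  After `log1p` scaling this puts negatives
below 1 and positives above 1 with ~5 log-sd of separation, the regime in
which product-mode gating is stable — a clean stain, chosen once as the
default study condition.  Setting `mu_pos = mu_neg` collapses typing to
chance, which the tests use as a negative control.

**Tissue layout** defaults to two lateral regions — one tumor-enriched, one
immune-enriched, region purity 0.85 — because the evaluation target is
agreement with contiguous pathologist-style region annotations; a fully
mixed (`"uniform"`) layout is available but makes spot-dominant labels a
coin flip in balanced spots, which no annotatable tissue resembles.

**Images** are Gaussian-blob nuclei fields; the moving image is the fixed
image pulled through the configured affine (rotation about the centre,
scale, shift), optionally composed with a smooth sinusoidal deformation,
plus pixel noise.  Blob centres are tracked analytically in both frames, so
registration accuracy is measured as mean landmark error in pixels.

**Spot grids** are hexagonal, 100 µm pitch, 55 µm diameter (5 µm/px by
default).  **Counts** are negative binomial (mean 5, size 2) over a
500-gene pool; the pool size matters because the permutation background
samples from all genes, and a pool much smaller than a real "all detected
genes" set would keep re-drawing the planted pair itself.  The planted
ligand–receptor pair is boosted by `fold_change` inside a 250-µm disc.

What the generator does **not** emulate: real H&E appearance and staining
artefacts, section-to-section cell-composition drift between the two
adjacent slices (the mapping's core biological assumption is taken as
exactly true), segmentation errors, spatial expression gradients other than
the single hotspot, and gene–gene correlation structure.  Passing tests
therefore demonstrate correctness of the computation under the stated
models, not performance on patient material.

## Problem sizes and numerical choices

The test and acceptance workloads use 256×256 images (20 registration
pairs), 2 000 cells, 100–200 spots, 500 genes and 1 000 background pairs —
sizes at which the full suite completes on a single CPU in minutes while
every statistical check retains power (e.g. the null calibration estimates
a 5% rate from 10 000 spot-level p-values).  Other conventions: type-7
quantiles; 32 MI bins; strict QC inequalities; assignment ties broken by
nearest centre then barcode order; dominant-type ties by declared group
order; "CD3e" is the canonical ASCII spelling of CD3ε, with the Unicode
form accepted on input.

## Known limitations

Registration is 2-D and intensity-based only; very large rotations
(beyond ~30°) must be handled with `initial_rotation`, as MI optimisation
from a centre-of-mass start will not find them.  The deformable stage uses
a coarse first-order grid and is off by default.  Composition estimates
inherit the adjacent-section assumption; where the two sections differ
materially, per-spot proportions are biased in ways no registration can
fix.  The L-R test treats spots as independent under the permutation null;
spatial autocorrelation of expression inflates neither the background nor
the observed scores preferentially, but p-values should be read as
descriptive rankings rather than strict error rates — which is how the
ranking is used.
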