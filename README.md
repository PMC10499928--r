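# spici

**S**patial **p**roteomics **i**nformed **c**ell **i**dentification:
reference-free estimation of per-spot cell-type composition for spot-based
spatial transcriptomics, by integrating a multiplexed protein imaging
section from the adjacent tissue slice.

## The problem

A Visium spot (55 µm across) captures the transcripts of roughly 1–9 cells,
and deconvolving its cell-type mixture normally requires a matched
single-cell RNA reference, which clinical specimens often lack.  When the
adjacent section has been imaged with a multiplexed protein panel
(PhenoCycler/CODEX), the segmented cells there can be typed directly from
their marker intensities and mapped onto the transcriptomics section.
`spici` implements this pipeline:

1. **QC** — cells with total intensity strictly below the 0.05 or above the
   0.95 quantile are discarded; intensities are `log1p`-scaled.  Spots with
   fewer than 200 detected genes are dropped.
2. **Cell typing** — cell *j* receives the type
   `C_j = argmax_C  prod_{i in C} x_i`, the type whose required-marker
   subset maximises the product of log-scaled intensities (geometric-mean
   scoring available as a mode).  The built-in registry covers 17 tumor and
   immune cell types over 11 markers.
3. **Registration** — the nuclear-stain image is aligned to the histology
   image by maximising mutual information over an affine (with optional
   spline-grid refinement); the result stores the forward point map used to
   carry cell centroids into spot coordinates.
4. **Composition** — each mapped cell joins the spot whose centre is within
   d/2 = 27.5 µm; per spot `P_s^C = N_C / N_s`.  Dominant labels are
   compared against reference annotations with accuracy and confusion
   matrices.
5. **Ligand–receptor ranking** — spot-level co-expression of L-R pairs
   (coupled with the 6-neighbour hex neighbourhood) is permutation-tested
   against a shared background of random gene–gene pairs and pairs are
   ranked by significant-spot count — the basis for prioritising druggable
   interactions.

A synthetic-data module generates every input (cell tables, image pairs
with known transforms, hex spot grids, count matrices with planted L-R
hotspots) so the whole pipeline is testable with known ground truth.

## Worked example

Simulate a section, type the cells, and build spot compositions:

```r
library(spici)

cfg   <- synth_config(seed = 42)          # 2000 cells, 10x10 spot grid
gen   <- make_cell_table(cfg)             # cells + planted ground truth
cells <- gen$cells |>
  filter_cells_quantile() |> getElement("cells") |>
  log_transform() |>
  annotate_cells(load_registry("paper17"))
cells
#> Cell table: 1800 cells, 11 markers [log]
#>   annotated; top types: Tumor (915), CD4 T cells (233), CD8 T cells (231)

a    <- assign_cells_to_spots(cells, gen$spots)
comp <- compute_composition(a, cells$cell_type, gen$spots)
comp
#> Spot composition: 100 spots (0 empty), 447 cells assigned, 1353 unassigned
#>       barcode   cell_type count proportion
#> 1 SYN-001-001 CD8 T cells     1        0.2
#> 2 SYN-001-001       Tumor     4        0.8
#> ...
```

1800 of 2000 cells survive the 5%/95% quantile filter; 447 of them fall
inside a 27.5-µm spot disc (the discs cover ~27% of the section at 100-µm
pitch — gap cells are deliberately unassigned).  Each spot's proportions
sum to 1 exactly.

Collapse the 17 types to tumor vs immune and score against the planted
region truth:

```r
reg    <- load_registry("paper17")
groups <- setNames(ifelse(reg$lineage == "tumor", "Tumor", "Immune"),
                   reg$type_name)
pred  <- dominant_type(comp, groups, c("Immune", "Tumor"))
truth <- dominant_type(compute_composition(gen$true_spot, gen$true_type,
                                           gen$spots),
                       groups, c("Immune", "Tumor"))
evaluate_labels(pred, truth)
#> Spot-label evaluation on 100 spots (0 excluded)
#>   accuracy: 1.000
#>         predicted
#> truth    Immune Tumor
#>   Immune     53     0
#>   Tumor       0    47
```

With registration in the loop (`run_pipeline()` orchestrates QC →
annotation → registration → mapping → composition → evaluation → L-R
ranking), accuracy on clean synthetic sections stays ≥ 0.9.  A thin CLI
over the same functions is installed at `inst/scripts/spici`
(`spici simulate|qc|annotate|register|map|evaluate|lr-rank|run`).

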