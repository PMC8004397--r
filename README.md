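# thymotraj

Trajectory, cell-cycle, and cross-species analysis of thymocyte
development from single-cell RNA-seq.

Double-positive (DP) thymocytes pass through proliferation (DPbla),
TCRα rearrangement (DPre) and selection (DPsel) on their way from
double-negative progenitors to the CD4/CD8 single-positive fates.
thymotraj implements the computational core needed to study that
process from a droplet scRNA-seq snapshot — for anyone asking *where a
cell sits* along development, *whether it is cycling and in which
phase*, and *which genes and transcription factors switch* along the
way or differ between human and mouse:

* **QC and normalization** — 10x-style MTX loading, the strict
  500/4500 detected-gene and 40% mitochondrial-fraction cell filters,
  gene-class removal, quantile normalization
  (`load_counts()`, `qc_filter()`, `quantile_normalize()`).
* **Population balance analysis (PBA)** — a kNN graph over cells and
  the graph-Laplacian system `L V = R` with net rates summing to zero:
  sinks at the ten top-scoring cells per terminal fate, a scalar
  potential `V` per cell (pseudotime from the mature end), exact
  absorbing-walk fate probabilities, and a rank-scaled cell order in
  [0, 1] (`pba_trajectory()` and friends).
* **Cell-cycle phases** — per-phase program scores (G1/S, S, G2/M, M,
  M/G1), the z > 1 classification rule, per-stage phase composition,
  and the order-vs-phase strip statistic that separates sequential
  from random proliferation (`assign_phase()`, `phase_strip()`).
* **Dynamic genes** — 20-cell sliding-window extrema, Gaussian
  smoothing (σ = 1% of the trajectory), and inflection points retained
  by the derivative ratio max|d|/median|d| > 3, with their density
  along the order (`detect_inflections()`, `inflection_density()`).
* **Clustering robustness** — per-cell-pair co-clustering consistency
  across a grid of clustering settings (`pairwise_consistency()`).
* **Regulon post-processing** — binarization thresholds, the 10%/90%
  assigned-cell filter, >0.4 between-stage differences, and the >0.4
  TF–gene correlation link filter (`binarize_and_filter_tfs()`,
  `stage_specific_tfs()`, `filter_links_by_correlation()`).
* **Cross-species comparison** — species-exclusive genes
  (nCells > 20 vs < 3), per-stage marker fold-change tests, driver-TF
  Fisher enrichment with BH correction, and the bulk CPM + t-test
  companion (`cross_species_de()`, `driver_tf_enrichment()`,
  `bulk_de()`).
* **Synthetic data** — a negative-binomial generator with ground-truth
  trajectory, branch, cell-cycle and QC-outlier structure
  (`simulate_dataset()`), so the whole pipeline is testable end to end
  without external data.

## Worked example

Simulate a 7-stage thymocyte snapshot (150 cells per stage), run QC,
normalize, and recover the trajectory and proliferation structure:

```r
library(thymotraj)

cfg  <- sim_config(cells_per_stage = 150, seed = 42)
ds   <- simulate_dataset(cfg)
ds$counts
#> count_matrix: 465 genes x 1050 cells (10 mito, 10 ribo, 5 pseudo)

qc   <- qc_filter(ds$counts, qc_params(min_genes = 50, max_genes = 4500))
norm <- quantile_normalize(qc$matrix)
traj <- pba_trajectory(norm, ds$truth$marker_genes[c("CD4sp", "CD8sp")])

truth <- ds$truth$cells[names(traj$order), ]
cor(traj$order, truth$true_order, method = "spearman")
#> [1] 0.996
round(tapply(traj$order, truth$stage, mean)[
  c("DN", "ISP", "DPbla", "DPre", "DPsel", "CD4sp", "CD8sp")], 2)
#>    DN   ISP DPbla  DPre DPsel CD4sp CD8sp
#>  0.07  0.21  0.36  0.50  0.64  0.88  0.83
```

The recovered order tracks the planted order (Spearman 0.996) and the
stage means climb DN → DPsel with both SP fates at the top. Every
terminal-branch cell's fate probabilities point at its true branch:

```r
fp <- traj$fate_probs
term <- truth$stage %in% c("CD4sp", "CD8sp")
mean(colnames(fp)[max.col(fp)][term] == truth$stage[term])
#> [1] 1
```

Phase classification then shows the two proliferation regimes. DPre
cells are quiescent (93% "none"; the small M/G1 fraction is the
decaying post-mitotic residual at the stage entry), while ISP and
DPbla cycle:

```r
asg  <- assign_phase(phase_scores(norm, ds$truth$phase_gene_sets))
asg  <- asg[names(traj$order), ]
round(phase_composition(asg$label, truth$stage)[
  c("ISP", "DPbla", "DPre"), ], 2)
#>        label
#> groups  G1/S    S G2/M    M M/G1 none
#>   ISP   0.14 0.21 0.20 0.27 0.18 0.00
#>   DPbla 0.23 0.19 0.23 0.15 0.20 0.00
#>   DPre  0.00 0.00 0.00 0.00 0.07 0.93

strip <- phase_strip(asg, traj$order, stages = truth$stage)
round(strip$stage_correlation[c("DN", "ISP", "DPbla")], 2)
#>    DN   ISP DPbla
#> -0.06 -0.62  0.98
```

In DPbla the phases run in chronological order along the trajectory
(r = 0.98): these cells differentiate *during* the cycle and exit it
on arrival in DPre. In the randomly cycling stages the correlation is
not reproducibly signed — near zero in DN here, spuriously negative in
ISP, where the order within an unstructured proliferating cluster is
only weakly pinned (see the methods vignette's limitations).

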