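# codexpipe

Single-cell processing and spatial statistics for highly multiplexed
fluorescence tissue imaging (CODEX-style multicycle acquisitions).

Multiplexed imaging renders dozens of antibody stains over repeated cycles
on the same tissue section, producing a multicycle, multichannel voxel
stack. Turning that stack into trustworthy single-cell biology in *densely
packed* tissue — lymphoid organs above all — requires solving three problems
that dissociated-cell cytometry never meets:

1. **Segmentation where membranes touch.** codexpipe builds a contrast
   image, (1 − membrane) × nuclear after per-channel scaling, low-pass
   filters it in frequency space, and floods a seeded watershed from nuclear
   peaks so that basins collide exactly in the membrane valleys between
   cells.
2. **Positional spillover.** Touching cells contaminate each other's
   membrane signal. With b<sub>ij</sub> the shared boundary voxel faces and
   B<sub>j</sub> the total boundary of cell j, the spill matrix
   S<sub>ij</sub> = c·b<sub>ij</sub>/B<sub>j</sub> (columns summing to 1,
   invertible for c &lt; 0.5) models the blending; compensation multiplies
   raw intensity vectors by S⁻¹. Three-step cleanup gating (stain density +
   cycle homogeneity, blank-cycle background, size) then removes debris and
   doublets.
3. **Spatial statistics.** On the pruned 2-D Delaunay graph of cell
   centroids the package computes cell-type interaction log-odds ratios
   (observed Beta-mean co-occurrence over expected), binomial significance
   with Benjamini–Hochberg FDR and the dual-threshold attraction/avoidance
   rule, cross-condition t-tests, and the χ deviation statistic; and it
   clusters first-tier neighborhood compositions (**i-niches**) with
   K-means, profiles marker expression of index cells per niche, and tests
   niche dependence of marker expression with a nested linear-model F-test.

A synthetic tissue-phantom generator (spheres with concentric nuclei and
membrane shells, compartments, planted attractions and niche archetypes,
full ground truth) makes every stage testable without external data. It is
aimed at imaging groups processing their own multicycle stacks and at
methods developers who need a ground-truthed sandbox for crowded-tissue
segmentation and neighborhood statistics.

## Worked example

Generate a dense 120-cell phantom (Gaussian noise, one blank cycle), then
run alignment → segmentation → quantification → compensation → gating →
interactions → niches in one call:

```r
library(codexpipe)

spec <- phantom_spec(image_shape = c(128L, 128L, 9L), n_cells = 120L,
                     noise_gaussian_sd = 2, blank_cycles = 3L, seed = 11L)
res <- run_pipeline("codex_run", spec, k_niches = 8)

res$mask
#> segmentation_mask: 128 x 128 x 9 voxels, 120 cells

unlist(res$benchmark)
#>      pct_nuclei_found          pct_singlets pct_unlabeled_regions
#>                   100                   100                     0

res$gated$report
#>                  gate removed remaining
#> 1 density_homogeneity       4       116
#> 2    blank_background       3       113
#> 3                size       4       109

round(res$interactions$log_odds, 2)
#>       B220  CD90  F480
#> B220  0.03 -0.10  0.05
#> CD90 -0.10 -0.03  0.14
#> F480  0.05  0.14 -0.28
```

All 120 phantom cells are recovered as singlets; the gate report shows the
three cleanup gates in order (11 objects removed in total); and the
interaction log-odds matrix is near zero everywhere — as it must be, since
this phantom places cell types at random (`res$interactions$flags` confirms
nothing is flagged attraction or avoidance). Marker expression conditioned
on the niche is equally null here:

```r
unlist(marker_niche_anova(res$gated$table, res$types, res$niche_model, "IgD"))[1:2]
#>         F         p
#> 1.2454100 0.2855616
```

The run directory now holds every artifact: `stack.tif` (+ channel-metadata
sidecar), `mask.tif`, `cells_raw.csv`, `cells.csv`, `cells.fcs` (FCS 3.0),
`spill_matrix.csv`, `gate_report.csv`, `interactions.csv`,
`niche_assignment.csv`, `niche_centroids.csv`, `niche_profile.csv`.

### Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "codex.R", package = "codexpipe"))')
Rscript $CLI pipeline --out codex_run --n-cells 120 --seed 11
Rscript $CLI segment --stack codex_run/stack.tif --cutoff 0.45 --min-distance 3
Rscript $CLI interactions --cells codex_run/truth.csv
```

Subcommands: `phantom`, `align`, `segment`, `quantify`, `compensate`,
`gate`, `interactions`, `niches`, `export`, `pipeline`.

## Layout

- `R/`, `src/` — implementation (R plus a small Rcpp core: seeded
  watershed, boundary-face census, local maxima).
- `inst/cli/codex.R` — command-line front end.
- `vignettes/processing-and-spatial-statistics.Rmd` — the models, their
  assumptions, parameter guidance and known limitations.
- `tests/testthat/` — unit, property and acceptance suites (phantom
  fixtures are generated in code; no binary test data).
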