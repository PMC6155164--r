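# smlmcoloc

Quantitative analysis of DNA-damage repair foci in multicolor
single-molecule localization microscopy (SMLM/STORM). The package is aimed
at imaging groups who localize nascent DNA (naDNA) and repair proteins
(RPA, RAD51, RAD52, BRCA1/2, ...) at single collapsed replication forks
and need statistics that are honest about chance colocalization at
super-resolution densities.

It implements the full pipeline from raw frames or localization tables to
population-level statistics:

* **Single-molecule localization** — 2D Gaussian PSF fits with acceptance
  filters: signal-to-noise ratio better than 3, FWHM up to 640 nm;
  per-frame background from a 2 × 2 µm window at the frame minimum.
* **Chromatic registration** — total-degree-3 bivariate polynomial maps
  fitted on mutual-nearest-neighbor matched fiducial beads, with residual
  (mapping-error) reporting and JSON serialization.
* **Rendering & segmentation** — 20 nm pixel renders, per-nucleus Otsu
  threshold computed from in-ROI pixels only, 8-connected cluster
  labeling, areas and intensity-weighted centers of mass.
* **Monte Carlo colocalization** — the coefficient
  `C = observed overlap / mean(simulated overlap)`, where one channel's
  clusters are rigidly redistributed uniformly inside the nucleus ROI in
  each of 20 simulations. `C = 1` is chance; `C = 2` is a doubling above
  chance. Number- and area-based overlaps, per-protein defaults, flagged
  undefined cases, Welch t tests across conditions/timepoints, and
  protein × timepoint heatmap matrices.
* **Focus demographics & geometry** — per-focus protein presence calls,
  {A-only, B-only, both} population fractions with
  prevalence/dependence/exclusion descriptors, intrafoci center-of-mass
  distances, single/double Gaussian histogram fits against the 135 nm /
  75 nm FWHM proximal reference component, proximal (135 ± 37.5 nm) vs
  distal (> 180 nm) classification, and 2D likelihood intensity maps.
* **Synthetic scenes with ground truth** — seeded generators for nuclei,
  classed focus populations, warped bead fields and raw Poisson frame
  stacks, used by the test suite to validate every stage.

## Worked example

Simulate a nucleus with 60 naDNA foci and 60 RPA clusters of which 70%
sit at foci, segment both channels, and score colocalization:

```r
library(smlmcoloc)
cfg <- scene_config(n_nadna_foci = 60,
                    n_protein_clusters = c(RPA = 60),
                    colocalized_fraction = 0.7, seed = 1)
scene <- generate_nucleus_scene(cfg)
seg <- segment_scene(scene$locs, scene$roi)
colocalization_coefficient(seg$sets$naDNA, seg$sets$RPA, scene$roi,
                           n_sims = 20, seed = 2, mask = seg$mask)
#> <coloc_result> nucleus 'nucleus' (naDNA vs randomized RPA):
#>   number: real 5 / sim mean 1.30 -> coefficient 3.846
#>   area:   real 3200 / sim mean 2300 nm^2 -> coefficient 1.391
```

Five naDNA clusters touch an RPA cluster against 1.3 expected by chance —
a ~3.8-fold enrichment in overlap *number*; the overlap *area* ratio is
milder because RPA clusters sit ~135 nm off the naDNA center and masks
only graze. Fitting an intrafoci distance sample against the proximal
reference model:

```r
set.seed(3)
d <- rnorm(500, 135, fwhm_to_sd(75))   # 135 nm center, 75 nm FWHM
fit_distance_distribution(d[d > 0])
#> <distance_fit> single model, n = 500, classification: proximal
#>   component 1: center 136.4 nm, FWHM 77.5 nm, amplitude 60.57
#>   RSS 377, R^2 0.9680
```

The fitted center (136.4 nm) falls inside the 135 ± 37.5 nm proximal
band, so the pair is classified as closely associated.

## Analysis workflow

The `analysis/` directory holds numbered drivers that chain the package
into the full study workflow, writing tables under `results/`:

1. `01_simulate_scenes.R` — scenes, bead fields and a raw stack with
   ground truth;
2. `02_localize_and_map.R` — localization with the acceptance filters and
   chromatic registration (reports recall, RMS error, median mapping
   error);
3. `03_colocalization_timecourse.R` — a control-vs-damage timecourse with
   population summaries, t tests and the arrival/departure heatmap;
4. `04_foci_populations.R` — population fractions for the 2 h / 8 h
   RPA/RAD51 mixtures and the intrafoci distance fit with its 2D
   likelihood map.

Run them in order with `Rscript analysis/01_simulate_scenes.R` etc.

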