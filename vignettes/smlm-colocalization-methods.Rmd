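---
title: "Quantifying repair-focus colocalization in multicolor SMLM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repair-focus colocalization in multicolor SMLM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The analysis problem

Homologous-recombination repair of collapsed replication forks produces
*foci*: sub-micron assemblies of nascent DNA (naDNA, pulse-labeled during
replication) decorated by repair proteins such as RPA, RAD51, RAD52, BRCA1
and BRCA2. Multicolor single-molecule localization microscopy (SMLM/STORM)
resolves these foci at tens-of-nanometer scale, but turning localization
tables into biology needs a statistical pipeline: are two proteins at the
same places more often than chance? what fraction of foci carry one
protein, the other, or both? and when two proteins share a focus, how far
apart do they sit?

`smlmcoloc` implements that pipeline end to end:

1. **Localization** — 2D Gaussian PSF fitting of raw frames with
   acceptance filters (SNR better than 3, FWHM at most 640 nm).
2. **Chromatic registration** — a total-degree-3 bivariate polynomial map
   per axis, fitted on matched fiducial beads, taking each color channel
   onto the red/far-red reference.
3. **Rendering and segmentation** — localization tables histogrammed on a
   20 nm grid, thresholded per nucleus with Otsu's method computed from
   in-ROI pixels only, and labeled by 8-connectivity.
4. **Monte Carlo colocalization** — the observed overlap (number or area)
   between two channels' clusters ratioed to the mean overlap over 20
   randomizations that rigidly relocate one channel's clusters uniformly
   within the nucleus ROI. A coefficient of 1 is chance; 2 is a doubling
   above chance.
5. **Focus demographics and geometry** — per-focus presence calls,
   population fractions, and single/double Gaussian fits of intrafoci
   center-of-mass distance histograms with proximal/distal classification.

Because raw acquisitions of this kind are terabyte-scale and not
redistributable, the package ships a seeded synthetic-scene generator with
complete ground truth; every stage is validated against it.

## The colocalization coefficient

For one nucleus, channels are segmented two at a time. The naDNA (or other
"fixed") channel keeps its real spatial distribution; the protein
channel's clusters are relocated `n_sims = 20` times to uniform random
positions fully inside the ROI, preserving each cluster's pixel mask
exactly (translation only by default; optional right-angle rotations).
With observed overlap $O$ and simulated overlaps $S_1 \dots S_{20}$,

$$ C = \frac{O}{\tfrac{1}{20}\sum_s S_s}. $$

Overlap *area* is the pixelwise intersection area of the two channels'
union masks; overlap *number* counts fixed-channel clusters touching at
least one partner cluster (the direction is recorded). Area is the default
for accumulating proteins (γH2A.X, RPA, RAD51, RAD52, BRCA2), number for
discrete ones (MRE11, BRCA1, CtIP, BLM); `coefficient_mode()` encodes
this. When the simulation mean is zero the coefficient is undefined: the
nucleus is flagged `insufficient-randomization-overlap` and excluded from
population means rather than reported as infinite.

**Statistical behaviour at low overlap density.** $C$ is a ratio
estimator: with $k$ expected overlap events per nucleus its per-nucleus
coefficient of variation is about $1/\sqrt{k}$ *plus* an upward Jensen
bias of roughly $\mathrm{cv}^2(S)/20$ from the reciprocal of the 20-sim
mean. Real nuclei in this assay carry tens to hundreds of overlaps, where
both terms are negligible; in deliberately sparse synthetic scenes (a few
events per nucleus) means over even 100 nuclei remain noisy and sit a few
percent above 1 under complete spatial randomness. This is a property of
the statistic itself, not of the implementation, and matters when
calibrating null expectations on sparse scenes.

```{r coloc-example}
library(smlmcoloc)
cfg <- scene_config(n_nadna_foci = 60,
                    n_protein_clusters = c(RPA = 60),
                    colocalized_fraction = 0.7, seed = 1)
scene <- generate_nucleus_scene(cfg)
seg <- segment_scene(scene$locs, scene$roi)
colocalization_coefficient(seg$sets$naDNA, seg$sets$RPA, scene$roi,
                           n_sims = 20, seed = 2, mask = seg$mask)
```

## Focus identification and population fractions

A focus is a segmented naDNA cluster. A protein is *present* at a focus
when one of its clusters intersects the naDNA mask or has a center of mass
within `association_radius_nm` (default 250 nm, the scale of a zoomed
focus) of the naDNA center. naDNA clusters with no protein are counted but
excluded from the records. For a protein pair, fractions over
{A-only, B-only, both} summarize the population, plus three descriptors:
*prevalence* (fraction both-positive), *dependence* of A on B (fraction of
B-positive foci also A-positive, and vice versa), and an *exclusion* flag
raised when the both-fraction falls below the product of the marginals —
the independence expectation. The exclusion/dependence definitions are
this package's operationalization of qualitative descriptors whose
original quantitative form is not public; they are deliberately simple and
documented here.

Otsu segmentation can split one bright naDNA focus into a main component
plus satellites, so record counts exceed true focus counts (about 1.5x at
the defaults). Satellites inherit the class of their parent focus almost
always; measured class fractions track ground truth within a percentage
point in validation, but absolute *counts* of records should not be read
as focus counts without deduplication.

## Intrafoci distances and the 135 nm reference

For foci carrying both proteins of a pair, the package measures the
distance between the centers of mass *of the two colors*: each protein's
center is the pixel-count-weighted center over all of its qualifying
clusters at that focus, so threshold fragmentation does not bias distances
inward (selecting only the nearest fragment would).

Distances are histogrammed (10 nm bins) and fitted by least squares with
Poisson weighting: an unweighted pass supplies predicted counts, then the
fit repeats with weights $1/\max(\hat\mu_i, 1)$ — the inverse of the
Poisson variance estimated from the model, which is both stable for empty
bins and statistically efficient. The reference component for closely
associated proteins is a Gaussian at 135 nm center and 75 nm FWHM
(calibrated on double-labeled RAD51). Model selection (`model = "auto"`)
tries a single Gaussian first and adopts the double model — component 1
fixed at 135/75 with free amplitude, component 2 free — only when it cuts
the residual sum of squares by more than half *and* an F test at
$\alpha = 0.05$ supports the extra parameters; in manual practice this
step is a by-eye judgement, so the threshold is stated explicitly here.

Classification of a single-Gaussian center: **proximal** in
[97.5, 172.5] nm (135 ± 37.5), **distal** beyond 180 nm, **mixed** for
accepted double fits, and **indeterminate** otherwise — including the
(172.5, 180] nm gap left open by the band definitions and centers below
97.5 nm. Boundaries are closed on the proximal side and open at 180.

At $n = 500$ distances, the fitted center has ~1.5 nm s.d. (well within a
±5 nm acceptance band); the fitted width has ~3% relative s.d. — the
information-theoretic floor $1/\sqrt{2n}$ — so width recovery is asserted
as unbiasedness plus a 10% per-replicate band rather than a 5% band no
unbiased estimator could meet 95% of the time.

The 2D likelihood map renders each fitted component as a radial Gaussian
ridge (a ring at the component's center distance with the component's
width), amplitudes in the fitted ratio, normalized to 1 — a presentation
artifact only.

## The synthetic-scene generator

`generate_nucleus_scene()` emulates the statistical structure of a labeled
S-phase nucleus:

* a polygonal nucleus ROI (default: 10 µm diameter circle);
* naDNA foci uniform in the ROI, each a cluster of localizations drawn
  from an isotropic Gaussian of s.d. = radius/2 (radius 50–100 nm — naDNA
  repair foci are compact and densely labeled, mean 200 localizations);
* protein clusters (radius 40–100 nm, mean 80 localizations, log-normal
  counts with log-s.d. 0.4, floored at 5): a configurable colocalized
  fraction sits at foci, the rest uniform in the ROI;
* per-localization isotropic precision noise (channel defaults 9.5 / 9.3 /
  17.7 nm for red / blue / green);
* uniform Poisson background (default 0.5 µm⁻²).

**Displacement semantics.** The displacement model (Gaussian, 135 nm
center, 75 nm FWHM, uniform direction) describes the distance calibrated
on *pairs* of labels. A lone protein at a focus is offset from the focus
center by one model draw; when two proteins share a focus, their *mutual
separation* is the model draw, split symmetrically about the focus center.
This is the only construction under which both the per-protein offsets and
the measured pair distances behave like the reference data.

`generate_focus_population()` lays classed foci on jittered grids inside
square nuclei (1.5 µm pitch, so neighbours stay far beyond the association
radius) and places protein clusters only for the channels present in each
sampled class. `generate_bead_field()` produces minimum-spacing fiducial
fields warped by a known polynomial for registration tests;
`generate_frames()` renders localization tables into Poisson-noise camera
frames for the localizer.

What the generator does **not** emulate: fluorophore blinking and repeat
localizations of one molecule, 3D structure (the pipeline is a 2D
projection by design), spatially varying background, nuclear
substructure, or label stoichiometry. Passing tests therefore demonstrate
correctness of the *pipeline computations* under the stated statistical
model, not robustness to every artifact of real acquisitions.

## Numerical and design choices

* FWHM ↔ s.d. conversion is fixed at $2\sqrt{2\ln 2}$ throughout.
* Rendering uses half-open 20 nm bins, 0-based pixel indices; counts mode
  conserves localization counts exactly. Gaussian mode (spread by each
  localization's precision) is available; counts is the default and what
  segmentation thresholds were designed against.
* Otsu runs on all in-ROI pixels, zeros included: in sparse SMLM renders
  excluding zeros would inflate thresholds and erase dim clusters. Ties in
  the between-class variance resolve to the lowest threshold; the returned
  threshold is the midpoint between the last background and first
  foreground level, with foreground strictly greater.
* Cluster labeling is 8-connected (configurable to 4). A labeled cluster
  keeps every pixel; there is no minimum-size filter, since a single
  detected molecule is a real observation.
* Randomization places each cluster by rejection over in-ROI anchor pixels
  (cap 10,000 tries) requiring full containment; relocated clusters may
  overlap each other. Sub-seeds for the 20 simulations derive from the
  master seed by multiplicative counter mixing, so one integer reproduces
  a whole cohort bit-identically.
* Bead matching is mutual-nearest-neighbor with a 500 nm gate; map fitting
  normalizes source coordinates (centered, scaled) before building the
  degree-3 monomial design, refuses rank-deficient (collinear) designs,
  and flags — but still corrects — localizations outside the training
  hull. "Third polynomial" is read as total degree 3 (10 coefficients per
  axis); a bicubic reading would differ negligibly at these warp
  magnitudes.
* The localizer detects candidates as 8-neighborhood maxima of a lightly
  smoothed, background-subtracted frame above `snr_min` background s.d.;
  background mean/s.d. come from a 2 × 2 µm window centered at the frame
  minimum. SNR is defined as fitted amplitude over background s.d. (the
  original tool's internal definition may differ; this one is fixed and
  documented). Accepted fits closer than one FWHM are both discarded;
  localization precision is reported as s.d./√N with N the fitted photon
  count — a standard shot-noise-limited estimate, stated here because no
  formula is inherited.
* Welch t tests compare each condition against the reference; groups with
  zero variance fall back to an ε-guarded statistic and are flagged
  `degenerate-variance`. Stars follow 0.05/0.01/0.001/0.0001.

## Problem sizes used in validation

The test-suite and acceptance runs use: 100 nuclei with 50 clusters per
channel for the complete-spatial-randomness calibration; 100-bead fields
at 3 nm noise for registration; 500 distance draws for fit recovery; and
2000 classed foci (20 nuclei of 100) per population mixture. These sizes
reproduce the statistical regimes of interest while keeping a full
validation run in minutes on one core.

## Known limitations

* The coefficient's ratio form is biased and noisy at very low overlap
  density (see above); prefer area mode and report flagged nuclei.
* Focus records are per naDNA *component*; fragmentation inflates record
  counts (fractions remain calibrated).
* No drift correction and no multi-emitter fitting; crowded candidates
  are rejected pairwise rather than fitted jointly.
* 2D only; overlap normalization absorbs, but cannot undo, the
  2D projection of 3D structure.
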