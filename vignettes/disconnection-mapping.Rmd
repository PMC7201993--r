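---
title: "Lesion-based structural disconnection mapping with disconnectr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-based structural disconnection mapping with disconnectr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disconnectr)
```

## The problem

A focal brain lesion does not only destroy the tissue it occupies: it
interrupts every white-matter pathway passing through it, and so can
dysconnect cortical regions far from the lesion itself. Comparing two
patient cohorts voxel by voxel on the lesion masks alone therefore misses
differences that live in connectivity space. The *normative disconnectome*
approach embeds each patient's lesion into a panel of healthy-control
tractograms: the streamlines that pass through the lesion in each control
are collected, their visitation maps are binarized and averaged over
controls, and the resulting map gives, at every template voxel, the
probability that the lesion disconnects that location.

`disconnectr` implements this pipeline end to end for binary lesion masks on
a shared template grid:

1. **Preprocessing** — hemisphere flipping (left lesions mirrored to the
   right for comparison), integer-factor downsampling (e.g. a 1 mm template
   grid to 2 mm), lesion volume computation.
2. **Disconnectome maps** — per-subject probability-of-disconnection maps
   from a streamline panel, thresholded into binary disconnection masks.
3. **Frequency and consensus maps** — per-group voxelwise overlap counts
   and the "75% of patients" consensus maps.
4. **Voxelwise statistics** — two-sample GLM with lesion volume as a
   nuisance covariate, permutation inference with threshold-free cluster
   enhancement (TFCE) and family-wise error (FWE) correction via the
   max-statistic distribution.
5. **Atlas overlap** — quantification of the significant
   (*disconnection-based*) map against tract, subcortical and
   cortical-network atlases.

A synthetic-data module generates lesion cohorts, tractogram panels and
atlases with a controllable planted group difference, so the entire pipeline
is exercised and validated without any imaging download.

## The model, operation by operation

### Coordinates and grids

All maps live on one `volume_grid` and are stored and compared in voxel
index space; the template affine is metadata only. Streamline points are
continuous voxel coordinates in which voxel $(i,j,k)$ (0-based) spans the
half-open cube $[i, i+1) \times [j, j+1) \times [k, k+1)$. Millimetre
coordinates are voxel coordinates scaled by the voxel size.

### Downsampling and flipping

Downsampling aggregates each block of source voxels into one target voxel.
The occupancy rule is a design choice the data do not fix: we lesion a
target voxel iff at least half of its source block is lesioned (ties
lesioned), because this majority rule preserves lesion volume in
expectation; `min_fraction` makes it configurable. Flipping mirrors the
voxel array about the grid's central plane on the left–right axis, so it is
an exact involution and preserves volume; on an odd-length axis the central
slice is its own image. Masks with voxels in both hemispheres after flipping
are allowed — bilateral (e.g. callosal) effects are real — so no midline
clipping is applied.

### Selecting streamlines and visitation maps

A lesion is carried into a control's native space through the control's
affine, by pull-resampling: each native voxel takes the value of the source
voxel its center maps into (nearest-voxel assignment). Partial-volume
interpolation is deliberately rejected: it would make binary maps
non-binary, and pull-resampling keeps the operation monotone (a larger
lesion can never produce a smaller native-space lesion).

A streamline is selected iff any of its segments passes through a lesioned
voxel. Segment–voxel traversal uses a 3-D digital-line walk (the
Amanatides–Woo voxel stepping algorithm), which is tolerance-free and
verifiable against a brute-force segment–cube clipping oracle; the test
suite performs exactly that comparison. Visitation maps mark every voxel
any selected streamline traverses, and are carried back to the template
grid through the inverse affine, again by nearest-voxel pull-resampling.

### The disconnectome probability map

With $n$ controls, the map value at voxel $v$ is
$$p(v) = \frac{1}{n} \#\{\text{controls whose selected streamlines visit } v\},$$
so $p \in [0,1]$ and $n\,p(v)$ is integer. We resolve the "normalized
visitation map" convention as *binarized* per-control maps, the stated
convention of the pipeline this reproduces; a streamline-count weighted
variant (each control's visitation counts normalized by their maximum) is
available behind `weighted = TRUE` but is not the default. The default
probability cutoff is 0.5 applied *strictly* (`>`): a voxel at exactly 0.5
is not considered disconnected, reading "above 50%" literally. Both the
cutoff and the strictness are parameters; `cutoff = 0` reproduces an
unthresholded analysis.

### Group statistics

At every voxel inside the analysis mask (by default the union of nonzero
voxels across subjects) we fit
$$y = \beta_0 + \beta_1\,\mathrm{group} + \beta_2\,\mathrm{volume} + \varepsilon$$
by ordinary least squares and test $\beta_1$ with a t-statistic; without the
covariate this is exactly the pooled-variance two-sample t. Lesion volume
enters mean-centered. Two numerical choices matter at degenerate voxels:
data constant across all subjects give $t = 0$ (they carry no signal and
would otherwise produce 0/0), and residual variances are floored at a tiny
relative value ($10^{-24}$ times the mean squared signal) so perfectly
separated voxels give very large finite statistics rather than infinities,
which TFCE could not process.

TFCE integrates cluster extent and height over all thresholds:
$$\mathrm{TFCE}(v) = \sum_{h = dh,\,2dh,\,\dots}^{\max} e_h(v)^{E}\, h^{H}\, dh$$
with the canonical parameters $H = 2$, $E = 0.5$, $dh = \max/100$ and
26-connectivity, all configurable. Only the positive part of a map is
enhanced; the opposite direction runs on the negated map, and both
directions are always computed.

Inference is by permutation of the map-wise maximum statistic:
$$p_{\mathrm{FWE}}(v) = \frac{1 + \#\{\text{permutation maxima} \ge \mathrm{TFCE}_{\mathrm{obs}}(v)\}}{n_{\mathrm{perm}} + 1},$$
the $+1/+1$ form that is valid at any finite permutation count. With a
nuisance covariate the permutation scheme is not innocuous; we default to
Freedman–Lane (permute the residuals of the nuisance-only model, add back
its fit), the standard choice of the established nonparametric GLM tools,
with plain label permutation available behind `scheme = "labels"`. Under
the label scheme, when `n_perm` reaches the number of distinguishable
relabelings $\binom{n}{n_1}$ the test enumerates them exhaustively (with a
warning) and the p-values are exact. Zero-variance voxels are excluded from
the maximum and reported with $p = 1$. The conventional full-scale setting
is 5000 permutations; the package default configuration uses smaller counts
so that a complete run stays interactive.

### Frequency, consensus, and atlas overlap

Frequency maps are plain per-voxel sums of binary masks. The consensus map
at fraction $f$ includes voxels covered by at least $\lceil f\,n\rceil$
subjects — the strictest reading of "$f$ of the patients"; a floor rule is
available. The disconnection consensus is computed on the *thresholded*
per-subject maps, matching the per-subject binarized usage; computing it on
raw probability maps is the plausible alternative, obtainable by passing
those maps explicitly.

Overlap of a binary disconnection-based map $D$ with a region $T$ is
reported two ways:
$$\%\mathrm{disconnected\ tract} = \frac{|D \cap T|}{|T|} \times 100,
\qquad
\%\mathrm{disco/parcel} = \frac{|D \cap T|}{|D|} \times 100.$$
The first asks how much of a tract is disconnected, the second how much a
region contributes to the whole disconnection; over an exhaustive disjoint
parcellation covering the map the second sums to 100. Display/retention
thresholds (tracts above 10%, networks above 2%) are strict inequalities.
Network rows aggregate cortical parcels by the union of member parcel
masks; with disjoint parcels this equals the per-parcel sum, and the union
convention is the documented one. The map entering these formulas defaults
to the FWE-significant group-difference map at $\alpha = 0.05$, but any
binary map can be supplied.

## What the synthetic data emulate — and what they do not

The generator reproduces the *structure* of a two-cohort lesion study:

* unequal group sizes, default 28 cases and 35 controls;
* per-group lesion size distributions (normal in voxel count, floored at
  one voxel) with the control group's lesions larger and more variable,
  scaled to the synthetic grid — the defaults (mean 110 vs 300 voxels, sd
  60 vs 180 on a $24^3$ grid of 2 mm voxels) keep the case:control volume
  ratio near the 1:2.8 seen in real cohorts of this kind;
* lesions as connected blobs grown by random boundary accretion from
  per-group focus regions; about half of the control group's lesions start
  in the left hemisphere and are flipped during preprocessing;
* a streamline panel of (default) 20 controls — scaled down from the
  164-control panels of normative disconnectome studies — with three
  bundles laid out as a fronto-temporal arch, a dorsal descending pathway
  and a transcallosal pathway; inter-individual variability enters as
  smooth per-streamline jitter (tapered to zero at the endpoints so bundle
  termination regions are respected) plus small random affines (rotation
  up to 5 degrees, translation up to 2 voxels), a tractable stand-in for
  affine-plus-diffeomorphic registration;
* an optional planted effect: with probability `strength`, each case
  lesion is translated onto the template course of a designated bundle,
  creating a true group difference in disconnection of that bundle.

One global seed hierarchically derives per-subject and per-control seeds,
so all generators are bit-reproducible and subsetting a cohort does not
reshuffle the remaining subjects.

What the synthetic data do **not** contain: real lesion morphology
(vascular-territory shapes, gray/white matter boundaries), nonlinear
deformation, fiber crossings, distance-dependent tractography biases, or
any clinical covariates. Passing the test suite therefore demonstrates
that the *computational contracts* hold — probabilities are fractions of
controls, the statistics control family-wise error at nominal level under
the null, planted effects are recovered where they were planted — not that
any particular neuroanatomical conclusion transfers to real data.

## Validation strategy and problem sizes

The test suite checks every stage against an independent oracle at small
problem sizes chosen to keep a complete run interactive:

* TFCE against per-threshold connected-component enumeration (via igraph)
  on fifty random $8^3$ maps, exact equality on the same threshold grid;
* permutation p-values against exhaustive enumeration of all 20
  relabelings for 3-vs-3 designs;
* the GLM t against the closed-form pooled t (1000 voxels, $10^{-10}$) and
  against per-voxel `lm()` fits when covariates are present;
* the family-wise false-positive rate over 200 null cohorts ($16^3$ grid,
  8+8 subjects, 500 permutations each), required to land in $[0.02, 0.09]$
  at $\alpha = 0.05$;
* recovery of a planted effect (20+20 subjects, 20-control panel, 1000
  permutations on a $20^3$ grid): significant voxels must lie on the target
  bundle and the overlap report must rank the target tract first;
* byte-identical artifacts across two pipeline runs with one seed.

## Worked example

```{r example, eval = FALSE}
grid <- volume_grid(c(24, 24, 24), voxel_size_mm = c(2, 2, 2))
cohort <- make_cohort(cohort_spec(grid = grid, seed = 7))
panel <- make_panel(n_controls = 20, n_streamlines = 25, grid,
                    jitter = 0.5, seed = 8)
cohort <- plant_effect(cohort, panel, target_bundle = 1, strength = 1,
                       seed = 9)
cohort <- lapply(cohort, function(m)
  if (m$side == "left") flip_to_right(m) else m)

dmaps <- lapply(cohort, disconnectome_map, panel = panel)
dbin  <- lapply(dmaps, function(d) threshold_disconnectome(d, 0.5) + 0)

design <- design_matrix(vapply(cohort, `[[`, "", "group"),
                        vapply(cohort, `[[`, 0, "volume_mm3"))
sm <- permutation_fwe(dbin, design, n_perm = 1000, seed = 10, grid = grid)
sig <- significant_map(sm, "g1_gt_g2", alpha = 0.05)

atlases <- make_atlas_set(panel, seed = 11)
overlap_report(sig, unname(atlases))
```

Or, equivalently, as one call writing all artifacts plus a manifest:

```{r pipeline, eval = FALSE}
run_pipeline(pipeline_config(seed = 7, n_perm = 1000), "run_dir")
```

## Known limitations

* Only affine template-to-native transforms are supported; diffeomorphic
  warps are out of scope, so real-data panels registered nonlinearly must
  be reduced to affines before import.
* The package *selects* streamlines from stored panels; it implements no
  tractography, diffusion model fitting, or registration of raw images.
* Nearest-voxel resampling is exact for the binary maps used here but
  would alias continuous maps under large rotations.
* Permutation exchangeability blocks and variance smoothing are not
  implemented; cluster-extent inference is deliberately absent in favour
  of TFCE.
* TRK streamline files are read and written in the TrackVis voxel-mm
  convention with an axis-aligned header affine; exotic header affines are
  not interpreted.
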