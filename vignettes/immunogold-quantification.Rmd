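---
title: "Quantifying immunogold labeling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immunogold labeling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goldquant)
```

## The measurement problem

In SDS-digested freeze-fracture replica labeling (SDS-FRL), membrane
proteins are immunolabeled with ~10 nm colloidal gold on the protoplasmic
fracture face (P-face) of a replicated membrane, and the readout is the
surface density of gold particles — immunoparticles per µm² — in identified
compartment profiles (somata, apical and oblique dendrites, spines, axon
terminals) across the laminae of hippocampal CA1. Complementary
pre-embedding immunogold sections report the *fraction* of particles on the
plasma membrane versus intracellular sites, and histoblots report regional
protein expression as background-corrected pixel densities. goldquant
implements each of these quantification stages over explicit geometric
inputs (profile polygons, particle coordinates) and pairs them with a
synthetic scene generator so that every stage can be validated against a
known ground truth — the original micrographs behind such studies are
rarely public, so calibrated simulation is the only route to end-to-end
testing.

## The generative model

Clustered membrane labeling is modelled as a Thomas-type parent–offspring
process inside each profile polygon:

- cluster centres are homogeneous Poisson with intensity $\lambda_c$
  (centres/µm²);
- each centre receives $k = 3 + \mathrm{NegBin}(\mu = \mu_k - 3,
  \text{size} = \phi)$ member particles, displaced isotropically from the
  centre with Gaussian scale $\sigma_r$ (truncated at $3\sigma_r$);
- an independent homogeneous scattered process with intensity $\lambda_s$
  is superposed;
- all particles respect a hard-core minimum centre separation.

The expected total density is $\lambda_c\,\mu_k + \lambda_s$, and the
packaged calibration (`inst/extdata/calibration.yaml`) stores, per condition
(genotype × age × compartment), the mean density this sum must equal. Two
modelling choices deserve comment:

**Offspring law.** Planted cluster sizes are shifted by 3 so every planted
cluster satisfies the minimum-cluster-size rule used downstream (clusters of
one or two particles are discarded); sub-threshold groups arise only from
the scattered process. The size distribution is a shifted *negative
binomial* rather than a shifted Poisson: observed cluster-size ranges in
this kind of data run from 3 up to ~30 particles while mean sizes are only
6–12, a dispersion a Poisson tail cannot produce. The shifted Poisson is
recovered as the `dispersion = Inf` limit, and the default dispersion
(size = 2; 1.5 in the cluster-composition calibration) was fixed once from
the printed size ranges.

**Hard core.** Gold conjugates are solid 10 nm spheres carried by an
IgG sandwich, so observed inter-particle distances cannot fall below
~1.5 particle diameters. The generator enforces a 15 nm minimum centre
separation by resampling positions (never dropping particles, so expected
counts are unchanged). Without this constraint a Gaussian cluster would
place particle pairs at physically impossible sub-diameter spacings that no
detector could resolve.

Offspring displaced outside the profile polygon are resampled until inside,
so expected per-profile counts are exactly area × (λ_cµ_k + λ_s) and
containment is exact; the slight inward distortion of cluster shapes within
~σ_r of the profile edge is the accepted cost.

Presynaptic labeling is two independent homogeneous processes, one inside
the active-zone polygon and one in the remainder of the terminal.
Pre-embedding labeling assigns each particle to the membrane with
probability $p$ and places membrane particles inside the profile within
`d_offset_nm` of the membrane contour, intracellular particles strictly
beyond it: keeping the two placement regions disjoint makes the
distance-threshold classifier identifiable, which is what lets partition
recovery be tested to percentage-point accuracy. Real pre-embedding
material blurs this boundary (silver enhancement, section thickness), so
the recovery tests validate the classifier's geometry, not its biological
error rate.

### What the calibration does and does not transcribe

Densities printed in the source study's results text anchor the calibration
(`source: body_text`): the four 6-month stratum-lacunosum-moleculare
conditions (64.34 and 101.58 particles/µm² in wild type, 28.83 and 49.76 in
the AD model), the four presynaptic active-zone/extrasynaptic pairs, twelve
membrane-vs-intracellular percentages, and six cluster totals with size
ranges over a 140 µm² reference area. Figure-legend values that conflict
with the body text are recorded under `alternates:` but not used. The
remaining compartments of the 11-compartment density gradient were shown
only graphically; the calibration fills them with a single plausible
soma → spine graded profile (`source: assumed`, 6.3 → 101.58
particles/µm²), and models the 12-month genotype deficit as a uniform 0.40
fraction since only its significance, not its magnitude, is printed. The
printed cluster counts and the printed slm densities are mutually
inconsistent under any single Thomas parameterization (234 clusters/140 µm²
at ~64 particles/µm² would need mean size ~33 against a printed maximum of
37), so the cluster-composition calibration is deliberately decoupled from
the density calibration; the two sections emulate the two different printed
analyses.

## Rasterization and detection

Scenes are rasterized at 1 nm/px (configurable within 0.5–5 nm/px) as
anti-aliased dark disks on a bright background (level 0.85, disk depth
0.55) with additive Gaussian noise (σ = 0.05) and a two-component sinusoidal
shading field (amplitude 0.06, scale 250 nm) standing in for uneven
illumination. This is deliberately *not* a physical replica model — no
platinum shadowing, no intramembrane-particle texture — because the
detection contract is fixed by recovery properties, not by image realism;
passing tests show the geometry/statistics chain is correct, not that the
detector would reach the same recall on real micrographs.

Detection is multi-scale Laplacian-of-Gaussian: scale-normalized responses
$\sigma^2 \nabla^2 (G_\sigma * I)$ over a diameter band of ±40% around
10 nm, each scale normalized by the response of an analytically rendered
full-contrast disk so that `response_threshold` (default 0.3) reads as a
fraction of ideal contrast. Candidates are 3×3 local maxima, greedily
non-maximum-suppressed at one particle diameter, and localized to sub-pixel
precision by the response centre of mass — necessary because cluster
statistics operate at nanometre scale (localization RMSE is ~0.2 nm on
noiseless rasters, and detection recall and precision exceed 0.95 at the
default noise). The seeded mode snaps operator clicks to the nearest
response maximum within one diameter and merges duplicates; seeds in flat
regions are dropped with a notice.

## Quantification conventions

- **Densities** are count/area per profile, in particles/µm²; degenerate
  profiles (< 0.01 µm²) are excluded with an error.
- **Background correction** subtracts the E-face density from the P-face
  density, floored at zero and flagged when the floor binds, and is meant
  to be applied at the condition level (E-face measurements are sparse).
  Both raw and corrected densities are reported, since published densities
  of this kind do not state which convention they use.
- **Membrane classification** uses a perpendicular-distance threshold
  `d_mem_nm` to the membrane contour, default 25 nm (silver-enhanced
  particles sit within ~20–30 nm of the membrane; no threshold is stated in
  the source procedure). The classifier is monotone in the threshold, and a
  sensitivity sweep is a one-liner over `classify_membrane`.
- **Aggregation** is two-stage: profile → animal mean → group mean ± SEM
  *between animals*; the per-profile SEM is available only as a diagnostic.
  With a single animal the SEM is returned as `NA` with a flag rather than
  silently computed across profiles.

## Cluster statistics

Clusters are connected components of the graph joining particle pairs
within `link_distance_nm` (single linkage, union-find), with components
below `min_cluster_size = 3` reported as scattered. The linkage radius is
the decisive *unstated* parameter of this analysis — the source software
fixes only the minimum size — so the package defaults to 50 nm
(~3 particle diameters, chosen once so that particles within a visually
contiguous cluster link while separate clusters at typical
nearest-cluster distances of hundreds of nm do not) and stamps the value
into every report header. Cluster ids are assigned by centroid
lexicographic order, making outputs order-independent. Hull areas come from
the convex hull of member coordinates (shoelace area; collinear members
give 0), nearest-cluster distances are centroid-to-centroid, and
composition histograms are pooled over profiles whose areas must sum to the
configured 140 µm² reference area within 5%.

For cluster-count *recovery* experiments, `plant_clusters()` places an
exact number of centres by dart-throwing with a minimum separation of
$2 \times 3\sigma_r + \text{link} + 10$ nm and resamples each offspring set
until it is single-linkage-connected, which makes recovery exact at any
seed rather than probabilistically.

## Group statistics

Two-way ANOVA (genotype × compartment) runs on per-animal means; balanced
designs use the classical sequential decomposition (verified against
explicit sum-of-squares arithmetic to 1e-10), unbalanced designs fall back
to Type-II sums of squares — a robust default where the source analysis is
silent on how unequal cell counts were handled. Post hoc per-compartment
WT-vs-model comparisons are pooled-variance t tests on animal means with
Bonferroni adjustment $p_{\text{adj}} = \min(1, m\,p)$, $m$ defaulting to
the number of compartment-wise comparisons (11 for gradient tables), and
stars follow the * < 0.05, **** < 0.0001 convention. The choice of the
animal as the experimental unit is deliberate: published figure text of
this kind sometimes quotes n as profile counts, but SEM "between animals"
implies the animal-level analysis, and using profiles as units would
overstate degrees of freedom.

## Densitometry

Histoblot readout is the mean of inverted pixel values (dark-high
convention: density = 1 − pixel, i.e. 255 − pixel on 8-bit scans) over
0.10 mm circular cursors, corrected by the mean of exactly eight background
ROIs (strict count check by default). Western-blot lanes are quantified as
background-subtracted integrated band intensity normalized to a reference
band. Corrected densities are invariant to constant intensity offsets and
linear in stain darkness — the two properties that make between-membrane
comparisons meaningful. The synthetic blot generator (polygonal regions,
Gaussian transfer blur, additive noise) exists purely so this module is
testable stand-alone.

## Numerical and degenerate-input choices

- Coordinates are continuous nm (never pixel-snapped), origin top-left,
  y down; polygons are simple closed rings with shoelace areas; containment
  uses the nonzero winding rule with a 1 nm boundary band so edge particles
  are assigned rather than lost to floating-point jitter.
- Zero-intensity processes return empty (typed) particle tables; zero-area
  polygons, absent contours/active zones, one-level factors, and
  wrong-sized background ROI sets are errors, not warnings.
- All generators draw from R's RNG only; one seed fixes the entire
  simulate → detect → quantify chain bit-for-bit (`reproduce()` rewrites
  identical tables on reruns).

## Problem sizes in the shipped checks

The packaged recovery analyses use the study's own sample sizes where
printed — 16 oblique dendrites and 21 spines per genotype for the 6-month
densities, 140 µm² of pooled oblique-dendrite area for cluster
compositions — and otherwise sizes chosen to make the sampling error small
relative to the recovery band: 60 terminals (~300 AZ particles) for
presynaptic densities, ≥ 2000 pooled particles for membrane percentages,
100–400 replicate draws for unbiasedness and error-control properties.

## Known limitations

- The detector contract is statistical (recall/precision on calibrated
  scenes); the original detection software's operator is unpublished, so no
  claim of operator-level equivalence is made.
- Synthetic textures omit replica-specific structure (IMP granularity,
  shadowing direction); detector thresholds tuned here should be re-tuned
  on real material.
- The E-face background process is spatially homogeneous; real nonspecific
  labeling can be structured.
- Cluster linkage at 50 nm is a package default, not a published value;
  conclusions sensitive to it should sweep `link_distance_nm`.
- Mixed-effects alternatives to the animal-mean ANOVA (and the
  nonparametric tests some supplementary analyses use) are out of scope in
  this version.
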