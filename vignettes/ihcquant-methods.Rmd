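---
title: "Quantifying per-cell IHC expression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying per-cell IHC expression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcquant)
```

# The measurement problem

Chromogenic immunohistochemistry (IHC) stains a protein of interest with a
colored substrate — here AEC, red — on top of a hematoxylin nuclear
counterstain, blue. Visual scoring of such slides is notoriously
observer-dependent, yet gene-dosage biology guarantees graded signals worth
resolving: a cell with one functional allele typically carries half the
protein of a wildtype cell, and a knockout none beyond nonspecific
background. `ihcquant` implements a tissue-cytometry measurement chain that
resolves such two-fold differences per cell, per compartment:

1. **Optical density.** Brightfield chromogens obey Beer--Lambert:
   per channel, OD $= -\log_{10}(I/I_0)$ is linear in chromogen
   concentration. `rgb_to_od()` applies the transform with an
   $\varepsilon = 1/255$ floor against $\log 0$ and clamps negative
   densities (pixels brighter than the white reference) to zero.
2. **Stain unmixing.** Each pixel's OD vector is modelled as
   $\mathrm{OD} = M c$, where the columns of $M$ are unit-norm stain color
   vectors. `unmix()` solves the $3 \times 3$ system exactly and clamps
   negative concentrations to zero, reporting the clamped fraction. The
   default $M$ pairs the published Ruifrok--Johnston hematoxylin vector
   with an AEC vector $(0.27, 0.57, 0.78)$ (normalized); a residual third
   vector (normalized cross product) completes the basis. Both defaults
   are overridable via `complete_stain_matrix()`.
3. **Nuclear segmentation.** Hematoxylin is the *master marker*: every
   cell is detected through its nucleus. `detect_nuclei()` smooths the
   hematoxylin map (Gaussian, $\sigma =$ average nuclear size / 8),
   thresholds at the background threshold, fills holes, and splits
   touching nuclei by a marker-controlled watershed on the Euclidean
   distance transform, with h-maxima seed suppression at 10% of the
   maximum distance. Objects below the discrimination area or the
   discrimination gray (mean hematoxylin) are discarded. These four
   parameters — average nuclear size, discrimination area, discrimination
   gray, background threshold — are the standard knobs of commercial
   tissue cytometers; the watershed realization behind them is this
   package's choice, since the commercial algorithms are unpublished.
4. **Ring masks.** Cytoplasmic signal is sampled in a ring: pixels at
   Euclidean distance in (gap, gap + width] from the nucleus, default gap
   0 and width 3 px. Pixels reachable from several nuclei belong to the
   nearest nucleus; exact ties go to the lower cell id. Rings may be
   empty in crowded tissue; such cells carry `NA` (never 0) cytoplasmic
   values and are excluded, not imputed, from nuclear/cytoplasmic (N/C)
   ratios.
5. **Feature table and gating.** `measure_cells()` emits one row per
   cell: nuclear area, mean hematoxylin, mean antigen concentration in
   nucleus and ring, centroid. Gates are closed rectangular intervals in
   feature space (`gate()`, `apply_gate()`); boundary cells are included —
   the commercial convention is unspecified, so the inclusive choice is
   documented here. `forward_gate()` and `backward_gate()` map between
   scattergram and image for visual quality control. The hepatocyte gate
   defaults to an Otsu split of log nuclear area, exploiting the two
   nuclear-size populations (large parenchymal vs small stromal nuclei).

Intensities throughout are unmixed stain concentrations in OD units. The
arbitrary units of commercial tools cannot be mapped onto OD, so every
downstream comparison in this package is deliberately unit-invariant:
ratios, percentages, ordinal scores, agreement statistics.

# Dosage and translocation statistics

**Knockout-anchored background.** The knockout group defines what
"negative" looks like: `background_cutoff()` takes the null group's
per-cell intensities and returns, by default, their empirical 0.99
quantile (R's linear-interpolation convention), or alternatively
mean + 2 sd. The method and level always accompany the value in reports,
because the anchoring convention is a free choice the original
tissue-cytometry literature leaves unstated.

**2:1:0 recovery.** `dosage_ratios()` subtracts the null-group mean from
each genotype's mean and rescales so the wildtype sits at 2 — the
anchoring that matches the expected 2:1:0 phrasing for di-allelic,
mono-allelic and null genotypes (rather than wildtype = 1). The
hemizygote's recovered level is the estimate of interest; its deviation
from 1 measures pipeline bias.

**Translocation.** `nc_ratio()` computes per-cell nuclear/cytoplasmic
mean-intensity ratios and their group mean ± SD. On stimulation a
transcription factor moves to the nucleus, so the N/C ratio rises while
the cytoplasmic compartment loses intensity. Group inference uses
Student's t (pooled variance, two-sided) or one-way ANOVA via
`compare_groups()`; p-values are reported and never feed back into
estimates. No multiple-testing correction is applied: the experiments are
single planned comparisons.

**Cross-assay normalization.** `normalize_to_100()` rescales any
arbitrary-unit assay so its maximum is exactly 100, the convention for
comparing image-based and densitometric quantification on one axis.

# Scoring and inter-rater agreement

Nuclear mean intensities convert into a four-level score (0 none … 3
strong) through three strictly increasing zone boundaries
(`score_matrix()`), left-closed by this package's convention. Default
boundaries come from a calibration sample — quartiles, or fixed fractions
of the observed range — and are always echoed in output, since published
scoring matrices rarely print their numeric boundaries.

Agreement between two raters is summarized by exact percent agreement and
by Cohen's kappa with linear weights $w_{ij} = 1 - |i - j|/(k-1)$:
$\kappa = (P_o - P_e)/(1 - P_e)$ with $P_o = \sum w_{ij} p_{ij}$ observed
and $P_e$ from the marginal products. Two constant, identical raters give
$P_o = P_e = 1$; the package returns 1 by convention and says so. Kappa
magnitudes are labelled with the Landis--Koch bands (slight ≤ 0.20 < fair
≤ 0.40 < moderate ≤ 0.60 < substantial ≤ 0.80 < almost perfect).
`three_way_overlap()` adds the percentage of cases where two raters and
the software all agree.

# The virtual-slide simulator

Real mouse-liver and human-tumor slides behind this class of experiment
are not publicly available, so validation runs on `simulate_slide()`,
a forward model that is the exact inverse of the measurement chain and
carries full per-cell ground truth.

What it emulates, and the defaults that define the study conditions:

* **Genotype dosage 2:1:0** (`dosage_level`), with a nonzero nonspecific
  antigen background (`background_od = 0.05`) present in every genotype.
* **Two nuclear-size populations**: parenchymal nuclei of radius
  $7 \pm 1$ px and stromal nuclei $3.5 \pm 0.5$ px, with
  `stromal_fraction = 0.15` — the middle of the 10–20% stromal
  contamination range typical of these tissues. Stromal cells carry a
  fixed antigen level of 1.0 relative units regardless of genotype, so
  knockout slides retain positive stroma (Kupffer/endothelial cells); the
  absolute stromal level relative to wildtype parenchyma is a free
  parameter no measurement pins down.
* **Cell-to-cell heterogeneity**: a log-normal multiplier with mean 1 and
  `heterogeneity_cv = 0.3`, emulating cell-cycle-driven expression
  variability; the distribution family is the package's choice.
* **Translocation**: `nuclear_fraction` splits each cell's antigen
  between nucleus and a concentric 6 px cytoplasmic annulus; mock (0.4)
  and stimulated (0.8) conditions differ only here.
* **Imaging noise**: additive Gaussian intensity noise
  (`noise_sd = 2` of 255) after the transmittance transform, then 8-bit
  quantization. One relative antigen unit renders as 0.3 OD of AEC
  (`od_per_unit`); the constant cancels in every compared quantity.

What it does **not** emulate: irregular nuclear morphology (nuclei are
circles — sufficient because all measurement operates on segmented masks,
not shape), tissue texture, uneven illumination, out-of-focus blur,
section thickness or staining-run variation. Passing tests therefore
demonstrate correctness of the measurement chain and statistics under a
controlled forward model, not robustness to every artifact of real
slides.

Placement uses bounded rejection sampling (nuclei may not overlap; center
distance must exceed the radius sum + 1 px) and fails with an explicit
density error rather than degrading. Coordinates are 0-based, row-major.
All randomness flows from one integer seed; identical (parameters, seed)
give bit-identical images and tables.

# Experiments, problem sizes and numerical choices

`run_dosage_experiment()` simulates wildtype/hemizygous/knockout slides
(default 3 replicates of ~300 cells on 512 × 512 px), runs the full
chain with hepatocyte gating, and reports background-subtracted relative
levels, a knockout-anchored cutoff and a one-way ANOVA.
`run_translocation_experiment()` contrasts mock and stimulated nuclear
fractions with matched knockout slides anchoring the positivity cutoffs.
`run_scoring_experiment()` builds a 22-case series (one compact slide per
case, expression scaled to the true score), scores it through the
intensity pipeline, and adds two simulated raters with a symmetric
ordinal confusion model (miscall probabilities 0.3 and 0.2; a miscall
moves one level, reflected at the scale ends) — a stated stand-in for
human raters, configurable. The bundled validation runs use these sizes;
they give Monte-Carlo error comfortably below the effects being measured
(≈1% standard error on a group mean at 900 gated cells with cv 0.3).

Numerical conventions collected in one place: quantiles are R type 7
(linear interpolation); Otsu's threshold for the hepatocyte gate is
computed on a 256-bin histogram of log nuclear area; watershed seeds are
suppressed below 10% of the maximum distance-transform value; gate
intervals and score zones are closed on the left; ties in ring-pixel
ownership resolve to the lower cell id; degenerate inputs (empty images,
empty null groups, all-zero normalization input, wildtype mean at or
below background) raise errors rather than returning silent defaults.

# Known limitations

* Stain vectors are fixed defaults; estimating them from the slide
  (Macenko-style) is out of scope, as is batch normalization across
  staining runs.
* The rater noise model is symmetric and memoryless; real pathologists
  show structured, prevalence-dependent disagreement.
* Ring masks assume the perinuclear annulus samples "cytoplasm"; in
  crowded tissue the ring of one cell may graze a neighbor's territory,
  mitigated but not eliminated by nearest-nucleus assignment.
* Whole-slide (pyramidal) formats and ROI polygons are not supported;
  regions of interest enter as logical masks over centroids
  (`filter_roi()`).
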