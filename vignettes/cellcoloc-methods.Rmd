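---
title: "Quantifying membrane-protein mislocalization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-protein mislocalization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cellcoloc` measures, per cell, how strongly a fluorescently tagged
membrane protein colocalizes with a plasma-membrane (PM) or endoplasmic
reticulum (ER) marker, and tests whether mutant genotypes differ from the
wild type. This vignette records the models, the parameters that matter,
and the design decisions taken where the method description left choices
open.

## The measurement model

Each field of view carries three channels: the tagged protein, one
co-marker (a WGA-style PM stain or a calreticulin-style ER stain) and
nuclei. The analysis unit is one segmented cell; its statistic is the
Pearson correlation between the protein and co-marker intensities over the
cell's pixel set. Pearson r is insensitive to channel gain and offset
(positive affine transforms), which is the property that makes it
comparable across images acquired under constant settings — the pipeline
assumes those settings are constant and performs no normalization or
background subtraction before correlating (an optional constant-background
subtraction exists but is off by default, since the upstream protocol
described none).

Correlation is undefined when a channel is constant inside a cell; such
cells are dropped and counted in the run log rather than imputed.

### Segmentation

Cells are delineated on the protein channel only (transfected cells are the
bright objects there):

1. **Median filter**, circular neighbourhood of radius 4 px. The radius
   phrasing of the upstream protocol implies a disc, not a box, so the
   kernel is `dx² + dy² ≤ r²`, truncated at image borders. Implemented in
   C++; even-sized neighbourhoods take the mean of the two central order
   statistics.
2. **Huang fuzzy-entropy threshold** on a 256-bin min–max-scaled histogram
   of the *filtered* image. For each candidate bin edge t the below/above
   classes get means μ₀, μ₁; the membership of grey level g is
   μ(g) = 1/(1 + |g − μ_class|/C) with C the occupied grey-level range, and
   the chosen t minimizes Σ h(g)·[−μ ln μ − (1−μ) ln(1−μ)]. Ties break
   toward the lowest t. Constant images have no threshold and raise an
   error. The protocol text reads as thresholding the filtered image; we
   follow that reading (flagged as an interpretation, not a guess beyond
   it).
3. **8-connected components** with particle-size filtering. Components
   outside `[min_area, max_area]` are dropped; survivors are relabelled
   from 1 in raster order of their top-left pixel, so labels are
   deterministic.

`min_area` defaults to 800 px²: roughly one third of the smallest cell the
synthetic generator renders, so noise fragments are removed while genuine
cells never are. This is configurable because the upstream particle-size
bounds were never stated. Cells touching the image border are kept by
default (`border_policy = "keep"`) — the protocol is silent, so the flag is
recorded per cell and analyses can exclude them instead.

Interactive ROI correction is replaced by a file-based override:
`apply_mask_override()` swaps in a curated label image wholesale, re-applies
the size filters, and marks provenance `"override"` per cell.

### Group inference

Per-cell r values are grouped by genotype and co-marker. Group spreads
differ strongly between membrane-dominant and ER-retained phenotypes, so
the omnibus test is Welch's heteroscedastic ANOVA,

$$F = \frac{\sum_i w_i(\bar x_i - \bar x_w)^2/(k-1)}
          {1 + \frac{2(k-2)}{k^2-1}\Lambda},\qquad
  w_i = n_i/s_i^2,\;
  \Lambda = \sum_i \frac{(1-w_i/W)^2}{n_i-1},$$

with df₂ = (k²−1)/(3Λ). Pairwise comparisons against the wild type use
Games–Howell: Welch–Satterthwaite degrees of freedom per pair and
q = √2·t referred to the studentized range distribution with the **full**
group count k. Using the full k (rather than k = 2 per pair) makes the
correction familywise over the whole panel of plotted comparisons; at
k = 2 the procedure reduces exactly to the two-sided Welch t-test, which is
one of the test suite's invariants. Inference is two-sided throughout, and
significance stars follow the 0.05/0.01/0.001 convention.

Two analysis-unit conventions circulate for this kind of experiment:
per-cell values or per-image means. The per-cell convention is the default
here because the experiment's distributions are plotted per cell and the
stated minimum ("30 cells per genotype", enforced by `min_cells = 30`)
is a cell count; `summarize_groups()` on image-aggregated records supports
the other reading if wanted. Image-level clustering is not modelled — a
known limitation, noted below.

Descriptive summaries report median and quartiles (type-7 linear
interpolation; no convention was stated upstream, so R's default order
statistic rule is used) plus mean, SD and range.

## The synthetic scene generator

Ground-truthed scenes stand in for raw microscopy, which is not
redistributable. Each cell is an ellipse (semi-major axis 34–48 px,
axis ratio bounded at 0.7 to cap eccentricity) placed by rejection sampling
with overlaps forbidden outright; the protein channel per cell is

α · ring + (1 − α) · ER texture, scaled by `protein_amplitude`, plus background,

where the ring is the difference of two concentric ellipses
(`membrane_ring_width` = 3 px) and the ER texture is band-pass-filtered
seeded Gaussian noise (scale 4 px) over a 0.35 pedestal, masked to the
interior. The pedestal makes transfected cells contiguous objects on the
protein channel — as real diffuse reticular fluorescence does — which is
what lets a single intensity threshold delineate whole cells at wild-type
mixtures. The co-marker channel renders the *same* template instance
(ring for PM, texture for ER), so the α ∈ {0, 1} noise-free limits give
per-cell r exactly 1 — an exact oracle the tests rely on. All channels are
blurred with a Gaussian PSF (σ = 1 px) and degraded with scaled-Poisson
(gain 0.25) plus additive Gaussian (SD 2) noise; intensities are clamped at
zero.

Defaults mirror the emulated study design: 2 cells per field, 20 fields per
genotype and co-marker (≈ 40 cells per genotype, comfortably above the
30-cell gate), wild-type-like α = 0.8, ER-retained mutant-like α = 0.1, one
global intensity scale for 16-bit export (constant acquisition settings).
`pixel_size` (0.16 µm/px) is carried as metadata only and never enters any
computation.

What the generator does **not** emulate: touching or overlapping cells
(delegated to mask overrides), 3-D structure, photobleaching, chromatic
shift, channel crosstalk (the emulated acquisition avoided it by serial
scanning), untransfected cells, and cell-to-cell biological variability in
α (all cells of a genotype share one mixture). Passing tests therefore
demonstrate that the pipeline recovers known mixtures under realistic noise
— not that it handles densely packed or heterogeneous real samples, where
the override path and per-cell provenance flags exist precisely because
automation is insufficient.

## Cohort module conventions

- **Rarity filter**: MAF ≤ 1% *inclusive*, per available database; a
  variant absent from all databases passes (absence is evidence of rarity,
  and annotated panels routinely show "–" for retained variants). Calls in
  segmental duplications, repeats or homopolymer runs are excluded as
  likely false positives via the `in_excluded_region` flag.
- **Classification** is HGVS-string-driven only (no genome or transcript
  model): stop-containing protein consequences → `ptc`; del/dup/ins →
  `indel`; intronic offsets beyond ±2 → `splice` (±1/2 are canonical-site
  hits, grouped with `ptc`); remaining substitutions with a protein change
  → `missense`.
- **Percentages** are reported half-up at two decimals (one decimal for
  cohort-level fractions quoted that way); the exact ratio is always kept
  alongside, and rounding is applied only at reporting.
- **Contingency testing** defaults to the two-sided Fisher exact test
  (minimum-likelihood rule, implemented as the hypergeometric sum and
  verified against `stats::fisher.test` exhaustively on small tables), with
  the sample odds ratio ad/bc and a Woolf logit CI; zero cells trigger the
  flagged Haldane–Anscombe 0.5 correction for the OR/CI only. The source
  study did not name its test, so the package reports Fisher's p rather
  than asserting agreement with any published p-value.
- The individual-level roster behind the published tallies is not public;
  `synthetic_belgian_roster()` constructs a synthetic roster whose
  aggregate counts (mutation observations per class, carrier counts,
  compound-carrier counts per cohort) match the printed values, and is
  labelled synthetic everywhere.

## Numerical choices and degenerate inputs

- Huang scan is O(bins²) vectorized; ties toward the lowest threshold make
  it deterministic. Binarization is `≥ t` with t returned as a bin edge on
  the original intensity scale, so a two-valued image thresholds exactly
  between its values.
- Welch ANOVA refuses zero within-group variance (naming the group) and
  groups of size < 2; F = 0 and p = 1 fall out naturally for identical
  means.
- Randomization testing (optional, off by default) permutes co-marker
  blocks inside the ROI bounding box and uses add-one smoothing,
  p = (1 + #{r* ≥ r})/(1 + n); its null calibration is a test-suite
  property.
- All stochastic stages consume an explicit seed; scene generation
  snapshots and restores the caller's RNG state. Per-image seeds derive
  arithmetically from (base seed, genotype index, image index) modulo
  2³¹−1.
- Test and acceptance problem sizes — 11–15 genotypes × 20 fields × 2
  cells at 256² px, 2000-replicate null calibrations, exhaustive Fisher
  verification to n = 30 with sampled coverage to n = 200 — were chosen as
  the smallest designs that still exercise every gate of the emulated
  study (≥ 30 cells per genotype, familywise error resolution of ±1% at
  the 5% level).

## Known limitations

- Image-level clustering of cells is ignored by design (cells are treated
  as independent observations); a mixed model would be the extension.
- Only Pearson colocalization is implemented — no Manders/Costes
  coefficients, no object-based methods.
- Segmentation does not split touching cells (no watershed, no
  nuclei-seeded growth); curated overrides are the intended remedy.
- The Huang threshold is global per image; strong illumination gradients
  would need flat-fielding upstream.
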