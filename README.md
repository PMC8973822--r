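# cellcoloc

Missense mutations in membrane transporters often act not by abolishing
catalysis but by derailing trafficking: the mutant protein fails to reach
the plasma membrane (PM) and is retained in the endoplasmic reticulum (ER).
`cellcoloc` quantifies this phenotype from multi-channel fluorescence
microscopy and ties it to rare-variant cohort statistics. It is aimed at
cell biologists and neurogenetics groups who score subcellular localization
of tagged constructs (e.g. EmGFP fusions of an ABC transporter in HeLa
cells, co-stained with WGA for the PM or calreticulin for the ER) across
many genotypes, and who report carrier frequencies of the same variants in
patient/control cohorts.

## What it computes

**Per-cell colocalization.** Cells are delineated on the protein channel by
a circular median filter (radius 4 px), Huang fuzzy-entropy auto-thresholding
and particle-size filtering; each cell's colocalization with the co-marker
channel is the Pearson correlation over its pixels,

r = Σ(aᵢ−ā)(bᵢ−b̄) / √( Σ(aᵢ−ā)² · Σ(bᵢ−b̄)² ),

computed over exactly the ROI pixels, with no intensity sub-thresholding.
The Huang threshold minimizes the fuzziness S(t) = Σ_g h(g)·H(μ_t(g)) with
membership μ_t(g) = 1/(1 + |g − μ_class(t)|/C) and H the binary Shannon
entropy.

**Group inference.** Genotypes are compared per co-marker with Welch's
heteroscedastic one-way ANOVA (weights wᵢ = nᵢ/sᵢ²) and Games–Howell
post-hoc comparisons against the wild type: t = |x̄ᵢ−x̄ⱼ|/√(sᵢ²/nᵢ+sⱼ²/nⱼ)
with Welch–Satterthwaite degrees of freedom, referred as q = √2·t to the
studentized range distribution with the full group count.

**Synthetic ground truth.** A seeded scene generator renders HeLa-like
cells whose protein channel is an α-mixture of a membrane ring and a
reticular ER texture (α = membrane fraction; wild-type-like α = 0.8,
ER-retained mutant-like α = 0.1), plus Gaussian PSF blur and
Poisson–Gaussian noise — so the whole pipeline is testable end-to-end with
known truth and exact limiting cases (α = 1 ⇒ per-cell r with the PM marker
is exactly 1 in the noise-free limit).

**Cohort arithmetic.** MAF-based rarity filtering (≤ 1%, inclusive; missing
database frequencies pass), HGVS-driven variant classification
(missense / indel / splice / PTC), carrier frequencies reported half-up to
two decimals, Fisher exact 2×2 tests with Woolf confidence intervals, and
compound (multi-variant) carrier counts.

## Worked example

Simulate a wild type against one ER-retained mutant, segment, measure and
test (≈ 30 s):

```r
library(cellcoloc)
config <- run_config(
  genotype_alphas     = c(WT = 0.8, p.G1820S = 0.1),
  images_per_genotype = 16,
  comarkers           = "PM",
  base_seed           = 42)
report <- run_imaging_pipeline(config)
print(report)
print(report$summaries, digits = 3)
```

```
<run_report> 32 scenes, 64 cells segmented, 64 measured (0 dropped); fingerprint 0820573f
== Co-marker PM ==
Welch heteroscedastic one-way ANOVA
  F = 12947.5154 on 1 and 31.09 df, p = 2.6e-42 (k = 2 groups)
  Games-Howell vs WT:
    p.G1820S     diff = -1.5161  p_adj = 7.971e-14 ***

  genotype_label comarker  n   mean      sd median     q1     q3    min    max
1       p.G1820S       PM 32 -0.544 0.07532 -0.558 -0.601 -0.503 -0.654 -0.369
2             WT       PM 32  0.972 0.00287  0.971  0.970  0.974  0.967  0.976
```

Wild-type cells correlate almost perfectly with the PM marker (median
r ≈ 0.97) while the mutant's correlation collapses (median r ≈ −0.56,
because its signal sits in the ring-free interior); the Games–Howell
comparison against WT is significant at p < 0.001 (`***`). The same run
with `comarkers = "ER"` shows the mirror image: the mutant gains ER
colocalization.

Cohort side:

```r
print(carrier_frequency(115, 1376))   # 8.36% (115/1376)
fix <- synthetic_belgian_roster()
tally_carriers(fix$roster, fix$variants, fix$cohort_sizes)
```

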