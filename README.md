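# srnaspike

Absolute normalization of small RNA sequencing data with spike-in
oligonucleotides.

Small RNA-Seq reports abundances in relative units — reads per million
genome-matching reads (RPM) — which cannot be compared across tissues
whose sRNA populations differ in composition. `srnaspike` implements, end
to end, a spike-in based absolute normalization scheme for plant-style
sRNA-Seq:

* **Spike-in design.** Each spike-in *set* is a semi-random 13 nt core —
  composition-matched to positions 5–17 of abundant miRNAs, excluded
  from the target genome on both strands — flanked by all 256 possible
  4-mers on each end: 4⁸ = 65,536 distinct 21-mers per set, identified
  in sequencing data by the core tag. Candidate sets are ranked by the
  Kolmogorov–Smirnov distance between their members' RNA secondary
  structure minimum-free-energy (MFE) distribution and that of
  endogenous miRNAs (ViennaRNA `RNAfold` at 4 °C, or a self-contained
  Nussinov-style backend), and the mix is formulated as a log10-spaced
  dilution series spanning the endogenous dynamic range.
* **Quantification.** Exact 3′-adapter trimming (18–30 nt inserts), read
  collapsing, perfect-match alignment on both strands with a 100-locus
  ceiling and `count / n_hits` weight sharing, spike-in counting by core
  tag, class assignment (20–22 nt miRNA/tasiRNA within ±2 nt of mature
  annotations; 20–22 and 23–24 nt transposon siRNAs), and family /
  precursor aggregation.
* **Normalization.** Per-set spike-in RPM against known molecules per µg
  total RNA (MPU) fits a log–log standard curve
  (`log10(MPU) = a·log10(RPM) + b`, Pearson r and p reported); family
  RPMs convert through it to MPU. ERCC spike-ins do the same for
  mRNA-Seq TPMs (transcripts below TPM 1.0 stay undefined), enabling
  sRNA:precursor and sRNA:target stoichiometries across platforms.
* **Comparison statistics.** Pooled-variance two-sample t and two-sample
  KS tests, ≥2-fold & p < 0.05 differential calls, ≥1 RPM expression
  filtering, stoichiometry medians.
* **Synthetic truth.** A generator for genomes with planted miRNA /
  tasiRNA / transposon loci, libraries with per-21-mer lognormal cloning
  bias, and ERCC-like tables — every downstream estimate is validated
  against known ground truth.

## Worked example

A fully synthetic end-to-end run (design-style mix, 100 kb genome with
planted loci, 200,000 reads, lognormal cloning bias):

```r
library(srnaspike)
res <- run_pipeline(list(seed = 1L), out_dir = "spikerun")
res$norm$curve
#> Spike-in standard curve (srna_rpm, log10 scale)
#>   log10(MPU) = 1.0108 * log10(relative) + 3.0397
#>   n = 8 points, Pearson r = 0.9938, p = 5.81e-07
head(res$norm$families[res$norm$families$sclass == "miRNA", ], 4)
#>   family_id sclass count        rpm      mpu
#> 1    miR101  miRNA   160   890.1896  1049670
#> 2    miR102  miRNA   477  2653.8776  3166467
#> 3    miR103  miRNA  5760 32046.8240 39279336
#> 4    miR104  miRNA  7536 41927.9280 51539852
res$stoich_precursor$median_ratio
#> [1] 1.766941
```

The curve is the heart of the method: the 8 calibration points (one per
spike-in set, spanning 4 decades of input molarity) line up with Pearson
r ≈ 0.99 despite every individual 21-mer carrying a 2-fold-scale random
ligation bias, because each set's count averages 65,536 member
sequences. `mpu` is each family's absolute abundance in molecules per µg
total RNA obtained through that curve; the stoichiometry median says
mature miRNAs outnumber their precursor transcripts ~1.8-fold in this
simulation, the kind of cross-platform ratio that relative units cannot
provide. A thin CLI wrapper is installed as `exec/srnaspike`
(subcommands `run`, `simulate`, `design`).

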