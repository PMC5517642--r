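---
title: "Absolute normalization of sRNA-Seq data with spike-in oligonucleotides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute normalization of sRNA-Seq data with spike-in oligonucleotides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaspike)
```

## The problem

Small RNA sequencing reports *relative* abundances — reads per million
genome-matching reads (RPM). Comparisons of RPM values across tissues are
only valid when the underlying small RNA populations have similar
composition, which is routinely violated in plants: the share of 20–22 nt
reads can nearly double between tissues simply because 23–24 nt siRNA
pools shrink. Exogenous spike-in oligonucleotides added at known molarity
to total RNA before library construction let each library be re-expressed
on an *absolute* scale, molecules detected per µg of total RNA (MPU), so
that levels can be compared across tissues, genotypes and even platforms
(sRNA-Seq versus mRNA-Seq).

The catch is that a single synthetic oligo has idiosyncratic ligation
efficiency, driven largely by its secondary structure, so single-sequence
spike-ins historically required per-oligo correction factors. The design
implemented here avoids that: each spike-in *set* is a 13 nt core
sequence, absent from the target genome, flanked on both ends by all 256
possible 4-mers. One set is therefore 4^8 = 65,536 distinct 21-mers
sharing one 13 nt identification tag, and the set-level read count
averages over 65,536 independent ligation efficiencies.

## The design algorithm

`design_spikeins()` implements the full pipeline:

1. **Composition matching.** A 4×13 base-frequency matrix is tallied at
   positions 5–17 (from the 5′ end) of the most abundant half of the
   supplied mature miRNAs (`build_frequency_matrix()`, `top_fraction =
   0.5`). Abundance ranks the miRNAs; the tally itself is unweighted.
2. **Core sampling.** `sample_cores()` draws each of the 13 positions
   independently from the matrix columns (1000 candidates by default),
   resampling duplicates so cores are distinct.
3. **Genome exclusion.** `filter_genome_matching()` removes every core
   with a perfect match in the genome. Both strands are checked: reads
   are cloned from either orientation downstream, so a one-strand check
   would leave an ambiguity the 13 nt tag is supposed to rule out.
4. **Structure matching.** Each surviving candidate is expanded
   (`expand_set()`) and the minimum free energy (MFE) of a seeded random
   subsample of members (2000 by default; full enumeration available) is
   compared to the MFE distribution of the endogenous miRNAs themselves.
   Candidates are ranked by the two-sample Kolmogorov–Smirnov statistic
   — the paper-scale procedure examined the distributions visually, so a
   formal, order-invariant criterion had to be chosen; minimum KS *D*
   with a lexicographic tie-break makes the selection deterministic and
   permutation-invariant. Folding uses ViennaRNA's `RNAfold -T 4 --noPS`
   when the external backend is selected; the self-contained default is a
   Nussinov-style dynamic program with pair energies −1.0 (GC), −0.8
   (AU), −0.5 (GU) kcal/mol, a 3 nt minimum hairpin loop, and 0 for the
   pairless optimum. The simplified model ranks hairpin-prone sequences
   essentially like the nearest-neighbour model at 21 nt scale, which is
   all distribution matching needs; its absolute energies are not
   thermodynamic.
5. **Distinctness.** Selected cores must be pairwise Hamming ≥ 4 (and,
   being equal length, never substrings of one another), keeping tag
   counting unambiguous even with a sequencing error or two.
6. **Mix formulation.** `formulate_mix()` assigns molecules-per-µg
   amounts log10-equispaced from a user-chosen maximum across a chosen
   dynamic range (default 4 decades), one amount per set, so the dilution
   series brackets the endogenous abundances it will calibrate.

## The quantification pipeline

`process_library()` reproduces the published read processing:

* **Trimming** (`trim_adapter()`): the insert left of the leftmost exact
  3′-adapter occurrence, or of a terminal adapter prefix of ≥ 8 nt;
  inserts outside 18–30 nt are discarded. The original in-house trimmer's
  mismatch policy is not documented, so exact matching was chosen for
  reproducibility.
* **Collapsing** (`collapse_reads()`): identical inserts become one
  record with a count; quality strings play no further role because
  alignment is perfect-match only.
* **Alignment** (`align_perfect()`): every perfect-match locus on both
  strands of the reference; reads with more than 100 loci are discarded
  entirely (the bowtie `-v 0 -m 100` semantics), and each retained hit
  carries weight `count / n_hits`, so multi-mapping reads contribute one
  read's worth of mass in total.
* **Spike-in counting** (`count_spikein_tags()`): a read belongs to a set
  iff it contains that set's 13 nt core; reads containing two cores are
  discarded with a warning. Spike-in reads are routed to per-set
  pseudo-chromosomes rather than materializing 524,288 member reference
  sequences — with genome-excluded cores the two are equivalent, and a
  read that carries a core *and* matches the genome (impossible unless
  the sheet is corrupt) is discarded loudly.
* **Class assignment** (`assign_mature()`, `assign_sirna()`): 20–22 nt
  reads on the sense strand contained within a mature miRNA/tasiRNA
  interval padded by 2 nt on each side count toward that feature. The
  published "within ±2 nt" phrasing is ambiguous between end-offset and
  containment semantics; padded containment was chosen and is enforced at
  the boundary (shift of 2 accepted, 3 rejected) in the tests. 20–24 nt
  reads overlapping a transposon by ≥ 1 nt on either strand are siRNAs,
  binned 20–22 / 23–24; a read overlapping *k* transposons contributes
  `weight / k` to each (the source procedure does not specify; equal
  splitting conserves mass). Reads satisfying both rules are counted in
  both classes and the doubly-assigned weight is reported, not resolved.
* **Aggregation** (`aggregate_families()`, `per_precursor_counts()`):
  family values are sums over members (miR169a/b/c → miR169); precursor
  values are sums over their annotated mature products.

## Standard curves and MPU conversion

`standard_curve()` fits least squares of log10(known MPU) on
log10(relative abundance). The log–log scale is the default because the
calibration series spans decades; a linear-scale fit would be dominated
by the largest point (`scale = "linear"` is available for a literal
reading of the plotted relationship). Pearson's *r* of the calibration
points and its two-sided p-value (t approximation) are reported.
Calibration sets with zero reads carry no information about the fit and
are dropped with a warning, not imputed. `to_mpu()` applies the fitted
power law; a relative abundance of exactly 0 maps to 0 MPU by convention.
`mrna_to_mpu()` does the same for mRNA-Seq using ERCC spike-ins, and only
converts transcripts with TPM ≥ 1.0 — below that floor the estimate is
left undefined rather than extrapolated.

Comparisons (`call_differential()`: ≥ 2-fold difference of replicate
means *and* pooled-variance t-test p < 0.05; `ks_two_sample()` for
population-level shifts; `filter_expressed()`: ≥ 1 RPM in every
replicate, inclusive) and stoichiometry summaries (`stoichiometry()`:
per-pair mature/partner MPU ratios with group medians) follow the
published analysis choices; no multiple-testing correction is applied by
default, with Benjamini–Hochberg available as an option.

## What the synthetic data emulate — and what they do not

`make_genome()` plants unique 21 nt mature miRNA sequences (each
occurring exactly once genome-wide), phased tasiRNA loci (4 fixed 21 nt
registers — schematic, sufficient for coordinate rules, not for phasing
biology) and transposon intervals in a 100 kb random background, and
records every true molecule amount. `simulate_library()` draws reads
multinomially with probability proportional to molecules; mature
features get a small fixed isomiR offset profile (80% exact, ±1 nt 7%
each, ±2 nt 3% each) so the containment rule is exercised.

The cloning-bias model is the load-bearing choice. Each spike-in member
21-mer receives an independent lognormal ligation efficiency with
sd(log2) = 1 and **unit mean** (meanlog = −sdlog²/2). Unit mean makes
"efficiency" a relative quantity — the expected library composition
equals the molecule shares — which is what lets set-level averaging over
65,536 members be tested cleanly: the set total's relative spread shrinks
by a factor ≈ 256 relative to a single-sequence spike-in of equal
molarity. Endogenous reads are simulated without per-sequence bias; in
real libraries endogenous sRNAs have biases too, so real MPU estimates
inherit an irreducible per-sequence uncertainty the simulation does not
model. Passing recovery tests therefore demonstrates correctness of the
counting and calibration machinery, not that real single-feature MPUs
are accurate to 20%.

Fixture scale: the default validation fixture uses depth 2×10⁵ reads, 8
sets over 4 decades, and a spike-in share of ~10% of alignable reads.
Production libraries need only 1–2% of reads for the spike-ins because
they are sequenced 100× deeper; at desk-scale depth the quantity that
must be preserved is reads per calibration point (the dilution series
bottoms out near single reads even at 10%), not the percentage.
`library_stats()` reports the realized share for any library.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; GFF3 (1-based
  inclusive) is converted at the I/O boundary only.
* Sequences are stored as given (U or T) and canonicalized U→T inside
  every comparison.
* KS p-values use the asymptotic Kolmogorov distribution, with the
  theta-series form below λ = 1 for numerical stability; exact small-n
  p-values are not attempted.
* The pooled t statistic of two zero-variance samples is defined as 0
  (p = 1) when the means agree and ±∞ (p = 0) otherwise.
* Ties in candidate ranking are broken by core lexicographic order;
  ties in alignment output are avoided by sorting on (chrom, start,
  read sequence), making every pipeline output byte-reproducible from
  (inputs, parameters, seed).
* `sample_cores()` fails after a bounded number of resampling rounds on
  matrices too degenerate to yield the requested number of distinct
  cores; an empty genome passes all cores (vacuous exclusion).

## Worked example

```{r example, eval = FALSE}
res <- run_pipeline(list(seed = 1L), out_dir = tempfile("spikerun"))
res$norm$curve          # sRNA spike-in standard curve (slope, r, p)
head(res$norm$families) # per-family RPM and MPU
res$stoich_precursor$median_ratio  # median mature/precursor MPU ratio
```

## Known limitations

* The internal MFE backend is a base-pair-counting model; for synthesis
  decisions use the `external_rnafold` backend.
* Alignment is strictly perfect-match, as in the source pipeline;
  sequencing errors cost reads rather than producing mismatched hits.
* Degradome-derived target pairs are consumed, never inferred.
* The simulator draws fresh bias factors per library; correlated biases
  across libraries from a shared protocol are not modelled.
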