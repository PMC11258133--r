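---
title: "Methods: telomere motif discovery, k-mer genome profiling and assembly QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: telomere motif discovery, k-mer genome profiling and assembly QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

teloscope implements three connected analyses for draft plant genome
projects: discovery of the telomeric repeat unit directly from raw short
reads, estimation of genome size and heterozygosity from a k-mer
multiplicity spectrum, and assembly-level quality summaries (contig
statistics, contig-end telomere scans, binned density tracks, a
repeat-versus-depth comparison, structural-variant spectra and Circos
exports). A synthetic diploid genome simulator with fully recorded ground
truth makes every stage testable without any external sequencing data.
This vignette explains the models and the choices behind them.

## Telomere motif discovery from reads

Telomeric repeats form long tandem arrays at chromosome termini, so a
short read sampled from a telomere is an uninterrupted run of one short
unit. The discovery procedure exploits exactly this property:

1. **Subsample** a fixed number of reads (default 20 million) uniformly
   without replacement, preserving input order. Uniform sampling is used
   rather than taking the first N records, because the leading records of
   a sequencing run are not an unbiased sample of the flowcell; a
   `first_n` compatibility flag covers the alternative reading.
2. **Trim** each read to a fixed interior window: discard the first 10 bp
   and the last 81 bp of a 151-bp read, keeping a 60-bp window
   (10 + 60 + 81 = 151). The leading cut avoids start-of-read artefacts;
   the short window makes the full-periodicity requirement below sharp.
   Reads shorter than 70 bp are skipped and counted, never truncated.
3. **Detect tandem units**: a window qualifies when its smallest period
   `u` — scanned from 1 upward — lies in 6–10 bp, the unit is primitive,
   and the window holds at least 4 complete copies. Scanning periods from
   1 means homopolymer and dinucleotide windows are rejected outright
   rather than reported at an inflated multiple of their true period. By
   default zero mismatches are allowed (the array must be sequential and
   continuous); a mismatch allowance is exposed for noisier data, and `N`
   bases violate every period. The 6–10 bp range spans all eight known
   telomere units screened (6-mers TTAGGG/TTCAGG up to the 10-mer
   TTTTTTAGGG) while excluding simple microsatellites.
4. **Canonicalise**: units recovered from reads are arbitrary rotations
   of either strand. Each unit is mapped to a display form — the G-rich
   strand rotated so its longest G-run is terminal (ties: longest leading
   T-run, then lexicographic) — and to a strand/rotation-invariant
   canonical key (minimal rotation over both strands) used for exact
   matching. `TAGGGTT`, `CCCTAAA` and `TTTAGGG` all collapse to
   `TTTAGGG`.
5. **Classify** against a catalog of eight telomere families
   (Arabidopsis-, vertebrate-, Chlamydomonas-, two Genlisea-,
   Klebsormidium-, Cestrum- and Papaver-type). An exact canonical-key
   match assigns the family. A non-matching unit within circular edit
   distance 1 of any catalog motif that also carries a G-run of length
   at least 2 is reported as a **novel candidate**. Distance 1 is the
   smallest threshold that admits a genuine single-substitution variant
   such as TTCAGGG (one change from TTTAGGG) while the G-run requirement
   excludes AT-rich microsatellites.
6. **Call** the sample's telomere: the motif with the highest relative
   abundance, provided it has at least 50 supporting windows and at
   least half of all telomere-like hits; ties and sub-threshold tables
   are reported as undetermined with all candidates listed.

Counting is reported both as windows and as summed unit copies; relative
abundance is normalised over telomere-like hits only (catalog plus novel
candidates), so abundances sum to 1 whenever any hit exists, and raw
counts are always emitted alongside. Normalisation is per sample.

## K-mer spectrum genome profiling

`count_kmers()` counts canonical k-mers (the lexicographic minimum of a
k-mer and its reverse complement) with a rolling 2-bit encoding; k-mers
containing `N` are skipped, and the histogram tail is capped at
multiplicity 10^6. The default sizes are k = 27 for short reads and
k = 21 for long reads; any odd k between 11 and 31 behaves equivalently
(the implementation accepts k down to 1, which the unit tests use for
hand-checkable cases).

`fit_genome_profile()` is a deliberately simple peak-based diploid model
of the spectrum, not a mixture fit:

* the **error boundary** `m0` is the first trough scanned from
  multiplicity 1 (sequencing errors create near-unique k-mers piling up
  at the left edge); a spectrum with no interior minimum followed by a
  peak is rejected with a diagnostic;
* the dominant peak above `m0` is located; if a companion local maximum
  with at least 10% of its height sits near twice its position
  (1.6–2.4x), the spectrum is read as a heterozygous peak at `kcov`
  plus a homozygous peak at `2 kcov`; otherwise the single peak is
  homozygous and `kcov` is half its position;
* **genome size** `len` is the k-mer mass above `m0` divided by the
  homozygous coverage;
* the **heterozygous mass fraction** `f` is the mass in
  `(m0, 1.5 kcov]` over all genomic mass, converted to a per-base rate
  with `ab = 1 - (1 - f)^(1/k)` (a k-mer is haplotype-specific if any of
  its k bases covers a SNP); `aa = 1 - ab`;
* `err` is the mass fraction below `m0`, `uniq` the mass up to
  `1.5 x` homozygous coverage over `hom x len` (the single-copy
  fraction of the genome), and `dup` — a read-duplication rate — is not
  estimated by this model and reported as missing.

No smoothing is applied by default; a centred moving average of width 3
is available for small noisy spectra.

**Known limitation.** Because the heterozygous window extends to
`1.5 kcov`, the lower tail of the homozygous peak leaks into `f` when
the peaks are close in units of their Poisson spread. At 40x and above
the bias is modest (the recovery tests observe ab inflated by roughly a
quarter to a third of its value); at 30x with heterozygosity below
about 0.3% the inflation can exceed half the true value. The recovery
tests therefore exercise the estimator at 40–50x, the regime it is
designed for, and `ab` from shallower data should be read as an upper
bound. Genome-size recovery is insensitive to this effect: `len`
depends only on total mass and the homozygous coverage and is accurate
to a few percent in all tested regimes, stable under halving the read
set.

## Assembly QC

* **Contig statistics**: N50 is the length at which the cumulative
  descending contig lengths first reach half the assembly size.
* **Contig-end telomere scan**: the terminal 10 kb of each contig is
  searched for the motif in its terminus-appropriate orientation (G-rich
  display form at 3' ends, its reverse complement at 5' ends). Copies
  separated by at most 50 bp form clusters; 10 clustered copies yield a
  call with its span from the terminus.
* **Binned tracks**: contigs at or above a minimum length are tiled with
  100-kb bins from coordinate 0, the last bin truncated. Depth is summed
  and averaged per bin from a three-column all-positions depth dump
  (missing positions count as depth 0). The repeat fraction of a bin is
  the union of masked intervals clipped to the bin over the true bin
  width, so terminal partial bins stay comparable. Gene, SNP and SV
  counts assign each feature to the bin containing its start coordinate
  — count-based heatmaps stay integral, at the cost of ignoring span
  overlap for long features.
* **Repeat/depth split**: bins are divided at the median repeat fraction
  (ties fall in the "less repetitive" group) and each group's mean-depth
  distribution is summarised by median and standard deviation. Similar
  medians across groups indicate repeat-dense regions assembled without
  collapse; strong depth excess in the repeat-rich group indicates
  collapsed repeats.
* **SV spectrum**: variant length is `|SVLEN|`, falling back to
  `END - POS`; records shorter than 50 bp are dropped (the conventional
  SV/indel boundary) and the rest tabulated over deletion, insertion,
  inversion, interspersed duplication and tandem duplication, with
  half-decade log10 length histograms. A bare `DUP` type is treated as a
  tandem duplication.
* **Gene x SV intersection**: a gene is affected when any of its CDS
  intervals overlaps any SV footprint by at least 1 bp in half-open
  coordinates; insertion footprints are a single base. CDS rather than
  whole gene spans are used because a variant in an intron does not
  disrupt the coding product. Each gene is counted once. No minimum
  overlap beyond 1 bp is imposed.

Coordinates are 0-based half-open internally; GFF3, VCF and RepeatMasker
coordinates are converted on read and write. RepeatMasker classes are
aggregated into seven summary categories (Retroelement, DNA transposon,
Rolling-circle, Small RNA, Satellite, Simple repeat, Low complexity)
plus Unclassified; class totals sum alignment lengths without overlap
deduplication, whereas bin repeat fractions always deduplicate.

## The synthetic data generator

`simulate_genome()` builds a diploid toy genome whose every feature is
recorded: telomere arrays of a chosen motif at both ends of each
chromosome (C-strand array at the 5' terminus, G-strand at the 3', the
orientation real telomeres have), random single-copy interior, 3–10
shuffled repeat families of 0.3–5 kb placed without overlap until a
target genome fraction is covered, planted gene/CDS intervals, and a
second haplotype derived by substituting SNPs at a requested per-base
rate and applying structural variants (DEL/INS/INV/DUP applied
right-to-left so coordinates stay valid). Short reads are drawn
uniformly from both haplotypes and strands with independent substitution
errors; long reads follow a lognormal length distribution with the
requested mean (default 17,289 bp, a typical HiFi library) and are
error-free by default, as Q20+ consensus reads are nearly so. FASTQ
qualities are a constant Q40 because no stage consumes them. All outputs
are byte-identical under a fixed seed.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate — includes: real transposon families and
their nested, diverged copies (repeat families here are shuffled random
sequence, so k-mer repeat peaks are cleaner than in real genomes);
quality-score error profiles and indel sequencing errors; heterozygous
indels (substitutions only, which keeps the two-peak spectrum model
exact); PCR/optical duplicates (`dup` is accordingly not estimated); and
biased coverage. Recovery results on synthetic data bound what the
methods can do under their own assumptions, not their accuracy on real
repeat-rich genomes.

SNPs are placed only in the interior so that planted telomere arrays
stay pure; with telomeres at well under 1% of the genome the realised
SNP count still matches the requested rate within binomial error.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data
chosen to finish in minutes on one core while leaving the contracts
sharp: motif-recovery scenarios use 200-kb genomes with 60 telomere
copies per end and 100,000 reads (nine scenarios, including one with the
Papaver-type unit withheld from the catalog to force the novel-candidate
path); genome-profile recovery uses 0.5–1 Mb diploids at 40–50x with
k = 21; the subsampling contract is exercised at its full 21-million
record scale on the index-selection core. Randomised oracle comparisons
(period detection, circular edit distance, N50, interval overlap,
dictionary k-mer counting) run on hundreds to a thousand small
instances under fixed seeds.

Tie-breaks are deterministic everywhere: strand choice falls back to
the lexicographically smaller minimal rotation, equal-abundance motif
calls return undetermined rather than picking arbitrarily, and bins
with repeat fraction equal to the median go to the less-repetitive
group. Degenerate inputs (empty window sets, empty histograms, monotone
spectra, header-only annotation files, all-zero tracks) are exercised
in the unit tests and either produce well-defined empty results or fail
with a diagnostic naming the cause.
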