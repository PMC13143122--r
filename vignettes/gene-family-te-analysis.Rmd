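---
title: "Gene-family expansion, TE co-localization and IDS motif analysis with tefam"
author: "tefam authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-family expansion, TE co-localization and IDS motif analysis with tefam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tefam)
library(GenomicRanges)
```

## The problem

Tandemly expanded multi-copy gene families are a recurring signature of rapid
functional innovation — the motivating case for this package is the expansion
of geranylgeranyl pyrophosphate synthase (GGPPS)-like genes in termite
genomes, where a cluster of highly similar paralogs, many of them
pseudogenized, sits in repeat-rich genomic territory. Three questions arise
whenever such a family is studied in a draft assembly:

1. **Where are the family loci, and which copies are still genes?** Copies
   are discovered by homology and classified as intact genes or pseudogenes
   from integrity rules (all protein-coding exons present, no frameshift
   indels, no nonsense mutations).
2. **Are transposable elements (TEs) co-localized with the family?**
   TE density around family loci is compared against a genome-wide
   resampling null, and the spatial arrangement of TEs around loci is
   profiled.
3. **Which family proteins retain the catalytic motif architecture of
   canonical isoprenyl diphosphate synthases (IDS)?** Proteins are scanned
   for the aspartate-rich DDxxD motifs (FARM and SARM) and a set of
   insect-GGPPS motifs (IGMs), and classified as canonical or divergent.

Because the real data for such an analysis are genome-scale, `tefam` ships a
synthetic-genome generator that plants paralog clusters, lesions and TE
landscapes with exact ground truth. Every statistical claim the package makes
is validated end-to-end against that truth in the test suite.

## Windows and TE density

All interval logic uses Bioconductor containers (`GRanges`, 1-based closed
coordinates); GFF3 and BED files are read and written through `rtracklayer`,
which handles the dialect conversions.

A focal locus is measured inside a *window* built by `expand_to_window()`:
either the gene span padded by 50 kb on each side (`gene_span_pad`, the
default for focal loci) or a fixed 100 kb window centred on the gene midpoint
(`fixed_center`, used for the permutation null and for profiles). Windows are
clipped at contig ends; clipped windows are kept and their realized width is
used as the denominator, so loci on short contigs are not silently dropped.

**TE density is defined as the merged base-pair coverage fraction**: the
union of all TE annotations intersected with the window, divided by the
window width (`coverage_fraction()`). Merging first means nested and
overlapping annotations never double-count. An element-count mode
(elements per kb by midpoint containment) is exposed via `stat = "count"`
for sensitivity analyses but is never the default, because the headline
quantities of interest (densities around 0.4-0.65 on a repeat-rich genome)
are fractions of covered sequence, not element tallies.

## The permutation null

`permutation_test()` compares the mean density over the focal window set
against the mean over an equally sized set of random fixed-width windows,
repeated `n_perm` times (default 1,000). Windows are drawn uniformly over
all eligible start positions pooled across contigs (a contig is chosen with
probability proportional to `length - width + 1`), so the null is exactly
"the same number of windows, anywhere in the assembly". The comparison is of
*set means* — the focal mean against the distribution of null set means —
because the scientific claim is about the family-wide average, not any
single locus.

The empirical p-value is plus-one corrected,

> p = (1 + #\{null mean >= observed mean\}) / (n_perm + 1),

so it can never be exactly zero; with 1,000 permutations the smallest
reportable p is 1/1001. `fold` is observed mean / mean of null means, and
`percent_of_null` is the same number as a percentage (150 means the focal
density is 150% of the resampling average). The test is one-sided
(enrichment) by default; a two-sided variant doubles the smaller tail.

No GC- or chromatin-matched resampling is attempted, and annotation tracks
are not circularly permuted; the null is deliberately the plain random-window
draw. Runs of N are *not* masked by default (an optional `exclude` mask can
be passed when an assembly has large gaps).

At desk scale the focal windows are a non-negligible fraction of the
simulated genome, so the null mean is slightly contaminated by enriched
territory and the measured fold under a planted 1.5x regime converges to 1.5
only as the genome grows. The test suite verifies the fold lands in
[1.35, 1.65] under the standard 10 Mb setup, and that p-values are uniform
when no enrichment is planted (Kolmogorov-Smirnov test over 200 simulated
datasets).

## Meta-locus profiles and satellite peaks

`density_profile()` centres a fixed-width window on each focal gene's
midpoint, splits it into strand-oriented 1 kb bins (bin index increases 5'
to 3' along the gene; minus-strand profiles are reversed exactly), and
averages bins over loci. Peak calling is deliberately simple and fully
declared: the profile is smoothed with a centred moving average (default 3
bins) and local maxima above `mean + peak_z * sd` of the smoothed profile
(default `peak_z = 2`) are reported with signed offsets from the gene
center. When family members sit in tandem clusters with a characteristic
spacing, the neighbouring paralogs' TE surroundings appear as *satellite
peaks* at that spacing (e.g. +/-23 kb).

A mean + z * sd threshold is self-limiting when a large fraction of the
window is elevated (the peaks inflate the sd they are compared against), so
satellite detection works best when TE co-localization is tight around the
loci; that is also the regime the motivating observations describe (elements
immediately flanking the genes). The satellite-recovery test therefore
plants a compact signature element centred on each gene body — making the
expected profile a narrow comb at 0, +/-23 kb, +/-46 kb — rather than a
broad 50 kb enrichment plateau, which would produce overlapping windows and
no distinct periodicity.

`family_representation()` compares TE family composition between focal
windows and the whole genome by counting *elements* (midpoint containment),
not base pairs, mirroring how relative family frequencies among all
predicted TEs are usually reported; frequencies are normalized within each
universe. No per-family test is run by default (composition is descriptive);
a chi-square with Holm correction can be layered on by the user.

## Locus discovery and integrity classification

Discovery is exon-level local alignment, self-contained in the package:
each reference exon is Smith-Waterman-aligned against both strands of each
contig with match +1, mismatch -1, gap open 2, gap extend 1 (Biostrings
convention: an L-long gap costs open + L * extend). A hit qualifies when

* identity >= 0.80, where **identity = matches / aligned columns including
  gaps** (the denominator must be pinned down for the threshold to mean
  anything), and
* the alignment covers at least 50% of the reference exon.

For whole-genome scans the alignment is anchored by exact 12-mer seeds
(`matchPDict`) and only seed-supported regions are aligned — a pure speedup;
an exhaustive recursive-masking mode exists and is the oracle the seeded
mode is tested against. Qualifying hits are chained into candidate loci when
they share a strand, have ascending exon index in gene orientation, and are
separated by at most 20 kb (the intron/intergenic scale of multi-kb tandem
loci); a chain qualifies when it contains at least 2 hits with consecutive
exon indices. Chimeric or duplicated exon arrangements break the
ascending-index rule and surface as separate loci, never merged.

Classification (`classify_locus()`) then applies the integrity rules:

* `missing_exon` — some reference exon has no qualifying hit;
* `frameshift_indel` — the total indel length within some exon's alignment
  is not a multiple of 3;
* `premature_stop` — the conceptual translation of the spliced candidate
  CDS contains a stop before its final codon;
* `no_terminal_stop` — the translation does not end in a stop.

A locus is a **gene** iff no reason fires. In-frame indels alone do *not*
pseudogenize a copy: "indels or nonsense mutations" is read as
integrity-breaking lesions, and a clean in-frame deletion leaves the reading
frame and both stops intact. Likewise all six exons must have a qualifying
hit for gene status — absence of evidence for an exon is treated as a
missing exon, which is the conservative reading.

Two numerical details matter here. First, each present exon is *re-aligned*
end-to-end (exon side global) against its hit region extended by a margin,
so a Smith-Waterman hit whose ends were trimmed by terminal mismatches
cannot silently truncate the candidate CDS and fake a frameshift; uncovered
exon ends count as deletions. Second, this re-alignment uses stiffer gap
penalties (open 6, extend 2) than the discovery scan: a true frameshift
indel still wins by a large margin because it rescues the entire downstream
frame, while a spurious single-base gap that substitution noise can make
marginally optimal under the discovery scoring is suppressed. Without this,
roughly one in sixty intact copies at 5% divergence acquired a phantom 1 bp
indel from a flank-base coincidence.

## Motif scanning and IDS family calls

A motif is an ordered list of per-column residue classes (wildcards
allowed). `build_motif_regex()` trains one from an alignment slice: a
residue enters a column's class when its within-column frequency among
non-gap characters is at least 0.05 (admits rare-but-real residues, excludes
singleton noise in panels of >= 20 sequences); a column observed with >= 15
residues, all admitted, becomes a wildcard; gap-majority columns are
rejected with an error. `scan_motif()` reports every matching position and
is tested against a brute-force membership oracle.

FARM and SARM share the DDxxD consensus, so telling them apart is a
convention, declared here: **FARM is the first DDxxD-class hit; SARM is the
next hit starting at least 80 residues downstream of the FARM start**
(the helix bundle between the two motifs in IDS structures; configurable).
Family calls follow the conservation logic of the divergent clade:
*canonical* = FARM, SARM and all six IGMs present; *divergent_like* = FARM
and IGM3 present with at least one other IGM absent; everything else
*indeterminate*. `filter_phylogeny_set()` implements the standard inclusion
rule for IDS phylogenies (length >= 150 aa and both FARM and SARM present).
`logo_matrix()` returns per-column frequencies and information content
(log2(20) minus Shannon entropy) for logo rendering.

The exact IGM column boundaries live in an external alignment convention
that is not reproduced here, so `built_in_motifs()` ships *synthetic
placeholder* IGM definitions (clearly flagged in their documentation; IGM4
carries the conserved KT dipeptide) and real analyses should supply trained
definitions. The classification *rules* — which motifs decide which call —
are the substance; the placeholder consensus strings only make the package
runnable out of the box and give the synthetic panel its ground truth.

## The synthetic-data generator

`simulate_genome()` emulates the study conditions as its defaults: four
contigs totalling 7 Mb; 28 family loci (15 intact genes, 13 pseudogenes
with a balanced assignment of frameshift / nonsense / exon-deletion
lesions) in tandem clusters of 7 with Normal(23 kb, 1 kb) start-to-start
spacing; 5% per-base divergence among paralogs; a TE landscape with 0.43
background coverage and 1.5x coverage inside the 50 kb-padded focal
windows; and an optional antisense signature element near the last exon of
every locus (off by default).

Design choices worth knowing:

* **The reference gene** has six fully coding, codon-aligned exons
  (171/246/213/198/228/159 bp = 404 codons + stop) whose protein is the
  canonical synthetic IDS panel protein, so pipeline runs exercise the motif
  classifier on real translations. Codon-aligned exon boundaries (all
  phase 0) are a simplification; real genes split codons across junctions.
* **Divergence is codon-safe for copies labelled "gene"**: substitutions
  that would create a premature stop are redrawn and the start/stop codons
  are protected, so truth labels are exact by construction, not by luck.
  Pseudogene templates get the same treatment *before* their lesion is
  applied, so the planted lesion is the only integrity-breaking change.
* **TE placement is a stationary Boolean model** with log-normal element
  lengths (median 500 bp): the Poisson start rate is derived as
  `-log(1 - c) / E[length]` so the *realized merged coverage* equals the
  target `c`, and the focal rate targets `min(1, factor * c)`. A naive
  intensity multiplier would saturate and the realized coverage ratio would
  undershoot the configured factor.
* **TEs are annotation-only**: BED rows are emitted but the genome sequence
  is not rewritten. TE *prediction* is out of scope (the analysis consumes
  annotations), every downstream statistic consumes intervals, and keeping
  placement independent of gene bodies is exactly what the null-calibration
  property requires.
* **Introns are randomized per copy** except for 10 bp of conserved splice
  context at each boundary, so exon-level homology has realistic contrast
  against intron sequence.
* Background sequence is i.i.d. with configurable GC. There is no
  phylogenetically realistic sequence evolution (no codon models, no indel
  evolution along a tree) and no repeat landscape beyond the planted
  elements — passing tests demonstrate the statistics and the rules, not
  robustness to every idiosyncrasy of real assemblies.

All randomness derives from the single config seed (child streams are
spawned deterministically), and identical configs produce byte-identical
output files.

## Problem sizes used in the validation suite

The package's own validation uses desk-scale problem sizes, chosen so the
full suite exercises every claim in minutes: coverage statistics are checked
against a per-base mask oracle on 1,000 random instances with windows up to
100 kb; null calibration uses 200 simulated 5 Mb datasets with 10 isolated
loci and 200 permutations each; enrichment recovery uses 50 replicates of a
10 Mb genome with 20 clustered focal loci; lesion recovery plants 500 loci
(250 intact / 250 lesioned) at 5% divergence on a 13 Mb genome; satellite
recovery uses 10 seeds of a 10-member 23 kb cluster. The acceptance script
(`scripts/acceptance.R`) re-runs the full pipeline on the 7 Mb
study-condition genome with 1,000 permutations.

## Known limitations

* Identity thresholds are applied per exon alignment; a locus whose exons
  individually fall just below 0.80 identity is invisible even if the
  full-length alignment would qualify.
* The seeded scan requires one exact 12-mer per exon copy; at divergence
  beyond ~15% sensitivity decays (the exhaustive mode remains available).
* Peak detection is a declared convenience, not a statistical test; treat
  reported satellite peaks as descriptive.
* The enantiomer module implements the ratio and the two-sample comparison
  only (Welch by default, pooled-variance Student's t by flag); it does not
  model chromatographic error structure.
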