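# tefam

Analysis of tandemly expanded gene families in draft genome assemblies:
locus discovery and gene/pseudogene integrity classification for a focal
multi-copy family, permutation-based testing of transposable-element (TE)
co-localization with binned meta-locus density profiles and TE-family
composition, and motif-based classification of isoprenyl diphosphate
synthase (IDS) proteins into canonical and divergent clades. A synthetic
genome generator with planted paralog clusters, lesions and TE landscapes
provides exact ground truth, so the whole pipeline is validated end to end.

The package is written for genome biologists studying gene-family
expansions — the motivating system is the expansion of GGPPS-like genes in
termite genomes, where tandem paralogs at ~23 kb spacing, extensive
pseudogenization and a TE-rich neighbourhood co-occur — but every component
is generic: any six-exon (or *n*-exon) reference model, any TE annotation
track, any motif set.

## The statistics at the core

**TE density** of a window *W* is the merged base-pair coverage fraction

    d(W) = | union(TEs) ∩ W | / |W|

(nested/overlapping annotations merged first). Focal windows are gene spans
padded by 50 kb per side; the null re-draws the same number of 100 kb
windows uniformly across the assembly, `n_perm` times, and compares *set
means*. The empirical p-value is plus-one corrected,

    p = (1 + #{ mean(null set) >= mean(focal set) }) / (n_perm + 1),

and the enrichment is reported as `fold = observed / mean(null)` (150% of
null means the focal neighbourhood carries one-and-a-half times the genomic
TE load). Strand-oriented 1 kb binned profiles around gene centers expose
*satellite peaks* at the paralog spacing; TE family composition is compared
between focal windows and the genome by element counts.

**Locus discovery** is a self-contained exon-level Smith–Waterman scan
(match +1, mismatch −1, gap open 2, gap extend 1) keeping hits with
identity ≥ 0.80 (matches / aligned columns incl. gaps) covering ≥ 50% of
the exon, chained into loci when ≥ 2 consecutive exon indices co-occur on
one strand within 20 kb. **Integrity classification** calls a locus a
pseudogene on any of: missing exon, frameshift (per-exon indel sum ≢ 0
mod 3), premature stop, missing terminal stop — in-frame indels alone do
not pseudogenize.

**Motif classification**: FARM = first DDxxD hit, SARM = next DDxxD hit
≥ 80 residues downstream; canonical = FARM + SARM + all six insect-GGPPS
motifs (IGMs); divergent-like = FARM + IGM3 with ≥ 1 other IGM lost.
Phylogeny input filtering keeps sequences ≥ 150 aa with both FARM and SARM.

## Worked example

```r
library(tefam)

cfg <- sim_config(seed = 11, contig_lengths = c(ctg1 = 2e6, ctg2 = 2e6),
                  n_genes = 8, n_pseudogenes = 6, cluster_size = 7,
                  background_te_density = 0.43, focal_enrichment_factor = 1.5,
                  divergence = 0.05)
report <- run_pipeline(config = cfg, n_perm = 1000, seed = 11)
report
#> tefam pipeline report (v0.1.0, seed 11)
#>   loci: 14 ( 8 genes / 6 pseudogenes )
#>   TE enrichment: 0.656 vs 0.468 (140% of null), p = 0.000999
head(report$loci[, c("locus_id", "contig", "start", "classification", "reasons")])
#>   locus_id contig   start classification                                          reasons
#> 1 locus001   ctg1  981651     pseudogene frameshift_indel,premature_stop,no_terminal_stop
#> 2 locus002   ctg1 1004013           gene
#> 3 locus003   ctg1 1028323           gene
#> 4 locus004   ctg1 1051020     pseudogene                                   premature_stop
#> 5 locus005   ctg1 1073559           gene
#> 6 locus006   ctg1 1097307           gene
```

Reading the output: all 14 planted loci were rediscovered by the exon
homology scan and every integrity label matches the planted truth — the
`reasons` column explains each pseudogene call (a frameshift corrupts the
downstream translation, hence the accompanying stop-codon reasons). The mean
TE density inside the 50 kb-padded focal windows is 0.656 versus 0.468
across 1,000 random window sets — 140% of the genomic average, with the
smallest p-value reportable at 1,000 permutations (1/1001). On this 4 Mb
toy genome the null is visibly contaminated by the enriched focal territory;
the fold approaches the planted 1.5× as the genome grows.

Individual stages are available as plain functions (`annotate_genome()`,
`permutation_test()`, `density_profile()`, `family_representation()`,
`classify_proteins()`, `enantiomer_ratio_test()`), and
`inst/scripts/tefam-cli.R` wraps them as shell subcommands
(`simulate`, `annotate`, `enrich`, `classify`, `run`, `stats-enantiomer`).

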