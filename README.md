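# somaclone

Genome-wide detection of somatic polymorphism among vegetatively
propagated clones, built and validated entirely on synthetic data.

Clones of a single cultivar (grapevine is the motivating system) differ
only by somatic mutations accumulated over propagation cycles: SNPs,
short indels and - dominating the spectrum - new transposable-element
(TE) insertions. `somaclone` implements the full comparison pipeline for
long 454-style reads and, because each stage must be verifiable without
external downloads, ships a first-class simulator producing repeat-rich
reference genomes, mutated clone genomes with a ground-truth mutation
ledger, and realistic read sets.

## What the package does

* **Simulation** — TE library with subfamily-variant structure (a
  recently amplified Gypsy element, a high-copy Copia element, older
  Gypsy and Caulimoviridae-like elements, plus LINE and class-II
  families); repeat-rich ancestral reference with genes, exons and a
  centromere-like block; clone derivation at configurable per-Mb somatic
  rates (defaults 1.6 SNPs / 5.1 indels / 35.2 TE insertions per Mb of
  pair divergence); 454-style reads (length ~ N(355, 60), quality decay
  Q34 to Q20, homopolymer errors, 0.58% EmPCR duplicates, organelle and
  contaminant spikes); in-silico shearing of assemblies into 1000-base
  optimal-quality fragments.
* **Tiered alignment** (C++ seed-and-extend core) — step 1: strict
  whole-read placement at >= 95% identity on a single locus; step 2:
  repeat-masked alignment of the unique segment (>= 150 unmasked bases),
  recording TE-junction evidence (>= 100 adjacent masked bases); step 3:
  relaxed affine gaps (open 0.1) at >= 90% identity. Unaligned reads are
  classified LOW_QUALITY / REPEAT / PARALOG / CYTOPLASMIC / CONTAMINANT /
  UNKNOWN, and an alignment quality score in [0, 90] expresses placement
  uniqueness.
* **Coverage-gated calling** — polymorphisms between a clone pair are
  called only where both clones have >= 6 independent reads, with
  within-clone allele frequency >= 0.3 and supporting-read quality > 60:
  SNPs by allele-set comparison, indels from mid-read step-1/2 evidence
  with a homopolymer screen, TE insertions from clustered masked-junction
  reads with an informative-read support fraction.
* **S-SAP** — in-silico banding from a TE-anchored primer (most conserved
  LTR window) to the nearest restriction site, band matrices, Nei-Li
  distance `D = 1 - 2*n_xy/(n_x + n_y)`, neighbor-joining trees with
  bootstrap over band columns.
* **LTR-form dynamics** — harvest of LTR-derived read segments, greedy
  consensus clustering (major form = >= 10 segments at >= 90% identity),
  major/minor form distributions, and conserved-region trees whose tight
  >= 99%-identity groups flag recent transposition.

## Worked example

```r
library(somaclone)

lib <- build_te_library(6, seed = 7)
anc <- build_ancestral_genome(2, c(6e5, 4e5), repeat_fraction = 0.3,
                              library = lib, seed = 11)
anc
#> ancestral_genome: 2 chromosome(s), 1.00 Mb, 31.0% repeats, 39 genes

dc <- derive_clone(anc, snp_rate = 1.6, indel_rate = 5.1, te_rate = 35.2,
                   library = lib, seed = 13, clone_id = "c1")
table(dc$ledger$type)
#> INDEL   SNP TE_INS
#>     5     1    30

reads <- simulate_reads(dc$genome, 20000, seed = 5,
                        profile = read_profile(),
                        organelles = anc$organelles,
                        contaminants = anc$contaminants)
aln <- run_tiered_alignment(reads, seq_index(anc$chromosomes), lib,
                            organelles = anc$organelles,
                            contaminants = anc$contaminants)
aln
#> tiered_alignment: 20000 reads
#>       category     n percent
#>  ALIGNED_STEP1 14740   73.70
#>  ALIGNED_STEP2   172    0.86
#>  ALIGNED_STEP3    40    0.20
#>         REPEAT  3983   19.91
#>        PARALOG    91    0.46
#>    CYTOPLASMIC   811    4.06
#>        UNKNOWN   163    0.81
#>    CONTAMINANT     0    0.00
#>    LOW_QUALITY     0    0.00
```

About 74% of reads align at the strict step, a fifth are repeat or
multi-locus reads (discarded, as single-locus placement is required), and
the organelle spike-in is recovered as the cytoplasmic class. A clone
pair is then compared inside its >= 6x shared regions with
`clone_pileup()`, `regions_at_depth()`, `shared_regions()` and
`call_pair()`; `run_pipeline(somaclone_config(seed = 1))` orchestrates
every stage and `make_report()` assembles the summary tables.

The numbered scripts under `analysis/` run the whole study on a 10-Mb
two-clone simulation (`01_simulate.R` through `07_report.R`, writing
tables under `results/`): alignment classification, coverage tiers and
shared territory, polymorphism calls with per-Mb rates scored against the
mutation ledger, S-SAP fingerprints of a 16-clone panel, and LTR-form
tables with recent-activity flags.

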