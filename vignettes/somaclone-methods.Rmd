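---
title: "Methods: simulating and detecting somatic polymorphism among clones"
author: "somaclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting somatic polymorphism among clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Vegetatively propagated cultivars (grapevine clones are the motivating
system) accumulate somatic mutations over propagation cycles: SNPs, short
indels, and - dominating the mutational spectrum - new insertions of
transposable elements (TEs). Measuring this divergence genome-wide from
long-read pyrosequencing data requires a pipeline whose every stage copes
with the defining nuisance of plant genomes: a large, nested repeat
fraction. `somaclone` implements that pipeline end-to-end and, because no
desk-scale real data can validate it, ships a first-class synthetic-data
generator with a mutation ledger so every stage is scored against known
truth.

## The synthetic study system

`build_te_library()` creates the repeat universe. Four focal LTR
retroelement families mirror the structure reported for grape:

* **Gret1-like** (Gypsy): four major LTR subfamily variants at copy shares
  0.25 / 0.18 / 0.05 / 0.03; the dominant variant carries zero per-copy
  divergence - a recent amplification burst of identical copies.
* **Copia10-like**: four majors (0.19 / 0.07 / 0.07 / 0.03), all with small
  per-copy divergence (no recent burst).
* **Gypsy19-like** and **Cauliv1-like**: one major each (0.10 / 0.07).
* The remaining copy share of each family is a *minor* pool: every genomic
  copy is drawn independently at ~17% divergence from the family base LTR,
  so no two minor copies can support a common consensus. This is the model
  of "ancient diffuse copies": the large per-copy divergence is what makes
  them unclusterable, which is exactly what distinguishes minor from major
  forms downstream.
* LINE-like (class I, no LTR) and a class-II DNA-transposon family round
  out the library.

Major/minor divergence scales (12% between majors, 2-4% within an aged
major lineage, 17% per minor copy) are the package's own calibration: they
keep majors clusterable at the 90% identity threshold, minors harvestable
at the 75% threshold but never clusterable, and distinct majors separated
well beyond the clustering radius.

`build_ancestral_genome()` assembles a reference: random background at GC
0.35, dispersed TE copies plus one dense tandem block per chromosome (a
centromere stand-in consuming a quarter of the repeat budget), and
gene/exon annotation placed outside repeats until exons cover ~6.9% of
bases. Copy counts per subfamily variant follow the weights
deterministically (minimum two copies per major variant - a major form is
by definition a multi-copy lineage); minor copies are drawn by weight.

`derive_clone()` draws Poisson numbers of SNPs, indels (1-10 bp, short
lengths favoured) and TE insertions at configured per-Mb rates, at
positions at least 10 bp apart, and applies them through `apply_ledger()`
so the ledger exactly determines the clone sequence (a tested round-trip).
New TE insertions copy an *active major* lineage (dominant variant with
probability 0.8) with a 5 bp target-site duplication and random
orientation; ancient minor lineages do not transpose. The published
per-Mb rates describe the divergence *between* two clones, so the pair
experiments give each clone half of each rate.

`simulate_reads()` emulates a 454 GS-FLX run: lengths ~ Normal(355, 60)
truncated to [60, 700]; per-base quality decaying linearly Q34 to Q20
(endpoints chosen to give the reported mean run quality near Q30);
substitutions at the phred-implied rate; homopolymer runs of three or more
gaining/losing one base with probability 0.02 per run; 0.58% EmPCR
duplicates; 3.8% organelle and 0.013% contaminant spikes from bundled
synthetic organelle/contaminant sequences. `shear_assembly()` tiles
assembly contigs into 1000-base fragments at the maximum quality symbol,
the treatment used for assembly-derived data entering the same pipeline.

## Tiered alignment

The aligner is a seeded (k = 13, every 5th query position, both strands)
banded affine-gap (Gotoh) fitting aligner written in C++:

1. **Strict**: whole read, accept at identity >= 0.95 when the second-best
   candidate locus trails the best by more than 5% of the read length
   (multi-locus reads are discarded - single-locus placements only).
2. **Masked**: strict rejects are repeat-masked against the library
   (banded local alignment, identity >= 0.80 over >= 50 bp, merged
   intervals); when >= 150 contiguous unmasked bases remain, that unique
   segment is aligned under strict rules. An adjacent masked segment of
   >= 100 bp makes the read *TE-junction evidence*: the unique-segment
   boundary coordinate is a candidate insertion site, the masked segment's
   best library hit its family.
3. **Relaxed**: whatever remains (not repeat, not multi-locus) is aligned
   whole with gap-open 0.1 and per-base extension penalties, accepted at
   identity >= 0.90 (the identity floor prevents arbitrary placements that
   near-free gaps would otherwise allow).

Unaligned reads are classified by priority: LOW_QUALITY (< 100 bp or mean
quality < Q20) > REPEAT (>= 90% masked) > PARALOG (multi-locus) >
CYTOPLASMIC (>= 90% identity to organelle references) > CONTAMINANT >
UNKNOWN. The alignment quality score Q = min(90, 90 x (best - second) /
length) is phred-like in [0, 90]; a unique hit with no plausible
competitor (no candidate above identity ~0.80) scores 90. Competitors are
enumerated from the top 24 seed-count candidate loci per read: this must
comfortably exceed the copy number of near-identical repeat lineages, or a
read from an unrepresented somatic copy is placed on its closest paralog
with an unduly confident score.

## Coverage gates and composition

Depth counts *independent* reads (duplicates - identical sequence at the
same position - collapse to one, the natural reading of "independent" in
a platform with EmPCR duplicates). Call-eligible territory is the
intersection of both clones' >= 6x regions. Composition statistics (GC,
CpG, CnG, exon share of aligned bases) and two randomness checks - the
Pearson correlation between per-window (100 kb, full windows only) aligned
reads and repeat-annotated bases, and the per-chromosome aligned-bases ~
length fit - verify that accepted reads are a representative genome sample
outside repeats. Short terminal windows are excluded from the correlation
because they are jointly depleted in reads and repeat bases and would bias
it toward zero or positive values.

## Polymorphism calling

All calls are rule-gated inside the shared >= 6x regions: each clone's
allele set is the set of alleles at within-clone frequency >= 0.3, a
polymorphism is an allele-set difference, and the supporting evidence must
carry an alignment quality score above 60. Three hygiene rules stand in
for the study's manual inspection step, each targeting a concrete
artefact mode observed in validation:

* mismatches closer than 5 bp to another event on the same read are
  misalignment signatures (unaligned junction tails) and are dropped;
* relaxed-step (step 3) mismatch evidence counts only when a step-1/2 read
  shows the same allele at the same site (near-free gaps can smear
  spurious substitutions);
* sites piling far above the expected coverage (default ceiling
  2.5 x coverage + 6) indicate collapsed paralogous copies and are
  skipped.

Indels additionally require step-1/2 reads with the event >= 20 bp from
both read ends (the "read terminal region" is not quantified in the
source study; 20 bp is the package default), and calls inside reference
homopolymer runs >= 6 bp are flagged low-confidence - the classic
pyrosequencing failure mode.

TE insertions: junction reads within +/- 15 bp cluster to one site
(median position). The supporting fraction gate (>= 0.3) is computed over
*informative* reads only - junction reads plus reads cleanly spanning the
site window; reads that merely end nearby neither support nor refute an
insertion and would otherwise dilute every true site, since at a real
insertion almost no carrier read can span the window. The other clone
must have >= 6x spanning coverage and zero junction reads in the window.
Because the carrier's coverage necessarily dips at the junction (its
reads end there), the region gate for TE sites tests the site window
rather than the exact base.

## S-SAP, distances and trees

`insilico_ssap()` amplifies from the most conserved LTR window (highest
mean identity across major variants, 3'-proximal among near-ties) to the
nearest restriction-site motif; distances within the size window are gel
bands, binned at +/- 2 bp (a gel-resolution stand-in). The function
default motif is the EcoRI site GAATTC; the analysis configuration uses
the 4-bp MseI-like motif TTAA with a (50, 1500) size window, the classic
frequent-cutter choice for S-SAP fingerprinting - with a 6-cutter most
junctions simply have no site within gel range in a random-sequence
genome, which measures restriction-site density rather than the marker
system. Nei-Li distance D = 1 - 2 n_xy / (n_x + n_y) over band
presence/absence feeds neighbor joining (`ape::nj`; negative branch
lengths clamped to zero), with support from 1000 bootstrap resamplings of
band columns - the standard reading of "1000 permutations" for this kind
of fragment data.

## LTR forms and recent activity

Segments locally aligning to a family's base LTR at >= 75% over >= 100 bp
are harvested from a low-coverage (1.2x) read survey of the *ancestral*
genome. Two deliberate choices here:

* Low coverage keeps single-locus read stacks (expected ~2 segments per
  LTR occurrence) far below the 10-segment major-form threshold, so a
  major form can only emerge from a multi-copy lineage - matching the
  low-coverage regime of the original long-read data. At high coverage the
  read-count criterion would degenerate into a per-locus stack counter.
* The survey reads come from the ancestor because the form distribution
  characterises the genome-wide copy structure; in real data somatic
  additions are a negligible fraction of copies, but the simulation's
  somatic rates are (intentionally) enormous relative to its small
  genome, and clone reads would let the recent burst swamp the form
  table.

Clustering is greedy: the longest unassigned segment seeds a cluster;
segments joining at >= 90% identity to the running column-majority
consensus (ties broken alphabetically; >= 50 overlapping columns required)
are added and the consensus updates. A vectorised screen against the seed
consensus shortlists candidates within 5 points of the threshold before
exact incremental verification - segments below that screen cannot reach
the threshold against a consensus that stays within the cluster's own
divergence. Because reads are shorter than the LTR, one form can emerge
as two clusters seeded at different LTR regions; a merge pass joins
clusters (of three or more segments) whose consensi agree at the
clustering identity. Clusters of >= 10 segments are major forms; all other
segments pool as minor.

The conserved-region tree extracts the final 200 bp of the LTR (the
region is only marked graphically in the source material; the 3' end is
the default and configurable) from fully covering segments, builds
p-distance + neighbor-joining trees with bootstrap over alignment
columns, and flags *recent activity* when >= 5 segments form a mutual
>= 99% identity group - copies that have had no time to diverge. Trees are
built on at most `max_tips` segments for tractability; the activity flag
always uses all covering segments.

## Numerical and statistical choices

* Coordinates are 0-based half-open in memory, 1-based in GFF3/BED/TSV
  outputs.
* Every stochastic step takes an explicit seed; pipeline stage seeds
  derive from the single configuration seed, and a fixed seed reproduces
  every artifact byte-for-byte.
* The per-base depth of uniformly placed reads is compared to its Poisson
  law at positions spaced one read length apart: neighbouring bases share
  covering reads, so a chi-square over all bases would wildly overstate
  the evidence; the spaced subsample gives independent observations.
* Ledger scoring tolerances: SNPs +/- 2 bp, indels +/- 10 bp with exact
  signed length, TE insertions +/- 20 bp (junction placement jitters by
  the target-site duplication and clustering radius). Entries of the two
  clones closer than 10 bp to each other are excluded from truth as
  inherently ambiguous.
* The rate-recovery experiment compares called per-Mb rates against the
  density of ledger events inside the same shared regions (and against the
  nominal rates), over 20 replicate half-Mb pair simulations.

## Problem sizes

The bundled experiments run a 10-Mb, four-chromosome, 30%-repeat genome at
12x raw coverage per clone for ledger recovery; a 3-Mb one-clone run with
the full noise model for read QC; a 16-clone, 3-Mb panel for S-SAP
fingerprints; and twenty 0.45-Mb replicate pairs for rate recovery. These
sizes give every estimator enough events to be scored meaningfully (for
example, several hundred TE-insertion truth sites per recovery run).

## What passing tests do and do not show

The generator produces clean, haploid, uniformly sampled genomes whose
repeats derive from a known library. Passing recovery at 100%/100% for
SNPs and indels and >= 90%/95% for TE insertions under error-free reads
demonstrates the *logic* of the gates and the junction machinery, not
performance on real 454 data, where homopolymer noise, diploidy (allele
frequencies near 0.5, chimeric cell layers), unannotated repeats and
library incompleteness all erode it - this is exactly why the original
analysis required manual inspection of every candidate. The noisy-profile
QC run exercises the error model and classification, but calling under
full noise inherits the homopolymer indel artefact mode; the
low-confidence flag marks, and does not remove, that class.

## Known limitations

* Haploid clone model: somatic changes are unambiguous in truth space; no
  heterozygous background, no periclinal chimerism.
* The masker is library-driven; there is no de-novo repeat discovery.
* The in-silico S-SAP ignores primer thermodynamics and amplification
  competition; band intensity is binary.
* Alignment is seed-limited: a true locus whose every 13-mer is disrupted
  (divergence above ~15%) can be missed; the relaxed step's identity floor
  (0.90) bounds how far placements may stray.
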