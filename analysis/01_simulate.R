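#!/usr/bin/env Rscript
# Simulate the study system: a repeat-rich ancestral reference (10 Mb, four
# chromosomes, 30% TE-derived with a dense centromere-like block per
# chromosome), two clones diverged by somatic SNPs / indels / TE insertions
# at pair-level rates 1.6 / 5.1 / 35.2 per Mb, and error-free 454-style read
# sets at 12x raw coverage per clone (the error model itself is exercised in
# 07_report.R). Writes the reference, annotation and mutation ledgers.
library(somaclone)

dir.create("results/cache", showWarnings = FALSE, recursive = TRUE)
cfg <- somaclone_config(
  seed = 1,
  simulate = list(snp_rate = 0.8, indel_rate = 2.55, te_rate = 17.6,
                  profile = clean_profile()),
  run = list(do_calls = FALSE, do_ssap = FALSE, do_ltr = FALSE))
sim <- cfg$simulate
lib <- build_te_library(sim$n_families, seed = somaclone:::stage_seed(cfg, 1L))
anc <- build_ancestral_genome(sim$n_chrom, sim$chrom_len, sim$repeat_fraction,
                              lib, seed = somaclone:::stage_seed(cfg, 2L))
write_genome_files(anc, "results", prefix = "reference")
write_te_library(lib, "results/te_library.fa")
clones <- list(); ledgers <- list(); readsets <- list()
n_read <- ceiling(sim$coverage * sum(nchar(anc$chromosomes)) / 355)
for (i in seq_along(sim$clones)) {
  cid <- sim$clones[i]
  dc <- derive_clone(anc, sim$snp_rate, sim$indel_rate, sim$te_rate, lib,
                     seed = somaclone:::stage_seed(cfg, 10L + i), clone_id = cid)
  clones[[cid]] <- dc$genome
  ledgers[[cid]] <- dc$ledger
  readsets[[cid]] <- simulate_reads(dc$genome, n_read,
                                    seed = somaclone:::stage_seed(cfg, 20L + i),
                                    profile = sim$profile)
  led <- dc$ledger; led$pos1 <- led$pos + 1
  write.table(led, sprintf("results/ledger_%s.tsv", cid), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d SNPs, %d indels, %d TE insertions; %d reads\n", cid,
              sum(led$type == "SNP"), sum(led$type == "INDEL"),
              sum(led$type == "TE_INS"), n_read))
}
saveRDS(list(cfg = cfg, lib = lib, anc = anc, clones = clones,
             ledgers = ledgers, readsets = readsets),
        "results/cache/01_sim.rds")
cat("ancestral genome:", round(sum(nchar(anc$chromosomes)) / 1e6, 2), "Mb;",
    nrow(anc$repeats), "TE copies;", nrow(anc$genes), "genes\n")
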