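#!/usr/bin/env Rscript
# Three-step tiered alignment of both clone read sets against the ancestral
# reference: strict whole-read placement, repeat-masked alignment of the
# unique segment (recording TE-junction evidence), relaxed-gap alignment of
# the remainder, and classification of unaligned reads. Writes the per-clone
# classification tables (run-summary layout).
library(somaclone)

sim <- readRDS("results/cache/01_sim.rds")
index <- seq_index(sim$anc$chromosomes)
midx <- mask_index(sim$lib)
alns <- list()
for (cid in names(sim$readsets)) {
  alns[[cid]] <- run_tiered_alignment(sim$readsets[[cid]], index, midx,
                                      organelles = sim$anc$organelles,
                                      contaminants = sim$anc$contaminants)
  write.table(alns[[cid]]$summary, sprintf("results/classification_%s.tsv", cid),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- alns[[cid]]$summary
  cat(sprintf("%s: %.1f%% aligned (step1 %.1f / step2 %.1f / step3 %.1f), repeat %.1f%%, paralog %.1f%%\n",
              cid, sum(s$percent[grepl("ALIGNED", s$category)]),
              s$percent[s$category == "ALIGNED_STEP1"],
              s$percent[s$category == "ALIGNED_STEP2"],
              s$percent[s$category == "ALIGNED_STEP3"],
              s$percent[s$category == "REPEAT"],
              s$percent[s$category == "PARALOG"]))
}
saveRDS(alns, "results/cache/02_aln.rds")
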