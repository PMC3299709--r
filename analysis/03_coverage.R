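#!/usr/bin/env Rscript
# Coverage analysis: per-clone depth profiles, the coverage-tier table
# (1x..6x spans), the pair's >= 6x shared regions (the call-eligible
# territory), aligned-read composition vs the reference, and the
# coverage/repeat window correlation with the chromosome-length fit.
library(somaclone)

sim <- readRDS("results/cache/01_sim.rds")
alns <- readRDS("results/cache/02_aln.rds")
index <- seq_index(sim$anc$chromosomes)
piles <- list(); tiers <- list()
for (cid in names(alns)) {
  piles[[cid]] <- clone_pileup(alns[[cid]], index, sim$readsets[[cid]],
                               clone_id = cid)
  tiers[[cid]] <- data.frame(clone = cid, depth = 1:6,
    mb = vapply(1:6, function(k)
      region_span(regions_at_depth(piles[[cid]]$depth, k)) / 1e6, numeric(1)))
}
tier_tab <- do.call(rbind, tiers)
write.table(tier_tab, "results/coverage_tiers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
r6 <- lapply(piles, function(p) regions_at_depth(p$depth, 6))
sh <- shared_regions(r6[[1]], r6[[2]])
df <- as.data.frame(sh)[, 1:3]
write.table(df, "results/shared_regions_6x.bed", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
cat(sprintf("shared >=6x territory: %.2f Mb (%.0f%% of the genome)\n",
            region_span(sh) / 1e6,
            100 * region_span(sh) / sum(nchar(sim$anc$chromosomes))))
cid <- names(piles)[1]
comp <- composition_stats(piles[[cid]]$records, sim$readsets[[cid]],
                          sim$anc, sim$anc$exons)
write.table(comp, "results/composition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
wc <- window_correlations(piles[[cid]]$records, sim$anc$repeats, sim$anc)
cat(sprintf("window repeat correlation r = %.3f (p = %.2g); chromosome-length R^2 = %.3f\n",
            wc$window_r, wc$window_p, wc$chrom_r2))
write.table(data.frame(window_r = wc$window_r, window_p = wc$window_p,
                       chrom_r2 = wc$chrom_r2),
            "results/correlations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(list(piles = piles, shared = sh), "results/cache/03_cov.rds")
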