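#!/usr/bin/env Rscript
# Pairwise polymorphism calling inside the >= 6x shared regions: SNPs,
# indels (step-1/2 mid-read evidence, homopolymer screen) and TE insertions
# (masked-junction reads), with gene annotation, per-Mb rates, and scoring
# against the simulation's mutation ledgers.
library(somaclone)

sim <- readRDS("results/cache/01_sim.rds")
cov <- readRDS("results/cache/03_cov.rds")
piles <- cov$piles; sh <- cov$shared
calls <- call_pair(piles[[1]], piles[[2]], shared = sh, reference = sim$anc,
                   max_depth = ceiling(2.5 * sim$cfg$simulate$coverage + 6))
ar <- annotate_and_rates(calls, sim$anc$genes, sh)
out <- ar$calls; if (nrow(out)) out$pos1 <- out$pos + 1
write.table(out, "results/polymorphism_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ar$rates, "results/polymorphism_rates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("calls in %.2f Mb shared: %d SNPs, %d indels, %d TE insertions\n",
            ar$shared_mb, sum(calls$type == "SNP"),
            sum(calls$type == "INDEL"), sum(calls$type == "TE_INSERTION")))
print(ar$rates, row.names = FALSE, digits = 3)
# ledger scoring
for (case in list(c("SNP", "SNP", 2), c("INDEL", "INDEL", 10),
                  c("TE_INSERTION", "TE_INS", 20))) {
  truth <- somaclone:::ledger_truth(sim$ledgers, case[2], sh,
                                    te_pad = switch(case[2], TE_INS = 15,
                                                    INDEL = 1, 0),
                                    piles = if (case[2] == "TE_INS") NULL else piles)
  m <- somaclone:::match_calls(calls[calls$type == case[1], , drop = FALSE],
                               truth, tol = as.numeric(case[3]),
                               check_family = case[2] == "TE_INS")
  cat(sprintf("%s: recall %.3f, precision %.3f (truth in shared: %d)\n",
              case[1], m$recall, m$precision, m$n_truth))
}
saveRDS(list(calls = ar$calls, rates = ar$rates), "results/cache/04_calls.rds")
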