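# Unit tests on hand-built pileups: 6x haploid-style stacks with controlled
# allele counts, indel evidence placement and TE junction reads.

cover <- function(n, chrom = "chr1", start = 0L, len = 400L, step = 1L) {
  data.frame(chrom = chrom, start = start + seq_len(n) - 1L, len = len,
             step = step, stringsAsFactors = FALSE)
}

test_that("SNP calls respect the 0.3 within-clone allele frequency gate", {
  # clone A: 6 reads all G (reference); clone B: 4xT + 2x ref
  pa <- make_pileup(cover(6))
  pb_reads <- cover(6)
  pb_ev <- data.frame(read = 1:4, chrom = "chr1", pos = 200L,
                      type = "mismatch", alt = "T")
  pb <- make_pileup(pb_reads, pb_ev, clone_id = "cloneB")
  calls <- call_snps(pa, pb)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pos, 200)
  expect_equal(calls$carrier, "cloneB")
  expect_equal(calls$allele_b, "T/ref") # MAF 2/6 = 0.333 keeps both alleles
  # 5 ref + 1 alt: frequency 0.167 below the gate -> no call
  pb2 <- make_pileup(pb_reads,
                     data.frame(read = 1L, chrom = "chr1", pos = 200L,
                                type = "mismatch", alt = "T"),
                     clone_id = "cloneB")
  expect_equal(nrow(call_snps(pa, pb2)), 0)
})

test_that("SNP gates: depth, shared region, quality, deletion sites, depth ceiling", {
  pa <- make_pileup(cover(5)) # depth 5 < 6
  pb <- make_pileup(cover(6),
                    data.frame(read = 1:4, chrom = "chr1", pos = 200L,
                               type = "mismatch", alt = "T"),
                    clone_id = "cloneB")
  expect_equal(nrow(call_snps(pa, pb)), 0)
  pa6 <- make_pileup(cover(6))
  sh_far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000))
  expect_equal(nrow(call_snps(pa6, pb, shared = sh_far)), 0)
  # low-quality supporting reads fail the >60 gate
  rb <- cover(6); rb$mapq <- 40L
  pb_low <- make_pileup(rb, data.frame(read = 1:4, chrom = "chr1", pos = 200L,
                                       type = "mismatch", alt = "T"),
                        clone_id = "cloneB")
  expect_equal(nrow(call_snps(pa6, pb_low)), 0)
  # a deletion allele above the gate defers the site to the indel caller
  pb_del <- make_pileup(cover(6),
                        data.frame(read = 1:6,
                                   chrom = "chr1", pos = 200L,
                                   type = c(rep("del", 3), rep("mismatch", 3)),
                                   len = 2L, alt = c(rep("", 3), rep("T", 3))),
                        clone_id = "cloneB")
  expect_equal(nrow(call_snps(pa6, pb_del)), 0)
  # depth ceiling
  pb_hi <- make_pileup(cover(40),
                       data.frame(read = 1:20, chrom = "chr1", pos = 200L,
                                  type = "mismatch", alt = "T"),
                       clone_id = "cloneB")
  expect_gt(nrow(call_snps(pa6, pb_hi)), 0)
  expect_equal(nrow(call_snps(pa6, pb_hi, max_depth = 20)), 0)
})

test_that("indel calls use only mid-read step-1/2 evidence", {
  pa <- make_pileup(cover(6))
  ev <- data.frame(read = 1:3, chrom = "chr1", pos = 200L, type = "del",
                   len = 3L, alt = "", qdist = 60L)
  pb <- make_pileup(cover(6), ev, clone_id = "cloneB")
  calls <- call_indels(pa, pb)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$len, -3)
  expect_equal(calls$carrier, "cloneB")
  # same evidence from step-3 reads only: excluded
  rb3 <- cover(6, step = 3L)
  ev3 <- ev; ev3$step <- 3L
  pb3 <- make_pileup(rb3, ev3, clone_id = "cloneB")
  expect_equal(nrow(call_indels(pa, pb3)), 0)
  # evidence 5 bp from the read end: discarded
  ev_end <- ev; ev_end$qdist <- 5L
  pb_end <- make_pileup(cover(6), ev_end, clone_id = "cloneB")
  expect_equal(nrow(call_indels(pa, pb_end)), 0)
})

test_that("indel calls in reference homopolymer runs are flagged low-confidence", {
  ref <- c(chr1 = paste0(strrep("A", 190), strrep("T", 10),
                         random_dna(300, 0.5)))
  pa <- make_pileup(cover(6))
  ev <- data.frame(read = 1:4, chrom = "chr1", pos = 195L, type = "ins",
                   len = 1L, alt = "T", qdist = 60L)
  pb <- make_pileup(cover(6), ev, clone_id = "cloneB")
  calls <- call_indels(pa, pb, reference = ref)
  expect_equal(nrow(calls), 1)
  expect_true(calls$low_confidence)
})

test_that("TE insertions require junction support in one clone only", {
  # carrier: 4 junction reads ending at the site + 2 reads ending nearby;
  # other clone: 8 clean spanning reads
  jr <- cover(4, start = 0L, len = 200L)
  jr$junction_pos <- 200; jr$junction_side <- "right"
  jr$te_family <- "Gret1-like"; jr$step <- 2L
  extra <- cover(2, start = 400L, len = 200L) # elsewhere
  carrier <- make_pileup(as.data.frame(data.table::rbindlist(list(jr, extra), fill = TRUE)), clone_id = "cloneA")
  other <- make_pileup(cover(8, start = 0L, len = 400L), clone_id = "cloneB")
  calls <- call_te_insertions(carrier, other)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$carrier, "cloneA")
  expect_lt(abs(calls$pos - 200), 15)
  expect_equal(calls$family, "Gret1-like")
  # ancestral copy: junction reads in both clones -> no call
  jr_b <- jr; other2 <- make_pileup(as.data.frame(data.table::rbindlist(list(jr_b, cover(8, 0L, len = 400L)), fill = TRUE)),
                                    clone_id = "cloneB")
  expect_equal(nrow(call_te_insertions(carrier, other2)), 0)
  # insufficient other-clone depth -> no call
  shallow <- make_pileup(cover(4, start = 0L, len = 400L), clone_id = "cloneB")
  expect_equal(nrow(call_te_insertions(carrier, shallow)), 0)
})

test_that("TE junction fraction uses informative reads only", {
  # 2 junction reads vs 10 clean spanning reads in the carrier: fraction
  # 2/12 < 0.3 -> no call; removing the spanning reads enables the call
  jr <- cover(2, start = 0L, len = 200L)
  jr$junction_pos <- 200; jr$te_family <- "Gret1-like"; jr$step <- 2L
  span <- cover(10, start = 50L, len = 300L)
  other <- make_pileup(cover(8, start = 0L, len = 400L), clone_id = "cloneB")
  mixed <- make_pileup(as.data.frame(data.table::rbindlist(list(jr, span), fill = TRUE)), clone_id = "cloneA")
  expect_equal(nrow(call_te_insertions(mixed, other)), 0)
  clean <- make_pileup(jr, clone_id = "cloneA")
  expect_equal(nrow(call_te_insertions(clean, other)), 1)
})

test_that("pair calling is symmetric up to carrier labels", {
  pr <- fix_small_pair()
  run <- pr$run
  key <- names(run$calls)[1]
  pa <- run$pileups[[1]]; pb <- run$pileups[[2]]
  sh <- run$shared[[key]]
  fwd <- call_pair(pa, pb, sh, reference = run$ancestor)
  rev <- call_pair(pb, pa, sh, reference = run$ancestor)
  keyify <- function(x) sort(paste(x$type, x$chrom, x$pos, x$carrier))
  expect_equal(keyify(fwd), keyify(rev))
})

test_that("rates are per Mb of shared span with gene annotation", {
  calls <- data.frame(type = c(rep("SNP", 7)), chrom = "chr1",
                      pos = seq(1000, 7000, by = 1000),
                      carrier = "a", other = "b", allele_a = "T",
                      allele_b = "ref", depth_a = 6L, depth_b = 6L,
                      maf = 1, qual = 90L, family = NA, len = 0L,
                      low_confidence = FALSE)
  sh <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2e6))
  ann <- data.frame(chrom = "chr1", start = 500, end = 1500, gene_id = "g1")
  ar <- annotate_and_rates(calls, ann, sh)
  expect_equal(ar$rates$per_mb[ar$rates$type == "SNP"], 3.5)
  expect_equal(sum(ar$calls$in_gene), 1)
  expect_equal(ar$calls$gene_id[ar$calls$pos == 1000], "g1")
  # zero calls
  ar0 <- annotate_and_rates(calls[0, ], ann, sh)
  expect_true(all(ar0$rates$per_mb == 0))
  expect_error(annotate_and_rates(calls, ann, GenomicRanges::GRanges()),
               "shared span")
})

test_that("no call falls outside the pair's shared regions", {
  pr <- fix_small_pair()
  run <- pr$run
  key <- names(run$calls)[1]
  calls <- run$calls[[key]]
  sh <- run$shared[[key]]
  pad <- ifelse(calls$type == "TE_INSERTION", 15,
                ifelse(calls$type == "INDEL", 1, 0))
  expect_true(all(somaclone:::in_regions(calls$chrom, calls$pos, sh, pad = pad)))
})
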