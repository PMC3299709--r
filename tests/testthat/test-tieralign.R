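test_that("strict alignment accepts exact reads on either strand at full identity", {
  set.seed(1)
  ref <- random_dna(20000, 0.4)
  idx <- seq_index(c(chr1 = ref))
  read <- substr(ref, 1001, 1355)
  r <- align_single_read(read, idx, "STRICT")
  expect_true(r$accepted)
  expect_equal(r$record$identity, 1)
  expect_equal(r$record$start, 1000)
  expect_equal(r$record$step, 1)
  expect_equal(r$record$mapq, 90)
  r2 <- align_single_read(revcomp(read), idx, "STRICT")
  expect_true(r2$accepted)
  expect_equal(r2$record$start, 1000)
  expect_equal(r2$record$strand, "-")
})

test_that("the 95% identity boundary separates strict from relaxed acceptance", {
  set.seed(2)
  ref <- random_dna(20000, 0.4)
  idx <- seq_index(c(chr1 = ref))
  rd <- substr(ref, 2001, 2100)
  s <- strsplit(rd, "")[[1]]
  pos <- c(10, 25, 40, 55, 70, 85)
  s[pos] <- vapply(s[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  rd6 <- paste(s, collapse = "") # identity 0.94
  r <- align_single_read(rd6, idx, "STRICT")
  expect_false(r$accepted)
  r2 <- align_single_read(rd6, idx, "RELAXED")
  expect_true(r2$accepted)
  expect_equal(r2$record$identity, 0.94, tolerance = 0.011)
})

test_that("reads spanning an exact duplication are rejected as multi-locus", {
  set.seed(3)
  dupseg <- random_dna(2000, 0.4)
  ref <- paste0(random_dna(6000, 0.4), dupseg, random_dna(3000, 0.4), dupseg,
                random_dna(1000, 0.4))
  idx <- seq_index(c(chr1 = ref))
  r <- align_single_read(substr(dupseg, 500, 800), idx, "STRICT")
  expect_false(r$accepted)
  expect_equal(r$reason, "MULTI_LOCUS")
  # exhaustive-scan oracle: two equal-score loci exist
  hits <- gregexpr(substr(dupseg, 500, 800), ref, fixed = TRUE)[[1]]
  expect_equal(length(hits), 2)
})

test_that("indels inside reads produce correct gapped records and events", {
  set.seed(4)
  ref <- random_dna(15000, 0.4)
  idx <- seq_index(c(chr1 = ref))
  base <- substr(ref, 3001, 3360)
  delread <- paste0(substr(base, 1, 180), substr(base, 186, 360))
  r <- align_single_read(delread, idx, "STRICT")
  expect_true(r$accepted)
  expect_equal(r$record$cigar, "180M5D175M")
  insread <- paste0(substr(base, 1, 180), "ACGTA", substr(base, 181, 355))
  r2 <- align_single_read(insread, idx, "STRICT")
  expect_true(r2$accepted)
  expect_equal(r2$record$cigar, "180M5I175M")
})

test_that("mapq is 90 for unique hits, 0 for ties, and monotone in the score gap", {
  expect_equal(mapq_score(300, NA, 300), 90L)
  expect_equal(mapq_score(300, 300, 300), 0L)
  gaps <- seq(0, 300, by = 10)
  q <- mapq_score(300, 300 - gaps, 300)
  expect_true(all(diff(q) >= 0))
  expect_equal(max(q), 90L)
})

test_that("strict decisions match an exhaustive gapless scan oracle", {
  set.seed(6)
  ref <- random_dna(10000, 0.4)
  idx <- seq_index(c(chr1 = ref))
  refi <- utf8ToInt(ref)
  oracle <- function(read, min_id = 0.95, margin_frac = 0.05) {
    m <- nchar(read)
    scores_for <- function(q) {
      qi <- utf8ToInt(q)
      emb <- embed(refi, m)[, m:1, drop = FALSE]
      rowSums(emb == matrix(qi, nrow(emb), m, byrow = TRUE))
    }
    sc <- pmax(scores_for(read), scores_for(revcomp(read)))
    best <- max(sc)
    o <- order(-sc)
    # second-best at a distinct locus
    second <- 0
    for (j in o[-1]) if (abs(j - o[1]) > 30) { second <- sc[j]; break }
    accept <- best / m >= min_id && second < best - margin_frac * m
    list(accept = accept, start = o[1] - 1)
  }
  n_match <- 0
  for (i in 1:40) {
    len <- sample(150:300, 1)
    start <- sample(1000:8000, 1)
    rd <- substr(ref, start, start + len - 1)
    nmut <- sample(c(0, 2, round(0.04 * len), round(0.08 * len)), 1)
    if (nmut > 0) rd <- mutate_seq(rd, nmut / len)
    if (runif(1) < 0.5) rd <- revcomp(rd)
    got <- align_single_read(rd, idx, "STRICT")
    want <- oracle(rd)
    expect_equal(got$accepted, want$accept,
                 info = sprintf("case %d len=%d nmut=%d", i, len, nmut))
    if (got$accepted && want$accept) {
      expect_lt(abs(got$record$start - want$start), 3)
      n_match <- n_match + 1
    }
  }
  expect_gt(n_match, 10) # both accept and reject cases were exercised
})

test_that("tiered alignment partitions every read into exactly one category", {
  pr <- fix_small_pair()
  run <- pr$run
  cid <- run$config$simulate$clones[1]
  aln <- run$alignments[[cid]]
  expect_equal(sum(aln$summary$n), aln$n_reads)
  expect_equal(sum(aln$summary$percent), 100, tolerance = 0.05)
  expect_equal(nrow(aln$classification), aln$n_reads)
  expect_false(anyNA(aln$classification$category))
  aligned_ids <- aln$records$read_id
  cls <- aln$classification
  expect_setequal(cls$read_id[grepl("^ALIGNED", cls$category)], aligned_ids)
})

test_that("error-free reads from a repeat-free genome almost all align at step 1", {
  lib <- fix_library()
  g0 <- build_ancestral_genome(1, 3e5, 0, lib, seed = 8)
  rs <- simulate_reads(g0, 3000, seed = 9, profile = clean_profile())
  aln <- run_tiered_alignment(rs, seq_index(g0$chromosomes), lib)
  s1 <- aln$summary$percent[aln$summary$category == "ALIGNED_STEP1"]
  expect_gte(s1, 99)
})

test_that("error-free unique-region reads land within 2 bp of their origin", {
  lib <- fix_library()
  g0 <- build_ancestral_genome(1, 3e5, 0, lib, seed = 10)
  rs <- simulate_reads(g0, 2000, seed = 11, profile = clean_profile())
  aln <- run_tiered_alignment(rs, seq_index(g0$chromosomes), lib)
  rec <- aln$records
  prov <- rs$provenance[rec$read, ]
  ok <- abs(rec$start - prov$start) <= 2
  expect_gte(mean(ok), 0.95)
  expect_gte(nrow(rec) / n_reads(rs), 0.99)
})

test_that("unaligned reads classify by the documented priority", {
  lib <- fix_library()
  params <- align_params()
  expect_equal(classify_unaligned(random_dna(80), library = lib), "LOW_QUALITY")
  repeat_read <- substr(lib[["Gret1-like"]]$internal_seq, 1, 400)
  expect_equal(classify_unaligned(repeat_read, library = lib), "REPEAT")
  set.seed(13)
  org <- c(chloro = random_dna(20000, 0.37))
  spiked <- mutate_seq(substr(org[[1]], 5001, 5350), 0.02)
  expect_equal(classify_unaligned(spiked, library = lib, organelles = org),
               "CYTOPLASMIC")
  expect_equal(classify_unaligned(random_dna(300, 0.4), library = lib,
                                  multi_locus = TRUE), "PARALOG")
  expect_equal(classify_unaligned(random_dna(300, 0.4), library = lib),
               "UNKNOWN")
})

test_that("a repeat-rich simulation yields the expected repeat and paralog share", {
  pr <- fix_small_pair()
  run <- pr$run
  cid <- run$config$simulate$clones[1]
  s <- run$alignments[[cid]]$summary
  reppar <- sum(s$percent[s$category %in% c("REPEAT", "PARALOG")])
  expect_gt(reppar, 25 - 8)
  expect_lt(reppar, 25 + 8)
})
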