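fake_records <- function(chrom, start, len, seqs = NULL) {
  n <- length(start)
  if (n == 0) return(fake_records("chr1", 0L, 100L)[0, , drop = FALSE])
  len <- rep(len, length.out = n)
  data.frame(read = seq_len(n), read_id = sprintf("r%05d", seq_len(n)),
             chrom = rep(chrom, length.out = n), start = start,
             end = start + len, strand = rep("+", n),
             cigar = paste0(len, "M"), identity = rep(1, n),
             step = rep(1L, n), mapq = rep(90L, n), qlen = len,
             stringsAsFactors = FALSE)
}

test_that("depth counts independent reads and conserves aligned bases", {
  rec <- fake_records("chr1", rep(100L, 6) + 0:5, 355L)
  prof <- depth_profile(rec, c(chr1 = 1000))
  expect_equal(as.integer(prof$coverage$chr1[300]), 6L)
  expect_equal(sum(as.numeric(prof$coverage$chr1)), sum(rec$end - rec$start))
  # zero records
  p0 <- depth_profile(fake_records("chr1", integer(0), integer(0)),
                      c(chr1 = 500))
  expect_equal(sum(as.numeric(p0$coverage$chr1)), 0)
  # duplicates (same start + same length) collapse once
  rec2 <- fake_records("chr1", rep(10L, 4), 100L)
  p2 <- depth_profile(rec2, c(chr1 = 500))
  expect_equal(as.integer(p2$coverage$chr1[50]), 1L)
  expect_equal(sum(p2$independent), 1)
  # out-of-bounds record is an error naming the record
  bad <- fake_records("chr1", 450L, 100L)
  expect_error(depth_profile(bad, c(chr1 = 500)), "r00001")
})

test_that("uniform random placement yields Poisson per-base depth", {
  set.seed(99)
  L <- 1e6; n <- 10000; len <- 355L
  start <- sample.int(L - len, n, replace = TRUE)
  prof <- depth_profile(fake_records("chr1", start, len), c(chr1 = L))
  lambda <- n * len / L
  # depths at positions one read length apart are effectively independent
  pos <- seq(400, L - 400, by = 400)
  d <- as.integer(prof$coverage$chr1[pos])
  brk <- c(-Inf, seq(floor(lambda - 3 * sqrt(lambda)),
                     ceiling(lambda + 3 * sqrt(lambda))), Inf)
  obs <- table(cut(d, brk))
  pr <- diff(ppois(c(-Inf, brk[-c(1, length(brk))], Inf), lambda))
  keep <- pr * length(d) >= 5
  chi <- sum((as.numeric(obs[keep]) - pr[keep] * length(d))^2 /
               (pr[keep] * length(d)))
  p <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("depth-threshold regions are maximal, nested and monotone in k", {
  rec <- fake_records("chr1", rep(0L, 6), 1000L)
  prof <- depth_profile(fake_records("chr1", rep(0L, 6) + 0:5 * 0L, 1000L),
                        c(chr1 = 2000))
  # 6 identical reads collapse to 1; build overlapping distinct reads instead
  rec <- fake_records("chr1", c(0L, 1L, 2L, 3L, 4L, 5L), 1000L)
  prof <- depth_profile(rec, c(chr1 = 2000))
  r6 <- regions_at_depth(prof, 6)
  expect_equal(region_span(r6), 995) # bases covered by all six shifted reads
  r7 <- regions_at_depth(prof, 7)
  expect_equal(region_span(r7), 0)
  # random profile: nesting and monotone span
  set.seed(7)
  rr <- fake_records("chr1", sample.int(4000, 300, TRUE), 150L)
  pr <- depth_profile(rr, c(chr1 = 4200))
  spans <- vapply(1:8, function(k) region_span(regions_at_depth(pr, k)),
                  numeric(1))
  expect_true(all(diff(spans) <= 0))
  for (k in 1:7) {
    a <- regions_at_depth(pr, k); b <- regions_at_depth(pr, k + 1)
    expect_equal(region_span(GenomicRanges::intersect(a, b)), region_span(b))
  }
})

test_that("shared regions equal a per-base boolean-AND oracle", {
  set.seed(11)
  rand_regions <- function() {
    s <- sort(sample.int(900, 8))
    e <- pmin(s + sample.int(60, 8, TRUE), 1000)
    GenomicRanges::reduce(GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e)))
  }
  for (i in 1:30) {
    a <- rand_regions(); b <- rand_regions()
    got <- shared_regions(a, b)
    mask_a <- rep(FALSE, 1000); mask_b <- rep(FALSE, 1000)
    for (j in seq_along(a)) mask_a[GenomicRanges::start(a)[j]:GenomicRanges::end(a)[j]] <- TRUE
    for (j in seq_along(b)) mask_b[GenomicRanges::start(b)[j]:GenomicRanges::end(b)[j]] <- TRUE
    expect_equal(region_span(got), sum(mask_a & mask_b))
    both <- which(mask_a & mask_b)
    got_mask <- rep(FALSE, 1000)
    for (j in seq_along(got)) got_mask[GenomicRanges::start(got)[j]:GenomicRanges::end(got)[j]] <- TRUE
    expect_equal(which(got_mask), both)
  }
  # identical and disjoint cases
  a <- rand_regions()
  expect_equal(region_span(shared_regions(a, a)), region_span(a))
  b2 <- GenomicRanges::shift(a, 2000)
  expect_equal(region_span(shared_regions(a, b2)), 0)
})

test_that("composition statistics match direct string counting", {
  reads <- list(id = paste0("r", 1:1), seq = "GCGC", qual = "IIII")
  rec <- fake_records("chr1", 0L, 4L)
  ann <- data.frame(chrom = "chr1", start = 0, end = 2, gene_id = "g1")
  cs <- composition_stats(rec, reads, c(chr1 = "GCGCAAAA"), ann)
  expect_equal(cs$aligned[cs$statistic == "gc"], 100)
  expect_equal(cs$aligned[cs$statistic == "cpg"], 100 * 1 / 3)
  # direct-count oracle on random reads
  set.seed(21)
  rseqs <- vapply(1:10, function(i) random_dna(sample(50:150, 1), 0.45), "")
  reads2 <- list(id = paste0("r", 1:10), seq = rseqs)
  rec2 <- fake_records("chr1", rep(0L, 10), nchar(rseqs))
  cs2 <- composition_stats(rec2, reads2, c(chr1 = random_dna(2000, 0.45)), ann)
  n <- sum(nchar(rseqs))
  gc <- sum(vapply(rseqs, function(s) lengths(regmatches(s, gregexpr("[GC]", s))), 1))
  cpg <- sum(vapply(rseqs, function(s) {
    sum(substring(s, 1:(nchar(s) - 1), 2:nchar(s)) == "CG")
  }, 1))
  cng <- sum(vapply(rseqs, function(s) {
    tri <- substring(s, 1:(nchar(s) - 2), 3:nchar(s))
    sum(substr(tri, 1, 1) == "C" & substr(tri, 3, 3) == "G")
  }, 1))
  expect_equal(cs2$aligned[1], 100 * gc / n)
  expect_equal(cs2$aligned[2], 100 * cpg / (n - 10))
  expect_equal(cs2$aligned[3], 100 * cng / (n - 20))
})

test_that("aligned reads sampled from the reference reproduce its GC content", {
  g <- fix_genome()
  rs <- simulate_reads(g, 3000, seed = 31, profile = clean_profile())
  rec <- fake_records(rs$provenance$chrom, rs$provenance$start, nchar(rs$seq))
  cs <- composition_stats(rec, rs, g, g$exons)
  expect_lt(abs(cs$aligned[1] - cs$reference[1]), 0.5)
})

test_that("window correlations detect repeat exclusion and ignore uniform noise", {
  set.seed(41)
  # clustered repeats, reads placed only outside them
  L <- 2e6
  reps <- data.frame(chrom = "chr1",
                     start = seq(1e5, 9e5, by = 2e5),
                     end = seq(1e5, 9e5, by = 2e5) + 8e4)
  ok_start <- setdiff(seq(0, L - 400), unlist(mapply(seq, reps$start - 300,
                                                     reps$end, SIMPLIFY = FALSE)))
  rec <- fake_records("chr1", sample(ok_start, 5000, TRUE), 355L)
  wc <- window_correlations(rec, reps, c(chr1 = L))
  expect_lt(wc$window_r, 0)
  expect_lt(wc$window_p, 0.01)
  # uniform reads, uniform scattered repeats: no signal at 200 windows
  L2 <- 2e6
  reps2 <- data.frame(chrom = "chr1", start = seq(5000, L2 - 5000, length.out = 400),
                      end = seq(5000, L2 - 5000, length.out = 400) + 500)
  rec2 <- fake_records("chr1", sample.int(L2 - 400, 8000, TRUE), 355L)
  wc2 <- window_correlations(rec2, reps2, c(chr1 = L2), window = 1e4)
  expect_lt(abs(wc2$window_r), 0.12)
})
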