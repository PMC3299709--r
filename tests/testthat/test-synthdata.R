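test_that("TE library has the focal families with the expected form structure", {
  lib <- fix_library()
  expect_length(lib, 6)
  g <- lib[["Gret1-like"]]
  majors <- Filter(function(v) isTRUE(v$major), g$subfamily_variants)
  expect_length(majors, 4)
  expect_equal(vapply(majors, `[[`, numeric(1), "weight"),
               c(0.25, 0.18, 0.05, 0.03), tolerance = 1e-9)
  for (f in lib) {
    if (length(f$subfamily_variants)) {
      expect_equal(sum(vapply(f$subfamily_variants, `[[`, numeric(1), "weight")), 1)
    }
    expect_gte(nchar(f$internal_seq), 500)
    if (nzchar(f$ltr_seq)) {
      expect_gte(nchar(f$ltr_seq), 100)
      expect_lte(nchar(f$ltr_seq), 1000)
    }
  }
  cl <- lib[["Cauliv1-like"]]
  expect_length(Filter(function(v) isTRUE(v$major), cl$subfamily_variants), 1)
  expect_equal(cl$subfamily_variants[[1]]$weight, 0.07, tolerance = 1e-9)
})

test_that("TE library edge cases: single family, invalid input, determinism", {
  one <- build_te_library(1, seed = 3)
  expect_length(one, 1)
  expect_equal(sum(vapply(one[[1]]$subfamily_variants, `[[`, numeric(1),
                          "weight")), 1)
  expect_error(build_te_library(0), "n_families")
  expect_identical(build_te_library(4, seed = 5), build_te_library(4, seed = 5))
})

test_that("ancestral genome hits its repeat and exon construction targets", {
  g <- fix_genome()
  total <- sum(nchar(g$chromosomes))
  rep_frac <- sum(g$repeats$end - g$repeats$start) / total
  expect_lt(abs(rep_frac - 0.3), 0.02)
  exon_frac <- sum(g$exons$end - g$exons$start) / total
  expect_lt(abs(exon_frac - 0.069), 0.02)
  # repeats within chromosome bounds, exons nested in genes and off repeats
  lens <- setNames(nchar(g$chromosomes), names(g$chromosomes))
  expect_true(all(g$repeats$end <= lens[g$repeats$chrom]))
  expect_true(all(g$exons$start >= 0))
  ex_gr <- GenomicRanges::GRanges(g$exons$chrom,
                                  IRanges::IRanges(g$exons$start + 1, g$exons$end))
  rep_gr <- GenomicRanges::GRanges(g$repeats$chrom,
                                   IRanges::IRanges(g$repeats$start + 1, g$repeats$end))
  expect_equal(sum(IRanges::overlapsAny(ex_gr, rep_gr)), 0)
  gene_gr <- GenomicRanges::GRanges(g$genes$chrom,
                                    IRanges::IRanges(g$genes$start + 1, g$genes$end))
  expect_true(all(IRanges::overlapsAny(ex_gr, gene_gr)))
})

test_that("repeat_fraction 0 produces a repeat-free genome and bounds are enforced", {
  g0 <- build_ancestral_genome(1, 2e5, 0, fix_library(), seed = 2)
  expect_equal(nrow(g0$repeats), 0)
  expect_error(build_ancestral_genome(1, 2e5, 0.7, fix_library()),
               "repeat_fraction")
})

test_that("clone derivation is ledger-determined and reproducible", {
  g <- fix_genome()
  lib <- fix_library()
  dc <- derive_clone(g, 1.6, 5.1, 35.2, lib, seed = 13, clone_id = "c1")
  redo <- apply_ledger(g, dc$ledger, clone_id = "c1")
  expect_identical(redo$chromosomes, dc$genome$chromosomes)
  dc2 <- derive_clone(g, 1.6, 5.1, 35.2, lib, seed = 13, clone_id = "c1")
  expect_identical(dc2$ledger, dc$ledger)
  dc0 <- derive_clone(g, 0, 0, 0, lib, seed = 13)
  expect_identical(dc0$genome$chromosomes, g$chromosomes)
  expect_equal(nrow(dc0$ledger), 0)
  # within-clone separability: no two entries closer than 10 bp
  by_chrom <- split(dc$ledger$pos, dc$ledger$chrom)
  for (p in by_chrom) expect_true(all(diff(sort(p)) >= 10))
  expect_error(derive_clone(g, -1, 0, 0, lib), "rates")
})

test_that("mutation counts follow the configured Poisson rates", {
  g1 <- build_ancestral_genome(1, 1e6, 0.2, fix_library(), seed = 31)
  counts <- t(vapply(1:30, function(r) {
    led <- derive_clone(g1, 1.6, 5.1, 35.2, fix_library(), seed = 100 + r)$ledger
    c(snp = sum(led$type == "SNP"), indel = sum(led$type == "INDEL"),
      te = sum(led$type == "TE_INS"))
  }, numeric(3)))
  mb <- sum(nchar(g1$chromosomes)) / 1e6
  for (i in seq_along(c(1.6, 5.1, 35.2))) {
    lambda <- c(1.6, 5.1, 35.2)[i] * mb
    se <- sqrt(lambda / 30)
    expect_lt(abs(mean(counts[, i]) - lambda), 3 * se)
  }
})

test_that("error-free simulated reads are exact genome substrings with full provenance", {
  g <- fix_genome()
  rs <- simulate_reads(g, 500, seed = 9, profile = clean_profile())
  expect_equal(n_reads(rs), 500)
  expect_true(all(table(rs$provenance$category) == 500)) # all genomic
  ok <- vapply(seq_len(200), function(i) {
    pv <- rs$provenance[i, ]
    src <- substr(g$chromosomes[[pv$chrom]], pv$start + 1,
                  pv$start + nchar(rs$seq[i]))
    rs$seq[i] == src || rs$seq[i] == revcomp(src)
  }, logical(1))
  expect_true(all(ok))
})

test_that("the 454 noise model reproduces run-level QC statistics", {
  g <- fix_genome()
  rs <- simulate_reads(g, 20000, seed = 21, profile = read_profile(),
                       organelles = g$organelles,
                       contaminants = g$contaminants)
  expect_lt(abs(mean(nchar(rs$seq)) - 355), 3)
  dup <- mean(rs$provenance$category == "duplicate")
  expect_lt(abs(dup - 0.0058), 0.002)
  org <- mean(rs$provenance$category == "organelle")
  expect_lt(abs(org - 0.038), 0.006)
  # qualities are valid phred+33 and decay along the read
  q <- utf8ToInt(rs$qual[1])
  expect_true(all(q >= 33 & q <= 74))
  expect_gt(mean(head(q, 50)), mean(tail(q, 50)))
  expect_equal(nrow(rs$provenance), n_reads(rs))
  expect_error(read_profile(dup_frac = 1.5), "fractions")
})

test_that("assembly shearing tiles contigs at the configured fragment size", {
  sheared <- shear_assembly(c(ctg = random_dna(3500)), fragment_len = 1000)
  expect_equal(sort(nchar(sheared$seq)), c(500, 1000, 1000, 1000))
  expect_true(all(strsplit(paste(sheared$qual, collapse = ""), "")[[1]] == "I"))
  expect_equal(n_reads(shear_assembly(c(s = random_dna(80)))), 0)
  ctg2 <- c(a = random_dna(4000))
  expect_equal(sum(nchar(shear_assembly(ctg2, 1000)$seq)), 4000)
  expect_warning(out <- shear_assembly(character(0)), "empty")
  expect_equal(n_reads(out), 0)
  expect_error(shear_assembly(c(a = random_dna(500)), fragment_len = 50),
               "fragment_len")
})
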