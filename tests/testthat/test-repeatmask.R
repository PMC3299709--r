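test_that("exact library copies are masked with the correct family and extent", {
  lib <- fix_library()
  f <- lib[["Gret1-like"]]
  set.seed(5)
  rd <- paste0(random_dna(150, 0.4), substr(f$ltr_seq, 1, 120))
  m <- mask_sequence(rd, lib)
  expect_equal(nrow(m$intervals), 1)
  expect_equal(m$n_masked, 120)
  expect_equal(m$n_unmasked, 150)
  expect_equal(m$intervals$family, "Gret1-like")
  expect_gte(m$intervals$identity, 0.99)
  # no homology: nothing masked
  m0 <- mask_sequence(random_dna(300, 0.4), lib)
  expect_equal(m0$n_masked, 0)
  expect_equal(nrow(m0$intervals), 0)
})

test_that("masking decision agrees with a local-alignment oracle on embedded segments", {
  lib <- fix_library()
  f <- lib[["Copia10-like"]]
  set.seed(17)
  cases <- lapply(1:12, function(i) {
    seg_len <- sample(c(55, 60, 80, 120), 1)
    div <- sample(c(0.03, 0.30), 1) # clearly above / below the 0.8 gate
    seg <- mutate_seq(substr(f$internal_seq, 101, 100 + seg_len), div)
    list(read = paste0(random_dna(120, 0.4), seg, random_dna(120, 0.4)),
         seg = seg, div = div, seg_len = seg_len)
  })
  targets <- somaclone:::mask_targets(lib)
  for (cs in cases) {
    m <- mask_sequence(cs$read, lib)
    # oracle: best local alignment of the read against every library target
    best_id <- 0
    for (tg in targets) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(cs$read), Biostrings::DNAString(tg),
        type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
        gapOpening = 2.5, gapExtension = 0.5)
      w <- Biostrings::nchar(Biostrings::pattern(pa))
      if (w >= 50) {
        idv <- Biostrings::nmatch(pa) / Biostrings::nchar(Biostrings::alignedPattern(pa))
        best_id <- max(best_id, idv)
      }
    }
    expect_equal(m$n_masked >= 50, best_id >= 0.8,
                 info = sprintf("seg_len=%d div=%.2f", cs$seg_len, cs$div))
  }
})

test_that("masking is idempotent on hard-masked sequence", {
  lib <- fix_library()
  f <- lib[["Gret1-like"]]
  rd <- paste0(random_dna(100, 0.4), substr(f$ltr_seq, 1, 150))
  m <- mask_sequence(rd, lib)
  hard <- apply_mask(rd, m$intervals, hard = TRUE)
  m2 <- mask_sequence(hard, lib)
  expect_equal(m2$n_masked, 0)
})

test_that("masked composition classes follow the gate thresholds in order", {
  fake <- data.frame(n_masked = c(120, 99, 270, 0, 49, 100),
                     n_unmasked = c(200, 150, 30, 300, 300, 120))
  expect_equal(masked_composition(fake),
               c("TE_EVIDENCE", "OTHER", "REPEAT_READ",
                 "MOSTLY_UNIQUE", "MOSTLY_UNIQUE", "OTHER"))
  # exact boundary: 150 unmasked + 100 masked qualifies
  expect_equal(masked_composition(data.frame(n_masked = 100, n_unmasked = 150)),
               "TE_EVIDENCE")
})

test_that("reads over clone TE junctions with adequate flanks class as TE evidence", {
  lib <- fix_library()
  set.seed(23)
  n_ok <- 0
  for (i in 1:20) {
    f <- lib[[sample(4, 1)]]
    cp <- somaclone:::te_copy_seq(f, recent = TRUE)
    read <- paste0(random_dna(170, 0.4), substr(cp$seq, 1, 185))
    cls <- masked_composition(mask_sequence(read, lib))
    if (cls == "TE_EVIDENCE") n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 19) # >= 99% in expectation; allow one boundary case
})

test_that("an empty library masks nothing, with a warning", {
  expect_warning(m <- mask_reads(random_dna(200), structure(list(), class = "te_library")),
                 "empty")
  expect_equal(m$summary$n_masked, 0)
})
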