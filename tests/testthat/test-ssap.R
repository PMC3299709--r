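test_that("in-silico banding measures primer-to-site distances within range", {
  lib <- fix_library()
  fam <- lib[["Gret1-like"]]
  primer <- ssap_primer(fam)
  expect_equal(nchar(primer), 20)
  set.seed(3)
  # construct a genome: unique DNA + primer + 180 bp + enzyme site
  flank <- random_dna(5000, 0.4)
  mid <- gsub("GAATTC", "GAATTA", random_dna(180, 0.4), fixed = TRUE)
  g <- c(chr1 = paste0(flank, primer, mid, "GAATTC", random_dna(2000, 0.4)))
  bands <- insilico_ssap(g, fam, primer = primer, enzyme_site = "GAATTC",
                         size_range = c(50, 500))
  expect_true(180 %in% bands)
  # no enzyme site within range -> no band
  g2 <- c(chr1 = paste0(gsub("GAATTC", "GAATTA", random_dna(3000, 0.4)),
                        primer,
                        gsub("GAATTC", "GAATTA", random_dna(800, 0.4))))
  expect_length(insilico_ssap(g2, fam, primer = primer,
                              enzyme_site = "GAATTC",
                              size_range = c(50, 500)), 0)
  expect_error(insilico_ssap(g, fam, enzyme_site = "GAT"), "motif")
})

test_that("a private TE insertion adds a junction band to the clone's pattern", {
  lib <- fix_library()
  anc <- build_ancestral_genome(1, 3e5, 0.15, lib, seed = 51)
  dc <- derive_clone(anc, 0, 0, 20, lib, seed = 53, clone_id = "c1")
  fam <- lib[["Gret1-like"]]
  b_anc <- insilico_ssap(anc, fam, enzyme_site = "TTAA",
                         size_range = c(50, 1500))
  b_cl <- insilico_ssap(dc$genome, fam, enzyme_site = "TTAA",
                        size_range = c(50, 1500))
  ins <- dc$ledger[dc$ledger$type == "TE_INS" &
                     dc$ledger$family == "Gret1-like" &
                     dc$ledger$variant == "LTR1", ]
  if (nrow(ins) > 0) {
    # the primer sits on the dominant form, so each new dominant-form copy
    # contributes at least one new junction band
    expect_gt(length(setdiff(b_cl, b_anc)), 0)
  }
  # with no mutations the pattern is identical
  dc0 <- derive_clone(anc, 0, 0, 0, lib, seed = 54)
  expect_identical(insilico_ssap(dc0$genome, fam, enzyme_site = "TTAA",
                                 size_range = c(50, 1500)), b_anc)
})

test_that("band matrices bin lengths and count polymorphic bands", {
  bm <- band_matrix(list(s1 = c(100, 200), s2 = c(100, 300)))
  expect_equal(ncol(bm), 3)
  expect_equal(attr(bm, "n_polymorphic"), 2)
  expect_equal(attr(bm, "pct_polymorphic"), 200 / 3, tolerance = 1e-6)
  bm2 <- band_matrix(list(a = c(100, 200), b = c(100, 200)))
  expect_equal(attr(bm2, "n_polymorphic"), 0)
  # +/-2 bp co-migration: 100 and 101 merge into one column
  bm3 <- band_matrix(list(a = 100, b = 101))
  expect_equal(ncol(bm3), 1)
  expect_equal(sum(bm3), 2)
  expect_error(band_matrix(list(a = 100)), "2 samples")
})

test_that("the Nei-Li distance matches its closed form and a reference implementation", {
  expect_equal(nei_li_distance(c(1, 1, 0, 1), c(1, 0, 1, 1)), 1 - 4 / 6)
  expect_equal(nei_li_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(nei_li_distance(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_error(nei_li_distance(c(0, 0), c(1, 0)), "zero bands")
  skip_if_not_installed("vegan")
  set.seed(13)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    x <- random_band_row(n); y <- random_band_row(n)
    ours <- nei_li_distance(x, y)
    ref <- as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  # matrix form agrees with the scalar form
  bm <- t(replicate(6, random_band_row(40)))
  rownames(bm) <- paste0("s", 1:6)
  d <- as.matrix(nei_li_matrix(bm))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(d[i, j], nei_li_distance(bm[i, ], bm[j, ]))
  }
})

test_that("neighbor joining recovers the three-taxon closed form", {
  d <- matrix(c(0, 0.2, 0.4, 0.2, 0, 0.4, 0.4, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), (0.2 + 0.4 - 0.4) / 2)
  expect_equal(unname(bl["B"]), 0.1)
  expect_equal(unname(bl["C"]), 0.3)
})

test_that("neighbor joining is exact on additive matrices from random trees", {
  set.seed(29)
  for (i in 1:15) {
    tr <- ape::rtree(6, br = function(n) runif(n, 0.05, 0.5))
    tr <- ape::unroot(tr)
    d <- ape::cophenetic.phylo(tr)
    got <- nj_tree(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(got), tr)), 0)
    expect_equal(max(abs(ape::cophenetic.phylo(got)[rownames(d), colnames(d)] - d)),
                 0, tolerance = 1e-8)
  }
})

test_that("equidistant four-taxon matrices give zero internal branch length", {
  d <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  tr <- nj_tree(d)
  internal <- tr$edge[, 2] > ape::Ntip(tr)
  expect_true(all(abs(tr$edge.length[internal]) < 1e-12))
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap support is 100 for a bipartition present in all replicates", {
  set.seed(31)
  # two tight groups separated by many diagnostic bands
  g1 <- c(rep(1, 30), rep(0, 30), 1)
  g2 <- c(rep(0, 30), rep(1, 30), 1)
  bm <- rbind(a1 = g1, a2 = g1, b1 = g2, b2 = g2)
  bm[2, 1] <- 0; bm[4, 31] <- 0 # minor within-group noise
  tr <- ssap_tree(bm, bootstrap = 200, seed = 5)
  expect_true(any(tr$node.label == 100))
})
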