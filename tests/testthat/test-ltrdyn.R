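test_that("LTR harvest trims and orients read segments on the LTR", {
  lib <- fix_library()
  fam <- lib[["Gret1-like"]]
  set.seed(61)
  ltr <- fam$ltr_seq
  reads <- c(paste0(random_dna(100, 0.4), ltr, random_dna(80, 0.4)),
             paste0(random_dna(90, 0.4), revcomp(substr(ltr, 50, 300))),
             random_dna(400, 0.4))
  segs <- harvest_ltr_segments(reads, fam)
  expect_equal(sort(unique(segs$read)), c(1, 2))
  s1 <- segs[segs$read == 1, ]
  expect_gte(s1$ltr_end - s1$ltr_start, nchar(ltr) - 4)
  expect_equal(s1$seq, substr(ltr, s1$ltr_start + 1, s1$ltr_end))
  s2 <- segs[segs$read == 2, ]
  expect_equal(s2$seq, substr(ltr, s2$ltr_start + 1, s2$ltr_end))
  expect_error(harvest_ltr_segments(reads, lib[["LINE-1"]]), "no LTR")
})

test_that("harvested segment counts per variant follow the copy weights", {
  lib <- fix_library()
  fam <- lib[["Gret1-like"]]
  set.seed(63)
  # draw 400 segments directly from the variant distribution
  w <- vapply(fam$subfamily_variants, `[[`, numeric(1), "weight")
  vs <- sample(seq_along(w), 400, replace = TRUE, prob = w)
  reads <- vapply(vs, function(v) {
    s <- fam$subfamily_variants[[v]]$seq
    a <- sample(1:(nchar(s) - 150), 1)
    substr(s, a, min(a + sample(150:300, 1), nchar(s)))
  }, "")
  segs <- harvest_ltr_segments(reads, fam, min_identity = 0.75)
  # essentially every drawn segment is recovered
  expect_gte(nrow(segs), 0.95 * 400)
})

test_that("greedy clustering separates major forms from the minor pool", {
  lib <- fix_library()
  fam <- lib[["Gret1-like"]]
  ltr <- fam$ltr_seq
  mk_segs <- function(seqs) {
    out <- data.frame(read = seq_along(seqs), seq = seqs,
                      ltr_start = 0L, ltr_end = nchar(seqs),
                      identity = 1, stringsAsFactors = FALSE)
    attr(out, "family") <- fam$name
    attr(out, "ltr_len") <- nchar(ltr)
    class(out) <- c("ltr_segments", "data.frame")
    out
  }
  # 20 identical segments: one major form at proportion 1
  f1 <- cluster_forms(mk_segs(rep(ltr, 20)))
  expect_equal(nrow(f1$summary), 1)
  expect_equal(f1$summary$proportion, 1)
  expect_equal(f1$minor_proportion, 0)
  # 9 + 9 of a 20%-divergent variant: no cluster reaches 10 members
  set.seed(65)
  var <- mutate_seq(ltr, 0.2)
  f2 <- cluster_forms(mk_segs(c(rep(ltr, 9), rep(var, 9))))
  expect_equal(nrow(f2$summary), 0)
  expect_equal(f2$minor_proportion, 1)
  # partition: every segment in exactly one cluster
  expect_equal(sum(vapply(f2$clusters, `[[`, integer(1), "size")), 18)
  # proportions sum to 1
  f3 <- cluster_forms(mk_segs(c(rep(ltr, 15), rep(var, 12), mutate_seq(ltr, 0.25))))
  expect_equal(sum(f3$summary$proportion) + f3$minor_proportion, 1,
               tolerance = 1e-9)
  expect_error(cluster_forms(mk_segs(ltr)[0, ]), "segment")
})

test_that("conserved-region analysis flags recent bursts and builds trees", {
  lib <- fix_library()
  fam <- lib[["Cauliv1-like"]]
  ltr <- fam$ltr_seq
  mk_segs <- function(seqs) {
    out <- data.frame(read = seq_along(seqs), seq = seqs, ltr_start = 0L,
                      ltr_end = nchar(seqs), identity = 1,
                      stringsAsFactors = FALSE)
    attr(out, "family") <- fam$name
    attr(out, "ltr_len") <- nchar(ltr)
    class(out) <- c("ltr_segments", "data.frame")
    out
  }
  set.seed(67)
  # identical copies: activity flag true, star-like tree
  r1 <- conserved_region_tree(mk_segs(rep(ltr, 8)), bootstrap = 20, seed = 1)
  expect_true(r1$recent_activity)
  expect_equal(r1$clique_size, 8)
  expect_true(all(r1$tree$edge.length < 1e-9))
  # mutually divergent copies (pairwise >= 10%): no recent activity
  far <- vapply(1:8, function(i) mutate_seq(ltr, 0.10), "")
  r2 <- conserved_region_tree(mk_segs(far), bootstrap = 20, seed = 1)
  expect_false(r2$recent_activity)
  # fewer than three covering segments: no tree, flag still computed
  r3 <- conserved_region_tree(mk_segs(rep(ltr, 2)), bootstrap = 0)
  expect_null(r3$tree)
  expect_equal(r3$n_covering, 2)
})

test_that("simulated families reproduce the major/minor form structure", {
  pr <- fix_small_pair()
  lib <- pr$run$library
  set.seed(71)
  # study-condition segment pool for the Gret1-like family: 700 segments at
  # the ancestral copy weights, with per-copy divergence
  fam <- lib[["Gret1-like"]]
  w <- vapply(fam$subfamily_variants, `[[`, numeric(1), "weight")
  draw_seg <- function() {
    v <- fam$subfamily_variants[[sample(seq_along(w), 1, prob = w)]]
    s <- if (isTRUE(v$per_copy)) mutate_seq(fam$ltr_seq, v$per_copy_div)
         else mutate_seq(v$seq, v$copy_div)
    a <- sample(1:(nchar(s) - 160), 1)
    substr(s, a, min(a + sample(160:340, 1), nchar(s)))
  }
  reads <- vapply(1:700, function(i) draw_seg(), "")
  segs <- harvest_ltr_segments(reads, fam)
  forms <- cluster_forms(segs)
  expect_equal(nrow(forms$summary), 4)
  expect_lt(abs(sum(forms$summary$proportion) - 0.51), 0.06)
  expect_lt(abs(forms$minor_proportion - 0.49), 0.06)
})
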