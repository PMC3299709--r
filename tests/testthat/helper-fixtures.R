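# Shared fixtures, all generated in code. Expensive simulations are built
# lazily and memoised for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fix_library <- function() memo("library", function() build_te_library(6, seed = 7))

fix_genome <- function() memo("genome", function() {
  build_ancestral_genome(2, c(6e5, 4e5), 0.3, fix_library(), seed = 11)
})

# small two-clone comparison used by several module tests
fix_small_pair <- function() memo("small_pair", function() {
  clone_comparison_experiment(seed = 42, genome_mb = 2, coverage = 12,
                              ltr = FALSE)
})

# the study-scale recovery experiment shared by the acceptance tests
fix_big_pair <- function() memo("big_pair", function() {
  clone_comparison_experiment(seed = 20124, genome_mb = 10, coverage = 12,
                              ltr = TRUE)
})

fix_qc <- function() memo("qc", function() read_qc_experiment(seed = 314))

fix_ssap <- function() memo("ssap", function() ssap_experiment(seed = 2718))

fix_rates <- function() memo("rates", function() {
  rate_recovery_experiment(seed = 161, n_rep = 20)
})

# fabricate a clone_pileup from explicit per-read placements:
# reads: data.frame(chrom, start, len, step, mapq, junction_pos optional,
#   te_family optional); events: data.frame(read, chrom, pos, type, len, alt,
#   qdist, step)
make_pileup <- function(reads, events = NULL, chrom_len = c(chr1 = 10000L),
                        clone_id = "clone") {
  n <- nrow(reads)
  if (is.null(reads$strand)) reads$strand <- "+"
  if (is.null(reads$mapq)) reads$mapq <- 90L
  if (is.null(reads$step)) reads$step <- 1L
  if (is.null(reads$junction_pos)) reads$junction_pos <- NA_real_
  if (is.null(reads$junction_side)) reads$junction_side <- NA_character_
  if (is.null(reads$te_family)) reads$te_family <- NA_character_
  rec <- data.frame(
    read = seq_len(n), read_id = sprintf("%s_r%03d", clone_id, seq_len(n)),
    chrom = reads$chrom, start = reads$start, end = reads$start + reads$len,
    strand = reads$strand, cigar = paste0(reads$len, "M"),
    identity = 1, step = reads$step, best = reads$len, second = NA_real_,
    qlen = reads$len, qoffset = 0L, mask_bp = 0L,
    te_family = reads$te_family, junction_pos = reads$junction_pos,
    junction_side = reads$junction_side, mapq = reads$mapq,
    aln_qlen = reads$len, stringsAsFactors = FALSE)
  ev <- if (is.null(events)) {
    data.table::data.table(read = integer(0), chrom = character(0),
                           pos = integer(0), type = character(0),
                           len = integer(0), alt = character(0),
                           qdist = integer(0), step = integer(0))
  } else {
    if (is.null(events$qdist)) events$qdist <- 50L
    if (is.null(events$step)) events$step <- rec$step[events$read]
    if (is.null(events$len)) events$len <- 1L
    if (is.null(events$alt)) events$alt <- "A"
    data.table::as.data.table(events)
  }
  aln <- list(records = rec, events = ev)
  clone_pileup(aln, chrom_len, clone_id = clone_id, mismatch_cluster_bp = 0)
}

# deterministic random band rows with at least one presence
random_band_row <- function(n, p = 0.5) {
  repeat {
    x <- as.integer(runif(n) < p)
    if (sum(x) > 0) return(x)
  }
}
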