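# 454-style read simulation: truncated-normal read lengths, linear quality
# decay along the read, phred-scaled substitution errors, homopolymer
# run-length errors, EmPCR duplicate reads, organelle/contaminant spikes and
# a small failed-well (short read) fraction; plus in-silico shearing of
# assembly contigs into fixed-size optimal-quality fragments.

#' Read-simulation profile
#'
#' Defaults emulate a 454 GS-FLX run: mean read length 355 (sd 60, truncated
#' to \[60, 700\]), base quality decaying linearly from ~Q34 to ~Q20 along the
#' read, substitution errors at 10^(-Q/10), homopolymer runs >= 3 gaining or
#' losing one base with probability 0.02 per run, 0.58% EmPCR duplicates,
#' 3.8% organelle reads and 0.013% contaminant reads.
#'
#' @param mean_len,sd_len,min_len,max_len read-length model (bp).
#' @param q_start,q_end phred quality at read start / end.
#' @param subst_scale multiplier on the phred-implied substitution rate
#'   (0 disables substitution errors).
#' @param homopoly_rate per-run probability of a homopolymer length error.
#' @param dup_frac fraction of reads that are exact duplicates.
#' @param organelle_frac,contaminant_frac spike-in fractions.
#' @param short_frac fraction of degraded short (40--99 bp) reads
#'   (default 0: the truncated-normal length model governs every read).
#' @return list of class `read_profile`.
#' @export
read_profile <- function(mean_len = 355, sd_len = 60, min_len = 60,
                         max_len = 700, q_start = 34, q_end = 20,
                         subst_scale = 1, homopoly_rate = 0.02,
                         dup_frac = 0.0058, organelle_frac = 0.038,
                         contaminant_frac = 1.3e-4, short_frac = 0) {
  p <- list(mean_len = mean_len, sd_len = sd_len, min_len = min_len,
            max_len = max_len, q_start = q_start, q_end = q_end,
            subst_scale = subst_scale, homopoly_rate = homopoly_rate,
            dup_frac = dup_frac, organelle_frac = organelle_frac,
            contaminant_frac = contaminant_frac, short_frac = short_frac)
  fr <- c(p$homopoly_rate, p$dup_frac, p$organelle_frac, p$contaminant_frac,
          p$short_frac)
  if (any(fr < 0 | fr > 1)) stop("profile fractions must be in [0, 1]")
  structure(p, class = "read_profile")
}

#' Error-free read profile
#'
#' Convenience wrapper: no substitution/homopolymer errors, no duplicates, no
#' spikes, no short reads. Used for ledger-recovery experiments where the
#' truth must be unambiguous.
#'
#' @param ... overrides passed to [read_profile()].
#' @export
clean_profile <- function(...) {
  read_profile(subst_scale = 0, homopoly_rate = 0, dup_frac = 0,
               organelle_frac = 0, contaminant_frac = 0, short_frac = 0, ...)
}

#' Simulate a 454-style read set from a genome
#'
#' @param genome a `clone_genome`, `ancestral_genome` or named character
#'   vector of chromosome sequences.
#' @param n_reads number of reads.
#' @param seed RNG seed.
#' @param profile a [read_profile()].
#' @param organelles,contaminants named character vectors of spike-in source
#'   sequences (required when the corresponding fractions are > 0).
#' @return An object of class `read_set`: `id`, `seq`, `qual` (character
#'   vectors) and `provenance` (data.frame with clone_id, chrom, start
#'   (0-based on the source genome), strand, category).
#' @export
simulate_reads <- function(genome, n_reads, seed = 1L,
                           profile = read_profile(),
                           organelles = NULL, contaminants = NULL) {
  stopifnot(n_reads >= 1)
  seqs <- genome_seqs(genome)
  clone_id <- if (inherits(genome, "clone_genome")) genome$clone_id else "genome"
  if (profile$organelle_frac > 0 && is.null(organelles))
    stop("organelle_frac > 0 but no organelle sequences supplied")
  if (profile$contaminant_frac > 0 && is.null(contaminants))
    stop("contaminant_frac > 0 but no contaminant sequences supplied")
  with_seed(seed, {
    cat_prob <- c(genomic = 1 - profile$organelle_frac - profile$contaminant_frac,
                  organelle = profile$organelle_frac,
                  contaminant = profile$contaminant_frac)
    category <- sample(names(cat_prob), n_reads, replace = TRUE, prob = cat_prob)
    lens <- round(rnorm(n_reads, profile$mean_len, profile$sd_len))
    lens <- pmin(pmax(lens, profile$min_len), profile$max_len)
    short <- runif(n_reads) < profile$short_frac
    lens[short] <- sample(40:99, sum(short), replace = TRUE)

    src_seqs <- list(genomic = seqs, organelle = organelles,
                     contaminant = contaminants)
    chrom <- character(n_reads); start <- integer(n_reads)
    for (cat in unique(category)) {
      ii <- which(category == cat)
      pool <- src_seqs[[cat]]
      pl <- nchar(pool)
      ci <- sample.int(length(pool), length(ii), replace = TRUE, prob = pl)
      lens[ii] <- pmin(lens[ii], pl[ci] - 1)
      chrom[ii] <- names(pool)[ci]
      start[ii] <- floor(runif(length(ii)) * (pl[ci] - lens[ii])) # 0-based
    }
    seq_pool <- c(seqs, organelles, contaminants)
    reads <- character(n_reads)
    for (cn in unique(chrom)) {
      ii <- which(chrom == cn)
      reads[ii] <- substring(seq_pool[[cn]], start[ii] + 1, start[ii] + lens[ii])
    }
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    neg <- strand == "-"
    if (any(neg)) reads[neg] <- cpp_revcomp(reads[neg])
    # 454 error model (uses the current RNG stream)
    err <- cpp_apply_454(reads, profile$q_start, profile$q_end,
                         profile$subst_scale, profile$homopoly_rate)
    reads <- as.character(err$seq); quals <- as.character(err$qual)
    # EmPCR duplicates: replace a fraction of reads by copies of earlier reads
    dup <- runif(n_reads) < profile$dup_frac
    dup[1] <- FALSE
    for (i in which(dup)) {
      j <- sample.int(i - 1L, 1)
      reads[i] <- reads[j]; quals[i] <- quals[j]
      chrom[i] <- chrom[j]; start[i] <- start[j]; strand[i] <- strand[j]
      category[i] <- "duplicate"
    }
    ids <- sprintf("%s_r%07d", clone_id, seq_len(n_reads))
    structure(
      list(id = ids, seq = reads, qual = quals,
           provenance = data.frame(read_id = ids, clone_id = clone_id,
                                   chrom = chrom, start = start,
                                   strand = strand, category = category,
                                   stringsAsFactors = FALSE)),
      class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads, mean length %.1f\n", length(x$id),
              mean(nchar(x$seq))))
  print(table(x$provenance$category))
  invisible(x)
}

#' Number of reads in a read set
#' @param x a `read_set`.
#' @export
n_reads <- function(x) length(x$id)

#' Concatenate read sets
#' @param ... `read_set` objects.
#' @export
combine_read_sets <- function(...) {
  sets <- list(...)
  structure(
    list(id = unlist(lapply(sets, `[[`, "id"), use.names = FALSE),
         seq = unlist(lapply(sets, `[[`, "seq"), use.names = FALSE),
         qual = unlist(lapply(sets, `[[`, "qual"), use.names = FALSE),
         provenance = do.call(rbind, lapply(sets, `[[`, "provenance"))),
    class = "read_set")
}

#' Subsample a read set
#' @param x a `read_set`; @param n number of reads to keep; @param seed seed.
#' @export
subsample_reads <- function(x, n, seed = 1L) {
  n <- min(n, n_reads(x))
  keep <- with_seed(seed, sample.int(n_reads(x), n))
  structure(list(id = x$id[keep], seq = x$seq[keep], qual = x$qual[keep],
                 provenance = x$provenance[keep, , drop = FALSE]),
            class = "read_set")
}

#' Shear assembly contigs into pseudo-reads
#'
#' Contigs are tiled into non-overlapping fragments of `fragment_len`; a final
#' partial fragment is kept when it is at least 100 bp. Every base is given
#' the optimal quality symbol, emulating assembly-derived sequence treated as
#' read data.
#'
#' @param assembly named character vector of contig sequences (or a genome
#'   object).
#' @param fragment_len fragment size in bp (>= 100).
#' @param sample_id label recorded in provenance.
#' @return A `read_set` with category "genomic".
#' @export
shear_assembly <- function(assembly, fragment_len = 1000L, sample_id = "assembly") {
  if (fragment_len < 100) stop("fragment_len must be >= 100")
  seqs <- genome_seqs(assembly)
  seqs <- seqs[nchar(seqs) > 0]
  if (length(seqs) == 0) {
    warning("empty assembly: returning an empty read set")
    return(structure(list(id = character(0), seq = character(0),
                          qual = character(0),
                          provenance = data.frame(read_id = character(0),
                                                  clone_id = character(0),
                                                  chrom = character(0),
                                                  start = integer(0),
                                                  strand = character(0),
                                                  category = character(0))),
                     class = "read_set"))
  }
  frag_chrom <- character(0); frag_start <- integer(0); frag_seq <- character(0)
  for (cn in names(seqs)) {
    L <- nchar(seqs[[cn]])
    starts <- seq(0, max(L - 1, 0), by = fragment_len)
    ends <- pmin(starts + fragment_len, L)
    keep <- (ends - starts) >= 100
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) next
    frag_chrom <- c(frag_chrom, rep(cn, length(starts)))
    frag_start <- c(frag_start, starts)
    frag_seq <- c(frag_seq, substring(seqs[[cn]], starts + 1, ends))
  }
  ids <- sprintf("%s_f%06d", sample_id, seq_along(frag_seq))
  n <- length(ids)
  structure(
    list(id = ids, seq = frag_seq,
         qual = strrep("I", nchar(frag_seq)),
         provenance = data.frame(read_id = ids,
                                 clone_id = rep(sample_id, n),
                                 chrom = frag_chrom, start = frag_start,
                                 strand = rep("+", n),
                                 category = rep("genomic", n),
                                 stringsAsFactors = FALSE)),
    class = "read_set")
}

#' Write a read set as FASTQ (phred+33)
#'
#' @param reads a `read_set`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ path.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(x))
  structure(
    list(id = ids, seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities),
         provenance = data.frame(read_id = ids, clone_id = NA_character_,
                                 chrom = NA_character_, start = NA_integer_,
                                 strand = NA_character_,
                                 category = NA_character_,
                                 stringsAsFactors = FALSE)),
    class = "read_set")
}
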