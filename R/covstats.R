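# Depth profiles, coverage-tier regions, shared-region intersection and the
# composition / correlation statistics used to check that aligned reads are a
# representative sample of the genome.

#' Per-base depth profile from alignment records
#'
#' Counts distinct (independent) reads covering each base: duplicate reads
#' (identical sequence placed at the same position) are collapsed to one.
#'
#' @param records alignment records (data.frame from
#'   [run_tiered_alignment()]).
#' @param reference `seq_index`, genome object or named lengths giving
#'   chromosome sizes.
#' @param seqs optional character vector of read sequences (indexed by
#'   `records$read`); when given, duplicate collapse keys on the sequence as
#'   well as the position.
#' @return Object of class `depth_profile`: list of integer [S4Vectors::Rle]
#'   coverage vectors per chromosome, plus `total_aligned`,
#'   `independent` (logical per record).
#' @export
depth_profile <- function(records, reference, seqs = NULL) {
  lens <- chrom_lengths(reference)
  if (is.null(records) || nrow(records) == 0) {
    cov <- lapply(lens, function(L) S4Vectors::Rle(0L, L))
    return(structure(list(coverage = cov, lengths = lens, total_aligned = 0,
                          independent = logical(0)),
                     class = "depth_profile"))
  }
  bad <- records$end > lens[records$chrom] | records$start < 0
  if (any(bad, na.rm = TRUE))
    stop("record beyond chromosome end: ",
         paste(records$read_id[which(bad)[1]], collapse = ", "))
  key <- paste(records$chrom, records$start, records$strand,
               if (!is.null(seqs)) seqs[records$read] else records$qlen)
  independent <- !duplicated(key)
  ri <- records[independent, , drop = FALSE]
  cov <- lapply(names(lens), function(cn) {
    sub <- ri[ri$chrom == cn, , drop = FALSE]
    if (!nrow(sub)) return(S4Vectors::Rle(0L, lens[[cn]]))
    IRanges::coverage(IRanges::IRanges(sub$start + 1, sub$end),
                      width = lens[[cn]])
  })
  names(cov) <- names(lens)
  structure(list(coverage = cov, lengths = lens,
                 total_aligned = sum(ri$end - ri$start),
                 independent = independent),
            class = "depth_profile")
}

chrom_lengths <- function(reference) {
  if (inherits(reference, "depth_profile")) return(reference$lengths)
  if (inherits(reference, "seq_index"))
    return(setNames(reference$lengths, reference$names))
  if (is.numeric(reference)) {
    if (is.null(names(reference))) stop("chromosome lengths must be named")
    return(reference)
  }
  s <- genome_seqs(reference)
  setNames(nchar(s), names(s))
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile: %d chromosome(s), %.2f Mb aligned bases, mean depth %.2f\n",
              length(x$coverage), x$total_aligned / 1e6,
              x$total_aligned / sum(unlist(x$lengths))))
  invisible(x)
}

#' Regions at or above a depth threshold
#'
#' @param profile a [depth_profile()].
#' @param k minimum depth (>= 1).
#' @return `GRanges` of maximal runs with depth >= k (0 metadata); use
#'   [region_span()] for the total width.
#' @export
regions_at_depth <- function(profile, k) {
  stopifnot(k >= 1)
  grl <- lapply(names(profile$coverage), function(cn) {
    ir <- IRanges::reduce(as(profile$coverage[[cn]] >= k, "IRanges"))
    if (!length(ir)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(cn, ir)
  })
  out <- suppressWarnings(do.call(c, grl))
  GenomicRanges::sort(out)
}

#' Intersection of two region sets
#'
#' @param a,b `GRanges` region sets on the same reference.
#' @return `GRanges` intersection (disjoint, sorted).
#' @export
shared_regions <- function(a, b) {
  GenomicRanges::intersect(a, b, ignore.strand = TRUE)
}

#' Total span of a region set in bp
#' @param x `GRanges`.
#' @export
region_span <- function(x) sum(as.numeric(GenomicRanges::width(x)))

#' Composition statistics of aligned reads
#'
#' GC, CpG and CnG content of the aligned read sequences and the fraction of
#' aligned bases overlapping annotated exons; the same statistics are also
#' reported for the reference for comparison.
#'
#' @param records alignment records.
#' @param reads the `read_set` the records refer to.
#' @param reference genome object / named sequences.
#' @param annotation data.frame of exon intervals (chrom, start, end; 0-based
#'   half-open), e.g. `ancestor$exons`.
#' @return data.frame with rows gc, cpg, cng, exon and columns `aligned`,
#'   `reference` (all percentages).
#' @export
composition_stats <- function(records, reads, reference, annotation) {
  seqs <- reads$seq[records$read]
  comp_of <- function(x) {
    ss <- Biostrings::DNAStringSet(x)
    n <- sum(Biostrings::width(ss))
    mono <- colSums(Biostrings::letterFrequency(ss, c("G", "C")))
    di <- sum(Biostrings::vcountPattern("CG", ss, fixed = TRUE))
    tri <- colSums(Biostrings::trinucleotideFrequency(ss))
    cng <- sum(tri[c("CAG", "CCG", "CGG", "CTG")])
    k <- length(x)
    c(gc = 100 * sum(mono) / n,
      cpg = 100 * di / (n - k),
      cng = 100 * cng / (n - 2 * k))
  }
  aligned <- comp_of(seqs)
  refseqs <- genome_seqs(reference)
  refc <- comp_of(unname(refseqs))
  ex <- GenomicRanges::reduce(GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(annotation$start + 1, annotation$end)))
  rec_gr <- GenomicRanges::GRanges(records$chrom,
                                   IRanges::IRanges(records$start + 1, records$end))
  ov <- GenomicRanges::intersect(ex, GenomicRanges::reduce(rec_gr),
                                 ignore.strand = TRUE)
  # exon share of aligned bases, weighting multi-covered bases by depth
  hits <- IRanges::findOverlaps(rec_gr, ex)
  inter <- IRanges::pintersect(rec_gr[S4Vectors::queryHits(hits)],
                               ex[S4Vectors::subjectHits(hits)])
  exon_aligned <- sum(as.numeric(GenomicRanges::width(inter)))
  total_aligned <- sum(as.numeric(records$end - records$start))
  lens <- nchar(refseqs)
  exon_ref <- region_span(ex)
  data.frame(
    statistic = c("gc", "cpg", "cng", "exon"),
    aligned = c(aligned, 100 * exon_aligned / total_aligned),
    reference = c(refc, 100 * exon_ref / sum(lens)),
    row.names = NULL)
}

#' Window-level coverage/repeat correlation and chromosome-length fit
#'
#' Splits the genome into fixed windows and correlates per-window aligned-read
#' counts with per-window repeat-annotated bases (Pearson, with p-value);
#' additionally regresses per-chromosome aligned bases on chromosome length
#' and reports the R-squared.
#'
#' @param records alignment records.
#' @param repeats repeat annotation data.frame (chrom, start, end; 0-based).
#' @param reference genome / lengths.
#' @param window window size in bp (>= 10 kb).
#' @return list: `window_r`, `window_p`, `chrom_r2`, `windows` (data.frame).
#' @export
window_correlations <- function(records, repeats, reference, window = 1e5) {
  if (window < 1e4) stop("window must be >= 10 kb")
  lens <- chrom_lengths(reference)
  rows <- list()
  for (cn in names(lens)) {
    L <- lens[[cn]]
    # full-size windows only: a short terminal window has both few reads and
    # few repeat bases and would bias the correlation
    breaks <- seq(0, L, by = window)
    if (length(breaks) < 2) next
    nb <- length(breaks) - 1
    sub <- records[records$chrom == cn, , drop = FALSE]
    cnt <- if (nrow(sub)) tabulate(findInterval(sub$start, breaks,
                                                rightmost.closed = TRUE), nb)
           else rep(0L, nb)
    rsub <- repeats[repeats$chrom == cn, , drop = FALSE]
    repbp <- rep(0, nb)
    if (nrow(rsub)) {
      cov <- IRanges::coverage(IRanges::IRanges(rsub$start + 1, rsub$end),
                               width = L)
      v <- IRanges::viewSums(IRanges::Views(cov, start = breaks[-length(breaks)] + 1,
                                            end = breaks[-1]))
      repbp <- as.numeric(v)
    }
    rows[[cn]] <- data.frame(chrom = cn, win_start = breaks[-length(breaks)],
                             reads = cnt, repeat_bp = repbp)
  }
  win <- do.call(rbind, rows)
  ct <- cor.test(win$reads, win$repeat_bp, method = "pearson")
  per_chrom <- data.frame(
    chrom = names(lens), length = as.numeric(lens),
    aligned = vapply(names(lens), function(cn) {
      sub <- records[records$chrom == cn, , drop = FALSE]
      sum(as.numeric(sub$end - sub$start))
    }, numeric(1)))
  r2 <- if (nrow(per_chrom) >= 3) summary(lm(aligned ~ length, per_chrom))$r.squared
        else NA_real_
  list(window_r = unname(ct$estimate), window_p = ct$p.value,
       chrom_r2 = r2, windows = win, per_chrom = per_chrom)
}

#' Export a depth profile as bedGraph
#'
#' @param profile [depth_profile()].
#' @param path output path.
#' @export
write_bedgraph <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cn in names(profile$coverage)) {
    r <- profile$coverage[[cn]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0, head(ends, -1))
    vals <- S4Vectors::runValue(r)
    writeLines(sprintf("%s\t%d\t%d\t%d", cn, starts, ends, vals), con)
  }
  invisible(path)
}
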