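# Pairwise clone comparison: coverage-gated calling of SNPs, indels and
# TE-insertion polymorphisms inside >= 6x shared regions.
#
# Calls are rule-gated, not probabilistic: a site is eligible when both clones
# have >= 6 independent reads, an allele is real when it reaches >= 0.3
# frequency within its clone, and the locus must carry an alignment quality
# score above 60. Indel evidence is restricted to step-1/2 reads away from
# read ends; TE insertions are located by the masked-segment boundary of
# repeat/unique junction reads.

#' Build a clone pileup from a tiered alignment
#'
#' Collapses duplicate reads, keeps per-record metadata (step, mapq, junction
#' annotation) and per-base depth, and filters events down to independent
#' reads.
#'
#' @param aln a `tiered_alignment`.
#' @param reference reference genome / `seq_index` / named lengths.
#' @param reads the `read_set` aligned (used for duplicate collapse).
#' @param clone_id label.
#' @param mismatch_cluster_bp drop mismatch evidence within this distance of
#'   another event on the same read (misalignment screen; 0 disables).
#' @return Object of class `clone_pileup`.
#' @export
clone_pileup <- function(aln, reference, reads = NULL, clone_id = "clone",
                         mismatch_cluster_bp = 5) {
  prof <- depth_profile(aln$records, reference,
                        seqs = if (!is.null(reads)) reads$seq else NULL)
  rec <- aln$records
  rec$independent <- prof$independent
  # fresh data.table: events may arrive as a serialized or plain data.frame
  ev <- data.table::as.data.table(aln$events)
  if (nrow(ev)) {
    keep_reads <- rec$read[rec$independent]
    ev <- ev[ev$read %in% keep_reads]
    m <- match(ev$read, rec$read)
    ev$mapq <- rec$mapq[m]
    # mismatches clustered with other events on the same read are a
    # misalignment signature (unaligned junction tails, gap-smeared relaxed
    # alignments), not substitution evidence: drop them
    if (mismatch_cluster_bp > 0 && nrow(ev)) {
      mm <- ev$type == "mismatch"
      if (any(mm)) {
        sub <- data.table::copy(ev)
        data.table::setorder(sub, read, pos)
        d <- diff(sub$pos)
        same <- sub$read[-1] == sub$read[-nrow(sub)]
        close_next <- c(same & d <= mismatch_cluster_bp, FALSE)
        close_prev <- c(FALSE, same & d <= mismatch_cluster_bp)
        near <- close_next | close_prev
        drop_key <- paste(sub$read, sub$pos)[near & sub$type == "mismatch"]
        ev <- ev[!(mm & paste(ev$read, ev$pos) %in% drop_key)]
      }
    }
    # relaxed (step 3) alignments are placed with near-free gaps and can
    # scatter spurious substitutions; their mismatch evidence only counts
    # when a step-1/2 read shows the same allele at the same site
    if (nrow(ev)) {
      mm <- ev$type == "mismatch"
      if (any(mm & ev$step == 3L)) {
        key12 <- unique(paste(ev$chrom, ev$pos, ev$alt)[mm & ev$step < 3L])
        drop <- mm & ev$step == 3L &
          !(paste(ev$chrom, ev$pos, ev$alt) %in% key12)
        ev <- ev[!drop]
      }
    }
  } else {
    ev$mapq <- integer(0)
  }
  structure(list(clone_id = clone_id, records = rec, events = ev,
                 depth = prof),
            class = "clone_pileup")
}

#' @export
print.clone_pileup <- function(x, ...) {
  cat(sprintf("clone_pileup '%s': %d records (%d independent), %d events\n",
              x$clone_id, nrow(x$records), sum(x$records$independent),
              nrow(x$events)))
  invisible(x)
}

depth_at <- function(pile, chrom, pos) {
  # pos 0-based
  mapply(function(cn, p) {
    r <- pile$depth$coverage[[cn]]
    if (is.null(r) || p < 0 || p >= length(r)) return(0L)
    as.integer(r[p + 1])
  }, chrom, pos)
}

#' Allele counts at a site
#'
#' @param pile `clone_pileup`.
#' @param chrom chromosome; @param pos 0-based position.
#' @return Named counts A/C/G/T/del and total depth.
#' @export
site_alleles <- function(pile, chrom, pos) {
  cn <- chrom; p <- as.integer(pos)
  d <- depth_at(pile, cn, p)
  ev <- pile$events
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, del = 0L)
  if (nrow(ev)) {
    mm <- ev[chrom == cn & type == "mismatch" & pos == p]
    if (nrow(mm)) {
      tb <- table(mm$alt)
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
    }
    dl <- ev[chrom == cn & type == "del" & pos <= p & (pos + len) > p]
    counts["del"] <- nrow(dl)
  }
  ref_n <- max(d - sum(counts), 0L)
  list(counts = counts, depth = d, ref_count = ref_n)
}

# maximum mapq among independent records covering a site, per pileup
max_qual_at <- function(piles, chrom, pos) {
  max_qual_sites(piles, chrom, pos)
}

# vectorised over sites: best mapq among covering independent records of any
# pileup (0 where uncovered)
max_qual_sites <- function(piles, chrom, pos) {
  out <- rep(0L, length(pos))
  if (!length(pos)) return(out)
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1))
  for (p in piles) {
    rec <- p$records[p$records$independent, , drop = FALSE]
    if (!nrow(rec)) next
    rg <- GenomicRanges::GRanges(rec$chrom, IRanges::IRanges(rec$start + 1, rec$end))
    hits <- GenomicRanges::findOverlaps(sites, rg)
    if (!length(hits)) next
    qh <- rec$mapq[S4Vectors::subjectHits(hits)]
    agg <- tapply(qh, S4Vectors::queryHits(hits), max)
    idx <- as.integer(names(agg))
    out[idx] <- pmax(out[idx], as.integer(agg))
  }
  out
}

in_regions <- function(chrom, pos, regions, pad = 0) {
  if (is.null(regions)) return(rep(TRUE, length(pos)))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(pmax(pos - pad, 0) + 1, pos + pad + 1))
  IRanges::overlapsAny(gr, regions, ignore.strand = TRUE)
}

empty_calls <- function() {
  data.frame(type = character(0), chrom = character(0), pos = numeric(0),
             carrier = character(0), other = character(0),
             allele_a = character(0), allele_b = character(0),
             depth_a = integer(0), depth_b = integer(0), maf = numeric(0),
             qual = integer(0), family = character(0), len = integer(0),
             low_confidence = logical(0), stringsAsFactors = FALSE)
}

# per-clone mismatch allele summaries at candidate sites (independent reads)
mismatch_site_table <- function(pile) {
  ev <- pile$events
  if (!nrow(ev)) return(data.table::data.table(chrom = character(0),
                                               pos = integer(0),
                                               alt = character(0), n = integer(0),
                                               q = integer(0)))
  mm <- ev[ev$type == "mismatch"]
  if (!nrow(mm)) return(data.table::data.table(chrom = character(0),
                                               pos = integer(0),
                                               alt = character(0), n = integer(0),
                                               q = integer(0)))
  mm[, .(n = .N, q = max(mapq)), by = .(chrom, pos, alt)]
}

#' Call SNPs between two clone pileups
#'
#' At each candidate site the allele set of a clone is the set of bases
#' reaching the minor-allele-frequency gate among its independent reads; a SNP
#' is emitted where the two allele sets differ and the depth / quality gates
#' pass. Sites where a deletion allele passes the frequency gate in either
#' clone are left to the indel caller.
#'
#' @param pile_a,pile_b `clone_pileup` objects on the same reference.
#' @param shared `GRanges` of call-eligible (>= min_depth in both clones)
#'   regions, or `NULL` to skip the region gate.
#' @param min_depth minimum independent-read depth per clone (6).
#' @param min_maf minimum within-clone allele frequency (0.3).
#' @param min_qual minimum (exclusive) alignment quality score (60).
#' @param max_depth optional depth ceiling per clone: sites piling far above
#'   the expected coverage indicate collapsed paralogous copies and are
#'   skipped (`Inf` disables).
#' @return data.frame of calls (positions 0-based in `pos`).
#' @export
call_snps <- function(pile_a, pile_b, shared = NULL, min_depth = 6,
                      min_maf = 0.3, min_qual = 60, max_depth = Inf) {
  ta <- mismatch_site_table(pile_a)
  tb <- mismatch_site_table(pile_b)
  # a divergent allele needs >= min_maf * min_depth supporting reads, so
  # sites where every alt is a singleton can be skipped up front
  floor_n <- max(ceiling(min_maf * min_depth), 1)
  sites <- unique(data.table::rbindlist(list(ta[n >= floor_n, .(chrom, pos)],
                                             tb[n >= floor_n, .(chrom, pos)])))
  if (!nrow(sites)) return(empty_calls())
  sites <- sites[in_regions(sites$chrom, sites$pos, shared)]
  if (!nrow(sites)) return(empty_calls())
  # the quality gate applies to the reads supplying the divergent-allele
  # evidence, not to any read that happens to span the site
  qtab <- data.table::rbindlist(list(ta, tb))[, .(q = max(q)), by = .(chrom, pos)]
  sites <- qtab[sites, on = c("chrom", "pos")]
  out <- list()
  for (i in seq_len(nrow(sites))) {
    cn <- sites$chrom[i]; p <- sites$pos[i]
    aa <- site_alleles(pile_a, cn, p)
    ab <- site_alleles(pile_b, cn, p)
    if (aa$depth < min_depth || ab$depth < min_depth) next
    if (aa$depth > max_depth || ab$depth > max_depth) next
    fa <- c(aa$counts[1:4], ref = aa$ref_count) / aa$depth
    fb <- c(ab$counts[1:4], ref = ab$ref_count) / ab$depth
    if (aa$counts["del"] / aa$depth >= min_maf ||
        ab$counts["del"] / ab$depth >= min_maf) next
    set_a <- names(fa)[fa >= min_maf]
    set_b <- names(fb)[fb >= min_maf]
    if (!length(set_a) || !length(set_b)) next
    if (setequal(set_a, set_b)) next
    q <- sites$q[i]
    if (is.na(q) || q <= min_qual) next
    # carrier = the clone holding a private non-reference allele (the
    # reference allele cannot mark a carrier); tie-break on clone id so the
    # A/B and B/A comparisons agree
    priv_a <- setdiff(setdiff(set_a, set_b), "ref")
    priv_b <- setdiff(setdiff(set_b, set_a), "ref")
    carrier_is_a <- if (length(priv_a) && !length(priv_b)) TRUE
      else if (!length(priv_a) && length(priv_b)) FALSE
      else pile_a$clone_id <= pile_b$clone_id
    minor_freq <- min(c(fa[fa >= min_maf], fb[fb >= min_maf]))
    out[[length(out) + 1]] <- data.frame(
      type = "SNP", chrom = cn, pos = p,
      carrier = if (carrier_is_a) pile_a$clone_id else pile_b$clone_id,
      other = if (carrier_is_a) pile_b$clone_id else pile_a$clone_id,
      allele_a = paste(sort(set_a), collapse = "/"),
      allele_b = paste(sort(set_b), collapse = "/"),
      depth_a = aa$depth, depth_b = ab$depth, maf = minor_freq,
      qual = q, family = NA_character_, len = 0L, low_confidence = FALSE,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_calls())
  do.call(rbind, out)
}

indel_site_table <- function(pile, end_margin) {
  ev <- pile$events
  if (!nrow(ev)) return(data.table::data.table(chrom = character(0),
                                               pos = integer(0), type = character(0),
                                               len = integer(0), n = integer(0),
                                               q = integer(0)))
  id <- ev[ev$type %in% c("ins", "del") & ev$step %in% c(1L, 2L) &
             ev$qdist >= end_margin]
  if (!nrow(id)) return(data.table::data.table(chrom = character(0),
                                               pos = integer(0), type = character(0),
                                               len = integer(0), n = integer(0),
                                               q = integer(0)))
  id[, .(n = .N, q = max(mapq)), by = .(chrom, pos, type, len)]
}

#' Call indel polymorphisms between two clone pileups
#'
#' Indel evidence is counted only from step-1/step-2 reads in which the indel
#' lies at least `end_margin` bp from both ends of the aligned read; reads
#' aligned at the relaxed third step are never used. The same depth / MAF /
#' quality gates as for SNPs apply. Calls whose site sits in a reference
#' homopolymer run >= `homopolymer_len` are flagged low-confidence (the
#' classic pyrosequencing artefact mode).
#'
#' @inheritParams call_snps
#' @param end_margin read-terminal exclusion zone in bp (20).
#' @param reference reference genome (for the homopolymer screen); optional.
#' @param homopolymer_len run length (>= bp) triggering the flag.
#' @return data.frame of calls (`pos` 0-based; `len` signed: + insertion).
#' @export
call_indels <- function(pile_a, pile_b, shared = NULL, min_depth = 6,
                        min_maf = 0.3, min_qual = 60, end_margin = 20,
                        reference = NULL, homopolymer_len = 6,
                        max_depth = Inf) {
  ta <- indel_site_table(pile_a, end_margin)
  tb <- indel_site_table(pile_b, end_margin)
  floor_n <- max(ceiling(min_maf * min_depth), 1)
  keys <- unique(data.table::rbindlist(list(ta[n >= floor_n, .(chrom, pos, type, len)],
                                            tb[n >= floor_n, .(chrom, pos, type, len)])))
  if (!nrow(keys)) return(empty_calls())
  # an indel sits on the junction between two reference bases, and aligners
  # may normalise its position by one base; the region gate therefore tests
  # the one-base-padded site window
  keys <- keys[in_regions(keys$chrom, keys$pos, shared, pad = 1)]
  if (!nrow(keys)) return(empty_calls())
  refseqs <- if (!is.null(reference)) genome_seqs(reference) else NULL
  qtab <- data.table::rbindlist(list(ta, tb))[, .(q = max(q)),
                                              by = .(chrom, pos, type, len)]
  keys <- qtab[keys, on = c("chrom", "pos", "type", "len")]
  out <- list()
  for (i in seq_len(nrow(keys))) {
    cn <- keys$chrom[i]; p <- keys$pos[i]
    ty <- keys$type[i]; ln <- keys$len[i]
    na <- ta[chrom == cn & pos == p & type == ty & len == ln, sum(n)]
    nb <- tb[chrom == cn & pos == p & type == ty & len == ln, sum(n)]
    # junction depth: an indel representation can shift by one base
    # (left/right normalisation), and every informative read spans the whole
    # ambiguity interval, so the deepest base of [p-1, p+1] carries the
    # independent-read count at the junction
    flank <- function(pile) max(depth_at(pile, cn, max(p - 1, 0)),
                                depth_at(pile, cn, p),
                                depth_at(pile, cn, p + 1))
    da <- flank(pile_a)
    db <- flank(pile_b)
    if (da < min_depth || db < min_depth) next
    if (da > max_depth || db > max_depth) next
    fa <- na / da; fb <- nb / db
    in_a <- fa >= min_maf; in_b <- fb >= min_maf
    if (in_a == in_b) next
    q <- keys$q[i]
    if (is.na(q) || q <= min_qual) next
    lowc <- FALSE
    if (!is.null(refseqs)) {
      ctx <- substr(refseqs[[cn]], max(p - homopolymer_len, 0) + 1,
                    p + homopolymer_len + 1)
      runs <- rle(strsplit(ctx, "")[[1]])
      lowc <- any(runs$lengths >= homopolymer_len)
    }
    out[[length(out) + 1]] <- data.frame(
      type = "INDEL", chrom = cn, pos = p,
      carrier = if (in_a) pile_a$clone_id else pile_b$clone_id,
      other = if (in_a) pile_b$clone_id else pile_a$clone_id,
      allele_a = ty, allele_b = ty,
      depth_a = da, depth_b = db, maf = max(fa, fb), qual = q,
      family = NA_character_,
      len = if (ty == "ins") ln else -ln,
      low_confidence = lowc, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_calls())
  do.call(rbind, out)
}

# junction clusters for one carrier pileup: data.frame site, n_support,
# family, side mix, max qual
junction_clusters <- function(pile, cluster_bp) {
  rec <- pile$records[pile$records$independent &
                        !is.na(pile$records$junction_pos), , drop = FALSE]
  if (!nrow(rec)) return(NULL)
  rec <- rec[order(rec$chrom, rec$junction_pos), , drop = FALSE]
  grp <- cumsum(c(1, diff(rec$junction_pos) > cluster_bp |
                    rec$chrom[-1] != rec$chrom[-nrow(rec)]))
  sp <- split(rec, grp)
  do.call(rbind, lapply(sp, function(s) {
    fam <- names(sort(table(s$te_family), decreasing = TRUE))[1]
    data.frame(chrom = s$chrom[1], site = round(median(s$junction_pos)),
               n_support = nrow(s), family = fam, qual = max(s$mapq),
               stringsAsFactors = FALSE)
  }))
}

# independent records of `pile` fully spanning each [site - pad, site + pad]
# window (vectorised over sites)
n_clean_spanning <- function(pile, chrom, site, pad) {
  rec <- pile$records[pile$records$independent &
                        is.na(pile$records$junction_pos), , drop = FALSE]
  if (!nrow(rec)) return(rep(0L, length(site)))
  win <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(pmax(site - pad, 0) + 1, site + pad))
  rg <- GenomicRanges::GRanges(rec$chrom, IRanges::IRanges(rec$start + 1, rec$end))
  suppressWarnings(GenomicRanges::countOverlaps(win, rg, type = "within"))
}

n_junctions_near <- function(pile, chrom, site, pad) {
  rec <- pile$records[pile$records$independent &
                        !is.na(pile$records$junction_pos), , drop = FALSE]
  if (!nrow(rec)) return(rep(0L, length(site)))
  win <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(pmax(site - pad, 0) + 1, site + pad))
  jp <- GenomicRanges::GRanges(rec$chrom,
                               IRanges::IRanges(rec$junction_pos + 1, rec$junction_pos + 1))
  suppressWarnings(GenomicRanges::countOverlaps(win, jp))
}

#' Call TE-insertion polymorphisms between two clone pileups
#'
#' Junction reads (repeat/unique straddlers aligned by their unmasked
#' portion) vote for an insertion site; nearby junctions within
#' `cluster_bp` collapse to one site. A site is called in a carrier clone
#' when junction reads make up at least `min_frac` of that clone's
#' informative reads at the site (junction reads plus reads cleanly spanning
#' the site window - reads merely ending nearby are uninformative), the other
#' clone has >= `min_depth` spanning coverage with no junction reads in the
#' window, and the quality gate passes. Run in both directions to obtain both
#' carriers.
#'
#' @inheritParams call_snps
#' @param cluster_bp junction clustering radius (15 bp).
#' @param min_frac minimum junction-read fraction among informative reads.
#' @return data.frame of calls; `family` is the inserted element family,
#'   `maf` the junction-read fraction.
#' @export
call_te_insertions <- function(pile_a, pile_b, shared = NULL, min_depth = 6,
                               min_frac = 0.3, min_qual = 60, cluster_bp = 15) {
  call_dir <- function(carrier, other) {
    cl <- junction_clusters(carrier, cluster_bp)
    if (is.null(cl)) return(empty_calls())
    # the junction itself sits in the carrier's local coverage dip, so the
    # region gate is evaluated on the site window, not the exact base
    cl <- cl[in_regions(cl$chrom, cl$site, shared, pad = cluster_bp), , drop = FALSE]
    if (!nrow(cl)) return(empty_calls())
    span_clean <- n_clean_spanning(carrier, cl$chrom, cl$site, cluster_bp)
    frac <- cl$n_support / (cl$n_support + span_clean)
    other_junc <- n_junctions_near(other, cl$chrom, cl$site, cluster_bp)
    d_other <- pmin(depth_at(other, cl$chrom, pmax(cl$site - 1, 0)),
                    depth_at(other, cl$chrom, cl$site))
    keep <- frac >= min_frac & other_junc == 0 & d_other >= min_depth &
      cl$qual > min_qual
    if (!any(keep)) return(empty_calls())
    data.frame(
      type = "TE_INSERTION", chrom = cl$chrom[keep], pos = cl$site[keep],
      carrier = carrier$clone_id, other = other$clone_id,
      allele_a = "insertion", allele_b = "ref",
      depth_a = (cl$n_support + span_clean)[keep], depth_b = d_other[keep],
      maf = frac[keep], qual = cl$qual[keep], family = cl$family[keep],
      len = NA_integer_, low_confidence = FALSE, stringsAsFactors = FALSE)
  }
  rbind(call_dir(pile_a, pile_b), call_dir(pile_b, pile_a))
}

#' Call all polymorphism types between a clone pair
#'
#' @inheritParams call_snps
#' @param reference reference genome (homopolymer screen).
#' @param end_margin,cluster_bp see [call_indels()] / [call_te_insertions()].
#' @return data.frame of all calls.
#' @export
call_pair <- function(pile_a, pile_b, shared = NULL, reference = NULL,
                      min_depth = 6, min_maf = 0.3, min_qual = 60,
                      end_margin = 20, cluster_bp = 15, max_depth = Inf) {
  rbind(
    call_snps(pile_a, pile_b, shared, min_depth, min_maf, min_qual,
              max_depth = max_depth),
    call_indels(pile_a, pile_b, shared, min_depth, min_maf, min_qual,
                end_margin, reference, max_depth = max_depth),
    call_te_insertions(pile_a, pile_b, shared, min_depth, min_maf, min_qual,
                       cluster_bp))
}

#' Annotate calls with gene overlap and compute per-Mb rates
#'
#' @param calls data.frame of calls.
#' @param annotation gene intervals (chrom, start, end, gene_id; 0-based).
#' @param shared `GRanges` of the pair's call-eligible regions.
#' @return list: `calls` (with in_gene, gene_id), `rates` (per type: count,
#'   per_mb, in_gene, in_gene_per_mb), `shared_mb`.
#' @export
annotate_and_rates <- function(calls, annotation, shared) {
  mb <- region_span(shared) / 1e6
  if (mb <= 0) stop("shared span must be > 0")
  if (nrow(calls)) {
    gr <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos + 1, calls$pos + 1))
    genes <- GenomicRanges::GRanges(
      annotation$chrom, IRanges::IRanges(annotation$start + 1, annotation$end),
      gene_id = annotation$gene_id)
    hit <- GenomicRanges::findOverlaps(gr, genes, select = "first")
    calls$in_gene <- !is.na(hit)
    calls$gene_id <- ifelse(is.na(hit), NA_character_,
                            annotation$gene_id[hit])
  } else {
    calls$in_gene <- logical(0); calls$gene_id <- character(0)
  }
  types <- c("SNP", "INDEL", "TE_INSERTION")
  rates <- do.call(rbind, lapply(types, function(ty) {
    sub <- calls[calls$type == ty, , drop = FALSE]
    data.frame(type = ty, count = nrow(sub), per_mb = nrow(sub) / mb,
               in_gene = sum(sub$in_gene), in_gene_per_mb = sum(sub$in_gene) / mb)
  }))
  list(calls = calls, rates = rates, shared_mb = mb)
}
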