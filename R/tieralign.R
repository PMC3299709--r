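# Three-step tiered alignment with full read classification.
#
# Step 1 (STRICT): whole-read seed-and-extend, accept at identity >= 0.95 on a
# single locus (second-best score must trail by a margin). Step 2 (MASKED):
# strict-rejected reads are repeat-masked; if >= 150 contiguous unmasked bases
# remain, that unique segment is aligned under strict rules, and an adjacent
# masked segment >= 100 bp marks the read as TE-junction evidence. Step 3
# (RELAXED): remaining reads are aligned whole with a near-zero gap-open
# penalty, accepted at identity >= 0.90. Unaligned reads are classified as
# LOW_QUALITY / REPEAT / PARALOG / CYTOPLASMIC / CONTAMINANT / UNKNOWN,
# in that priority order.

#' Alignment parameter set
#'
#' @param strict_min_id,relaxed_min_id acceptance identities for steps 1/2 and
#'   step 3.
#' @param margin_frac unique-locus margin: the second-best score must be below
#'   best - `margin_frac` * read length.
#' @param strict_band,relaxed_band DP band half-widths.
#' @param strict_gap_open,strict_gap_ext,relaxed_gap_open,relaxed_gap_ext
#'   affine gap penalties (match = +1, mismatch = -1); the relaxed step uses a
#'   minimal gap-open of 0.1 with per-base extension penalties.
#' @param min_len,min_qual read floor: length >= 100 bp and mean quality >= Q20.
#' @param mask_min_id,mask_min_len repeat-masking thresholds.
#' @param unmasked_min minimum contiguous unmasked bases for step 2 (150).
#' @param te_masked_min minimum adjacent masked bases for TE-junction evidence
#'   (100).
#' @param repeat_frac masked fraction above which an unaligned read is a
#'   repeat read (0.9).
#' @param organelle_min_id identity for cytoplasmic/contaminant assignment.
#' @param seed_step query seed stride for the aligner.
#' @param n_candidates candidate loci evaluated per read; must comfortably
#'   exceed the copy number of near-identical repeat lineages so competing
#'   placements are seen and scored.
#' @return list of class `align_params`.
#' @export
align_params <- function(strict_min_id = 0.95, relaxed_min_id = 0.90,
                         margin_frac = 0.05, strict_band = 12L,
                         relaxed_band = 30L, strict_gap_open = 6,
                         strict_gap_ext = 1, relaxed_gap_open = 0.1,
                         relaxed_gap_ext = 0.5, min_len = 100L, min_qual = 20,
                         mask_min_id = 0.8, mask_min_len = 50L,
                         unmasked_min = 150L, te_masked_min = 100L,
                         repeat_frac = 0.9, organelle_min_id = 0.9,
                         seed_step = 5L, n_candidates = 24L) {
  structure(as.list(environment()), class = "align_params")
}

#' Alignment quality score (0--90)
#'
#' Phred-style uniqueness score: `min(90, round(90 * 10 * (best - second) /
#' (10 * read_len)))`, i.e. scaled score gap per base; a unique hit with no
#' second candidate scores 90, a tie scores 0.
#'
#' @param best,second best and second-best alignment scores (matched bases);
#'   `second` may be `NA` when no second candidate exists.
#' @param read_len read length.
#' @return Integer vector of scores in \[0, 90\].
#' @export
mapq_score <- function(best, second, read_len) {
  stopifnot(all(best >= second | is.na(second)))
  q <- ifelse(is.na(second), 90,
              pmin(90, round(10 * (best - second) / read_len * 9)))
  as.integer(pmax(q, 0))
}

mean_qual <- function(qual) {
  vapply(qual, function(q) {
    if (!nzchar(q)) return(0)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

# run cpp_map_reads and shape the result into records + events data.tables
map_batch <- function(seqs, index, min_id, params, band, gap_open, gap_ext) {
  cpp_map_reads(index$ptr, seqs, min_id, params$margin_frac,
                as.integer(band), gap_open, gap_ext,
                as.integer(params$seed_step),
                as.integer(params$n_candidates), 512L)
}

#' Align a single read against a reference
#'
#' One-read convenience wrapper over the tiered machinery, mostly for
#' interactive use and tests.
#'
#' @param read read sequence (single string).
#' @param reference `seq_index` (or sequences to index).
#' @param mode "STRICT", "MASKED" or "RELAXED".
#' @param library TE library (required for mode "MASKED").
#' @param params [align_params()].
#' @return A list: either `list(accepted = TRUE, record = <1-row data.frame>)`
#'   or `list(accepted = FALSE, reason = "NO_HIT"|"MULTI_LOCUS"|"TOO_MASKED")`.
#' @export
align_single_read <- function(read, reference, mode = c("STRICT", "MASKED", "RELAXED"),
                              library = NULL, params = align_params()) {
  mode <- match.arg(mode)
  index <- as_seq_index(reference)
  offset <- 0L
  qlen_full <- nchar(read)
  seg <- read
  if (mode == "MASKED") {
    if (is.null(library)) stop("mode MASKED requires a repeat library")
    m <- mask_sequence(read, library, params$mask_min_id, params$mask_min_len)
    run <- longest_unmasked_run(m$intervals, nchar(read))
    if (is.null(run) || run[2] - run[1] < params$unmasked_min)
      return(list(accepted = FALSE, reason = "TOO_MASKED"))
    offset <- run[1]
    seg <- substr(read, run[1] + 1, run[2])
  }
  strictish <- mode != "RELAXED"
  res <- map_batch(seg, index,
                   if (strictish) params$strict_min_id else params$relaxed_min_id,
                   params,
                   if (strictish) params$strict_band else params$relaxed_band,
                   if (strictish) params$strict_gap_open else params$relaxed_gap_open,
                   if (strictish) params$strict_gap_ext else params$relaxed_gap_ext)
  if (res$status[1] == 1L) return(list(accepted = FALSE, reason = "NO_HIT"))
  if (res$status[1] == 2L) return(list(accepted = FALSE, reason = "MULTI_LOCUS"))
  step <- switch(mode, STRICT = 1L, MASKED = 2L, RELAXED = 3L)
  rec <- data.frame(
    read_id = "read1", chrom = index$names[res$chrom[1]], start = res$start[1],
    end = res$start[1] + res$ref_span[1], strand = res$strand[1],
    cigar = res$cigar[1], identity = res$identity[1], step = step,
    mapq = mapq_score(res$best[1], res$second[1], nchar(seg)),
    n_loci = res$n_loci[1], qlen = qlen_full, qoffset = offset,
    stringsAsFactors = FALSE)
  list(accepted = TRUE, record = rec)
}

# longest gap between mask intervals; returns c(start, end) or NULL
longest_unmasked_run <- function(intervals, len) {
  comp <- interval_complement(intervals$start, intervals$end, len)
  if (!nrow(comp)) return(NULL)
  i <- which.max(comp$end - comp$start)
  c(comp$start[i], comp$end[i])
}

#' Run the full three-step tiered alignment
#'
#' @param reads a `read_set`.
#' @param reference `seq_index` over the reference genome (or sequences).
#' @param library TE library for masking (or `mask_index`).
#' @param organelles,contaminants named character vectors of organelle /
#'   contaminant reference sequences (optional; used for classification).
#' @param params [align_params()].
#' @return list of class `tiered_alignment`:
#'   * `records`: one row per aligned read (read_id, chrom, start, end,
#'     strand, cigar, identity, step, mapq, qlen, qoffset, mask_bp,
#'     te_family, junction_pos, junction_side, read (index into `reads`));
#'   * `events`: per-record mismatch/indel events (read (index), chrom, pos,
#'     type in mismatch/ins/del, len, alt, qdist = distance of the event from
#'     the nearer end of the full read, step);
#'   * `classification`: read_id, category for every read;
#'   * `summary`: category percentages in the layout of a run-summary table.
#' @export
run_tiered_alignment <- function(reads, reference, library,
                                 organelles = NULL, contaminants = NULL,
                                 params = align_params()) {
  index <- as_seq_index(reference)
  nr <- n_reads(reads)
  qlen <- nchar(reads$seq)
  category <- rep(NA_character_, nr)

  # read floor: too short or low mean quality
  mq <- mean_qual(reads$qual)
  low <- qlen < params$min_len | mq < params$min_qual
  category[low] <- "LOW_QUALITY"
  todo <- which(!low)

  # ---- step 1: STRICT on whole reads
  s1 <- map_batch(reads$seq[todo], index, params$strict_min_id, params,
                  params$strict_band, params$strict_gap_open, params$strict_gap_ext)
  acc1 <- s1$status == 0L
  multi1 <- s1$status == 2L
  rec1 <- build_records(s1, todo, acc1, index, reads, step = 1L, offset0 = NULL)
  category[todo[acc1]] <- "ALIGNED_STEP1"

  # ---- step 2: mask strict-rejected reads, align longest unmasked run.
  # Reads that are >= repeat_frac masked are repeat reads and skip further
  # alignment; multi-locus reads still get a masked-alignment attempt (their
  # unique flank may align and carry TE-junction evidence) but are otherwise
  # paralogs and skip the relaxed step.
  rej <- todo[!acc1]
  rec2 <- NULL
  mask_sum <- NULL
  repeat_read <- rep(FALSE, nr)
  if (length(rej)) {
    mr <- mask_reads(reads$seq[rej], library, params$mask_min_id,
                     params$mask_min_len)
    mask_sum <- mr$summary
    repeat_read[rej] <- mask_sum$n_masked >= params$repeat_frac * mask_sum$length
    runs <- unmasked_runs(mr$hits, qlen[rej])
    eligible <- which(runs$len >= params$unmasked_min & mask_sum$n_masked > 0 &
                        !repeat_read[rej])
    if (length(eligible)) {
      segs <- substring(reads$seq[rej[eligible]], runs$start[eligible] + 1,
                        runs$end[eligible])
      s2 <- map_batch(segs, index, params$strict_min_id, params,
                      params$strict_band, params$strict_gap_open,
                      params$strict_gap_ext)
      acc2 <- s2$status == 0L
      rec2 <- build_records(s2, rej[eligible], acc2, index, reads, step = 2L,
                            offset0 = runs$start[eligible])
      if (!is.null(rec2)) {
        rec2$records <- annotate_junctions(rec2$records, mr$hits,
                                           match(rec2$records$read, rej),
                                           qlen, params)
      }
      category[rej[eligible][acc2]] <- "ALIGNED_STEP2"
      multi2 <- logical(length(rej)); multi2[eligible] <- s2$status == 2L
    } else multi2 <- logical(length(rej))
  } else multi2 <- logical(0)

  is_multi <- rep(FALSE, nr)
  is_multi[todo] <- multi1
  if (length(rej)) is_multi[rej] <- is_multi[rej] | multi2

  # ---- step 3: RELAXED on remaining non-repeat, non-paralog reads
  rej3 <- which(is.na(category) & !repeat_read & !is_multi)
  rec3 <- NULL
  if (length(rej3)) {
    s3 <- map_batch(reads$seq[rej3], index, params$relaxed_min_id, params,
                    params$relaxed_band, params$relaxed_gap_open,
                    params$relaxed_gap_ext)
    acc3 <- s3$status == 0L
    is_multi[rej3] <- is_multi[rej3] | s3$status == 2L
    rec3 <- build_records(s3, rej3, acc3, index, reads, step = 3L, offset0 = NULL)
    category[rej3[acc3]] <- "ALIGNED_STEP3"
  }

  # ---- classify unaligned reads
  un <- which(is.na(category))
  if (length(un)) {
    category[un[repeat_read[un]]] <- "REPEAT"
    un <- which(is.na(category))
    category[un[is_multi[un]]] <- "PARALOG"
    un <- which(is.na(category))
    if (length(un) && !is.null(organelles)) {
      hit <- identity_hits(reads$seq[un], organelles, params)
      category[un[hit]] <- "CYTOPLASMIC"
      un <- which(is.na(category))
    }
    if (length(un) && !is.null(contaminants)) {
      hit <- identity_hits(reads$seq[un], contaminants, params)
      category[un[hit]] <- "CONTAMINANT"
      un <- which(is.na(category))
    }
    category[un] <- "UNKNOWN"
  }

  records <- do.call(rbind, c(list(rec1$records),
                              if (!is.null(rec2)) list(rec2$records),
                              if (!is.null(rec3)) list(rec3$records)))
  events <- data.table::rbindlist(c(list(rec1$events),
                                    if (!is.null(rec2)) list(rec2$events),
                                    if (!is.null(rec3)) list(rec3$events)))
  if (!is.null(records)) {
    records <- records[order(records$chrom, records$start), , drop = FALSE]
    rownames(records) <- NULL
  }
  lv <- c("ALIGNED_STEP1", "ALIGNED_STEP2", "ALIGNED_STEP3", "REPEAT",
          "PARALOG", "CYTOPLASMIC", "UNKNOWN", "CONTAMINANT", "LOW_QUALITY")
  tab <- table(factor(category, levels = lv))
  summary <- data.frame(category = lv, n = as.integer(tab),
                        percent = round(100 * as.integer(tab) / nr, 2))
  structure(
    list(records = records, events = events,
         classification = data.frame(read_id = reads$id, category = category,
                                     stringsAsFactors = FALSE),
         summary = summary, n_reads = nr),
    class = "tiered_alignment")
}

#' @export
print.tiered_alignment <- function(x, ...) {
  cat(sprintf("tiered_alignment: %d reads\n", x$n_reads))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# shape a cpp_map_reads result into records + events for accepted reads
build_records <- function(res, read_idx, accepted, index, reads, step, offset0) {
  if (!any(accepted)) return(NULL)
  ai <- which(accepted)
  glob <- read_idx[ai]
  offs <- if (is.null(offset0)) rep(0L, length(ai)) else as.integer(offset0[ai])
  qlen_full <- nchar(reads$seq[glob])
  records <- data.frame(
    read = glob,
    read_id = reads$id[glob],
    chrom = index$names[res$chrom[ai]],
    start = res$start[ai],
    end = res$start[ai] + res$ref_span[ai],
    strand = res$strand[ai],
    cigar = res$cigar[ai],
    identity = res$identity[ai],
    step = step,
    best = res$best[ai],
    second = res$second[ai],
    qlen = qlen_full,
    qoffset = offs,
    mask_bp = 0L,
    te_family = NA_character_,
    junction_pos = NA_real_,
    junction_side = NA_character_,
    stringsAsFactors = FALSE)
  # mapq based on the aligned segment length
  aln_qlen <- if (is.null(offset0)) qlen_full else
    vapply(res$cigar[ai], cigar_query_len, integer(1), USE.NAMES = FALSE)
  records$mapq <- mapq_score(res$best[ai], res$second[ai], aln_qlen)
  records$aln_qlen <- aln_qlen
  ev <- res$events
  events <- NULL
  if (length(ev$read)) {
    keep <- ev$read %in% ai
    if (any(keep)) {
      eread_local <- ev$read[keep]
      m <- match(eread_local, ai)
      evlen <- ev$len[keep]
      # distance from the nearer end of the aligned segment (orientation-
      # invariant; equals full-read distance for whole-read alignments)
      seg_len <- aln_qlen[m]
      consumed <- ifelse(ev$type[keep] == 3L, 0L, evlen)
      qdist <- pmin(ev$qpos[keep], seg_len - (ev$qpos[keep] + consumed))
      events <- data.table::data.table(
        read = glob[m],
        chrom = index$names[res$chrom[eread_local]],
        pos = ev$refpos[keep],
        type = c("mismatch", "ins", "del")[ev$type[keep]],
        len = evlen,
        alt = ev$alt[keep],
        qdist = as.integer(qdist),
        step = step)
    }
  }
  if (is.null(events))
    events <- data.table::data.table(read = integer(0), chrom = character(0),
                                     pos = integer(0), type = character(0),
                                     len = integer(0), alt = character(0),
                                     qdist = integer(0), step = integer(0))
  list(records = records, events = events)
}

cigar_query_len <- function(cigar) {
  if (is.na(cigar)) return(NA_integer_)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  as.integer(sum(lens[ops %in% c("M", "I")]))
}

# longest unmasked run per sequence given merged mask hits
unmasked_runs <- function(hits, lens) {
  n <- length(lens)
  start <- integer(n); end <- as.integer(lens)
  if (nrow(hits)) {
    dt <- data.table::as.data.table(hits)
    dt$len_total <- lens[dt$seq]
    data.table::setorder(dt, seq, start)
    runs <- dt[, {
      gs <- c(0L, end)
      ge <- c(start, len_total[1])
      i <- which.max(ge - gs)
      list(rs = gs[i], re = ge[i])
    }, by = seq]
    start[runs$seq] <- runs$rs
    end[runs$seq] <- runs$re
  }
  data.frame(start = start, end = end, len = pmax(end - start, 0L))
}

# attach TE junction annotation to step-2 records: an adjacent masked segment
# >= te_masked_min next to the aligned unmasked run marks a junction read;
# the junction reference coordinate is the run boundary on that side.
annotate_junctions <- function(records, mask_hits, rej_local, qlen, params) {
  if (is.null(records) || !nrow(records)) return(records)
  sp <- split(mask_hits, mask_hits$seq)
  for (i in seq_len(nrow(records))) {
    li <- rej_local[i]
    hits <- sp[[as.character(li)]]
    if (is.null(hits)) next
    q0 <- records$qoffset[i]
    q1 <- q0 + records$aln_qlen[i] # query end of aligned run (approx. for indels)
    full <- records$qlen[i]
    records$mask_bp[i] <- sum(hits$end - hits$start)
    # masked segment immediately left / right of the run (within 10 bp)
    leftm <- hits[hits$end >= q0 - 10 & hits$start < q0, , drop = FALSE]
    rightm <- hits[hits$start <= q1 + 10 & hits$end > q1, , drop = FALSE]
    lbp <- if (nrow(leftm)) max(leftm$end - leftm$start) else 0
    rbp <- if (nrow(rightm)) max(rightm$end - rightm$start) else 0
    if (max(lbp, rbp) < params$te_masked_min) next
    if (records$aln_qlen[i] < params$unmasked_min) next
    side_query <- if (lbp >= rbp) "left" else "right"
    seg <- if (side_query == "left") leftm[which.max(leftm$end - leftm$start), ]
           else rightm[which.max(rightm$end - rightm$start), ]
    # map query side to reference side through strand
    plus <- records$strand[i] == "+"
    ref_side <- if ((side_query == "left") == plus) "left" else "right"
    records$junction_pos[i] <- if (ref_side == "left") records$start[i] else records$end[i]
    records$junction_side[i] <- ref_side
    records$te_family[i] <- seg$family
  }
  records
}

# TRUE for sequences matching any target at >= organelle_min_id identity
identity_hits <- function(seqs, targets, params) {
  idx <- seq_index(targets, k = 13L, step = 2L)
  res <- cpp_map_reads(idx$ptr, seqs, params$organelle_min_id, 0, 16L,
                       2.5, 0.5, as.integer(params$seed_step), 8L, 512L)
  res$status != 1L & !is.na(res$identity) & res$identity >= params$organelle_min_id
}

#' Classify a single unaligned read
#'
#' Priority: LOW_QUALITY (short/low-quality) > REPEAT (>= 90% masked) >
#' PARALOG (multi-locus) > CYTOPLASMIC > CONTAMINANT > UNKNOWN.
#'
#' @param read read sequence.
#' @param qual quality string (optional).
#' @param library TE library.
#' @param multi_locus logical: was any alignment step rejected as MULTI_LOCUS?
#' @param organelles,contaminants reference sequence sets (optional).
#' @param params [align_params()].
#' @return Single category string.
#' @export
classify_unaligned <- function(read, qual = NULL, library = NULL,
                               multi_locus = FALSE, organelles = NULL,
                               contaminants = NULL, params = align_params()) {
  if (nchar(read) < params$min_len ||
      (!is.null(qual) && mean_qual(qual) < params$min_qual))
    return("LOW_QUALITY")
  if (!is.null(library)) {
    m <- mask_sequence(read, library, params$mask_min_id, params$mask_min_len)
    if (m$n_masked >= params$repeat_frac * m$length) return("REPEAT")
  }
  if (multi_locus) return("PARALOG")
  if (!is.null(organelles) && any(identity_hits(read, organelles, params)))
    return("CYTOPLASMIC")
  if (!is.null(contaminants) && any(identity_hits(read, contaminants, params)))
    return("CONTAMINANT")
  "UNKNOWN"
}
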