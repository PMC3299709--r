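# Library-driven repeat masking of reads (and arbitrary sequences), plus the
# masked/unmasked composition classes that gate TE-insertion evidence.
#
# A sequence is masked wherever a banded local alignment against any library
# target (family internal region, base LTR or subfamily variant) reaches the
# identity/length thresholds; overlapping hits are merged and the best-identity
# family is recorded per merged interval.

#' Build (or pass through) a masking index for a TE library
#'
#' @param library a `te_library`, or an existing `mask_index`.
#' @return An object of class `mask_index`.
#' @export
mask_index <- function(library) {
  if (inherits(library, "mask_index")) return(library)
  targets <- mask_targets(library)
  if (length(targets) == 0 || all(!nzchar(targets))) {
    return(structure(list(index = NULL, family = character(0)),
                     class = "mask_index"))
  }
  idx <- seq_index(targets, k = 11L, step = 1L)
  structure(list(index = idx,
                 family = sub("\\|.*$", "", names(targets))),
            class = "mask_index")
}

#' Mask repeats in a set of sequences
#'
#' @param seqs character vector of sequences.
#' @param library `te_library` or `mask_index`.
#' @param min_identity minimum local-alignment identity to mask (default 0.8).
#' @param min_len minimum masked segment length in bp (default 50).
#' @return A list with `hits` (data.frame of merged masked intervals per
#'   sequence: seq (index), start, end (0-based half-open), family, identity)
#'   and `summary` (data.frame: seq, length, n_masked, n_unmasked).
#' @export
mask_reads <- function(seqs, library, min_identity = 0.8, min_len = 50) {
  midx <- mask_index(library)
  lens <- nchar(seqs)
  empty_hits <- data.frame(seq = integer(0), start = integer(0),
                           end = integer(0), family = character(0),
                           identity = numeric(0), stringsAsFactors = FALSE)
  if (is.null(midx$index)) {
    warning("empty repeat library: nothing masked")
    return(list(hits = empty_hits,
                summary = data.frame(seq = seq_along(seqs), length = lens,
                                     n_masked = 0L, n_unmasked = lens)))
  }
  raw <- cpp_local_hits(seqs, midx$index$ptr, min_identity, as.integer(min_len),
                        band = 16L, gap_open = 2.5, gap_ext = 0.5,
                        seed_step = 2L, max_targets = 6L, max_per_kmer = 64L,
                        stop_unexplained = as.integer(min_len) - 10L)
  hits <- data.frame(seq = raw$query, start = raw$qstart, end = raw$qend,
                     family = midx$family[raw$target], identity = raw$identity,
                     stringsAsFactors = FALSE)
  if (nrow(hits)) {
    dt <- data.table::as.data.table(hits)
    data.table::setorder(dt, seq, start, end)
    # merge overlapping/adjacent hits per sequence, keeping best-identity family
    dt[, grp := cumsum(c(1L, ifelse(start[-1] <= cummax(head(end, -1)), 0L, 1L))),
       by = seq]
    merged <- dt[, .(start = min(start), end = max(end),
                     family = family[which.max(identity)],
                     identity = max(identity)), by = .(seq, grp)]
    merged[, grp := NULL]
    hits <- as.data.frame(merged)
  }
  masked <- integer(length(seqs))
  if (nrow(hits)) {
    agg <- tapply(hits$end - hits$start, hits$seq, sum)
    masked[as.integer(names(agg))] <- as.integer(agg)
  }
  list(hits = hits,
       summary = data.frame(seq = seq_along(seqs), length = lens,
                            n_masked = masked, n_unmasked = lens - masked))
}

#' Mask a single sequence
#'
#' @param seq a single sequence string.
#' @param library `te_library` or `mask_index`.
#' @inheritParams mask_reads
#' @return An object of class `mask_result`: `intervals` (data.frame start,
#'   end, family, identity; 0-based half-open, disjoint, sorted), `n_masked`,
#'   `n_unmasked`, `length`.
#' @export
mask_sequence <- function(seq, library, min_identity = 0.8, min_len = 50) {
  stopifnot(length(seq) == 1, nzchar(seq))
  mr <- mask_reads(seq, library, min_identity, min_len)
  structure(
    list(intervals = mr$hits[, c("start", "end", "family", "identity")],
         n_masked = mr$summary$n_masked[1],
         n_unmasked = mr$summary$n_unmasked[1],
         length = mr$summary$length[1]),
    class = "mask_result")
}

#' @export
print.mask_result <- function(x, ...) {
  cat(sprintf("mask_result: %d bp, %d masked / %d unmasked, %d interval(s)\n",
              x$length, x$n_masked, x$n_unmasked, nrow(x$intervals)))
  invisible(x)
}

#' Classify a sequence by masked composition
#'
#' Classes, evaluated in order: `TE_EVIDENCE` (at least `unmasked_min`
#' unmasked and at least `masked_min` masked bases: the read straddles a
#' repeat/unique junction and can localise a TE insertion), `REPEAT_READ`
#' (at least `repeat_frac` of the read masked), `MOSTLY_UNIQUE` (fewer than
#' `min_len` masked bases), else `OTHER`.
#'
#' @param mask a `mask_result`, or a data.frame/list with `n_masked`,
#'   `n_unmasked` columns (vectorised).
#' @param unmasked_min,masked_min TE-evidence thresholds (150 / 100 bp).
#' @param repeat_frac repeat-read threshold (0.9 of read length).
#' @param min_len masking length floor (50 bp).
#' @return Character vector of classes.
#' @export
masked_composition <- function(mask, unmasked_min = 150, masked_min = 100,
                               repeat_frac = 0.9, min_len = 50) {
  nm <- if (inherits(mask, "mask_result")) mask$n_masked else mask$n_masked
  nu <- if (inherits(mask, "mask_result")) mask$n_unmasked else mask$n_unmasked
  len <- nm + nu
  out <- rep("OTHER", length(nm))
  out[nm < min_len] <- "MOSTLY_UNIQUE"
  out[nm >= repeat_frac * len] <- "REPEAT_READ"
  out[nu >= unmasked_min & nm >= masked_min] <- "TE_EVIDENCE"
  out
}

#' Soft-mask a sequence given mask intervals
#'
#' Lowercases masked intervals (soft) or replaces them with N (hard).
#'
#' @param seq sequence string.
#' @param intervals data.frame with 0-based half-open `start`, `end`.
#' @param hard logical; hard-mask with N.
#' @return Masked sequence string.
#' @export
apply_mask <- function(seq, intervals, hard = FALSE) {
  if (!nrow(intervals)) return(seq)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    piece <- substr(seq, s + 1, e)
    piece <- if (hard) strrep("N", e - s) else tolower(piece)
    substr(seq, s + 1, e) <- piece
  }
  seq
}

#' Per-read masking report
#'
#' @param reads a `read_set`.
#' @param library `te_library` or `mask_index`.
#' @inheritParams mask_reads
#' @return data.frame: read_id, length, n_masked, n_unmasked, class,
#'   best_family.
#' @export
mask_report <- function(reads, library, min_identity = 0.8, min_len = 50) {
  mr <- mask_reads(reads$seq, library, min_identity, min_len)
  best <- rep(NA_character_, n_reads(reads))
  if (nrow(mr$hits)) {
    dt <- data.table::as.data.table(mr$hits)
    b <- dt[, .(family = family[which.max((end - start) * identity)]), by = seq]
    best[b$seq] <- b$family
  }
  data.frame(read_id = reads$id, length = mr$summary$length,
             n_masked = mr$summary$n_masked,
             n_unmasked = mr$summary$n_unmasked,
             class = masked_composition(mr$summary, min_len = min_len),
             best_family = best, stringsAsFactors = FALSE)
}
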