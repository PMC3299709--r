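# Transposable-element library: named families with LTR / internal sequences,
# subfamily variant structure and per-family transposition activity weights.
# The four focal LTR families mirror the copy-number and LTR-form structure
# reported for grape (a Gypsy element with a recent amplification burst, a
# high-copy Copia element, an older Gypsy and a Caulimoviridae-like element).

#' Construct a single TE family
#'
#' @param name family label.
#' @param te_class "I" (retroelements) or "II" (DNA transposons).
#' @param superfamily e.g. "Gypsy", "Copia", "LINE", "Caulimoviridae-like".
#' @param ltr_seq LTR sequence ("" for non-LTR families).
#' @param internal_seq internal sequence (>= 500 bp).
#' @param tsd_len target-site duplication length in bp.
#' @param subfamily_variants list of `list(seq, weight, copy_div)`: LTR variant
#'   sequence, its share of genomic copies, and the per-copy divergence applied
#'   when an ancestral copy of that variant is placed (0 = recent, identical
#'   copies). Weights are normalised to sum to 1.
#' @param activity_weight relative probability that a new somatic insertion
#'   comes from this family.
#' @return An object of class `te_family`.
#' @export
te_family <- function(name, te_class, superfamily, ltr_seq, internal_seq,
                      tsd_len = 5L, subfamily_variants = list(),
                      activity_weight = 1) {
  stopifnot(te_class %in% c("I", "II"))
  if (nchar(internal_seq) < 500) stop("internal_seq must be >= 500 bp")
  if (nzchar(ltr_seq) && (nchar(ltr_seq) < 100 || nchar(ltr_seq) > 1000))
    stop("ltr_seq length must be in [100, 1000] when present")
  if (length(subfamily_variants)) {
    w <- vapply(subfamily_variants, function(v) v$weight, numeric(1))
    if (any(w < 0)) stop("variant weights must be >= 0")
    w <- w / sum(w)
    for (i in seq_along(subfamily_variants)) subfamily_variants[[i]]$weight <- w[i]
  }
  structure(
    list(name = name, te_class = te_class, superfamily = superfamily,
         ltr_seq = ltr_seq, internal_seq = internal_seq,
         tsd_len = as.integer(tsd_len),
         subfamily_variants = subfamily_variants,
         activity_weight = activity_weight),
    class = "te_family")
}

# variants for a family whose LTR forms split into `major_weights` recent-ish
# clusters plus a diffuse pool of old, heavily diverged minor copies.
build_variants <- function(base_ltr, major_weights, major_div, copy_div_major,
                           n_minor, minor_div, copy_div_minor) {
  out <- list()
  for (i in seq_along(major_weights)) {
    out[[length(out) + 1]] <- list(
      name = paste0("LTR", i),
      seq = mutate_seq(base_ltr, major_div),
      weight = major_weights[i],
      copy_div = copy_div_major[i],
      major = TRUE)
  }
  minor_w <- (1 - sum(major_weights)) / n_minor
  for (j in seq_len(n_minor)) {
    out[[length(out) + 1]] <- list(
      name = paste0("minor", j),
      seq = mutate_seq(base_ltr, minor_div),
      weight = minor_w,
      copy_div = copy_div_minor,
      # every genomic copy of a minor lineage diverges independently from
      # the family base: no two minor copies can support a common consensus
      per_copy = TRUE,
      per_copy_div = minor_div + copy_div_minor,
      major = FALSE)
  }
  out
}

#' Build a repeat (TE) library
#'
#' With `n_families >= 4` the first four families are the focal LTR elements
#' Gret1-like (Gypsy; four major LTR forms at copy shares 0.25/0.18/0.05/0.03,
#' the first a recent burst of identical copies), Copia10-like (four majors,
#' 0.19/0.07/0.07/0.03), Gypsy19-like (one major, 0.10) and Cauliv1-like
#' (Caulimoviridae-like; one major, 0.07). Remaining copy share in each family
#' is a diffuse pool of heavily diverged minor variants. Further families are
#' LINE-like (class I, no LTR) and DNA-transposon-like (class II).
#'
#' @param n_families number of families (>= 1).
#' @param seed RNG seed.
#' @return An object of class `te_library` (list of [te_family()]).
#' @export
build_te_library <- function(n_families, seed = 1L) {
  if (!is.numeric(n_families) || n_families < 1)
    stop("n_families must be >= 1")
  n_families <- as.integer(n_families)
  with_seed(seed, {
    fams <- list()
    specs <- list(
      list(name = "Gret1-like", superfamily = "Gypsy", ltr_len = 420,
           int_len = 3000, majors = c(0.25, 0.18, 0.05, 0.03),
           copy_div_major = c(0, 0.03, 0.03, 0.03), n_minor = 30,
           activity = 5),
      list(name = "Copia10-like", superfamily = "Copia", ltr_len = 350,
           int_len = 2600, majors = c(0.19, 0.07, 0.07, 0.03),
           copy_div_major = c(0.03, 0.03, 0.03, 0.03), n_minor = 35,
           activity = 4),
      list(name = "Gypsy19-like", superfamily = "Gypsy", ltr_len = 500,
           int_len = 3200, majors = 0.10, copy_div_major = 0.04,
           n_minor = 40, activity = 3),
      list(name = "Cauliv1-like", superfamily = "Caulimoviridae-like",
           ltr_len = 300, int_len = 2800, majors = 0.07,
           copy_div_major = 0.04, n_minor = 40, activity = 2))
    n_focal <- if (n_families >= 4) 4L else 0L
    if (n_focal > 0) {
      for (i in seq_len(n_focal)) {
        sp <- specs[[i]]
        base_ltr <- random_dna(sp$ltr_len, gc = 0.42)
        internal <- random_dna(sp$int_len, gc = 0.42)
        # minors: ancient diffuse copies - each genomic copy diverges
        # independently (large copy_div), so no two copies form a
        # clusterable lineage, yet they stay detectable by the harvest
        variants <- build_variants(base_ltr, sp$majors, major_div = 0.12,
                                   copy_div_major = sp$copy_div_major,
                                   n_minor = sp$n_minor, minor_div = 0.13,
                                   copy_div_minor = 0.04)
        fams[[i]] <- te_family(sp$name, "I", sp$superfamily,
                               ltr_seq = base_ltr, internal_seq = internal,
                               tsd_len = 5L, subfamily_variants = variants,
                               activity_weight = sp$activity)
      }
    }
    extra <- n_families - n_focal
    for (j in seq_len(max(extra, 0))) {
      if (j %% 2 == 1) {
        fams[[n_focal + j]] <- te_family(
          paste0("LINE-", (j + 1) %/% 2), "I", "LINE", ltr_seq = "",
          internal_seq = random_dna(4000, gc = 0.40), tsd_len = 8L,
          activity_weight = 1)
      } else {
        fams[[n_focal + j]] <- te_family(
          paste0("DTX-", j %/% 2), "II", "hAT-like", ltr_seq = "",
          internal_seq = random_dna(2500, gc = 0.38), tsd_len = 8L,
          activity_weight = 1)
      }
    }
    # when fewer than 4 families were requested, fall back to generic
    # single-variant LTR families so the library is still usable end-to-end
    if (n_focal == 0) {
      for (i in seq_len(n_families)) {
        base_ltr <- random_dna(400, gc = 0.42)
        fams[[i]] <- te_family(
          paste0("TE-", i), "I", "Gypsy", ltr_seq = base_ltr,
          internal_seq = random_dna(2500, gc = 0.42), tsd_len = 5L,
          subfamily_variants = list(list(name = "LTR1", seq = base_ltr,
                                         weight = 1, copy_div = 0.02)),
          activity_weight = 1)
      }
    }
    names(fams) <- vapply(fams, function(f) f$name, character(1))
    structure(fams, class = "te_library", seed = seed)
  })
}

#' @export
print.te_library <- function(x, ...) {
  cat(sprintf("te_library: %d families\n", length(x)))
  for (f in x) {
    cat(sprintf("  %-14s class %-2s %-20s LTR %4d bp, internal %4d bp, %d variant(s)\n",
                f$name, f$te_class, f$superfamily, nchar(f$ltr_seq),
                nchar(f$internal_seq), length(f$subfamily_variants)))
  }
  invisible(x)
}

#' Full element sequence for one genomic copy of a family
#'
#' Draws a subfamily variant (unless fixed), applies the variant's per-copy
#' divergence independently to each LTR and to the internal region, and
#' returns the LTR-internal-LTR (or bare internal) sequence.
#'
#' @param family a `te_family`.
#' @param variant integer variant number, or `NULL` to draw by weight.
#' @param recent logical; recent insertions carry no per-copy divergence and
#'   are biased toward the dominant (first) variant.
#' @return list(seq, variant, variant_name)
#' @keywords internal
te_copy_seq <- function(family, variant = NULL, recent = FALSE) {
  nv <- length(family$subfamily_variants)
  if (nv == 0) {
    div <- if (recent) 0 else 0.03
    return(list(seq = mutate_seq(family$internal_seq, div), variant = NA_integer_,
                variant_name = NA_character_))
  }
  if (is.null(variant)) {
    w <- vapply(family$subfamily_variants, function(v) v$weight, numeric(1))
    if (recent) {
      # new transpositions come from the active (major) lineages; diffuse
      # ancient minor copies are transpositionally dead. Dominant variant
      # most of the time, otherwise by weight among majors.
      is_major <- vapply(family$subfamily_variants,
                         function(v) isTRUE(v$major), logical(1))
      pool <- if (any(is_major)) which(is_major) else seq_len(nv)
      variant <- if (runif(1) < 0.8) pool[1] else
        pool[sample.int(length(pool), 1, prob = w[pool])]
    } else {
      variant <- sample.int(nv, 1, prob = w)
    }
  }
  v <- family$subfamily_variants[[variant]]
  div <- if (recent) 0 else v$copy_div
  if (isTRUE(v$per_copy) && !recent) {
    # ancient diffuse lineage: draw this copy's LTRs fresh from the family
    # base so no two copies are mutually alignable at consensus level
    ltr5 <- mutate_seq(family$ltr_seq, v$per_copy_div)
    ltr3 <- mutate_seq(family$ltr_seq, v$per_copy_div)
  } else {
    ltr5 <- mutate_seq(v$seq, div)
    ltr3 <- mutate_seq(v$seq, div)
  }
  int <- mutate_seq(family$internal_seq, div)
  list(seq = paste0(ltr5, int, ltr3), variant = variant,
       variant_name = if (!is.null(v$name)) v$name else paste0("v", variant))
}

#' Write a TE library as FASTA
#'
#' One record per family LTR, per subfamily variant and per internal sequence.
#'
#' @param library a `te_library`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_te_library <- function(library, path) {
  seqs <- mask_targets(library)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# named target sequences used for masking and family assignment:
# internal region, base LTR and every subfamily variant of each family.
mask_targets <- function(library) {
  out <- character(0)
  for (f in library) {
    out[paste0(f$name, "|internal")] <- f$internal_seq
    if (nzchar(f$ltr_seq)) out[paste0(f$name, "|ltr")] <- f$ltr_seq
    for (i in seq_along(f$subfamily_variants)) {
      v <- f$subfamily_variants[[i]]
      nm <- if (!is.null(v$name)) v$name else paste0("v", i)
      out[paste0(f$name, "|", nm)] <- v$seq
    }
  }
  out
}
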