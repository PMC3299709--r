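# Ancestral reference construction and clone derivation.
#
# The ancestral genome is a stand-in for a repeat-rich plant reference:
# random background sequence, dispersed TE copies drawn from the library, one
# dense repeat block per chromosome (centromere stand-in), gene/exon
# annotation placed outside repeats, plus organelle and contaminant
# companion sequences used to spike reads. All in-memory coordinates are
# 0-based half-open; GFF3/BED writers convert to their standard dialects.

#' Build an ancestral reference genome
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length(s) in bp (scalar recycled, or vector of
#'   length `n_chrom`).
#' @param repeat_fraction proportion of bases covered by TE copies (0--0.6),
#'   including one dense centromere-like block per chromosome.
#' @param library a [build_te_library()] object.
#' @param seed RNG seed.
#' @param gc background GC content.
#' @param exon_fraction target fraction of bases annotated as exons.
#' @param family_weights per-family probability that a dispersed copy belongs
#'   to that family; default favours the focal LTR families.
#' @param centromere_share share of the repeat budget spent on the dense block.
#' @return An object of class `ancestral_genome` with elements `chromosomes`
#'   (named character), `genes`, `exons`, `repeats` (data.frames, 0-based
#'   half-open), `organelles`, `contaminants` (named character), `params`.
#' @export
build_ancestral_genome <- function(n_chrom, chrom_len, repeat_fraction, library,
                                   seed = 1L, gc = 0.35, exon_fraction = 0.069,
                                   family_weights = NULL,
                                   centromere_share = 0.25) {
  if (repeat_fraction < 0 || repeat_fraction > 0.6)
    stop("repeat_fraction must be in [0, 0.6]")
  stopifnot(n_chrom >= 1)
  chrom_len <- as.numeric(rep(chrom_len, length.out = n_chrom))
  if (is.null(family_weights)) {
    nf <- length(library)
    family_weights <- rep(1, nf)
    focal <- match(c("Gret1-like", "Copia10-like", "Gypsy19-like", "Cauliv1-like"),
                   names(library))
    if (!anyNA(focal)) {
      family_weights[] <- 0.22 / max(nf - 4, 1)
      family_weights[focal] <- c(0.32, 0.16, 0.10, 0.20)
      if (nf == 4) family_weights <- family_weights[focal] / sum(family_weights[focal])
    }
    family_weights <- family_weights / sum(family_weights)
  }
  with_seed(seed, {
    chroms <- character(n_chrom)
    names(chroms) <- paste0("chr", seq_len(n_chrom))
    rep_rows <- list(); gene_rows <- list(); exon_rows <- list()
    for (ci in seq_len(n_chrom)) {
      L <- chrom_len[ci]
      chrom <- names(chroms)[ci]
      rep_budget <- repeat_fraction * L
      cen_budget <- centromere_share * rep_budget
      disp_budget <- rep_budget - cen_budget

      # plan copies first (family draws against the budget), then assign
      # subfamily variants per family: major-variant copy numbers follow
      # their weights deterministically (minimum 2 where the family has
      # room - a "major form" is by definition a multi-copy lineage),
      # minors are drawn by weight
      plan_copies <- function(budget) {
        fams <- integer(0); spent <- 0
        while (spent < budget && repeat_fraction > 0) {
          fi <- sample.int(length(library), 1, prob = family_weights)
          f <- library[[fi]]
          fams <- c(fams, fi)
          spent <- spent + 2 * nchar(f$ltr_seq) + nchar(f$internal_seq)
        }
        fams
      }
      disp_fams <- plan_copies(disp_budget)
      cen_fams <- plan_copies(cen_budget)
      # TE families are multi-copy by nature: a family drawn once gets a
      # second dispersed copy, so somatic insertions always have at least
      # one paralogous competitor in the reference
      tab <- table(c(disp_fams, cen_fams))
      singles <- as.integer(names(tab)[tab == 1])
      if (length(singles)) disp_fams <- c(disp_fams, singles)
      all_fams <- c(disp_fams, cen_fams)
      variants <- integer(length(all_fams))
      for (fi in unique(all_fams)) {
        slots <- which(all_fams == fi)
        f <- library[[fi]]
        nv <- length(f$subfamily_variants)
        if (nv == 0) { variants[slots] <- NA_integer_; next }
        w <- vapply(f$subfamily_variants, `[[`, numeric(1), "weight")
        is_major <- vapply(f$subfamily_variants,
                           function(v) isTRUE(v$major), logical(1))
        n <- length(slots)
        alloc <- integer(nv)
        for (j in which(is_major)) {
          alloc[j] <- min(max(round(w[j] * n), 2L), n - sum(alloc))
        }
        n_minor <- n - sum(alloc)
        vs <- rep(seq_len(nv), alloc)
        if (n_minor > 0 && any(!is_major)) {
          vs <- c(vs, sample(which(!is_major), n_minor, replace = TRUE,
                             prob = w[!is_major]))
        } else if (n_minor > 0) {
          vs <- c(vs, sample(seq_len(nv), n_minor, replace = TRUE, prob = w))
        }
        variants[slots] <- sample(vs)
      }
      gen_copy <- function(k) {
        fi <- all_fams[k]
        v <- if (is.na(variants[k])) NULL else variants[k]
        cp <- te_copy_seq(library[[fi]], variant = v, recent = FALSE)
        list(family = names(library)[fi], variant = cp$variant_name,
             seq = cp$seq)
      }
      copies <- lapply(seq_along(disp_fams), gen_copy)
      cen_parts <- lapply(seq_along(cen_fams) + length(disp_fams), gen_copy)
      copy_bp <- sum(vapply(copies, function(x) nchar(x$seq), 1)) +
        sum(vapply(cen_parts, function(x) nchar(x$seq), 1))
      bg_len <- max(round(L - copy_bp), 1000)
      bg <- random_dna(bg_len, gc = gc)

      # insertion offsets in the background (sorted, min spacing 500 bp)
      n_ins <- length(copies) + (length(cen_parts) > 0)
      offs <- sort(sample.int(max(bg_len - 1000, n_ins + 1), n_ins))
      cen_slot <- if (length(cen_parts)) which.min(abs(offs - bg_len / 2)) else 0L

      pieces <- character(0); reps <- list()
      prev <- 0; pos <- 0
      ins_i <- 0
      for (oi in seq_along(offs)) {
        pieces <- c(pieces, substr(bg, prev + 1, offs[oi]))
        pos <- pos + (offs[oi] - prev)
        prev <- offs[oi]
        if (oi == cen_slot) {
          for (p in cen_parts) {
            reps[[length(reps) + 1]] <- data.frame(
              chrom = chrom, start = pos, end = pos + nchar(p$seq),
              family = p$family, variant = p$variant %||% NA_character_,
              centromeric = TRUE, stringsAsFactors = FALSE)
            pieces <- c(pieces, p$seq)
            pos <- pos + nchar(p$seq)
          }
        } else {
          ins_i <- ins_i + 1
          p <- copies[[ins_i]]
          reps[[length(reps) + 1]] <- data.frame(
            chrom = chrom, start = pos, end = pos + nchar(p$seq),
            family = p$family, variant = p$variant %||% NA_character_,
            centromeric = FALSE, stringsAsFactors = FALSE)
          pieces <- c(pieces, p$seq)
          pos <- pos + nchar(p$seq)
        }
      }
      pieces <- c(pieces, substr(bg, prev + 1, bg_len))
      chroms[ci] <- paste(pieces, collapse = "")
      rep_df <- if (length(reps)) do.call(rbind, reps) else
        data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                   family = character(0), variant = character(0),
                   centromeric = logical(0))
      rep_rows[[ci]] <- rep_df

      # genes in non-repeat gaps; 4 exons of 450 bp per 3 kb gene
      Lc <- nchar(chroms[ci])
      gene_len <- 3000; exon_len <- 450; n_exon <- 4
      target_exon <- exon_fraction * Lc
      gaps <- interval_complement(rep_df$start, rep_df$end, Lc)
      gaps <- gaps[gaps$end - gaps$start >= gene_len + 200, , drop = FALSE]
      exon_bases <- 0; gid <- 0
      genes <- list(); exons <- list()
      while (exon_bases < target_exon && nrow(gaps) > 0) {
        gi <- sample.int(nrow(gaps), 1,
                         prob = (gaps$end - gaps$start))
        g <- gaps[gi, ]
        slack <- (g$end - g$start) - gene_len
        gstart <- g$start + sample.int(max(slack, 1), 1) - 1
        gid <- gid + 1
        gene_id <- sprintf("%s_g%04d", chrom, gid)
        genes[[gid]] <- data.frame(chrom = chrom, start = gstart,
                                   end = gstart + gene_len, gene_id = gene_id,
                                   stringsAsFactors = FALSE)
        estep <- (gene_len - n_exon * exon_len) / (n_exon - 1) + exon_len
        for (e in seq_len(n_exon)) {
          es <- gstart + round((e - 1) * estep)
          exons[[length(exons) + 1]] <- data.frame(
            chrom = chrom, start = es, end = es + exon_len, gene_id = gene_id,
            exon = e, stringsAsFactors = FALSE)
        }
        exon_bases <- exon_bases + n_exon * exon_len
        # split the used gap so genes do not overlap
        left <- data.frame(start = g$start, end = gstart - 200)
        right <- data.frame(start = gstart + gene_len + 200, end = g$end)
        gaps <- rbind(gaps[-gi, , drop = FALSE],
                      left[left$end - left$start >= gene_len + 200, , drop = FALSE],
                      right[right$end - right$start >= gene_len + 200, , drop = FALSE])
      }
      gene_rows[[ci]] <- if (length(genes)) do.call(rbind, genes) else NULL
      exon_rows[[ci]] <- if (length(exons)) do.call(rbind, exons) else NULL
    }
    genes <- do.call(rbind, gene_rows[!vapply(gene_rows, is.null, TRUE)])
    exons <- do.call(rbind, exon_rows[!vapply(exon_rows, is.null, TRUE)])
    if (is.null(genes)) {
      genes <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), gene_id = character(0))
      exons <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), gene_id = character(0), exon = integer(0))
    }
    organelles <- c(chloroplast_like = random_dna(30000, gc = 0.37),
                    mitochondrion_like = random_dna(40000, gc = 0.42))
    contaminants <- c(yeast_like = random_dna(20000, gc = 0.38),
                      coli_like = random_dna(20000, gc = 0.50))
    structure(
      list(chromosomes = chroms, genes = genes, exons = exons,
           repeats = do.call(rbind, rep_rows), organelles = organelles,
           contaminants = contaminants,
           params = list(seed = seed, repeat_fraction = repeat_fraction,
                         gc = gc, exon_fraction = exon_fraction)),
      class = "ancestral_genome")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# complement of sorted/unsorted intervals within [0, L)
interval_complement <- function(start, end, L) {
  if (length(start) == 0) return(data.frame(start = 0, end = L))
  o <- order(start)
  start <- start[o]; end <- end[o]
  gaps <- list(); prev <- 0
  for (i in seq_along(start)) {
    if (start[i] > prev) gaps[[length(gaps) + 1]] <- c(prev, start[i])
    prev <- max(prev, end[i])
  }
  if (prev < L) gaps[[length(gaps) + 1]] <- c(prev, L)
  if (!length(gaps)) return(data.frame(start = numeric(0), end = numeric(0)))
  m <- do.call(rbind, gaps)
  data.frame(start = m[, 1], end = m[, 2])
}

#' @export
print.ancestral_genome <- function(x, ...) {
  rb <- if (nrow(x$repeats)) sum(x$repeats$end - x$repeats$start) else 0
  cat(sprintf("ancestral_genome: %d chromosome(s), %.2f Mb, %.1f%% repeats, %d genes\n",
              length(x$chromosomes), sum(nchar(x$chromosomes)) / 1e6,
              100 * rb / sum(nchar(x$chromosomes)), nrow(x$genes)))
  invisible(x)
}

#' Derive a clone genome by somatic mutation
#'
#' Draws Poisson numbers of SNPs, short indels and TE insertions at the given
#' per-Mb rates, samples their positions (>= 10 bp apart within the clone),
#' and applies them through [apply_ledger()], so the returned ledger exactly
#' determines the returned sequence.
#'
#' @param ancestor an `ancestral_genome`.
#' @param snp_rate,indel_rate,te_rate expected events per Mb.
#' @param library TE library used for insertions.
#' @param seed RNG seed.
#' @param clone_id label recorded in the ledger.
#' @param tsd logical; add a target-site duplication at TE insertions.
#' @return list with elements `genome` (class `clone_genome`) and `ledger`
#'   (data.frame; positions are 0-based in ancestor coordinates).
#' @export
derive_clone <- function(ancestor, snp_rate, indel_rate, te_rate, library,
                         seed = 1L, clone_id = "clone", tsd = TRUE) {
  if (any(c(snp_rate, indel_rate, te_rate) < 0)) stop("rates must be >= 0")
  with_seed(seed, {
    entries <- list()
    bases <- c("A", "C", "G", "T")
    for (chrom in names(ancestor$chromosomes)) {
      seqc <- ancestor$chromosomes[[chrom]]
      L <- nchar(seqc)
      mb <- L / 1e6
      n_snp <- rpois(1, snp_rate * mb)
      n_indel <- rpois(1, indel_rate * mb)
      n_te <- rpois(1, te_rate * mb)
      n_tot <- n_snp + n_indel + n_te
      if (n_tot == 0) next
      # rejection-sample positions at least 10 bp apart
      pos <- sort(sample.int(L - 100, min(n_tot * 3, L - 101)))
      pos <- pos[c(TRUE, diff(pos) >= 10)]
      if (length(pos) < n_tot) n_tot <- length(pos)
      pos <- sample(pos, n_tot)
      types <- sample(rep(c("SNP", "INDEL", "TE_INS"),
                          c(n_snp, n_indel, n_te))[seq_len(n_tot)])
      act <- vapply(library, function(f) f$activity_weight, numeric(1))
      for (i in seq_len(n_tot)) {
        p <- pos[i]
        if (types[i] == "SNP") {
          ref <- substr(seqc, p + 1, p + 1)
          alt <- sample(setdiff(bases, ref), 1)
          entries[[length(entries) + 1]] <- data.frame(
            clone_id = clone_id, type = "SNP", chrom = chrom, pos = p,
            ref = ref, alt = alt, indel_len = NA_integer_,
            seq = NA_character_, family = NA_character_,
            variant = NA_character_, orient = NA_character_,
            tsd_len = NA_integer_, stringsAsFactors = FALSE)
        } else if (types[i] == "INDEL") {
          len <- sample.int(10L, 1, prob = 0.55 ^ (0:9))
          if (runif(1) < 0.5) { # insertion
            entries[[length(entries) + 1]] <- data.frame(
              clone_id = clone_id, type = "INDEL", chrom = chrom, pos = p,
              ref = NA_character_, alt = NA_character_, indel_len = len,
              seq = random_dna(len, 0.4), family = NA_character_,
              variant = NA_character_, orient = NA_character_,
              tsd_len = NA_integer_, stringsAsFactors = FALSE)
          } else {
            entries[[length(entries) + 1]] <- data.frame(
              clone_id = clone_id, type = "INDEL", chrom = chrom, pos = p,
              ref = NA_character_, alt = NA_character_, indel_len = -len,
              seq = substr(seqc, p + 1, p + len), family = NA_character_,
              variant = NA_character_, orient = NA_character_,
              tsd_len = NA_integer_, stringsAsFactors = FALSE)
          }
        } else {
          fi <- sample.int(length(library), 1, prob = act)
          fam <- library[[fi]]
          cp <- te_copy_seq(fam, recent = TRUE)
          orient <- sample(c("+", "-"), 1)
          tl <- if (tsd) fam$tsd_len else 0L
          entries[[length(entries) + 1]] <- data.frame(
            clone_id = clone_id, type = "TE_INS", chrom = chrom, pos = p,
            ref = NA_character_, alt = NA_character_, indel_len = NA_integer_,
            seq = if (orient == "+") cp$seq else revcomp(cp$seq),
            family = fam$name, variant = cp$variant_name, orient = orient,
            tsd_len = tl, stringsAsFactors = FALSE)
        }
      }
    }
    ledger <- if (length(entries)) do.call(rbind, entries) else empty_ledger()
    ledger <- ledger[order(ledger$chrom, ledger$pos), , drop = FALSE]
    rownames(ledger) <- NULL
    genome <- apply_ledger(ancestor, ledger, clone_id = clone_id)
    list(genome = genome, ledger = ledger)
  })
}

empty_ledger <- function() {
  data.frame(clone_id = character(0), type = character(0), chrom = character(0),
             pos = numeric(0), ref = character(0), alt = character(0),
             indel_len = integer(0), seq = character(0), family = character(0),
             variant = character(0), orient = character(0),
             tsd_len = integer(0), stringsAsFactors = FALSE)
}

#' Apply a mutation ledger to an ancestral genome
#'
#' Entries are applied in descending position order per chromosome so that
#' coordinates (0-based, in ancestor space) stay valid. TE insertions place
#' the element immediately after the target site and duplicate `tsd_len`
#' target bases. Re-applying the same ledger reproduces the clone exactly.
#'
#' @param ancestor an `ancestral_genome`.
#' @param ledger data.frame as produced by [derive_clone()].
#' @param clone_id label for the derived genome.
#' @return An object of class `clone_genome`.
#' @export
apply_ledger <- function(ancestor, ledger, clone_id = "clone") {
  chroms <- ancestor$chromosomes
  for (chrom in unique(ledger$chrom)) {
    seqc <- chroms[[chrom]]
    sub <- ledger[ledger$chrom == chrom, , drop = FALSE]
    sub <- sub[order(-sub$pos), , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      e <- sub[i, ]
      p <- e$pos
      if (e$type == "SNP") {
        if (substr(seqc, p + 1, p + 1) != e$ref)
          stop("ledger SNP reference mismatch at ", chrom, ":", p)
        substr(seqc, p + 1, p + 1) <- e$alt
      } else if (e$type == "INDEL") {
        if (e$indel_len > 0) {
          seqc <- paste0(substr(seqc, 1, p), e$seq,
                         substr(seqc, p + 1, nchar(seqc)))
        } else {
          len <- -e$indel_len
          seqc <- paste0(substr(seqc, 1, p),
                         substr(seqc, p + len + 1, nchar(seqc)))
        }
      } else if (e$type == "TE_INS") {
        tl <- e$tsd_len
        tsd_seq <- if (tl > 0) substr(seqc, p + 1, p + tl) else ""
        seqc <- paste0(substr(seqc, 1, p + tl), e$seq, tsd_seq,
                       substr(seqc, p + tl + 1, nchar(seqc)))
      } else stop("unknown ledger entry type: ", e$type)
    }
    chroms[[chrom]] <- seqc
  }
  structure(list(clone_id = clone_id, chromosomes = chroms),
            class = "clone_genome")
}

#' @export
print.clone_genome <- function(x, ...) {
  cat(sprintf("clone_genome '%s': %d chromosome(s), %.2f Mb\n", x$clone_id,
              length(x$chromosomes), sum(nchar(x$chromosomes)) / 1e6))
  invisible(x)
}

#' Write genome files (FASTA + GFF3 + repeat BED)
#'
#' @param genome an `ancestral_genome`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_genome_files <- function(genome, dir, prefix = "reference") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("write_genome_files() needs the rtracklayer package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$chromosomes), fa)
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  gr_genes <- GenomicRanges::GRanges(
    genome$genes$chrom,
    IRanges::IRanges(genome$genes$start + 1, genome$genes$end),
    type = "gene", ID = genome$genes$gene_id)
  gr_exons <- GenomicRanges::GRanges(
    genome$exons$chrom,
    IRanges::IRanges(genome$exons$start + 1, genome$exons$end),
    type = "exon", Parent = genome$exons$gene_id)
  rtracklayer::export(c(gr_genes, gr_exons), gff, format = "gff3")
  bed <- file.path(dir, paste0(prefix, "_repeats.bed"))
  rep_gr <- GenomicRanges::GRanges(
    genome$repeats$chrom,
    IRanges::IRanges(genome$repeats$start + 1, genome$repeats$end),
    name = genome$repeats$family)
  rtracklayer::export(rep_gr, bed, format = "bed")
  invisible(c(fasta = fa, gff3 = gff, bed = bed))
}
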