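# In-silico S-SAP: amplify from a TE-anchored primer (the most conserved LTR
# end) to the nearest restriction site, score fragment lengths as gel bands,
# build presence/absence matrices, Nei-Li distances and neighbor-joining
# trees with bootstrap support over band columns.

#' Most conserved LTR primer site of a family
#'
#' Slides a window over the family's base LTR and picks the window with the
#' highest mean identity across the major subfamily variants, preferring
#' windows near the 3' end (so amplification runs out of the element into the
#' flank).
#'
#' @param family `te_family` with a non-empty LTR.
#' @param width primer length in bp.
#' @return Primer sequence string.
#' @export
ssap_primer <- function(family, width = 20) {
  ltr <- family$ltr_seq
  if (!nzchar(ltr)) stop("family has no LTR")
  if (nchar(ltr) < width) stop("LTR shorter than primer width")
  vars <- family$subfamily_variants
  majors <- Filter(function(v) isTRUE(v$major) || v$weight >= 0.05, vars)
  if (!length(majors)) return(substr(ltr, nchar(ltr) - width + 1, nchar(ltr)))
  # primers are designed on the dominant (transpositionally active) form -
  # the sequence real LTR-bearing reads would show - picking the window most
  # conserved across the other major forms, 3'-proximal among near-ties
  dom <- majors[[which.max(vapply(majors, `[[`, numeric(1), "weight"))]]
  ref <- dom$seq
  L <- nchar(ref)
  ref_chars <- strsplit(ref, "")[[1]]
  var_chars <- lapply(majors, function(v) strsplit(v$seq, "")[[1]])
  score <- vapply(seq_len(L - width + 1), function(s) {
    idx <- s:(s + width - 1)
    mean(vapply(var_chars, function(vc) {
      if (length(vc) < s + width - 1) return(0)
      mean(vc[idx] == ref_chars[idx])
    }, numeric(1)))
  }, numeric(1))
  best <- max(score)
  s <- max(which(score >= best - 0.02))
  substr(ref, s, s + width - 1)
}

#' In-silico S-SAP band lengths for one genome and element
#'
#' Finds every genomic occurrence of the element-anchored primer (both
#' strands, exact match) and measures the distance from the primer 3' end to
#' the nearest downstream restriction-site motif; distances within
#' `size_range` are scored as bands.
#'
#' @param genome genome object or named character sequences.
#' @param family `te_family` (for the default primer).
#' @param primer primer sequence; default [ssap_primer()] of the family.
#' @param enzyme_site restriction motif (length >= 4).
#' @param size_range numeric c(min, max) band length window in bp.
#' @return Sorted numeric vector of band lengths (possibly with duplicates
#'   from co-migrating fragments removed).
#' @export
insilico_ssap <- function(genome, family, primer = NULL,
                          enzyme_site = "GAATTC", size_range = c(50, 500)) {
  if (nchar(enzyme_site) < 4) stop("enzyme motif must be >= 4 bp")
  if (is.null(primer)) primer <- ssap_primer(family)
  seqs <- genome_seqs(genome)
  bands <- numeric(0)
  prc <- as.character(cpp_revcomp(primer))
  for (cn in names(seqs)) {
    s <- seqs[[cn]]
    sites <- as.integer(gregexpr(enzyme_site, s, fixed = TRUE)[[1]])
    sites <- sites[sites > 0] # 1-based motif starts
    # forward primer: fragment runs rightward from primer end
    fw <- as.integer(gregexpr(primer, s, fixed = TRUE)[[1]])
    fw <- fw[fw > 0]
    for (p in fw) {
      p3 <- p + nchar(primer) - 1 # 1-based last primer base
      nxt <- sites[sites > p3]
      if (!length(nxt)) next
      d <- nxt[1] - p3 - 1
      if (d >= size_range[1] && d <= size_range[2]) bands <- c(bands, d)
    }
    # reverse-strand primer: fragment runs leftward
    rv <- as.integer(gregexpr(prc, s, fixed = TRUE)[[1]])
    rv <- rv[rv > 0]
    for (p in rv) {
      p3 <- p # 1-based first base = primer 3' end on minus strand
      prev <- sites[sites + nchar(enzyme_site) - 1 < p3]
      if (!length(prev)) next
      last <- prev[length(prev)]
      d <- p3 - (last + nchar(enzyme_site) - 1) - 1
      if (d >= size_range[1] && d <= size_range[2]) bands <- c(bands, d)
    }
  }
  sort(unique(bands))
}

#' Band presence/absence matrix across samples
#'
#' Band lengths are binned at +/- `bin` bp (single-linkage merging of lengths
#' whose gaps are <= `bin`), emulating gel resolution; columns are
#' (element, binned length) labels.
#'
#' @param band_sets named list: per sample, a named list of per-element band
#'   length vectors (or a bare numeric vector for a single element).
#' @param bin gel resolution in bp.
#' @return Object of class `band_matrix`: binary matrix (samples x bands)
#'   with attributes `n_polymorphic`, `pct_polymorphic`.
#' @export
band_matrix <- function(band_sets, bin = 2) {
  if (length(band_sets) < 2) stop("need >= 2 samples")
  norm <- lapply(band_sets, function(s) {
    if (is.numeric(s)) list(band = s) else s
  })
  elements <- unique(unlist(lapply(norm, names)))
  samples <- names(band_sets)
  cols <- list()
  mat <- NULL
  for (el in elements) {
    lens <- sort(unique(unlist(lapply(norm, function(s) s[[el]]))))
    if (!length(lens)) next
    grp <- cumsum(c(1, diff(lens) > bin))
    centers <- round(tapply(lens, grp, mean))
    sub <- matrix(0L, nrow = length(samples), ncol = length(centers),
                  dimnames = list(samples,
                                  paste0(el, ":", centers)))
    for (si in seq_along(samples)) {
      b <- norm[[si]][[el]]
      if (!length(b)) next
      # assign each band to its merged group via nearest length
      gi <- grp[vapply(b, function(x) which.min(abs(lens - x)), integer(1))]
      sub[si, unique(gi)] <- 1L
    }
    mat <- if (is.null(mat)) sub else cbind(mat, sub)
  }
  if (is.null(mat)) stop("no bands in any sample")
  keep <- colSums(mat) > 0
  mat <- mat[, keep, drop = FALSE]
  poly <- colSums(mat) > 0 & colSums(mat) < nrow(mat)
  structure(mat, class = c("band_matrix", "matrix"),
            n_polymorphic = sum(poly),
            pct_polymorphic = 100 * sum(poly) / ncol(mat))
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix: %d samples x %d bands, %d polymorphic (%.1f%%)\n",
              nrow(x), ncol(x), attr(x, "n_polymorphic"),
              attr(x, "pct_polymorphic")))
  invisible(x)
}

#' Nei-Li distance between two binary band rows
#'
#' `D = 1 - 2 * n_xy / (n_x + n_y)` where `n_xy` is the number of shared
#' bands and `n_x`, `n_y` the band counts of each sample.
#'
#' @param x,y equal-length binary vectors, each with at least one presence.
#' @return Distance in \[0, 1\].
#' @export
nei_li_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  x <- as.integer(x != 0); y <- as.integer(y != 0)
  nx <- sum(x); ny <- sum(y)
  if (nx == 0 || ny == 0) stop("a sample with zero bands has undefined distance")
  nxy <- sum(x & y)
  1 - 2 * nxy / (nx + ny)
}

#' Nei-Li distance matrix from a band matrix
#'
#' @param bm binary matrix (samples x bands).
#' @return `dist` object.
#' @export
nei_li_matrix <- function(bm) {
  b <- matrix(as.integer(bm != 0), nrow = nrow(bm),
              dimnames = dimnames(bm))
  nx <- rowSums(b)
  if (any(nx == 0)) stop("a sample with zero bands has undefined distance")
  nxy <- tcrossprod(b)
  d <- 1 - 2 * nxy / outer(nx, nx, `+`)
  diag(d) <- 0
  stats::as.dist(d)
}

#' Neighbor-joining tree with optional bootstrap support
#'
#' Saitou-Nei agglomeration via [ape::nj()]; negative branch lengths are
#' clamped to zero. When `bootstrap > 0` and a `resample` function is given,
#' support values (% of replicates containing each bipartition) are attached
#' as node labels.
#'
#' @param d `dist` or square matrix.
#' @param bootstrap number of bootstrap replicates (0 = none).
#' @param seed RNG seed for resampling.
#' @param resample function(i) returning a resampled `dist` for replicate i.
#' @return `phylo` tree (unrooted), with `node.label` support when
#'   bootstrapped.
#' @export
nj_tree <- function(d, bootstrap = 0, seed = 1L, resample = NULL) {
  d <- stats::as.dist(d)
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  if (bootstrap > 0 && !is.null(resample)) {
    boots <- with_seed(seed, lapply(seq_len(bootstrap), function(i) {
      bt <- ape::nj(resample(i))
      bt$edge.length[bt$edge.length < 0] <- 0
      bt
    }))
    cnt <- ape::prop.clades(tr, boots, rooted = FALSE)
    cnt[is.na(cnt)] <- 0
    tr$node.label <- round(100 * cnt / bootstrap)
  }
  tr
}

#' S-SAP tree from a band matrix
#'
#' Nei-Li distances + neighbor joining; bootstrap resamples band columns
#' (with replacement) and recomputes distance and topology.
#'
#' @param bm a [band_matrix()].
#' @param bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return `phylo` tree with percent support node labels.
#' @export
ssap_tree <- function(bm, bootstrap = 1000, seed = 1L) {
  d <- nei_li_matrix(bm)
  nj_tree(d, bootstrap = bootstrap, seed = seed, resample = function(i) {
    cols <- sample.int(ncol(bm), ncol(bm), replace = TRUE)
    sub <- bm[, cols, drop = FALSE]
    # a resample may empty a sample's band set; fall back to original row
    empty <- rowSums(sub) == 0
    if (any(empty)) sub[empty, 1] <- 1L
    nei_li_matrix(sub)
  })
}
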