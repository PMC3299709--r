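# LTR-form dynamics: harvest LTR-derived read segments, cluster them greedily
# into consensus forms (major forms = clusters of >= 10 segments at >= 90%
# identity to their consensus), and build conserved-region trees whose tight
# groups of near-identical segments indicate recent transposition.
#
# Segments are placed in LTR coordinate space by their local alignment to the
# family's base LTR, so consensus building is a column-wise majority vote
# over that star alignment (ties broken alphabetically).

#' Harvest LTR-derived segments from reads
#'
#' Read substrings locally aligning to the family's base LTR at
#' `min_identity` over at least `min_len` bp, trimmed to the aligned span and
#' orientation-normalised to the LTR strand.
#'
#' @param reads a `read_set` (or character vector of sequences).
#' @param family `te_family` with non-empty `ltr_seq`.
#' @param min_identity minimum local identity (0.75).
#' @param min_len minimum aligned span (100 bp).
#' @return data.frame of class `ltr_segments`: read, seq, ltr_start, ltr_end
#'   (0-based half-open on the LTR), identity; attribute `family`,
#'   `ltr_len`.
#' @export
harvest_ltr_segments <- function(reads, family, min_identity = 0.75,
                                 min_len = 100) {
  if (!nzchar(family$ltr_seq)) stop("family has no LTR sequence")
  seqs <- if (inherits(reads, "read_set")) reads$seq else reads
  idx <- seq_index(c(ltr = family$ltr_seq), k = 11L, step = 1L)
  raw <- cpp_local_hits(seqs, idx$ptr, min_identity, as.integer(min_len),
                        band = 24L, gap_open = 2.5, gap_ext = 0.5,
                        seed_step = 2L, max_targets = 4L, max_per_kmer = 256L,
                        stop_unexplained = 0L)
  if (!length(raw$query)) {
    out <- data.frame(read = integer(0), seq = character(0),
                      ltr_start = integer(0), ltr_end = integer(0),
                      identity = numeric(0))
    attr(out, "family") <- family$name
    attr(out, "ltr_len") <- nchar(family$ltr_seq)
    class(out) <- c("ltr_segments", "data.frame")
    return(out)
  }
  seg <- substring(seqs[raw$query], raw$qstart + 1, raw$qend)
  neg <- raw$strand < 0
  if (any(neg)) seg[neg] <- cpp_revcomp(seg[neg])
  out <- data.frame(read = raw$query, seq = seg, ltr_start = raw$tstart,
                    ltr_end = raw$tend, identity = raw$identity,
                    stringsAsFactors = FALSE)
  # one segment per (read, LTR region): keep the best-identity hit
  key <- paste(out$read, out$ltr_start %/% 50)
  ord <- order(-out$identity)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(key[ord]), , drop = FALSE]
  out <- out[order(out$read), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "family") <- family$name
  attr(out, "ltr_len") <- nchar(family$ltr_seq)
  class(out) <- c("ltr_segments", "data.frame")
  out
}

# integer-code matrix placement of segments on LTR columns (0 = not covered)
segment_matrix <- function(segments, ltr_len) {
  n <- nrow(segments)
  M <- matrix(0L, n, ltr_len)
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (i in seq_len(n)) {
    s <- segments$ltr_start[i]
    span <- min(nchar(segments$seq[i]), segments$ltr_end[i] - s)
    if (span <= 0) next
    ch <- strsplit(substr(segments$seq[i], 1, span), "")[[1]]
    v <- unname(code[ch]); v[is.na(v)] <- 0L
    M[i, (s + 1):(s + span)] <- v
  }
  M
}

consensus_from_counts <- function(counts) {
  # counts: 4 x L; ties broken alphabetically (A < C < G < T)
  cons <- integer(ncol(counts))
  covered <- colSums(counts) > 0
  cons[covered] <- apply(counts[, covered, drop = FALSE], 2, which.max)
  cons
}

row_identity <- function(row, cons, min_overlap = 50) {
  ov <- row != 0L & cons != 0L
  n <- sum(ov)
  if (n < min_overlap) return(NA_real_)
  sum(row[ov] == cons[ov]) / n
}

#' Greedy consensus clustering of LTR segments
#'
#' The longest unassigned segment seeds a cluster; remaining segments joining
#' at >= `identity` to the running majority-vote consensus are added (the
#' consensus updates as members join). Clusters with at least `min_size`
#' segments are major forms; all other segments pool into the minor-form
#' fraction.
#'
#' @param segments [harvest_ltr_segments()] output.
#' @param min_size minimum cluster size for a major form (10).
#' @param identity minimum identity to the cluster consensus (0.90).
#' @param min_overlap minimum overlapping columns to evaluate identity.
#' @return list of class `ltr_forms`: `clusters` (list of list(members,
#'   consensus, size, is_major)), `summary` (data.frame: form, size,
#'   proportion for each major form), `minor_proportion`, `n_segments`,
#'   `family`.
#' @export
cluster_forms <- function(segments, min_size = 10, identity = 0.90,
                          min_overlap = 50) {
  if (nrow(segments) < 1) stop("need at least one segment")
  ltr_len <- attr(segments, "ltr_len")
  M <- segment_matrix(segments, ltr_len)
  n <- nrow(M)
  ord <- order(-(segments$ltr_end - segments$ltr_start))
  unassigned <- rep(TRUE, n)
  clusters <- list()
  for (seed_i in ord) {
    if (!unassigned[seed_i]) next
    counts <- matrix(0L, 4, ltr_len)
    add_counts <- function(counts, row) {
      nz <- which(row != 0L)
      counts[cbind(row[nz], nz)] <- counts[cbind(row[nz], nz)] + 1L
      counts
    }
    counts <- add_counts(counts, M[seed_i, ])
    cons <- consensus_from_counts(counts)
    members <- seed_i
    unassigned[seed_i] <- FALSE
    # vectorised screen against the seed consensus; only near matches get the
    # exact incremental comparison (far segments cannot reach the threshold
    # against a consensus that stays within the cluster's own divergence)
    cand <- which(unassigned)
    if (length(cand)) {
      Mc <- M[cand, , drop = FALSE]
      consm <- matrix(cons, nrow = length(cand), ncol = ltr_len, byrow = TRUE)
      ovm <- Mc != 0L & consm != 0L
      ovn <- rowSums(ovm)
      matches <- rowSums(ovm & Mc == consm)
      screen <- ovn >= min_overlap & matches / pmax(ovn, 1) >= identity - 0.05
      shortlist <- cand[screen]
      shortlist <- shortlist[order(match(shortlist, ord))]
      for (si in shortlist) {
        idv <- row_identity(M[si, ], cons, min_overlap)
        if (!is.na(idv) && idv >= identity) {
          counts <- add_counts(counts, M[si, ])
          cons <- consensus_from_counts(counts)
          members <- c(members, si)
          unassigned[si] <- FALSE
        }
      }
    }
    clusters[[length(clusters) + 1]] <- list(
      members = members, cons = cons, size = length(members))
    if (!any(unassigned)) break
  }
  # merge pass: reads are shorter than the LTR, so one form can emerge as
  # two clusters seeded at different LTR regions; clusters whose consensi
  # agree are one form
  repeat {
    sizes <- vapply(clusters, `[[`, integer(1), "size")
    big <- which(sizes >= 3)
    merged <- FALSE
    if (length(big) >= 2) {
      big <- big[order(-sizes[big])]
      for (ii in seq_along(big)[-length(big)]) {
        for (jj in (ii + 1):length(big)) {
          a <- clusters[[big[ii]]]; b <- clusters[[big[jj]]]
          idv <- row_identity(b$cons, a$cons, min_overlap)
          if (!is.na(idv) && idv >= identity) {
            mem <- c(a$members, b$members)
            counts <- matrix(0L, 4, ltr_len)
            for (m0 in mem) {
              nz <- which(M[m0, ] != 0L)
              counts[cbind(M[m0, nz], nz)] <- counts[cbind(M[m0, nz], nz)] + 1L
            }
            clusters[[big[ii]]] <- list(members = mem,
                                        cons = consensus_from_counts(counts),
                                        size = length(mem))
            clusters[[big[jj]]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  clusters <- lapply(clusters, function(cl) {
    list(members = cl$members,
         consensus = paste(c("N", "A", "C", "G", "T")[cl$cons + 1L],
                           collapse = ""),
         size = cl$size, is_major = cl$size >= min_size)
  })
  sizes <- vapply(clusters, `[[`, integer(1), "size")
  majors <- which(vapply(clusters, `[[`, logical(1), "is_major"))
  majors <- majors[order(-sizes[majors])]
  summary <- data.frame(
    form = if (length(majors)) paste0("LTR", seq_along(majors)) else character(0),
    size = sizes[majors],
    proportion = sizes[majors] / n)
  structure(
    list(clusters = clusters, summary = summary,
         minor_proportion = 1 - sum(summary$proportion),
         n_segments = n, family = attr(segments, "family")),
    class = "ltr_forms")
}

#' @export
print.ltr_forms <- function(x, ...) {
  cat(sprintf("ltr_forms (%s): %d segments, %d major form(s), minor %.2f\n",
              x$family %||% "?", x$n_segments, nrow(x$summary),
              x$minor_proportion))
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Conserved-region tree and recent-activity flag
#'
#' Extracts a conserved LTR region (default: the final 200 bp of the 3' LTR
#' end) from every segment fully covering it, computes pairwise p-distances,
#' and builds a neighbor-joining tree with bootstrap over alignment columns.
#' The recent-activity flag is true when at least `activity_min` segments form
#' a mutual >= `activity_identity` identity group - the signature of copies
#' that have had no time to diverge.
#'
#' @param segments [harvest_ltr_segments()] output.
#' @param region c(start, end) on LTR coordinates (0-based half-open);
#'   default last 200 bp.
#' @param bootstrap bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param max_tips build the tree on at most this many segments (sampled
#'   deterministically); the activity flag always uses all covering segments.
#' @param activity_identity,activity_min recent-activity clique thresholds.
#' @return list of class `ltr_region_tree`: `tree` (`phylo` or NULL if < 3
#'   covering segments), `recent_activity` (logical), `n_covering`,
#'   `clique_size`.
#' @export
conserved_region_tree <- function(segments, region = NULL, bootstrap = 1000,
                                  seed = 1L, max_tips = 80,
                                  activity_identity = 0.99, activity_min = 5) {
  ltr_len <- attr(segments, "ltr_len")
  if (is.null(region)) region <- c(max(ltr_len - 200, 0), ltr_len)
  cover <- segments$ltr_start <= region[1] & segments$ltr_end >= region[2]
  segs <- segments[cover, , drop = FALSE]
  attr(segs, "family") <- attr(segments, "family")
  attr(segs, "ltr_len") <- ltr_len
  n <- nrow(segs)
  if (n == 0)
    return(structure(list(tree = NULL, recent_activity = FALSE,
                          n_covering = 0L, clique_size = 0L),
                     class = "ltr_region_tree"))
  M <- segment_matrix(segs, ltr_len)[, (region[1] + 1):region[2], drop = FALSE]
  # pairwise identity over the region
  L <- ncol(M)
  idmat <- matrix(1, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      eq <- t(M[(i + 1):n, , drop = FALSE]) == M[i, ]
      idmat[i, (i + 1):n] <- idmat[(i + 1):n, i] <- colSums(eq) / L
    }
  }
  # greedy quasi-clique: start from the segment with most tight neighbours,
  # drop the weakest member until all pairs pass
  adj <- idmat >= activity_identity
  clique_size <- 0L
  if (n >= 1) {
    start <- which.max(rowSums(adj))
    members <- which(adj[start, ])
    repeat {
      sub <- adj[members, members, drop = FALSE]
      bad <- rowSums(!sub)
      if (!any(bad > 0) || length(members) <= 1) break
      members <- members[-which.max(bad)]
    }
    clique_size <- length(members)
  }
  tree <- NULL
  if (n >= 3) {
    tips <- if (n > max_tips)
      with_seed(seed, sort(sample.int(n, max_tips))) else seq_len(n)
    Mt <- M[tips, , drop = FALSE]
    labels <- sprintf("seg%03d_r%d", tips, segs$read[tips])
    pdist <- function(Mx) {
      k <- nrow(Mx)
      dm <- matrix(0, k, k, dimnames = list(labels, labels))
      for (i in seq_len(k - 1)) {
        eq <- t(Mx[(i + 1):k, , drop = FALSE]) == Mx[i, ]
        dm[i, (i + 1):k] <- dm[(i + 1):k, i] <- 1 - colSums(eq) / ncol(Mx)
      }
      stats::as.dist(dm)
    }
    tree <- nj_tree(pdist(Mt), bootstrap = bootstrap, seed = seed,
                    resample = function(i) {
                      cols <- sample.int(ncol(Mt), ncol(Mt), replace = TRUE)
                      pdist(Mt[, cols, drop = FALSE])
                    })
  }
  structure(list(tree = tree,
                 recent_activity = clique_size >= activity_min,
                 n_covering = n, clique_size = clique_size),
            class = "ltr_region_tree")
}

#' @export
print.ltr_region_tree <- function(x, ...) {
  cat(sprintf("ltr_region_tree: %d covering segments, clique %d, recent activity: %s\n",
              x$n_covering, x$clique_size, x$recent_activity))
  invisible(x)
}
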