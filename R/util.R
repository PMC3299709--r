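# Shared low-level helpers: seeded RNG scoping, random sequence generation,
# k-mer index wrappers around the C++ core.

.datatable.aware <- TRUE

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb the global stream.
#'
#' @param seed integer seed; `NULL` leaves the RNG untouched.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Random DNA sequence
#'
#' @param n length in bases.
#' @param gc GC content (proportion).
#' @return A single character string of A/C/G/T.
#' @export
random_dna <- function(n, gc = 0.35) {
  if (n <= 0) return("")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  idx <- sample.int(4L, n, replace = TRUE, prob = probs)
  intToUtf8(c(65L, 67L, 71L, 84L)[idx])
}

#' Reverse complement of character sequences
#'
#' @param x character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) cpp_revcomp(x)

#' Substitute bases at a given rate
#'
#' Draws a binomial number of positions and substitutes each with a different
#' base; used to derive diverged repeat subfamily variants and aged copies.
#'
#' @param seq single DNA string.
#' @param rate per-base substitution probability.
#' @return Mutated sequence string.
#' @keywords internal
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  if (n == 0 || rate <= 0) return(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- setdiff(bases, chars[p])
    chars[p] <- alt[sample.int(3L, 1)]
  }
  paste(chars, collapse = "")
}

#' Build a k-mer index over reference sequences
#'
#' Thin wrapper around the C++ seed index used by the aligner and the masker.
#'
#' @param seqs named character vector of sequences.
#' @param k k-mer size (4--15).
#' @param step index every `step`-th reference position.
#' @return An object of class `seq_index`.
#' @export
seq_index <- function(seqs, k = 13L, step = 2L) {
  stopifnot(is.character(seqs), length(seqs) >= 1)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ptr <- cpp_build_index(names(seqs), unname(seqs), as.integer(k), as.integer(step))
  structure(
    list(ptr = ptr, names = names(seqs), lengths = nchar(unname(seqs)),
         seqs = seqs, k = as.integer(k), step = as.integer(step)),
    class = "seq_index")
}

#' @export
print.seq_index <- function(x, ...) {
  cat(sprintf("seq_index: %d sequence(s), %.0f bases, k=%d step=%d\n",
              length(x$names), sum(x$lengths), x$k, x$step))
  invisible(x)
}

as_seq_index <- function(x, k = 13L, step = 2L) {
  if (inherits(x, "seq_index")) return(x)
  if (inherits(x, "ancestral_genome") || inherits(x, "clone_genome"))
    return(seq_index(x$chromosomes, k = k, step = step))
  if (is.character(x)) return(seq_index(x, k = k, step = step))
  stop("cannot build a sequence index from class ", paste(class(x), collapse = "/"))
}

# chromosome sequences from a genome-like object
genome_seqs <- function(x) {
  if (inherits(x, "ancestral_genome") || inherits(x, "clone_genome")) return(x$chromosomes)
  if (inherits(x, "seq_index")) return(x$seqs)
  if (is.character(x)) {
    if (length(x) == 0) return(setNames(character(0), character(0)))
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("expected a genome, seq_index or named character vector")
}
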