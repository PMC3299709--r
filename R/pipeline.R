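# Orchestration: a validated configuration object, the end-to-end pipeline
# (simulate -> mask/align -> coverage -> call per pair -> S-SAP -> LTR forms)
# and report assembly mirroring the study's summary tables.

#' Default pipeline configuration
#'
#' Every parameter has a default; unknown keys are rejected. Defaults are the
#' study conditions: somatic rates 1.6 SNPs / 5.1 indels / 35.2 TE insertions
#' per Mb, depth gate 6, within-clone allele frequency gate 0.3, alignment
#' quality gate 60, major-form thresholds 10 segments / 90% identity.
#'
#' @param ... named overrides of the defaults; nested blocks (e.g.
#'   `simulate = list(coverage = 8)`) are merged.
#' @param seed global seed; stage seeds are derived from it.
#' @return list of class `somaclone_config`.
#' @export
somaclone_config <- function(..., seed = 1L) {
  defaults <- list(
    seed = as.integer(seed),
    simulate = list(
      n_families = 6L, n_chrom = 4L,
      chrom_len = c(3.2e6, 2.7e6, 2.3e6, 1.8e6),
      repeat_fraction = 0.3,
      clones = c("cloneA", "cloneB"),
      snp_rate = 1.6, indel_rate = 5.1, te_rate = 35.2,
      coverage = 12,
      profile = read_profile()),
    align = align_params(),
    call = list(min_depth = 6L, min_maf = 0.3, min_qual = 60L,
                end_margin = 20L, cluster_bp = 15L, max_depth = NULL),
    ssap = list(enzyme_site = "TTAA", size_range = c(50, 1500),
                primer_width = 20L, bootstrap = 1000L, bin = 2),
    ltr = list(harvest_coverage = 1.2, min_size = 10L, identity = 0.90,
               min_identity = 0.75, min_len = 100L, bootstrap = 200L,
               max_tips = 60L),
    run = list(do_ssap = TRUE, do_ltr = TRUE, do_calls = TRUE))
  overrides <- list(...)
  merge_cfg <- function(base, over, path = "") {
    for (nm in names(over)) {
      if (!nm %in% names(base))
        stop("unknown configuration key: ", paste0(path, nm))
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !inherits(base[[nm]], "read_profile") &&
          !inherits(base[[nm]], "align_params")) {
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]], paste0(path, nm, "$"))
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  cfg <- merge_cfg(defaults, overrides)
  if (!is.null(overrides$seed)) cfg$seed <- as.integer(overrides$seed)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "somaclone_config")
}

stage_seed <- function(cfg, offset) (cfg$seed * 97L + offset) %% 2100000000L

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates the TE library, ancestral reference and clone genomes, generates
#' reads, runs the tiered alignment and coverage extraction per clone, calls
#' polymorphisms for every clone pair inside their >= min_depth shared
#' regions, and (optionally) performs the S-SAP and LTR-form analyses.
#' Deterministic for a fixed configuration seed.
#'
#' @param config a [somaclone_config()].
#' @param outdir optional output directory for artifact files and a manifest.
#' @return list of class `somaclone_run` with all intermediate objects,
#'   per-pair call sets and a [make_report()] summary.
#' @export
run_pipeline <- function(config = somaclone_config(), outdir = NULL) {
  cfg <- config
  sim <- cfg$simulate
  message("stage: simulate")
  library <- build_te_library(sim$n_families, seed = stage_seed(cfg, 1L))
  ancestor <- build_ancestral_genome(sim$n_chrom, sim$chrom_len,
                                     sim$repeat_fraction, library,
                                     seed = stage_seed(cfg, 2L))
  genome_bp <- sum(nchar(ancestor$chromosomes))
  n_read <- ceiling(sim$coverage * genome_bp / sim$profile$mean_len)
  clones <- list(); ledgers <- list(); readsets <- list()
  for (i in seq_along(sim$clones)) {
    cid <- sim$clones[i]
    dc <- derive_clone(ancestor, sim$snp_rate, sim$indel_rate, sim$te_rate,
                       library, seed = stage_seed(cfg, 10L + i), clone_id = cid)
    clones[[cid]] <- dc$genome
    ledgers[[cid]] <- dc$ledger
    readsets[[cid]] <- simulate_reads(dc$genome, n_read,
                                      seed = stage_seed(cfg, 20L + i),
                                      profile = sim$profile,
                                      organelles = ancestor$organelles,
                                      contaminants = ancestor$contaminants)
  }
  message("stage: align")
  index <- seq_index(ancestor$chromosomes, k = 13L, step = 2L)
  midx <- mask_index(library)
  alns <- lapply(sim$clones, function(cid) {
    run_tiered_alignment(readsets[[cid]], index, midx,
                         organelles = ancestor$organelles,
                         contaminants = ancestor$contaminants,
                         params = cfg$align)
  })
  names(alns) <- sim$clones
  message("stage: coverage")
  piles <- lapply(sim$clones, function(cid) {
    clone_pileup(alns[[cid]], index, readsets[[cid]], clone_id = cid)
  })
  names(piles) <- sim$clones
  regions6 <- lapply(piles, function(p)
    regions_at_depth(p$depth, cfg$call$min_depth))
  pairs <- if (length(sim$clones) >= 2) utils::combn(sim$clones, 2, simplify = FALSE)
           else list()
  calls <- list(); rates <- list(); shared <- list()
  if (cfg$run$do_calls && length(pairs)) {
    message("stage: call")
    # depth ceiling against collapsed-paralog pileups: well above the
    # expected coverage unless explicitly configured
    max_depth <- cfg$call$max_depth %||% ceiling(2.5 * sim$coverage + 6)
    for (pr in pairs) {
      key <- paste(pr, collapse = "_vs_")
      sh <- shared_regions(regions6[[pr[1]]], regions6[[pr[2]]])
      shared[[key]] <- sh
      cl <- call_pair(piles[[pr[1]]], piles[[pr[2]]], shared = sh,
                      reference = ancestor,
                      min_depth = cfg$call$min_depth,
                      min_maf = cfg$call$min_maf,
                      min_qual = cfg$call$min_qual,
                      end_margin = cfg$call$end_margin,
                      cluster_bp = cfg$call$cluster_bp,
                      max_depth = max_depth)
      ar <- annotate_and_rates(cl, ancestor$genes, sh)
      calls[[key]] <- ar$calls
      rates[[key]] <- cbind(pair = key, ar$rates, shared_mb = ar$shared_mb)
    }
  }
  ssap <- NULL
  if (cfg$run$do_ssap) {
    message("stage: ssap")
    ltr_fams <- Filter(function(f) nzchar(f$ltr_seq), library)
    band_sets <- lapply(clones, function(g) {
      out <- lapply(ltr_fams, function(f)
        insilico_ssap(g, f, enzyme_site = cfg$ssap$enzyme_site,
                      size_range = cfg$ssap$size_range))
      names(out) <- names(ltr_fams)
      out
    })
    bm <- band_matrix(band_sets, bin = cfg$ssap$bin)
    tree <- if (nrow(bm) >= 3)
      ssap_tree(bm, bootstrap = cfg$ssap$bootstrap, seed = stage_seed(cfg, 40L))
      else NULL
    ssap <- list(band_sets = band_sets, matrix = bm, tree = tree)
  }
  ltr <- NULL
  if (cfg$run$do_ltr) {
    message("stage: ltr")
    # the LTR-form survey characterises the genome-wide (ancestral) copy
    # structure; real somatic additions are a negligible fraction of the
    # copy number, so the survey reads are drawn from the ancestor at low
    # coverage rather than from the mutation-enriched clone read sets
    n_sub <- ceiling(cfg$ltr$harvest_coverage * genome_bp / sim$profile$mean_len)
    sub <- simulate_reads(ancestor, n_sub, seed = stage_seed(cfg, 50L),
                          profile = sim$profile,
                          organelles = ancestor$organelles,
                          contaminants = ancestor$contaminants)
    ltr_fams <- Filter(function(f) nzchar(f$ltr_seq), library)
    ltr <- lapply(ltr_fams, function(f) {
      segs <- harvest_ltr_segments(sub, f, min_identity = cfg$ltr$min_identity,
                                   min_len = cfg$ltr$min_len)
      if (nrow(segs) == 0)
        return(list(segments = segs, forms = NULL, region = NULL))
      forms <- cluster_forms(segs, min_size = cfg$ltr$min_size,
                             identity = cfg$ltr$identity)
      region <- conserved_region_tree(segs, bootstrap = cfg$ltr$bootstrap,
                                      seed = stage_seed(cfg, 60L),
                                      max_tips = cfg$ltr$max_tips)
      list(segments = segs, forms = forms, region = region)
    })
    names(ltr) <- names(ltr_fams)
  }
  run <- structure(
    list(config = cfg, library = library, ancestor = ancestor,
         clones = clones, ledgers = ledgers, readsets = readsets,
         alignments = alns, pileups = piles, regions6 = regions6,
         shared = shared, calls = calls, rates = rates, ssap = ssap,
         ltr = ltr),
    class = "somaclone_run")
  run$report <- make_report(run)
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' Assemble a run report
#'
#' Collects the summary tables of a pipeline run: read-classification
#' percentages per clone, coverage tiers, aligned-read composition, per-pair
#' polymorphism counts and per-Mb rates, S-SAP polymorphic-band percentage,
#' and LTR form distributions. Every number is recomputed from the run's
#' artifact objects.
#'
#' @param run a `somaclone_run` (possibly partial).
#' @return list of class `somaclone_report`.
#' @export
make_report <- function(run) {
  clones <- names(run$pileups)
  classification <- NULL
  if (length(run$alignments)) {
    classification <- do.call(rbind, lapply(clones, function(cid) {
      s <- run$alignments[[cid]]$summary
      cbind(clone = cid, s)
    }))
  }
  tiers <- NULL
  if (length(run$pileups)) {
    tiers <- do.call(rbind, lapply(clones, function(cid) {
      p <- run$pileups[[cid]]
      data.frame(clone = cid, depth = 1:6,
                 mb = vapply(1:6, function(k)
                   region_span(regions_at_depth(p$depth, k)) / 1e6, numeric(1)))
    }))
  }
  pair_counts <- NULL; total_sites <- NA_integer_
  if (length(run$calls)) {
    pair_counts <- do.call(rbind, lapply(names(run$calls), function(key) {
      cl <- run$calls[[key]]
      data.frame(pair = key,
                 ssr = 0L,
                 snp = sum(cl$type == "SNP"),
                 indel = sum(cl$type == "INDEL"),
                 te_insertion = sum(cl$type == "TE_INSERTION"))
    }))
    total_sites <- sum(pair_counts$snp + pair_counts$indel +
                         pair_counts$te_insertion)
  }
  rates <- if (length(run$rates)) do.call(rbind, run$rates) else NULL
  ssap_summary <- NULL
  if (!is.null(run$ssap)) {
    bm <- run$ssap$matrix
    ssap_summary <- data.frame(
      n_bands = ncol(bm),
      n_polymorphic = attr(bm, "n_polymorphic"),
      pct_polymorphic = attr(bm, "pct_polymorphic"),
      unique_patterns = nrow(unique(unclass(bm))) == nrow(bm))
  }
  ltr_summary <- NULL
  if (!is.null(run$ltr)) {
    ltr_summary <- do.call(rbind, lapply(names(run$ltr), function(fam) {
      x <- run$ltr[[fam]]
      if (is.null(x$forms)) return(NULL)
      props <- x$forms$summary$proportion
      props <- c(props, rep(NA_real_, max(0, 4 - length(props))))[1:4]
      data.frame(family = fam, n_segments = x$forms$n_segments,
                 n_major = nrow(x$forms$summary),
                 ltr1 = props[1], ltr2 = props[2], ltr3 = props[3],
                 ltr4 = props[4],
                 major_total = sum(x$forms$summary$proportion),
                 minor = x$forms$minor_proportion,
                 recent_activity = if (!is.null(x$region))
                   x$region$recent_activity else NA)
    }))
  }
  structure(
    list(classification = classification, coverage_tiers = tiers,
         pair_counts = pair_counts, total_sites = total_sites,
         rates = rates, ssap = ssap_summary, ltr_forms = ltr_summary),
    class = "somaclone_report")
}

#' @export
print.somaclone_report <- function(x, ...) {
  for (nm in names(x)) {
    if (is.null(x[[nm]]) || (length(x[[nm]]) == 1 && is.na(x[[nm]]))) next
    cat("--", nm, "--\n")
    if (is.data.frame(x[[nm]])) print(x[[nm]], row.names = FALSE, digits = 3)
    else print(x[[nm]])
  }
  invisible(x)
}

#' Write pipeline artifacts and a manifest
#'
#' @param run a `somaclone_run`.
#' @param outdir output directory.
#' @return Paths written, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(outdir, "reference.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(run$ancestor$chromosomes), p)
  paths <- c(paths, p)
  for (cid in names(run$ledgers)) {
    p <- file.path(outdir, paste0("ledger_", cid, ".tsv"))
    led <- run$ledgers[[cid]]
    led$pos1 <- led$pos + 1
    write.table(led, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (key in names(run$calls)) {
    p <- file.path(outdir, paste0("calls_", key, ".tsv"))
    cl <- run$calls[[key]]
    if (nrow(cl)) cl$pos1 <- cl$pos + 1
    write.table(cl, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (cid in names(run$alignments)) {
    p <- file.path(outdir, paste0("classification_", cid, ".tsv"))
    write.table(run$alignments[[cid]]$summary, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(run$ssap)) {
    p <- file.path(outdir, "ssap_bands.tsv")
    write.table(cbind(sample = rownames(run$ssap$matrix),
                      as.data.frame(unclass(run$ssap$matrix))),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    if (!is.null(run$ssap$tree)) {
      p <- file.path(outdir, "ssap_tree.nwk")
      ape::write.tree(run$ssap$tree, p)
      paths <- c(paths, p)
    }
  }
  if (!is.null(run$ltr)) {
    for (fam in names(run$ltr)) {
      x <- run$ltr[[fam]]
      if (!is.null(x$region) && !is.null(x$region$tree)) {
        p <- file.path(outdir, paste0("ltr_tree_", gsub("[^A-Za-z0-9]", "_", fam), ".nwk"))
        ape::write.tree(x$region$tree, p)
        paths <- c(paths, p)
      }
    }
  }
  manifest <- file.path(outdir, "manifest.tsv")
  md5 <- tools::md5sum(paths)
  mf <- data.frame(file = basename(names(md5)), md5 = unname(md5))
  write.table(mf, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  seeds <- file.path(outdir, "run_config.txt")
  writeLines(c(paste("seed:", run$config$seed),
               paste("clones:", paste(run$config$simulate$clones, collapse = ",")),
               paste("coverage:", run$config$simulate$coverage),
               paste("rates:", paste(c(run$config$simulate$snp_rate,
                                       run$config$simulate$indel_rate,
                                       run$config$simulate$te_rate),
                                     collapse = "/"))),
             seeds)
  invisible(c(paths, manifest, seeds))
}

#' Load a bundled published summary table
#'
#' The package ships small TSV copies of the study-scale summary tables
#' (alignment percentages, LTR form distributions, run statistics, headline
#' polymorphism counts) used for desk-scale arithmetic checks.
#'
#' @param name one of "alignment_summary", "ltr_forms", "run_stats",
#'   "polymorphism_counts".
#' @return data.frame.
#' @export
published_table <- function(name = c("alignment_summary", "ltr_forms",
                                     "run_stats", "polymorphism_counts")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("published_", name, ".tsv"),
                      package = "somaclone")
  if (!nzchar(path)) stop("table not found: ", name)
  read.delim(path, check.names = FALSE)
}
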