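# End-to-end orchestration: configuration, the full annotation pipeline, and
# the consistency-checked summary report.

.mir_defaults <- list(
  adapter = NA_character_,   # 3' adapter to trim (NA: input already trimmed)
  min_read_len = 16L,        # size filter
  # discovery
  max_gap = 65L, flank = 20L, window_max = 300L, min_stack = 10L,
  precursor_min = 50L, precursor_max = 300L, min_loop = 3L,
  # homology
  homology_min_len = 60L, homology_min_identity = 0.8,
  mature_max_mismatch = 1L,
  # curation
  peak_window = 2L, peak_min_fraction = 0.75, peak_min_count = 10L,
  min_paired = 0.6, switch_min_total = 20L,
  # genomic context
  context_min_fraction = 0.15,
  # miRtrons
  mirtron_intron_min = 50L, mirtron_intron_max = 120L,
  mirtron_min_coverage = 0.95, mirtron_tail_max = 3L,
  # piRNA
  pirna_window = 10000L, pirna_min_size = 1000L, pirna_min_hits = 25,
  pirna_min_sig = 0.5, pirna_size_min = 24L, pirna_size_max = 32L,
  pirna_min_size_frac = 0.75, pirna_merge_gap = 500L,
  seed = 1L
)

#' Pipeline configuration
#'
#' Flat key-value configuration holding every stage threshold, with documented
#' defaults. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults (see `mircurate:::.mir_defaults`).
#' @return A `mir_config` list.
#' @export
mir_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.mir_defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(.mir_defaults, over)
  structure(cfg, class = "mir_config")
}

#' Write / read a configuration file (YAML)
#'
#' @param config A `mir_config`.
#' @param path File path.
#' @return The path (write) or a `mir_config` (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(mir_config, yaml::read_yaml(path))
}

# pool per-tissue collapsed reads into one collapsed set; returns the pooled
# data.frame plus a seq x tissue count matrix
.pool_reads <- function(reads_by_tissue) {
  seqs <- unique(unlist(lapply(reads_by_tissue, `[[`, "seq")))
  mat <- matrix(0L, length(seqs), length(reads_by_tissue),
                dimnames = list(seqs, names(reads_by_tissue)))
  for (t in names(reads_by_tissue)) {
    r <- reads_by_tissue[[t]]
    mat[r$seq, t] <- mat[r$seq, t] + r$count
  }
  tot <- rowSums(mat)
  ord <- order(-tot, seqs)
  pooled <- data.frame(id = paste0("p", seq_along(seqs)), seq = seqs[ord],
                       count = as.integer(tot[ord]), stringsAsFactors = FALSE)
  list(pooled = pooled, matrix = mat[pooled$seq, , drop = FALSE])
}

#' Run the full annotation pipeline
#'
#' Stages: preprocessing (optional adapter trim, size filter, genome
#' matching), discovery of candidate precursors from read stacks, homology
#' mapping of reference hairpins with mature confirmation, candidate-set
#' merging, folding and curation (mature calls, two-peak test, structure
#' validation, confidence classes), conserved/novel splitting, genomic-context
#' classification, miRtron detection, non-templated 3'-addition tables,
#' piRNA cluster calling, and a consistency-checked summary. Deterministic
#' for fixed inputs and configuration.
#'
#' @param genome Named character vector of chromosomes (or FASTA path).
#' @param reads_by_tissue Named list of collapsed read data.frames (or paths).
#' @param features Gene-feature table ([read_gtf()]) or GTF path.
#' @param ref_hairpins,ref_matures Named character vectors (or FASTA paths)
#'   of reference hairpin/mature sequences; NULL disables homology.
#' @param existing_annotation Interval data.frame (or GFF3 path) of
#'   already-annotated miRNA loci; NULL means none.
#' @param config A `mir_config`.
#' @return A `mir_annotation` object.
#' @export
run_pipeline <- function(genome, reads_by_tissue, features,
                         ref_hairpins = NULL, ref_matures = NULL,
                         existing_annotation = NULL, config = mir_config()) {
  is_path <- function(x) is.character(x) && length(x) == 1L && file.exists(x)
  if (is_path(genome)) genome <- read_fasta(genome)
  if (is_path(features)) features <- read_gtf(features, drop_mirna = FALSE)
  if (is_path(ref_hairpins)) ref_hairpins <- read_fasta(ref_hairpins)
  if (is_path(ref_matures)) ref_matures <- read_fasta(ref_matures)
  if (is_path(existing_annotation))
    existing_annotation <- read_gff3(existing_annotation)
  reads_by_tissue <- lapply(reads_by_tissue, function(r) {
    if (is_path(r)) r <- read_collapsed(r)
    if (!is.null(config$adapter) && !is.na(config$adapter))
      r$seq <- trim_adapter(r$seq, config$adapter)
    size_filter(r, min_len = config$min_read_len)
  })
  tissues <- names(reads_by_tissue)

  ## genome matching (pooled across tissues)
  pool <- .pool_reads(reads_by_tissue)
  gm <- genome_matching_reads(pool$pooled, genome)
  matched_seqs <- pool$pooled$seq[pool$pooled$id %in% gm$reads$id]
  gm_totals <- colSums(pool$matrix[matched_seqs, , drop = FALSE])
  stats <- data.frame(
    tissue = tissues,
    trimmed_ge16 = vapply(reads_by_tissue, function(r) sum(r$count), 0),
    genome_matching = as.numeric(gm_totals[tissues]))

  ## discovery
  clusters <- cluster_read_stacks(gm$alignments, max_gap = config$max_gap)
  windows <- do.call(rbind, lapply(seq_len(nrow(clusters)), function(i)
    excise_precursors(clusters[i, ], genome, flank = config$flank,
                      window_max = config$window_max)))
  if (is.null(windows))
    windows <- genomic_intervals(character(0), integer(0), integer(0) + 1L)[0, ]
  disc <- propose_candidates(windows, gm$alignments, genome,
                             min_stack = config$min_stack,
                             min_len = config$precursor_min,
                             max_len = config$precursor_max,
                             min_loop = config$min_loop)

  ## homology
  conserved_loci <- NULL
  if (!is.null(ref_hairpins)) {
    hits <- map_hairpins(ref_hairpins, genome,
                         min_len = config$homology_min_len,
                         min_identity = config$homology_min_identity)
    hits <- confirm_mature(hits, ref_matures %||% character(0), genome,
                           max_mismatch = config$mature_max_mismatch)
    conserved_loci <- hits[hits$mature_confirmed, , drop = FALSE]
  }
  hom_cands <- if (!is.null(conserved_loci) && nrow(conserved_loci)) {
    data.frame(chrom = conserved_loci$chrom, start = conserved_loci$start,
               end = conserved_loci$end, strand = conserved_loci$strand,
               source = "HOMOLOGY", stringsAsFactors = FALSE)
  } else disc[0, c("chrom", "start", "end", "strand", "source")]

  merged <- merge_candidate_sets(
    disc[, c("chrom", "start", "end", "strand", "source")], hom_cands)
  # re-resolve merged strand by dominant aligned read counts
  if (nrow(merged)) {
    for (i in seq_len(nrow(merged))) {
      sel <- gm$alignments[gm$alignments$target == merged$chrom[i] &
                             gm$alignments$start < merged$end[i] &
                             gm$alignments$end > merged$start[i], ]
      if (nrow(sel)) {
        per <- tapply(sel$count, sel$strand, sum)
        merged$strand[i] <- names(per)[which.max(per)]
      }
    }
    merged$id <- sprintf("%s/%d-%d(%s)", sub("^chr", "", merged$chrom),
                         merged$start + 1L, merged$end, merged$strand)
    w <- merged$end - merged$start
    merged <- merged[w >= config$precursor_min & w <= config$precursor_max, ,
                     drop = FALSE]
  }

  ## curation
  precursors <- if (nrow(merged)) stats::setNames(vapply(seq_len(nrow(merged)),
    function(i) genome_seq(genome, merged$chrom[i], merged$start[i],
                           merged$end[i], merged$strand[i]), ""),
    merged$id) else character(0)
  folds <- lapply(precursors, nussinov_fold, min_loop = config$min_loop)
  profiles <- build_profiles(precursors, reads_by_tissue,
                             rpm_totals = gm_totals)
  matures <- list(); conf <- list()
  for (id in names(precursors)) {
    fold <- folds[[id]]
    mt <- call_matures(profiles$profiles[[id]], fold)
    tp <- two_peak_test(profiles$profiles[[id]], fold,
                        window = config$peak_window,
                        min_fraction = config$peak_min_fraction,
                        min_count = config$peak_min_count)
    m5 <- if (!is.null(mt$mature5)) c(mt$mature5$start, mt$mature5$end)
    m3 <- if (!is.null(mt$mature3)) c(mt$mature3$start, mt$mature3$end)
    sp <- validate_hairpin(fold, m5, m3, min_paired = config$min_paired)
    both <- !is.null(mt$mature5) && !is.null(mt$mature3)
    matures[[id]] <- mt
    conf[[id]] <- classify_confidence(id, sp, tp$overall, both)
  }
  confidence <- do.call(rbind, conf)

  ## conserved / novel split; novel loci require HIGH support
  split <- split_known_novel(merged,
                             conserved_loci %||% merged[0, ],
                             existing_annotation %||% merged[0, ])
  loci <- merged
  loci$class <- ifelse(loci$id %in% split$conserved$id, "conserved", "novel")
  loci$newly_annotated <- FALSE
  if (nrow(split$conserved))
    loci$newly_annotated[match(split$conserved$id, loci$id)] <-
      split$conserved$newly_annotated
  if (!is.null(confidence)) {
    loci$confidence <- confidence$class[match(loci$id, confidence$hairpin_id)]
    drop <- loci$class == "novel" & loci$confidence != "HIGH"
    loci <- loci[!drop, , drop = FALSE]
  } else {
    loci$confidence <- character(0)
  }

  ## genomic context (known-miRNA annotation rows removed first)
  feat_ctx <- features[!grepl("mir", paste(features$gene_id,
                                           features$transcript_id),
                              ignore.case = TRUE), , drop = FALSE]
  introns <- derive_introns(feat_ctx)
  ctx <- classify_locus(loci, feat_ctx, introns,
                        min_fraction = config$context_min_fraction)
  loci$context <- ctx$category
  loci$host_transcript <- ctx$host_transcript

  ## miRtrons
  mirtrons <- detect_mirtrons(
    loci, introns, pool$pooled, genome,
    intron_range = c(config$mirtron_intron_min, config$mirtron_intron_max),
    min_coverage = config$mirtron_min_coverage,
    tail_max = config$mirtron_tail_max, window = config$peak_window,
    min_fraction = config$peak_min_fraction, min_count = config$peak_min_count)
  loci$mirtron <- loci$id %in% mirtrons$hairpin_id

  ## arm abundance, switching, 5' proportion histogram
  arm_table <- arm_abundance_table(profiles, folds)
  arm_table <- arm_table[arm_table$hairpin_id %in% loci$id, , drop = FALSE]
  switching <- detect_arm_switching(arm_table,
                                    min_total = config$switch_min_total)
  prop_hist <- five_prime_fraction_histogram(arm_table)

  ## expression matrix (RPM of per-tissue aligned counts)
  expr <- matrix(0, nrow(loci), length(tissues),
                 dimnames = list(loci$id, tissues))
  for (id in loci$id) {
    pr <- profiles$profiles[[id]]
    for (t in names(pr$tissues))
      expr[id, t] <- rpm_normalize(sum(pr$tissues[[t]]$start_counts),
                                   gm_totals[[t]])
  }

  ## isomiR (non-templated 3' additions) for every called mature
  isomir <- list()
  for (i in seq_len(nrow(loci))) {
    id <- loci$id[i]
    for (arm in c("mature5", "mature3")) {
      mt <- matures[[id]][[arm]]
      if (is.null(mt)) next
      if (loci$strand[i] == "-") {
        mlocus <- genomic_intervals(loci$chrom[i], loci$end[i] - mt$end,
                                    loci$end[i] - mt$start, "-")
      } else {
        mlocus <- genomic_intervals(loci$chrom[i], loci$start[i] + mt$start,
                                    loci$start[i] + mt$end, "+")
      }
      key <- paste0(id, ifelse(arm == "mature5", "-5p", "-3p"))
      isomir[[key]] <- isoform_table(reads_by_tissue, mt$sequence, genome,
                                     mlocus)
    }
  }

  ## piRNA clusters per tissue
  pirna <- list()
  seq_of <- stats::setNames(pool$pooled$seq, pool$pooled$id)
  for (t in tissues) {
    aln <- gm$alignments
    tc <- pool$matrix[seq_of[aln$read_id], t]
    aln$count <- as.integer(tc)
    aln <- aln[aln$count > 0L, , drop = FALSE]
    aln <- reallocate_counts(aln, window = config$pirna_window)
    aln$seq <- unname(seq_of[aln$read_id])
    pirna[[t]] <- call_clusters(
      aln, t, min_size = config$pirna_min_size,
      min_hits = config$pirna_min_hits, min_sig = config$pirna_min_sig,
      size_range = c(config$pirna_size_min, config$pirna_size_max),
      min_size_frac = config$pirna_min_size_frac,
      merge_gap = config$pirna_merge_gap)
  }
  pirna_all <- do.call(rbind, pirna)
  rownames(pirna_all) <- NULL
  pirna_merged <- merge_clusters_across_tissues(pirna_all)

  out <- structure(list(
    loci = loci, confidence = confidence, matures = matures, folds = folds,
    profiles = profiles, arm_table = arm_table, switching = switching,
    five_prime_hist = prop_hist, expression = expr, isomir = isomir,
    pirna = pirna_all, pirna_merged = pirna_merged, mirtrons = mirtrons,
    stats = stats, config = config, tissues = tissues,
    discovery = disc, conserved_loci = conserved_loci), class = "mir_annotation")
  out$report <- report_summary(out)
  out
}

#' Summary report with consistency enforcement
#'
#' Recomputes the headline counts from the annotation object and enforces the
#' internal invariants: conserved = high + low among conserved loci, total =
#' conserved + novel, and context categories summing to the total. Violations
#' (e.g. tampered intermediates) raise a hard failure.
#'
#' @param x A `mir_annotation`.
#' @return data.frame of `key`/`value` summary rows.
#' @export
report_summary <- function(x) {
  loci <- x$loci
  total <- nrow(loci)
  n_cons <- sum(loci$class == "conserved")
  n_novel <- sum(loci$class == "novel")
  n_high_cons <- sum(loci$class == "conserved" & loci$confidence == "HIGH")
  n_low_cons <- sum(loci$class == "conserved" & loci$confidence == "LOW")
  if (n_cons + n_novel != total)
    stop("report inconsistency: conserved + novel != total", call. = FALSE)
  if (n_high_cons + n_low_cons != n_cons)
    stop("report inconsistency: high + low != conserved", call. = FALSE)
  if (any(loci$class == "novel" & loci$confidence != "HIGH"))
    stop("report inconsistency: low-confidence novel locus retained",
         call. = FALSE)
  ctx_counts <- table(factor(loci$context, levels = c("UTR", "EXON", "INTRON",
                                                      "INTERGENIC")))
  if (sum(ctx_counts) != total)
    stop("report inconsistency: context categories do not sum to total",
         call. = FALSE)
  pir_by_tissue <- if (nrow(x$pirna)) table(x$pirna$tissue) else table(character(0))
  rows <- c(total_loci = total, conserved = n_cons, novel = n_novel,
            newly_annotated = sum(loci$newly_annotated),
            high_confidence_conserved = n_high_cons,
            low_confidence_conserved = n_low_cons,
            mirtrons = sum(loci$mirtron),
            stats::setNames(as.integer(ctx_counts),
                            paste0("context_", names(ctx_counts))),
            pirna_clusters_total = nrow(x$pirna),
            stats::setNames(as.integer(pir_by_tissue),
                            paste0("pirna_", names(pir_by_tissue))),
            pirna_merged = nrow(x$pirna_merged),
            arm_switching = sum(x$switching$switching))
  data.frame(key = names(rows), value = as.numeric(rows),
             stringsAsFactors = FALSE)
}

#' @export
print.mir_annotation <- function(x, ...) {
  cat("mir_annotation:", nrow(x$loci), "miRNA loci across",
      length(x$tissues), "tissues\n")
  cat("  conserved:", sum(x$loci$class == "conserved"),
      "(newly annotated:", sum(x$loci$newly_annotated), ") novel:",
      sum(x$loci$class == "novel"), "\n")
  cat("  high/low confidence:", sum(x$loci$confidence == "HIGH"), "/",
      sum(x$loci$confidence == "LOW"), "\n")
  cat("  miRtrons:", sum(x$loci$mirtron), " piRNA clusters:",
      nrow(x$pirna), "\n")
  invisible(x)
}

#' @export
summary.mir_annotation <- function(object, ...) {
  report_summary(object)
}

#' Export the final annotation as GFF3
#'
#' Attributes carry class (conserved/novel), confidence, genomic context and
#' the miRtron flag.
#'
#' @param x A `mir_annotation`.
#' @param path Output path.
#' @export
write_annotation <- function(x, path) {
  g <- x$loci[, c("chrom", "start", "end", "strand", "id", "class",
                  "confidence", "context", "mirtron")]
  g$type <- rep("miRNA_hairpin", nrow(g))
  writeLines(to_gff3(g), path)
  invisible(path)
}
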