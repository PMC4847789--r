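# Simplified piRNA cluster calling: multimapper count reallocation by local
# unique-mapper density, candidate merging, explicit signature/size/abundance
# filters, and cross-tissue merging.
#
# This openly simplifies proTRAC-style cluster prediction: the density
# normalisation, p-value model and top-fraction test are replaced by four
# explicit, configurable filters (span, normalised hits, 1T/10A signature,
# size-range fraction).

#' Reallocate multimapper counts by local unique-mapper density
#'
#' A read with m genomic loci distributes its count across those loci
#' proportionally to the summed count of uniquely mapping reads within
#' `window` of each locus; when every locus has zero unique density the count
#' splits uniformly (1/m). Unique reads keep their full count, so summed
#' weights per read are exactly 1 and total counts are conserved.
#'
#' @param alignments 0-mismatch genome alignment table ([align_all()]).
#' @param window Unique-density window (+/- nt around the locus).
#' @return `alignments` with `weight` and `norm_count` columns.
#' @export
reallocate_counts <- function(alignments, window = 10000L) {
  if (nrow(alignments) == 0L) {
    alignments$weight <- numeric(0)
    alignments$norm_count <- numeric(0)
    return(alignments)
  }
  nloci <- table(alignments$read_id)
  alignments$n_loci <- as.integer(nloci[alignments$read_id])
  uni <- alignments[alignments$n_loci == 1L, , drop = FALSE]
  dens <- vapply(seq_len(nrow(alignments)), function(i) {
    if (alignments$n_loci[i] == 1L) return(1)
    sel <- uni$target == alignments$target[i] &
      uni$start <= alignments$end[i] + window &
      uni$end >= alignments$start[i] - window
    sum(uni$count[sel])
  }, 0)
  w <- numeric(nrow(alignments))
  for (ids in split(seq_len(nrow(alignments)), alignments$read_id)) {
    d <- dens[ids]
    w[ids] <- if (length(ids) == 1L) 1
              else if (sum(d) == 0) 1 / length(ids)
              else d / sum(d)
  }
  alignments$weight <- w
  alignments$norm_count <- alignments$count * w
  alignments
}

#' 1T/10A signature fraction
#'
#' Fraction of reads (count-weighted) whose first base is T or whose tenth
#' base is A — the union, the primary piRNA sequence signature. Reads shorter
#' than 10 nt are excluded from the denominator.
#'
#' @param seqs Read sequences, in mapped-strand orientation.
#' @param counts Optional per-read counts (default 1 each).
#' @return Fraction in `[0, 1]` (NaN when no read qualifies).
#' @export
signature_frac <- function(seqs, counts = NULL) {
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  ok <- nchar(seqs) >= 10L
  seqs <- seqs[ok]; counts <- counts[ok]
  if (!length(seqs)) return(NaN)
  hit <- substr(seqs, 1L, 1L) == "T" | substr(seqs, 10L, 10L) == "A"
  sum(counts[hit]) / sum(counts)
}

#' Call piRNA clusters in one tissue
#'
#' Candidates are merges (gap <= `merge_gap`, strand-blind) of the loci of
#' reads in `size_range`. A candidate is accepted when its span is at least
#' `min_size`, its summed reallocated hits at least `min_hits`, its 1T/10A
#' signature fraction at least `min_sig`, and the fraction of all overlapping
#' reads that lie in `size_range` at least `min_size_frac`. Strand class is
#' MONO_PLUS / MONO_MINUS when one strand carries at least 80% of hits, DUAL
#' otherwise.
#'
#' @param weighted Reallocated alignment table ([reallocate_counts()]) with
#'   a `seq` column (read sequences).
#' @param tissue Library label attached to the calls.
#' @param min_size Minimum cluster span (nt).
#' @param min_hits Minimum summed normalised hits.
#' @param min_sig Minimum signature fraction.
#' @param size_range Read-length range regarded as piRNA-sized.
#' @param min_size_frac Minimum fraction of in-range reads in the window.
#' @param merge_gap Maximum gap merged within a candidate.
#' @return data.frame of `pirna_cluster` rows: interval, `tissue`,
#'   `normalized_hits`, `n_distinct_seqs`, `frac_1T_or_10A`, `strand_class`.
#' @export
call_clusters <- function(weighted, tissue, min_size = 1000L, min_hits = 25,
                          min_sig = 0.5, size_range = c(24L, 32L),
                          min_size_frac = 0.75, merge_gap = 500L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), tissue = character(0),
                      normalized_hits = numeric(0), n_distinct_seqs = integer(0),
                      frac_1T_or_10A = numeric(0), strand_class = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(weighted) == 0L) return(empty)
  rl <- nchar(weighted$seq)
  in_range <- rl >= size_range[1] & rl <= size_range[2]
  pir <- weighted[in_range, , drop = FALSE]
  if (nrow(pir) == 0L) return(empty)
  res <- list()
  groups <- list()
  for (ch in unique(pir$target)) {
    sel <- pir[pir$target == ch, , drop = FALSE]
    sel <- sel[order(sel$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(sel$start[-1] >
                                     cummax(sel$end[-nrow(sel)]) + merge_gap)))
    groups <- c(groups, split(sel, grp))
  }
  for (mem in groups) {
    span_start <- min(mem$start); span_end <- max(mem$end)
    if (span_end - span_start < min_size) next
    hits <- sum(mem$norm_count)
    if (hits < min_hits) next
    sig <- signature_frac(mem$seq, mem$count)
    if (is.nan(sig) || sig < min_sig) next
    all_in_win <- weighted[weighted$target == mem$target[1] &
                             weighted$start < span_end &
                             weighted$end > span_start, , drop = FALSE]
    rl_all <- nchar(all_in_win$seq)
    frac_sized <- sum(all_in_win$count[rl_all >= size_range[1] &
                                         rl_all <= size_range[2]]) /
      sum(all_in_win$count)
    if (frac_sized < min_size_frac) next
    plus <- sum(mem$norm_count[mem$strand == "+"]) / hits
    strand_class <- if (plus >= 0.8) "MONO_PLUS"
                    else if (plus <= 0.2) "MONO_MINUS" else "DUAL"
    res[[length(res) + 1L]] <- data.frame(
      chrom = mem$target[1], start = span_start, end = span_end,
      tissue = tissue, normalized_hits = hits,
      n_distinct_seqs = length(unique(mem$seq)), frac_1T_or_10A = sig,
      strand_class = strand_class, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Merge piRNA clusters across tissues
#'
#' @param clusters Row-bound per-tissue cluster calls ([call_clusters()]).
#' @param mono_only Restrict to mono-strand clusters before merging.
#' @return Non-overlapping merged interval data.frame.
#' @export
merge_clusters_across_tissues <- function(clusters, mono_only = FALSE) {
  if (mono_only)
    clusters <- clusters[clusters$strand_class != "DUAL", , drop = FALSE]
  merge_intervals(clusters)
}
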