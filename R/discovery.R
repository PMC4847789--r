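# Candidate precursor discovery from genome-wide read alignments: read-stack
# clustering, precursor excision, hairpin filtering, and merging of candidate
# sets.

#' Cluster read stacks along the genome
#'
#' Same-strand perfect alignments whose intervals lie within `max_gap` of each
#' other are merged into one stranded cluster carrying the summed read count.
#'
#' @param alignments Alignment table ([align_all()]) of 0-mismatch genome
#'   hits; `target` is the chromosome.
#' @param max_gap Maximum gap (nt) bridged within a cluster.
#' @return data.frame: `chrom`, `start`, `end`, `strand`, `count`,
#'   `n_stacks`.
#' @export
cluster_read_stacks <- function(alignments, max_gap = 65L) {
  out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    strand = character(0), count = numeric(0),
                    n_stacks = integer(0), stringsAsFactors = FALSE)
  if (nrow(alignments) == 0L) return(out)
  res <- list()
  for (key in unique(paste(alignments$target, alignments$strand))) {
    sel <- alignments[paste(alignments$target, alignments$strand) == key, ]
    sel <- sel[order(sel$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(sel$start[-1] >
                                     cummax(sel$end[-nrow(sel)]) + max_gap)))
    for (g in split(seq_len(nrow(sel)), grp)) {
      res[[length(res) + 1L]] <- data.frame(
        chrom = sel$target[g[1]], start = min(sel$start[g]),
        end = max(sel$end[g]), strand = sel$strand[g[1]],
        count = sum(sel$count[g]), n_stacks = length(unique(sel$start[g])),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Excise candidate precursor windows around a read cluster
#'
#' Extends the cluster by `flank` on each side, capped at `window_max`; when
#' the extended span exceeds the cap, a 5'-anchored and a 3'-anchored window
#' are both emitted. Windows are clipped at chromosome ends.
#'
#' @param cluster One-row cluster data.frame ([cluster_read_stacks()]).
#' @param genome Named character vector of chromosomes.
#' @param flank Flank added on each side.
#' @param window_max Maximum window width.
#' @return Interval data.frame of candidate windows.
#' @export
excise_precursors <- function(cluster, genome, flank = 20L,
                              window_max = 300L) {
  chrom_len <- nchar(genome[[cluster$chrom]])
  st <- max(0L, cluster$start - flank)
  en <- min(chrom_len, cluster$end + flank)
  if (en - st <= window_max) {
    wins <- genomic_intervals(cluster$chrom, st, en, cluster$strand)
  } else {
    wins <- genomic_intervals(cluster$chrom,
                              c(st, en - window_max),
                              c(st + window_max, en),
                              cluster$strand)
  }
  wins
}

#' Propose hairpin candidates from excised windows
#'
#' A window becomes a candidate when it contains two read stacks with count
#' `>= min_stack` at least `min_sep` nt apart, the genomic span of those two
#' stacks (the putative mature duplex, which defines the precursor) folds
#' into a single stem-loop, and the stacks' modal reads pair with each other
#' at `>= min_duplex` of their bases in the best ungapped antiparallel
#' alignment — the Dicer-duplex signature. The candidate is trimmed to the
#' duplex extent.
#'
#' @param windows Interval data.frame of candidate windows.
#' @param alignments 0-mismatch genome alignment table of the reads.
#' @param genome Named character vector of chromosomes.
#' @param min_stack Minimum summed count of each of the two defining stacks.
#' @param min_len,max_len Admissible precursor length range after trimming.
#' @param min_loop Folding minimum loop length.
#' @param min_sep Minimum distance (nt) between the two stack 5' ends.
#' @param min_duplex Minimum mutual pairing fraction of the two modal reads.
#' @return data.frame of candidates: locus columns, `id`
#'   (`chrom/start-end(strand)`, 1-based display convention), `precursor_seq`,
#'   `source`.
#' @export
propose_candidates <- function(windows, alignments, genome, min_stack = 10L,
                               min_len = 50L, max_len = 300L, min_loop = 3L,
                               min_sep = 16L, min_duplex = 0.6) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      id = character(0), precursor_seq = character(0),
                      source = character(0), stringsAsFactors = FALSE)
  if (nrow(windows) == 0L) return(empty)
  res <- list()
  for (i in seq_len(nrow(windows))) {
    wn <- windows[i, ]
    hit <- alignments$target == wn$chrom & alignments$strand == wn$strand &
      alignments$start >= wn$start & alignments$end <= wn$end
    aln <- alignments[hit, , drop = FALSE]
    if (nrow(aln) == 0L) next
    # stack = summed count per biological 5' end (interval end on the minus
    # strand); length-variant reads of one stack share the 5' end, not the
    # genomic start
    p5 <- if (wn$strand == "-") aln$end else aln$start
    stacks <- tapply(aln$count, p5, sum)
    stacks <- sort(stacks, decreasing = TRUE)
    if (length(stacks) < 2L) next
    # the two defining stacks: the modal stack, and the strongest stack at
    # least min_sep away (jitter neighbours are not a second arm); the
    # duplex span of those stacks defines the precursor, flank noise does not
    pos <- as.integer(names(stacks))
    far <- which(abs(pos - pos[1]) >= min_sep)
    if (!length(far) || stacks[far[1]] < min_stack ||
        stacks[1] < min_stack) next
    gpos <- c(pos[1], pos[far[1]])
    top <- aln[p5 %in% gpos, , drop = FALSE]
    gs <- min(top$start); ge <- max(top$end)
    if (ge - gs < min_len || ge - gs > max_len) next
    seq <- genome_seq(genome, wn$chrom, gs, ge, wn$strand)
    fold <- nussinov_fold(seq, min_loop = min_loop)
    met <- hairpin_metrics(fold)
    if (!met$single_stem) next
    # the two defining stacks must be the mature duplex: their modal reads
    # have to pair with each other in an ungapped antiparallel alignment
    modal_seq <- vapply(gpos, function(g) {
      sub <- top[(if (wn$strand == "-") top$end else top$start) == g, ,
                 drop = FALSE]
      sub <- sub[which.max(sub$count), ]
      genome_seq(genome, sub$target, sub$start, sub$end, wn$strand)
    }, "")
    if (min(duplex_fraction(modal_seq[1], modal_seq[2])) < min_duplex) next
    res[[length(res) + 1L]] <- data.frame(
      chrom = wn$chrom, start = gs, end = ge, strand = wn$strand,
      id = sprintf("%s/%d-%d(%s)", sub("^chr", "", wn$chrom), gs + 1L, ge,
                   wn$strand),
      precursor_seq = genome_seq(genome, wn$chrom, gs, ge, wn$strand),
      source = "DISCOVERY", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  out <- out[!duplicated(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge two candidate sets into one non-overlapping set
#'
#' Overlapping loci (strand-blind, any shared base) are unioned into one
#' record spanning both; provenance is kept in the `source` column. The
#' merged record's strand is re-resolved from member strands (the first
#' stranded member wins; callers can re-resolve by dominant-read strand).
#' The operation is idempotent and commutative.
#'
#' @param set_a,set_b Candidate data.frames (`chrom`, `start`, `end`,
#'   `strand`, `source`; other columns dropped on merge).
#' @return Merged candidate data.frame with regenerated ids.
#' @export
merge_candidate_sets <- function(set_a, set_b) {
  cols <- c("chrom", "start", "end", "strand", "source")
  for (cl in setdiff(cols, names(set_a))) set_a[[cl]] <- NA_character_
  for (cl in setdiff(cols, names(set_b))) set_b[[cl]] <- NA_character_
  all <- rbind(set_a[, cols, drop = FALSE], set_b[, cols, drop = FALSE])
  if (nrow(all) == 0L) {
    all$id <- character(0)
    return(all)
  }
  cover <- merge_intervals(all)
  ov <- intersect_intervals(cover, all)
  res <- lapply(seq_len(nrow(cover)), function(i) {
    members <- all[ov$b_idx[ov$a_idx == i], , drop = FALSE]
    strand <- members$strand[members$strand %in% c("+", "-")]
    strand <- if (length(strand)) strand[1] else "."
    data.frame(chrom = cover$chrom[i],
               start = min(members$start), end = max(members$end),
               strand = strand,
               source = paste(sort(unique(members$source)), collapse = "+"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$id <- sprintf("%s/%d-%d(%s)", sub("^chr", "", out$chrom),
                    out$start + 1L, out$end, out$strand)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
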