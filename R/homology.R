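# Homology mapping of reference (miRBase-style) hairpins onto a genome,
# mature-sequence confirmation, conserved/novel splitting, and cross-species
# homologue search for novel hairpins.

# seeded, ungapped-extension local alignment of one query against one target
# strand; returns best non-redundant hits as data.frame
.ungapped_hits <- function(qseq, tseq, seed_len = 12L, match = 1L,
                           mismatch = -2L, xdrop = 8L) {
  qlen <- nchar(qseq); tlen <- nchar(tseq)
  if (qlen < seed_len || tlen < seed_len) return(NULL)
  qb <- utf8ToInt(qseq); tb <- utf8ToInt(tseq)
  # exact seed positions
  starts <- seq_len(qlen - seed_len + 1L)
  hits <- list()
  seen <- character(0)
  for (qs in starts) {
    seed <- substr(qseq, qs, qs + seed_len - 1L)
    m <- gregexpr(seed, tseq, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    for (ts in m) {
      # diagonal = ts - qs; extend along it
      diag_key <- as.character(ts - qs)
      if (diag_key %in% seen) next
      seen <- c(seen, diag_key)
      # maximal scoring run on this diagonal containing the seed
      off <- ts - qs
      lo <- max(1L, 1L + max(0L, -off))
      hi <- min(qlen, tlen - off)
      sc <- ifelse(qb[lo:hi] == tb[(lo:hi) + off], match, mismatch)
      # best segment containing [qs, qs+seed_len-1] by X-drop from the seed
      l <- qs; r <- qs + seed_len - 1L
      best_l <- l; cur <- 0; best <- 0
      i <- l - 1L
      while (i >= lo) {
        cur <- cur + sc[i - lo + 1L]
        if (cur > best) { best <- cur; best_l <- i }
        if (best - cur > xdrop) break
        i <- i - 1L
      }
      l <- best_l
      best_r <- r; cur <- 0; best <- 0
      i <- r + 1L
      while (i <= hi) {
        cur <- cur + sc[i - lo + 1L]
        if (cur > best) { best <- cur; best_r <- i }
        if (best - cur > xdrop) break
        i <- i + 1L
      }
      r <- best_r
      nmatch <- sum(qb[l:r] == tb[(l:r) + off])
      hits[[length(hits) + 1L]] <- data.frame(
        q_start = l, q_end = r, t_start = l + off, t_end = r + off,
        alignment_length = r - l + 1L,
        identity = nmatch / (r - l + 1L), stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

#' Map reference hairpins onto a genome
#'
#' Seeded (exact 12-mer), ungapped-extension local alignment on both strands;
#' hits are retained when the alignment length is at least `min_len` and the
#' identity at least `min_identity`. This fills the homology-search role with
#' explicit length/identity retention instead of database e-value statistics.
#'
#' @param query_hairpins Named character vector of reference hairpin
#'   sequences.
#' @param genome Named character vector of chromosomes.
#' @param min_len Minimum retained alignment length (nt).
#' @param min_identity Minimum retained identity fraction.
#' @return data.frame: `query_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `alignment_length`, `identity`.
#' @export
map_hairpins <- function(query_hairpins, genome, min_len = 60L,
                         min_identity = 0.8) {
  query_hairpins <- dna_canon(query_hairpins)
  genome <- dna_canon(genome)
  res <- list()
  for (qi in seq_along(query_hairpins)) {
    qid <- names(query_hairpins)[qi]
    for (ch in names(genome)) {
      for (sd in c("+", "-")) {
        tseq <- if (sd == "+") genome[[ch]] else rc(genome[[ch]])
        h <- .ungapped_hits(query_hairpins[[qi]], tseq)
        if (is.null(h)) next
        h <- h[h$alignment_length >= min_len & h$identity >= min_identity, ,
               drop = FALSE]
        if (nrow(h) == 0L) next
        tlen <- nchar(tseq)
        st <- if (sd == "+") h$t_start - 1L else tlen - h$t_end
        en <- if (sd == "+") h$t_end else tlen - h$t_start + 1L
        res[[length(res) + 1L]] <- data.frame(
          query_id = qid, chrom = ch, start = st, end = en, strand = sd,
          alignment_length = h$alignment_length, identity = h$identity,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(query_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), alignment_length = integer(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Confirm homology hits with mature sequences
#'
#' A hit is confirmed when at least one associated mature sequence aligns
#' entirely within the hit locus with at most `max_mismatch` mismatches and no
#' gaps.
#'
#' @param hits Hit table from [map_hairpins()].
#' @param mature_seqs Named character vector of mature sequences; names must
#'   start with the corresponding hairpin `query_id` (miRBase-style
#'   `<hairpin>-5p`/`-3p`).
#' @param genome Named character vector of chromosomes.
#' @param max_mismatch Maximum mismatches allowed (default 1).
#' @return `hits` with `mature_confirmed` and `mature_mismatches` columns.
#' @export
confirm_mature <- function(hits, mature_seqs, genome, max_mismatch = 1L) {
  hits$mature_confirmed <- rep(FALSE, nrow(hits))
  hits$mature_mismatches <- rep(NA_integer_, nrow(hits))
  if (nrow(hits) == 0L) return(hits)
  mature_seqs <- dna_canon(mature_seqs)
  for (i in seq_len(nrow(hits))) {
    locus_seq <- substr(genome[[hits$chrom[i]]], hits$start[i] + 1L,
                        hits$end[i])
    mats <- mature_seqs[startsWith(names(mature_seqs), hits$query_id[i])]
    if (!length(mats)) next
    aln <- align_all(mats, c(locus = locus_seq),
                     max_mismatch = as.integer(max_mismatch),
                     strands = "both")
    if (nrow(aln)) {
      hits$mature_confirmed[i] <- TRUE
      hits$mature_mismatches[i] <- min(aln$mismatches)
    }
  }
  hits
}

#' Split candidates into conserved and novel sets
#'
#' A candidate is conserved when it overlaps (any shared base, strand-blind) a
#' mature-confirmed homology locus, novel otherwise; a conserved locus absent
#' from the existing annotation is additionally reported as newly annotated.
#' Conserved and novel partition the candidate set.
#'
#' @param candidates Candidate data.frame (`chrom`, `start`, `end`, ...).
#' @param conserved_loci Confirmed homology loci ([confirm_mature()], rows
#'   with `mature_confirmed`).
#' @param existing_annotation Interval data.frame of already-annotated miRNA
#'   loci (may have zero rows).
#' @return List: `conserved`, `novel` (row subsets of `candidates`, with
#'   `newly_annotated` flag on the conserved set).
#' @export
split_known_novel <- function(candidates, conserved_loci,
                              existing_annotation) {
  n <- nrow(candidates)
  is_cons <- rep(FALSE, n)
  if (n && nrow(conserved_loci)) {
    ov <- intersect_intervals(candidates, conserved_loci)
    is_cons[unique(ov$a_idx)] <- TRUE
  }
  conserved <- candidates[is_cons, , drop = FALSE]
  novel <- candidates[!is_cons, , drop = FALSE]
  newly <- rep(TRUE, nrow(conserved))
  if (nrow(conserved) && nrow(existing_annotation)) {
    ov <- intersect_intervals(conserved, existing_annotation)
    newly[unique(ov$a_idx)] <- FALSE
  }
  conserved$newly_annotated <- newly
  list(conserved = conserved, novel = novel)
}

#' Search another genome for homologues of novel hairpins
#'
#' Pipeline: [map_hairpins()] with the default length-60 retention, mature
#' confirmation at one mismatch, then genomic-context labels computed on both
#' genomes. Loci failing mature confirmation are removed.
#'
#' @param novel_hairpins Named character vector of novel hairpin sequences.
#' @param novel_loci Interval data.frame of the same hairpins on the source
#'   genome (same order/names via `id` column).
#' @param matures Named character vector of the hairpins' mature sequences
#'   (names prefixed by hairpin name).
#' @param other_genome Named character vector: target genome.
#' @param other_features,source_features Gene-feature tables for the target
#'   and source genomes ([read_gtf()]).
#' @param min_len,min_identity Retention thresholds for [map_hairpins()].
#' @return Homologue table: species locus, source locus id, strand and the
#'   genomic-context label in both genomes.
#' @export
find_cross_species_homologs <- function(novel_hairpins, novel_loci, matures,
                                        other_genome, other_features,
                                        source_features, min_len = 60L,
                                        min_identity = 0.8) {
  hits <- map_hairpins(novel_hairpins, other_genome, min_len = min_len,
                       min_identity = min_identity)
  hits <- confirm_mature(hits, matures, other_genome, max_mismatch = 1L)
  hits <- hits[hits$mature_confirmed, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      source_locus = character(0),
                      source_context = character(0),
                      target_context = character(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  tgt_ctx <- classify_locus(hits, other_features)
  src_ctx <- classify_locus(novel_loci, source_features)
  src_map <- stats::setNames(src_ctx$category, novel_loci$id)
  data.frame(chrom = hits$chrom, start = hits$start, end = hits$end,
             strand = hits$strand, source_locus = hits$query_id,
             source_context = unname(src_map[hits$query_id]),
             target_context = tgt_ctx$category, stringsAsFactors = FALSE)
}
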