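# Complete ungapped alignment of short queries to targets with at most k
# mismatches, on both strands. This fills the exhaustive-matcher role (no
# heuristic misses) that tools like PatMaN play in small-RNA pipelines;
# matching is delegated to Biostrings, which guarantees completeness for
# fixed-position mismatch search.

#' Find all ungapped alignments with at most k mismatches
#'
#' Every placement of every query on every target (both strands when
#' requested) with Hamming distance `<= max_mismatch` is reported; there are
#' no heuristic misses and no gaps. Reverse-strand hits are reported in
#' forward-reference coordinates with `strand == "-"`.
#'
#' @param queries Either a named character vector of sequences or a collapsed
#'   read data.frame (`id`, `seq`, `count`).
#' @param targets Named character vector of target sequences.
#' @param max_mismatch 0 or 1 mismatches allowed.
#' @param strands `"both"` or `"forward"`.
#' @return data.frame: `read_id`, `target`, `start` (0-based), `end`
#'   (exclusive), `strand`, `mismatches`, `count`.
#' @export
align_all <- function(queries, targets, max_mismatch = 0L,
                      strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (!max_mismatch %in% c(0L, 1L))
    stop("max_mismatch must be 0 or 1", call. = FALSE)
  if (is.data.frame(queries)) {
    qseq <- dna_canon(queries$seq); qid <- queries$id; qcount <- queries$count
  } else {
    qseq <- dna_canon(unname(queries))
    qid <- names(queries) %||% as.character(seq_along(queries))
    qcount <- rep(1L, length(queries))
  }
  if (length(qseq) == 0L) stop("queries must be non-empty", call. = FALSE)
  targets <- dna_canon(targets)
  tnames <- names(targets) %||% as.character(seq_along(targets))
  empty <- data.frame(read_id = character(0), target = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      count = integer(0), stringsAsFactors = FALSE)

  res <- list()
  tset <- Biostrings::DNAStringSet(targets)
  use_pdict <- max_mismatch == 0L && length(qseq) > 25L
  strand_set <- if (strands == "both") c("+", "-") else "+"
  for (sd in strand_set) {
    qs <- if (sd == "+") qseq else rc(qseq)
    if (use_pdict) {
      # bulk exact matching: constant-width groups through a PDict
      for (w in unique(nchar(qs))) {
        sel <- which(nchar(qs) == w)
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(qs[sel]))
        for (ti in seq_along(tset)) {
          if (w > nchar(targets[ti])) next
          ml <- Biostrings::matchPDict(pd, tset[[ti]])
          nh <- S4Vectors::elementNROWS(ml)
          if (!sum(nh)) next
          qidx <- rep(sel, nh)
          st <- unlist(IRanges::start(ml), use.names = FALSE)
          res[[length(res) + 1L]] <- data.frame(
            read_id = qid[qidx], target = tnames[ti], start = st - 1L,
            end = st - 1L + w, strand = sd, mismatches = 0L,
            count = qcount[qidx], stringsAsFactors = FALSE)
        }
      }
    } else {
      for (qi in seq_along(qs)) {
        pat <- Biostrings::DNAString(qs[qi])
        w <- nchar(qs[qi])
        for (ti in seq_along(tset)) {
          if (w > nchar(targets[ti])) next
          mm <- Biostrings::matchPattern(pat, tset[[ti]],
                                         max.mismatch = max_mismatch,
                                         with.indels = FALSE)
          if (!length(mm)) next
          st <- IRanges::start(mm)
          nmis <- vapply(seq_along(st), function(k) {
            sub <- substr(targets[ti], st[k], st[k] + w - 1L)
            sum(utf8ToInt(sub) != utf8ToInt(qs[qi]))
          }, 0L)
          res[[length(res) + 1L]] <- data.frame(
            read_id = qid[qi], target = tnames[ti], start = st - 1L,
            end = st - 1L + w, strand = sd, mismatches = as.integer(nmis),
            count = qcount[qi], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$target, out$start, out$strand, out$read_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-matching reads
#'
#' A read is genome-matching when it has at least one perfect (0-mismatch)
#' alignment anywhere in the genome, on either strand. The total count of
#' genome-matching reads is the per-library normalisation denominator for
#' reads-per-million scaling.
#'
#' @param reads Collapsed read data.frame (`id`, `seq`, `count`).
#' @param genome Named character vector of chromosome sequences.
#' @return List: `reads` (matching subset), `n_reads` (summed raw counts),
#'   `alignments` (full 0-mismatch alignment table).
#' @export
genome_matching_reads <- function(reads, genome) {
  if (nrow(reads) == 0L)
    return(list(reads = reads, n_reads = 0L,
                alignments = align_all(data.frame(id = "x", seq = "ACGT",
                                                  count = 1L),
                                       c(chr = "GGGG"))[0, ]))
  aln <- align_all(reads, genome, max_mismatch = 0L, strands = "both")
  keep <- reads$id %in% aln$read_id
  list(reads = reads[keep, , drop = FALSE],
       n_reads = sum(reads$count[keep]),
       alignments = aln)
}
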