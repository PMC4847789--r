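# Genomic interval arithmetic, intron derivation, genic classification and
# miRtron detection.
#
# Intervals are plain data.frames (chrom, start, end, strand) in 0-based
# half-open coordinates; set operations are delegated to IRanges.

#' Construct a genomic interval table
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions (`end - start` is the length).
#' @param strand `"+"`, `"-"` or `"."` (strandless).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(end <= start))
    stop("intervals require 0 <= start < end", call. = FALSE)
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = rep_len(as.character(strand), length(start)),
             stringsAsFactors = FALSE)
}

# internal: data.frame <-> IRangesList keyed by chromosome
.as_irl <- function(x) {
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(i) IRanges::IRanges(start = x$start[i] + 1L, end = x$end[i]))
}

.irl_to_df <- function(irl) {
  if (!length(irl))
    return(genomic_intervals(character(0), integer(0), integer(0) + 1L)[0, ])
  chroms <- rep(names(irl), vapply(irl, length, 1L))
  st <- unlist(lapply(irl, IRanges::start), use.names = FALSE)
  en <- unlist(lapply(irl, IRanges::end), use.names = FALSE)
  data.frame(chrom = chroms, start = st - 1L, end = en, strand = ".",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Merge intervals into a minimal non-overlapping cover
#'
#' Strand-blind, mirroring default coordinate merging of BEDTools-style
#' workflows. Touching intervals (shared endpoint) are merged.
#'
#' @param x Interval data.frame.
#' @return Merged interval data.frame (strand `"."`).
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(x[0, c("chrom", "start", "end", "strand")])
  out <- .irl_to_df(lapply(.as_irl(x), IRanges::reduce))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Intersect two interval sets
#'
#' Returns every pairwise overlap span together with the row indices of the
#' originating records.
#'
#' @param a,b Interval data.frames.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `a_idx`, `b_idx`.
#' @export
intersect_intervals <- function(a, b) {
  out <- genomic_intervals(character(0), integer(0), integer(0) + 1L)[0, ]
  out$a_idx <- integer(0); out$b_idx <- integer(0)
  if (nrow(a) == 0L || nrow(b) == 0L) return(out)
  res <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    ra <- IRanges::IRanges(a$start[ia] + 1L, a$end[ia])
    rb <- IRanges::IRanges(b$start[ib] + 1L, b$end[ib])
    ov <- IRanges::findOverlaps(ra, rb)
    if (!length(ov)) next
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    st <- pmax(IRanges::start(ra)[qi], IRanges::start(rb)[si])
    en <- pmin(IRanges::end(ra)[qi], IRanges::end(rb)[si])
    res[[ch]] <- data.frame(chrom = ch, start = st - 1L, end = en, strand = ".",
                            a_idx = ia[qi], b_idx = ib[si],
                            stringsAsFactors = FALSE)
  }
  if (!length(res)) return(out)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Subtract one interval set from another
#'
#' For each record of `a`, removes the spans covered by any record of `b`
#' (per-record, like `bedtools subtract`). Strand-blind.
#'
#' @param a,b Interval data.frames.
#' @return data.frame of remaining spans, with `a_idx` pointing at the source
#'   record in `a`.
#' @export
subtract_intervals <- function(a, b) {
  if (nrow(a) == 0L) {
    out <- a[0, c("chrom", "start", "end", "strand")]
    out$a_idx <- integer(0)
    return(out)
  }
  bcov <- merge_intervals(b)
  res <- lapply(seq_len(nrow(a)), function(i) {
    ra <- IRanges::IRanges(a$start[i] + 1L, a$end[i])
    ib <- which(bcov$chrom == a$chrom[i])
    rb <- IRanges::IRanges(bcov$start[ib] + 1L, bcov$end[ib])
    left <- IRanges::setdiff(ra, rb)
    if (!length(left)) return(NULL)
    data.frame(chrom = a$chrom[i], start = IRanges::start(left) - 1L,
               end = IRanges::end(left), strand = a$strand[i], a_idx = i,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- a[0, c("chrom", "start", "end", "strand")]
    out$a_idx <- integer(0)
  }
  rownames(out) <- NULL
  out
}

#' Derive introns from a gene-feature table
#'
#' Introns are the gaps between consecutive exons of one transcript; strand is
#' inherited from the transcript.
#'
#' @param features Feature data.frame from [read_gtf()].
#' @return Interval data.frame with `transcript_id` column, sorted.
#' @export
derive_introns <- function(features) {
  ex <- features[features$type == "exon", , drop = FALSE]
  res <- lapply(split(ex, ex$transcript_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) >= 2L && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons within transcript ", e$transcript_id[1],
           call. = FALSE)
    if (nrow(e) < 2L) return(NULL)
    data.frame(chrom = e$chrom[-1], start = e$end[-nrow(e)], end = e$start[-1],
               strand = e$strand[-1], transcript_id = e$transcript_id[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      transcript_id = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Classify hairpin loci by genomic context
#'
#' A locus is assigned to UTR, EXON or INTRON when the overlap with a feature
#' of that category covers at least `min_fraction` of the hairpin length
#' (default 15%); otherwise it is INTERGENIC. When several categories pass,
#' precedence is UTR > EXON > INTRON (UTRs lie within exons, so UTR-first
#' keeps the distinct UTR category). Overlap is strand-blind.
#'
#' @param loci Interval data.frame of hairpin loci (rownames or `id` column
#'   used as hairpin ids).
#' @param features Gene-feature table ([read_gtf()]), ideally with known
#'   miRNA rows removed.
#' @param introns Intron table ([derive_introns()]); derived from `features`
#'   when missing.
#' @param min_fraction Minimum overlap as a fraction of hairpin length.
#' @return data.frame: `id`, `category`, `host_transcript`, `overlap_fraction`.
#' @export
classify_locus <- function(loci, features, introns = NULL,
                           min_fraction = 0.15) {
  if (is.null(introns)) introns <- derive_introns(features)
  ids <- if ("id" %in% names(loci)) loci$id else as.character(seq_len(nrow(loci)))
  cats <- list(
    UTR = features[features$type %in% c("five_prime_utr", "three_prime_utr"), ],
    EXON = features[features$type == "exon", ],
    INTRON = introns
  )
  n <- nrow(loci)
  category <- rep("INTERGENIC", n)
  host <- rep(NA_character_, n)
  frac <- rep(0, n)
  for (cat in c("UTR", "EXON", "INTRON")) {
    ft <- cats[[cat]]
    if (nrow(ft) == 0L) next
    ov <- intersect_intervals(loci, ft)
    if (nrow(ov) == 0L) next
    ov$frac <- (ov$end - ov$start) / (loci$end[ov$a_idx] - loci$start[ov$a_idx])
    # best feature per locus for this category
    agg <- ov[order(ov$a_idx, -ov$frac), ]
    agg <- agg[!duplicated(agg$a_idx), ]
    hit <- agg$frac >= min_fraction & category[agg$a_idx] == "INTERGENIC"
    idx <- agg$a_idx[hit]
    category[idx] <- cat
    frac[idx] <- agg$frac[hit]
    tid <- ft$transcript_id %||% rep(NA_character_, nrow(ft))
    host[idx] <- tid[agg$b_idx[hit]]
  }
  data.frame(id = ids, category = category, host_transcript = host,
             overlap_fraction = frac, stringsAsFactors = FALSE)
}

#' Detect miRtrons
#'
#' A miRtron precursor is released by splicing rather than Drosha cleavage, so
#' it should coincide with a short intron. A call requires: intron length in
#' `intron_range`; a hairpin locus covering at least `min_coverage` of the
#' intron; and a precise two-peak read pattern whose modal 5' and 3' arm
#' starts lie within `tail_max` nucleotides of the intron ends (allowing a
#' short trimmed 5'/3' tail).
#'
#' @param hairpins Interval data.frame of hairpin loci (with `id` column).
#' @param introns Intron table ([derive_introns()]).
#' @param reads Collapsed read data.frame (`id`, `seq`, `count`), typically
#'   pooled over all tissues.
#' @param genome Named character vector of chromosome sequences.
#' @param intron_range Admissible intron length range (inclusive).
#' @param min_coverage Minimum fraction of the intron covered by the hairpin.
#' @param tail_max Maximum tail length between modal read ends and intron ends.
#' @param window,min_fraction,min_count Two-peak test parameters (see
#'   [two_peak_test()]).
#' @return data.frame of calls: `hairpin_id`, intron coordinates,
#'   `intron_coverage`, `end5_offset`, `end3_offset`.
#' @export
detect_mirtrons <- function(hairpins, introns, reads, genome,
                            intron_range = c(50L, 120L), min_coverage = 0.95,
                            tail_max = 3L, window = 2L, min_fraction = 0.75,
                            min_count = 10L) {
  len <- introns$end - introns$start
  cand <- introns[len >= intron_range[1] & len <= intron_range[2], , drop = FALSE]
  out <- data.frame(hairpin_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0), strand = character(0),
                    intron_coverage = numeric(0), end5_offset = integer(0),
                    end3_offset = integer(0), stringsAsFactors = FALSE)
  if (nrow(cand) == 0L || nrow(hairpins) == 0L) return(out)
  ov <- intersect_intervals(hairpins, cand)
  if (nrow(ov) == 0L) return(out)
  ov$cov <- (ov$end - ov$start) / (cand$end[ov$b_idx] - cand$start[ov$b_idx])
  ov <- ov[ov$cov >= min_coverage, , drop = FALSE]
  if (nrow(ov) == 0L) return(out)
  calls <- lapply(seq_len(nrow(ov)), function(k) {
    it <- cand[ov$b_idx[k], ]
    hp_id <- if ("id" %in% names(hairpins)) hairpins$id[ov$a_idx[k]] else
      as.character(ov$a_idx[k])
    iseq <- substr(genome[[it$chrom]], it$start + 1L, it$end)
    if (identical(it$strand, "-")) iseq <- rc(iseq)
    n <- nchar(iseq)
    hits <- align_all(reads, stats::setNames(iseq, "intron"),
                      max_mismatch = 0L, strands = "forward")
    if (nrow(hits) == 0L) return(NULL)
    starts <- integer(n)
    agg <- tapply(hits$count, hits$start, sum)
    starts[as.integer(names(agg)) + 1L] <- as.integer(agg)
    mid <- n %/% 2L
    tp <- .two_peak_arms(starts, loop_start = mid, loop_end = mid,
                         window = window, min_fraction = min_fraction,
                         min_count = min_count)
    if (!tp$overall) return(NULL)
    # modal 3' arm read end (reads are stacks: use the modal start's reads)
    arm3_hits <- hits[hits$start >= mid, , drop = FALSE]
    modal_end <- arm3_hits$end[which.max(arm3_hits$count)]
    off5 <- tp$modal5                 # 0-based offset from intron 5' end
    off3 <- n - modal_end
    if (off5 > tail_max || off3 > tail_max) return(NULL)
    data.frame(hairpin_id = hp_id, chrom = it$chrom, start = it$start,
               end = it$end, strand = it$strand, intron_coverage = ov$cov[k],
               end5_offset = off5, end3_offset = off3,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls)) return(out)
  calls <- calls[!duplicated(calls$hairpin_id), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}
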