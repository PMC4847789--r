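# Small-RNA library preprocessing: adapter trimming, size filtering, read
# collapsing, size-distribution statistics and reads-per-million scaling.

#' Trim a 3' adapter from reads
#'
#' Exact-match trimming: the read is cut at the leftmost position where a
#' prefix of the adapter of length at least `min_overlap` matches exactly and
#' the match runs to the read end (or covers the whole adapter, for internal
#' adapter occurrences followed by spurious bases). Reads without a match are
#' returned unchanged; trimming never drops a read.
#'
#' @param reads Character vector of read sequences.
#' @param adapter Adapter sequence (3' adapter).
#' @param min_overlap Minimum matching adapter prefix length.
#' @return Character vector of trimmed sequences.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 8L) {
  adapter <- dna_canon(adapter)
  if (nchar(adapter) == 0L) stop("adapter must be non-empty", call. = FALSE)
  if (nchar(adapter) < min_overlap)
    stop("adapter shorter than min_overlap", call. = FALSE)
  reads <- dna_canon(reads)
  seed <- substr(adapter, 1L, min_overlap)
  alen <- nchar(adapter)
  vapply(reads, function(r) {
    rlen <- nchar(r)
    hits <- gregexpr(seed, r, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(r)
    for (p in hits) {
      avail <- min(alen, rlen - p + 1L)
      if (substr(r, p, p + avail - 1L) == substr(adapter, 1L, avail) &&
          (p + avail - 1L == rlen || avail == alen)) {
        return(substr(r, 1L, p - 1L))
      }
    }
    r
  }, "", USE.NAMES = FALSE)
}

#' Filter reads by minimum length
#'
#' @param reads Collapsed read data.frame or character vector.
#' @param min_len Minimum admissible length (inclusive).
#' @return Same type as input, reads shorter than `min_len` removed.
#' @export
size_filter <- function(reads, min_len = 16L) {
  if (is.data.frame(reads)) reads[nchar(reads$seq) >= min_len, , drop = FALSE]
  else reads[nchar(reads) >= min_len]
}

#' Collapse raw reads into distinct sequences with counts
#'
#' Count-conserving: the summed counts equal the number of input reads.
#'
#' @param reads Character vector of raw read sequences.
#' @param prefix Id prefix for collapsed reads.
#' @return data.frame (`id`, `seq`, `count`), sorted by decreasing count.
#' @export
collapse_reads <- function(reads, prefix = "read") {
  if (length(reads) == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  tb <- table(dna_canon(reads))
  ord <- order(-as.integer(tb), names(tb))
  data.frame(id = paste0(prefix, seq_along(tb)),
             seq = names(tb)[ord], count = as.integer(tb)[ord],
             stringsAsFactors = FALSE)
}

#' Read-length histogram
#'
#' @param reads Collapsed read data.frame.
#' @return Named integer vector: summed read counts per length.
#' @export
length_histogram <- function(reads) {
  if (nrow(reads) == 0L) return(stats::setNames(integer(0), character(0)))
  agg <- tapply(reads$count, nchar(reads$seq), sum)
  stats::setNames(as.integer(agg), names(agg))
}

#' Reads-per-million normalisation
#'
#' Scales a raw count to reads per million genome-matching reads of the same
#' library.
#'
#' @param count Raw read count(s).
#' @param genome_matching_total Library total of genome-matching reads.
#' @return Numeric RPM value(s).
#' @export
rpm_normalize <- function(count, genome_matching_total) {
  stopifnot_scalar_num(genome_matching_total, "genome_matching_total",
                       min = .Machine$double.xmin)
  count * 1e6 / genome_matching_total
}

#' Per-library preprocessing statistics
#'
#' Runs the preprocessing tiers on one library and reports the counts the
#' tiers retain: all reads, trimmed reads of length >= `min_len`, and
#' genome-matching reads, plus the length histogram of the filtered reads.
#'
#' @param raw_reads Character vector of raw reads (adapter-containing or not).
#' @param genome Named character vector of chromosome sequences.
#' @param tissue Library label.
#' @param adapter Optional adapter to trim (NULL to skip trimming).
#' @param min_len Size-filter threshold.
#' @return List with `tissue`, `total_reads`, `trimmed_ge16`,
#'   `genome_matching`, `length_histogram` and the collapsed filtered reads.
#' @export
library_stats <- function(raw_reads, genome, tissue, adapter = NULL,
                          min_len = 16L) {
  total <- length(raw_reads)
  trimmed <- if (is.null(adapter)) dna_canon(raw_reads)
             else trim_adapter(raw_reads, adapter)
  kept <- size_filter(trimmed, min_len = min_len)
  reads <- collapse_reads(kept)
  gm <- genome_matching_reads(reads, genome)
  list(tissue = tissue, total_reads = total, trimmed_ge16 = length(kept),
       genome_matching = gm$n_reads, length_histogram = length_histogram(reads),
       reads = reads, genome_matching_reads = gm$reads)
}
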