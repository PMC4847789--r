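# Non-templated 3' addition (isomiR) detection: adenylation and uridylation
# of mature miRNAs, tabulated per tissue.

#' Detect non-templated 3' additions of a mature miRNA
#'
#' Reads equal to the mature sequence are CANONICAL. Reads one base longer
#' whose prefix equals the mature are classified by the extra base: when it
#' differs from the templated genomic base immediately 3' of the mature locus
#' (strand-adjusted) the read is PLUS_A / PLUS_U (the extra base is a
#' non-templated addition) or PLUS_OTHER; when it matches the template the
#' read is a templated extension (CANONICAL_EXT) and never counted as an
#' addition. Reads matching the mature prefix are classified exactly once;
#' all other reads are ignored.
#'
#' @param reads Collapsed read data.frame (`id`, `seq`, `count`).
#' @param mature Mature sequence (string).
#' @param genome Named character vector of chromosomes.
#' @param locus One-row interval data.frame of the mature on the genome
#'   (`chrom`, `start`, `end`, `strand`).
#' @return data.frame: `isoform` (CANONICAL, CANONICAL_EXT, PLUS_A, PLUS_U,
#'   PLUS_OTHER), `count`, plus attribute `templated_base` (NA with a warning
#'   flag when the locus abuts the chromosome end).
#' @export
detect_nta <- function(reads, mature, genome, locus) {
  mature <- dna_canon(mature)
  mlen <- nchar(mature)
  chrom_len <- nchar(genome[[locus$chrom]])
  next_base <- NA_character_
  undecidable <- FALSE
  if (identical(locus$strand, "-")) {
    if (locus$start >= 1L)
      next_base <- rc(substr(genome[[locus$chrom]], locus$start, locus$start))
    else undecidable <- TRUE
  } else {
    if (locus$end < chrom_len)
      next_base <- substr(genome[[locus$chrom]], locus$end + 1L,
                          locus$end + 1L)
    else undecidable <- TRUE
  }
  iso <- c("CANONICAL", "CANONICAL_EXT", "PLUS_A", "PLUS_U", "PLUS_OTHER")
  counts <- stats::setNames(integer(5), iso)
  canon <- reads$seq == mature
  counts["CANONICAL"] <- sum(reads$count[canon])
  ext <- nchar(reads$seq) == mlen + 1L & startsWith(reads$seq, mature)
  if (any(ext)) {
    extra <- substr(reads$seq[ext], mlen + 1L, mlen + 1L)
    cnt <- reads$count[ext]
    cls <- if (undecidable) rep("PLUS_OTHER", length(extra)) else
      ifelse(extra == next_base, "CANONICAL_EXT",
             ifelse(extra == "A", "PLUS_A",
                    ifelse(extra == "T", "PLUS_U", "PLUS_OTHER")))
    agg <- tapply(cnt, cls, sum)
    counts[names(agg)] <- counts[names(agg)] + as.integer(agg)
  }
  out <- data.frame(isoform = iso, count = unname(counts),
                    stringsAsFactors = FALSE)
  attr(out, "templated_base") <- next_base
  attr(out, "undecidable") <- undecidable
  out
}

#' Tissue-by-isoform count matrix for one mature
#'
#' @param reads_by_tissue Named list of collapsed read data.frames.
#' @param mature,genome,locus As in [detect_nta()].
#' @return Integer matrix: tissues x isoform classes; row sums equal the
#'   total reads matching the mature prefix in that tissue.
#' @export
isoform_table <- function(reads_by_tissue, mature, genome, locus) {
  iso <- c("CANONICAL", "CANONICAL_EXT", "PLUS_A", "PLUS_U", "PLUS_OTHER")
  out <- matrix(0L, length(reads_by_tissue), 5L,
                dimnames = list(names(reads_by_tissue), iso))
  for (tissue in names(reads_by_tissue)) {
    rec <- detect_nta(reads_by_tissue[[tissue]], mature, genome, locus)
    out[tissue, ] <- rec$count
  }
  out
}
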