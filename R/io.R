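# Readers/writers for FASTA, GTF, GFF3, BED and collapsed-read files.
#
# Internal coordinate convention is 0-based half-open on all data frames;
# only the serializers below convert (GTF/GFF3 are 1-based inclusive,
# BED is 0-based half-open).

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and RNA `U` is stored as DNA `T`, so miRBase-style
#' RNA references and genomic DNA live in one alphabet.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate FASTA record names in ", path, call. = FALSE)
  out <- dna_canon(as.character(ss))
  names(out) <- nm
  out
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping.
#' @export
write_fasta <- function(x, path, wrap = 60L) {
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all sequences must be named", call. = FALSE)
  ss <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = as.integer(wrap))
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#'
#' @param path Path to a FASTQ file.
#' @return Character vector of read sequences (uppercased, U -> T).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  dna_canon(as.character(ss))
}

#' Read collapsed small-RNA reads
#'
#' Collapsed FASTA stores each distinct read once with an occurrence count in
#' the header, `>id_x<count>`.
#'
#' @param path Path to a collapsed FASTA file.
#' @return data.frame with columns `id`, `seq`, `count`.
#' @export
read_collapsed <- function(path) {
  x <- read_fasta(path)
  m <- regmatches(names(x), regexec("^(.*)_x([0-9]+)$", names(x)))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("malformed collapsed-read header (expected `id_x<count>`): ",
         names(x)[bad][1], call. = FALSE)
  count <- as.integer(vapply(m, `[`, "", 3L))
  if (any(count < 1L))
    stop("collapsed read count must be >= 1", call. = FALSE)
  data.frame(id = vapply(m, `[`, "", 2L), seq = unname(x), count = count,
             stringsAsFactors = FALSE)
}

#' Write collapsed small-RNA reads
#'
#' @param reads data.frame with columns `id`, `seq`, `count`.
#' @param path Output path.
#' @export
write_collapsed <- function(reads, path) {
  if (any(reads$count < 1L))
    stop("collapsed read count must be >= 1", call. = FALSE)
  x <- reads$seq
  names(x) <- paste0(reads$id, "_x", reads$count)
  write_fasta(x, path)
}

#' Read a GTF gene annotation into a feature table
#'
#' Coordinates are converted from GTF's 1-based inclusive convention to the
#' package-internal 0-based half-open convention. Only exon, UTR and CDS
#' features are kept.
#'
#' @param path Path to a GTF file.
#' @param drop_mirna Drop rows whose gene_id/gene_name/gene_biotype mentions
#'   an annotated miRNA (used before genomic-context classification so known
#'   miRNA gene rows do not self-classify hairpins).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`, `type`
#'   (exon/five_prime_utr/three_prime_utr/CDS), `transcript_id`, `gene_id`.
#' @export
read_gtf <- function(path, drop_mirna = FALSE) {
  raw <- readLines(path)
  dat <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(dat)) {
    f <- strsplit(dat, "\t", fixed = TRUE)
    st <- suppressWarnings(as.numeric(vapply(f, `[`, "", 4L)))
    en <- suppressWarnings(as.numeric(vapply(f, `[`, "", 5L)))
    bad <- which(!is.na(st) & !is.na(en) & en < st)
    if (length(bad))
      stop("GTF parse error: end < start at line ",
           which(!startsWith(raw, "#") & nzchar(raw))[bad[1]], call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  keep_types <- c("exon", "five_prime_utr", "three_prime_utr", "UTR", "CDS")
  gr <- gr[as.character(gr$type) %in% keep_types]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    transcript_id = if (!is.null(gr$transcript_id)) gr$transcript_id else NA_character_,
    gene_id = if (!is.null(gr$gene_id)) gr$gene_id else NA_character_,
    stringsAsFactors = FALSE
  )
  df$type[df$type == "UTR"] <- "three_prime_utr"
  if (drop_mirna) {
    nm <- paste(df$gene_id,
                if (!is.null(gr$gene_name)) gr$gene_name else "",
                if (!is.null(gr$gene_biotype)) gr$gene_biotype else "")
    df <- df[!grepl("mir|miRNA", nm, ignore.case = TRUE), , drop = FALSE]
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a feature table as GTF
#'
#' @param features data.frame as returned by [read_gtf()] (0-based half-open).
#' @param path Output path.
#' @export
write_gtf <- function(features, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   features$gene_id, features$transcript_id)
  lines <- sprintf("%s\tmircurate\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   features$chrom, features$type,
                   features$start + 1L, features$end,
                   features$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Format intervals as BED6 text
#'
#' @param x Interval data.frame (`chrom`, `start`, `end`, optional `strand`,
#'   `name`, `score`). BED is 0-based half-open, identical to the internal
#'   convention.
#' @return Character vector of BED lines.
#' @export
to_bed <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  name <- if ("name" %in% names(x)) x$name else rep(".", nrow(x))
  score <- if ("score" %in% names(x)) x$score else rep(".", nrow(x))
  sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, x$start, x$end, name, score, strand)
}

#' Format intervals as GFF3 text
#'
#' Converts internal 0-based half-open coordinates to GFF3's 1-based
#' inclusive convention. Columns other than the positional ones are emitted
#' as `key=value` attributes.
#'
#' @param x Interval data.frame; requires `chrom`, `start`, `end`; optional
#'   `strand`, `type`, `id`, plus arbitrary attribute columns.
#' @param source Value for the GFF3 source column.
#' @return Character vector of GFF3 lines (including the version pragma).
#' @export
to_gff3 <- function(x, source = "mircurate") {
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  type <- if ("type" %in% names(x)) x$type else rep("region", nrow(x))
  attr_cols <- setdiff(names(x), c("chrom", "start", "end", "strand", "type"))
  attrs <- rep("", nrow(x))
  if (nrow(x)) {
    attrs <- vapply(seq_len(nrow(x)), function(i) {
      vals <- vapply(attr_cols, function(cl) {
        v <- x[[cl]][i]
        if (is.na(v)) NA_character_ else paste0(cl, "=", v)
      }, "")
      paste(vals[!is.na(vals)], collapse = ";")
    }, "")
  }
  attrs[attrs == ""] <- "."
  c("##gff-version 3",
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            x$chrom, source, type, x$start + 1L, x$end, strand, attrs))
}

#' Read a GFF3 file into an interval table
#'
#' @param path Path to a GFF3 file.
#' @return data.frame with 0-based half-open `chrom`, `start`, `end`,
#'   `strand`, `type` and one column per attribute key present.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  mc <- S4Vectors::mcols(gr)
  for (cl in setdiff(colnames(mc), c("type", "source", "phase", "score"))) {
    v <- mc[[cl]]
    if (is(v, "CharacterList")) v <- vapply(v, function(z) paste(z, collapse = ","), "")
    df[[cl]] <- as.character(v)
  }
  df
}
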