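# Synthetic-data generator: a toy genome, gene annotation, reference miRNA
# set and per-tissue small-RNA libraries with planted ground truth.
#
# The generator emulates the structure of a multi-tissue small-RNA study:
# nine tissue libraries; 20-24 nt Dicer-like read stacks on planted stem-loops
# with modal 5' starts at both arms and minor start jitter; a length peak at
# 22 nt; non-templated 3' A/U isomiRs at controllable fractions; a uniform
# degradation background; and 24-30 nt piRNA-cluster reads with a first-base-T
# bias concentrated in the testis library.

#' Default tissue panel
#' @export
MIR_TISSUES <- c("blood", "brain", "heart", "kidney", "lung", "ovary",
                 "skin", "smooth_muscle", "testis")

#' Generate a random toy genome
#'
#' @param n_chrom Number of chromosomes.
#' @param length_per_chrom Length of each chromosome (>= 10000).
#' @param gc GC content in (0, 1); 0 gives an A/T-only sequence.
#' @param seed RNG seed (the output is deterministic for a fixed seed).
#' @return Named character vector (`chr1`, `chr2`, ...).
#' @export
make_genome <- function(n_chrom, length_per_chrom, gc = 0.42, seed = 1L) {
  if (n_chrom < 1L || length_per_chrom < 10000L)
    stop("need n_chrom >= 1 and length_per_chrom >= 10000", call. = FALSE)
  if (gc < 0 || gc >= 1) stop("gc must be in [0, 1)", call. = FALSE)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- vapply(seq_len(n_chrom), function(i) {
    paste(sample(names(p), length_per_chrom, replace = TRUE, prob = p),
          collapse = "")
  }, "")
  stats::setNames(out, paste0("chr", seq_len(n_chrom)))
}

#' Construct a hairpin plant specification
#'
#' @param id Plant identifier.
#' @param context Genomic context the plant must realise: `"INTRON"`,
#'   `"EXON"`, `"UTR"`, `"INTERGENIC"` or `"MIRTRON"`.
#' @param arm5_seq,arm3_seq Mature arm sequences, 20-24 nt; `arm3_seq` must
#'   reverse-complement `arm5_seq` at all but at most 3 positions (A-T, G-C
#'   and G-T wobble all count as pairing).
#' @param loop_seq Terminal loop, 8-20 nt.
#' @param strand `"+"` or `"-"`.
#' @param tissue_expression Named numeric vector of expected read counts.
#' @param arm5_fraction Fraction of reads from the 5' arm; scalar or named
#'   per-tissue vector.
#' @param nta_fractions Named fractions for non-templated additions,
#'   `c(A = ..., U = ...)`; must sum below 1.
#' @param jitter_prob Probability a read 5' start deviates from the modal
#'   start.
#' @param tail3 Extra intron nucleotides past the hairpin 3' end (miRtron
#'   plants only; emulates a short trimmed tail).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(id, context, arm5_seq, arm3_seq, loop_seq, strand = "+",
                       tissue_expression, arm5_fraction = 0.7,
                       nta_fractions = c(A = 0, U = 0), jitter_prob = 0.1,
                       tail3 = 0L) {
  context <- match.arg(context, c("INTRON", "EXON", "UTR", "INTERGENIC",
                                  "MIRTRON"))
  arm5_seq <- dna_canon(arm5_seq); arm3_seq <- dna_canon(arm3_seq)
  loop_seq <- dna_canon(loop_seq)
  if (nchar(arm5_seq) < 20L || nchar(arm5_seq) > 24L)
    stop("arm5_seq must be 20-24 nt", call. = FALSE)
  if (nchar(loop_seq) < 8L || nchar(loop_seq) > 20L)
    stop("loop_seq must be 8-20 nt", call. = FALSE)
  a5 <- strsplit(arm5_seq, "")[[1]]
  a3r <- rev(strsplit(arm3_seq, "")[[1]])
  L <- min(length(a5), length(a3r))
  npair <- sum(vapply(seq_len(L), function(i) .PAIRABLE[a5[i], a3r[i]], TRUE))
  if (npair < nchar(arm5_seq) - 3L)
    stop("arm3_seq must pair with arm5_seq at >= (length - 3) positions",
         call. = FALSE)
  if (sum(nta_fractions) >= 1)
    stop("nta_fractions must sum below 1", call. = FALSE)
  structure(list(id = id, context = context, arm5_seq = arm5_seq,
                 arm3_seq = arm3_seq, loop_seq = loop_seq, strand = strand,
                 tissue_expression = tissue_expression,
                 arm5_fraction = arm5_fraction, nta_fractions = nta_fractions,
                 jitter_prob = jitter_prob, tail3 = as.integer(tail3)),
            class = "plant_spec")
}

#' Insert a hairpin into a genome
#'
#' Writes `arm5 + loop + arm3` (reverse-complemented for minus-strand plants)
#' at the requested position and returns the realised interval.
#'
#' @param genome Named character vector of chromosomes.
#' @param spec A `plant_spec`.
#' @param chrom Chromosome name.
#' @param position 0-based start position.
#' @param occupied Optional interval data.frame of previously planted
#'   features; overlap raises a placement error.
#' @return List: `genome` (updated), `interval` (one-row interval data.frame).
#' @export
plant_hairpin <- function(genome, spec, chrom, position, occupied = NULL) {
  hp <- paste0(spec$arm5_seq, spec$loop_seq, spec$arm3_seq)
  w <- nchar(hp)
  if (position < 0L || position + w > nchar(genome[[chrom]]))
    stop("position leaves no room for the hairpin", call. = FALSE)
  iv <- genomic_intervals(chrom, position, position + w, spec$strand)
  if (!is.null(occupied) && nrow(occupied) &&
      nrow(intersect_intervals(iv, occupied)))
    stop("placement error: hairpin overlaps a previously planted feature",
         call. = FALSE)
  written <- if (spec$strand == "-") rc(hp) else hp
  substr(genome[[chrom]], position + 1L, position + w) <- written
  list(genome = genome, interval = iv)
}

# strand-adjusted genomic substring: 0-based half-open interval
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(genome[[chrom]], start + 1L, end)
  if (identical(strand, "-")) rc(s) else s
}

# sample one plant's reads in one tissue (raw, uncollapsed)
.plant_reads <- function(genome, pl, tissue, depth_scale) {
  n <- round(pl[[paste0("expr_", tissue)]] * depth_scale)
  if (is.na(n) || n <= 0L) return(character(0))
  af <- pl[[paste0("af_", tissue)]]
  l5 <- nchar(pl$arm5_seq); ll <- nchar(pl$loop_seq); l3 <- nchar(pl$arm3_seq)
  chrom_len <- nchar(genome[[pl$chrom]])
  ws <- max(0L, pl$start - 10L); we <- min(chrom_len, pl$end + 10L)
  hs <- genome_seq(genome, pl$chrom, ws, we, pl$strand)
  off <- if (pl$strand == "-") we - pl$end else pl$start - ws
  m5 <- pl$arm5_seq; m3 <- pl$arm3_seq
  arm5 <- stats::runif(n) < af
  u <- stats::runif(n)
  isoA <- u < pl$nta_A
  isoU <- !isoA & u < pl$nta_A + pl$nta_U
  plain <- !isoA & !isoU
  reads <- character(n)
  reads[isoA] <- paste0(ifelse(arm5[isoA], m5, m3), "A")
  reads[isoU] <- paste0(ifelse(arm5[isoU], m5, m3), "T")
  np <- sum(plain)
  if (np) {
    shift <- integer(np)
    jit <- stats::runif(np) < pl$jitter_prob
    shift[jit] <- sample(1:5, sum(jit), replace = TRUE) *
      sample(c(-1L, 1L), sum(jit), replace = TRUE)
    len <- sample(c(21L, 22L, 23L), np, replace = TRUE,
                  prob = c(0.2, 0.6, 0.2))
    st <- off + ifelse(arm5[plain], 0L, l5 + ll) + shift
    st <- pmax(0L, pmin(st, nchar(hs) - len))
    reads[plain] <- substr(rep(hs, np), st + 1L, st + len)
  }
  reads
}

# sample one piRNA cluster's reads in one tissue
.cluster_reads <- function(genome, cl, tissue, depth_scale) {
  n <- round(cl[[paste0("expr_", tissue)]] * depth_scale)
  if (is.na(n) || n <= 0L) return(character(0))
  span <- genome_seq(genome, cl$chrom, cl$start, cl$end, cl$strand)
  w <- nchar(span)
  bases <- strsplit(span, "")[[1]]
  tpos <- which(bases == "T"); npos <- which(bases != "T")
  tpos <- tpos[tpos <= w - 30L]; npos <- npos[npos <= w - 30L]
  want_t <- stats::runif(n) < cl$frac_1T
  if (!length(tpos)) want_t[] <- FALSE
  if (!length(npos)) want_t[] <- TRUE
  st <- integer(n)
  st[want_t] <- sample(tpos, sum(want_t), replace = TRUE)
  st[!want_t] <- sample(npos, sum(!want_t), replace = TRUE)
  len <- sample(24:30, n, replace = TRUE)
  substr(rep(span, n), st, st + len - 1L)
}

#' Simulate one tissue's small-RNA library
#'
#' Draws reads from every planted hairpin (modal arm sequences with start
#' jitter and read length in \{21, 22, 23\} weighted 0.2/0.6/0.2, plus
#' non-templated +A/+U isoforms at the planted fractions), from piRNA
#' clusters (24-30 nt, first-base-T biased) and from a uniform degradation
#' background.
#'
#' @param truth Truth table from [synthetic_dataset()] (or [read_truth()]).
#' @param genome Named character vector of chromosomes.
#' @param tissue Tissue name (must be one of `truth$tissues`).
#' @param depth_scale Multiplier on all expected counts.
#' @param seed RNG seed; the output is byte-deterministic for a fixed seed.
#' @return Collapsed read data.frame (`id`, `seq`, `count`).
#' @export
simulate_reads <- function(truth, genome, tissue, depth_scale = 1, seed = 1L) {
  if (!tissue %in% truth$tissues)
    stop("unknown tissue: ", tissue, call. = FALSE)
  if (depth_scale <= 0) stop("depth_scale must be > 0", call. = FALSE)
  set.seed(seed)
  reads <- character(0)
  for (i in seq_len(nrow(truth$plants)))
    reads <- c(reads, .plant_reads(genome, truth$plants[i, ], tissue,
                                   depth_scale))
  for (i in seq_len(nrow(truth$pirna_clusters)))
    reads <- c(reads, .cluster_reads(genome, truth$pirna_clusters[i, ],
                                     tissue, depth_scale))
  n_bg <- round(length(reads) * truth$bg_frac / (1 - truth$bg_frac))
  if (n_bg > 0L) {
    chroms <- sample(names(genome), n_bg, replace = TRUE,
                     prob = nchar(genome))
    len <- sample(16:30, n_bg, replace = TRUE)
    st <- vapply(seq_len(n_bg), function(k) {
      sample.int(nchar(genome[[chroms[k]]]) - len[k], 1L) - 1L
    }, 0L)
    sd <- sample(c("+", "-"), n_bg, replace = TRUE)
    bg <- vapply(seq_len(n_bg), function(k) {
      genome_seq(genome, chroms[k], st[k], st[k] + len[k], sd[k])
    }, "")
    reads <- c(reads, bg)
  }
  collapse_reads(reads, prefix = paste0(tissue, "_r"))
}

#' Write truth files (tabular + GFF3)
#'
#' @param truth Truth list from [synthetic_dataset()].
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "truth_plants.tsv")
  p2 <- file.path(dir, "truth_pirna.tsv")
  p3 <- file.path(dir, "truth.gff3")
  p4 <- file.path(dir, "truth_meta.tsv")
  utils::write.table(truth$plants, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$pirna_clusters, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gff <- truth$plants[, c("chrom", "start", "end", "strand", "id")]
  gff$type <- rep("miRNA_hairpin", nrow(gff))
  gff$mirtron <- tolower(truth$plants$context == "MIRTRON")
  writeLines(to_gff3(gff), p3)
  meta <- data.frame(key = c("bg_frac", "tissues"),
                     value = c(truth$bg_frac,
                               paste(truth$tissues, collapse = ",")))
  utils::write.table(meta, p4, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}

#' Read truth files back
#'
#' Round-trips the tabular truth written by [write_truth()].
#'
#' @param dir Directory holding the truth files.
#' @return Truth list (`plants`, `pirna_clusters`, `tissues`, `bg_frac`).
#' @export
read_truth <- function(dir) {
  plants <- utils::read.table(file.path(dir, "truth_plants.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  pir <- utils::read.table(file.path(dir, "truth_pirna.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  meta <- utils::read.table(file.path(dir, "truth_meta.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  list(plants = plants, pirna_clusters = pir,
       tissues = strsplit(meta$value[meta$key == "tissues"], ",")[[1]],
       bg_frac = as.numeric(meta$value[meta$key == "bg_frac"]))
}
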