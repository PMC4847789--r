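# The bundled synthetic study: a deterministic multi-tissue small-RNA dataset
# with planted ground truth, used by the end-to-end validation and the
# examples. Defaults: 3 chromosomes x 200 kb, 30 planted miRNA hairpins
# (3 of them miRtrons; UTR/exon/intron/intergenic contexts), 9 tissue
# libraries, and 2 testis-restricted piRNA clusters.

# random arm pair: arm3 reverse-complements arm5 except at k planted
# mismatches (interior positions, mutated to a non-pairing base). Arms with
# strong internal self-structure are rejected: a genuine pre-miRNA arm pairs
# with the opposite arm, not with itself, and a self-folding arm would not
# present the planted duplex as the dominant structure.
.random_arm_pair <- function(len = 22L, k = 0L, max_try = 200L) {
  for (try in seq_len(max_try)) {
    a5 <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    a3r <- vapply(a5, function(b) switch(b, A = "T", C = "G", G = "C",
                                         T = "A"), "")
    if (k > 0L) {
      pos <- sample(4:(len - 3L), k)
      for (p in pos) {
        bad <- c("A", "C", "G", "T")[!.PAIRABLE[a5[p], ]]
        a3r[p] <- sample(bad, 1L)
      }
    }
    arm5 <- paste(a5, collapse = "")
    arm3 <- paste(rev(a3r), collapse = "")
    self5 <- nrow(nussinov_fold(arm5)$clean_pairs)
    self3 <- nrow(nussinov_fold(arm3)$clean_pairs)
    if (self5 == 0L && self3 == 0L)
      return(list(arm5 = arm5, arm3 = arm3))
  }
  stop("could not sample a self-structure-free arm pair", call. = FALSE)
}

# find a free placement on a random chromosome; occupied is a growing
# interval data.frame, buffered to keep features apart
.place <- function(width, genome, occupied, buffer = 300L, max_try = 5000L) {
  chroms <- names(genome)
  for (k in seq_len(max_try)) {
    ch <- sample(chroms, 1L)
    hi <- nchar(genome[[ch]]) - width - 2000L
    st <- sample(2000:hi, 1L)
    iv <- genomic_intervals(ch, max(0L, st - buffer), st + width + buffer)
    if (nrow(occupied) == 0L ||
        nrow(intersect_intervals(iv, occupied)) == 0L)
      return(list(chrom = ch, start = st,
                  occupied = rbind(occupied,
                                   genomic_intervals(ch, st, st + width))))
  }
  stop("could not place feature of width ", width, call. = FALSE)
}

#' Generate the bundled synthetic small-RNA study
#'
#' Builds a toy genome, plants 30 miRNA hairpins (3 miRtrons, plus UTR, exon,
#' intron and intergenic loci; 18 present in a miRBase-style reference set of
#' which 12 are already in the existing annotation), 2 testis-restricted
#' piRNA clusters with a first-base-T bias, gene models realising each
#' context, and 9 tissue libraries. Plant behaviour covers the phenomena the
#' pipeline must detect: precise two-peak processing (most plants), imprecise
#' processing (high start jitter), single-arm expression, low expression,
#' +A/+U non-templated additions, and tissue-dependent arm switching.
#'
#' @param seed RNG seed; every output is deterministic given the seed.
#' @param n_chrom,chrom_len,gc Genome shape.
#' @param tissues Tissue panel (default [MIR_TISSUES]).
#' @param depth_scale Library depth multiplier.
#' @param bg_frac Fraction of each library that is uniform degradation
#'   background.
#' @param dir Optional directory; when given, all inputs (genome FASTA,
#'   annotation GTF, reference FASTAs, existing-annotation GFF3, per-tissue
#'   collapsed reads) and the truth files are written there.
#' @return List: `genome`, `truth` (plants, pirna_clusters, features,
#'   tissues, bg_frac), `reads_by_tissue`, `ref_hairpins`, `ref_matures`,
#'   `existing_annotation`, and `paths` when `dir` was given.
#' @export
synthetic_dataset <- function(seed = 42L, n_chrom = 3L, chrom_len = 200000L,
                              gc = 0.42, tissues = MIR_TISSUES,
                              depth_scale = 1, bg_frac = 0.05, dir = NULL) {
  genome <- make_genome(n_chrom, chrom_len, gc = gc, seed = seed)
  set.seed(seed + 1L)

  contexts <- c(rep("MIRTRON", 3), rep("UTR", 3), rep("EXON", 4),
                rep("INTRON", 8), rep("INTERGENIC", 12))
  n_plants <- length(contexts)
  conserved_idx <- c(1, 4, 5, 7, 8, 11:15, 19:26)
  high_jitter_idx <- c(19, 20)     # imprecise processing -> LOW
  single_arm_idx <- c(21, 22)      # no 3p expression -> LOW
  tiny_idx <- c(23, 27)            # total count < 50 (23 conserved, 27 novel)
  switching_idx <- c(24, 25, 26)   # opposite arm dominance across tissues
  nta_idx <- c(4, 5, 7, 8, 11)     # +A/+U isoforms planted
  in_existing_idx <- conserved_idx[1:12]

  plants <- list()
  occupied <- genomic_intervals(character(0), integer(0), integer(0) + 1L)[0, ]
  features <- list()
  tx_n <- 0L

  for (i in seq_len(n_plants)) {
    ctx <- contexts[i]
    # 1-2 planted duplex mismatches: genuine pre-miRNA duplexes are imperfect,
    # and a perfect duplex makes the hairpin an exact palindrome whose reads
    # align to both genomic strands, leaving the locus strand undefined
    arms <- .random_arm_pair(22L, k = sample(1:2, 1L))
    loop <- paste0("C", paste(sample(c("A", "C"), sample(16:19, 1L),
                                     replace = TRUE), collapse = ""))
    strand <- sample(c("+", "-"), 1L)
    tail3 <- if (ctx == "MIRTRON" && i == 3L) 2L else 0L
    jit <- if (i %in% high_jitter_idx) 0.8 else 0.1
    af <- if (i %in% single_arm_idx) 1.0 else sample(c(0.3, 0.65, 0.7), 1L)
    nta <- if (i %in% nta_idx) c(A = 0.1, U = 0.3) else c(A = 0, U = 0)

    # per-tissue expression
    expr <- stats::setNames(numeric(length(tissues)), tissues)
    af_t <- stats::setNames(rep(af, length(tissues)), tissues)
    if (i %in% tiny_idx) {
      expr[sample(tissues, 1L)] <- 20
    } else if (i %in% switching_idx) {
      expr[c("brain", "lung", "testis", "blood", "heart")] <- 400
      af_t[c("brain", "lung", "testis")] <- 0.8
      af_t[c("blood", "heart")] <- 0.2
    } else {
      on <- sample(tissues, sample(4:9, 1L))
      expr[on] <- sample(150:1000, length(on), replace = TRUE)
    }

    spec <- plant_spec(id = sprintf("plant%02d", i), context = ctx,
                       arm5_seq = arms$arm5, arm3_seq = arms$arm3,
                       loop_seq = loop, strand = strand,
                       tissue_expression = expr, arm5_fraction = af_t,
                       nta_fractions = nta, jitter_prob = jit, tail3 = tail3)
    hp_w <- nchar(arms$arm5) + nchar(loop) + nchar(arms$arm3)
    hosted <- ctx %in% c("MIRTRON", "UTR", "EXON", "INTRON")
    reserve <- hp_w + if (hosted) 1600L else 200L
    pl <- .place(reserve, genome, occupied)
    occupied <- pl$occupied
    hp_start <- pl$start + if (hosted) 800L else 100L
    planted <- plant_hairpin(genome, spec, pl$chrom, hp_start)
    genome <- planted$genome
    iv <- planted$interval

    # flanking base control so planted +A/+U additions are non-templated:
    # the strand-adjusted base right after the 3p mature must not be A or T
    if (sum(nta) > 0) {
      if (strand == "+")
        substr(genome[[pl$chrom]], iv$end + 1L, iv$end + 1L) <- "C"
      else
        substr(genome[[pl$chrom]], iv$start, iv$start) <- "G"
    }

    # gene features realising the context (transcript strand = plant strand)
    if (hosted) {
      tx_n <- tx_n + 1L
      tid <- sprintf("TX%02d", tx_n); gid <- sprintf("G%02d", tx_n)
      add_feat <- function(type, st, en) {
        features[[length(features) + 1L]] <<- data.frame(
          chrom = pl$chrom, start = st, end = en, strand = strand,
          type = type, transcript_id = tid, gene_id = gid,
          stringsAsFactors = FALSE)
      }
      if (ctx %in% c("MIRTRON", "INTRON")) {
        if (ctx == "MIRTRON") {
          ist <- if (strand == "+") iv$start else iv$start - tail3
          ien <- if (strand == "+") iv$end + tail3 else iv$end
        } else {
          ist <- iv$start - 250L; ien <- iv$end + 250L
        }
        add_feat("exon", ist - 250L, ist)
        add_feat("exon", ien, ien + 250L)
      } else if (ctx == "EXON") {
        add_feat("exon", iv$start - 100L, iv$end + 100L)
        add_feat("exon", iv$end + 400L, iv$end + 600L)
      } else {                       # UTR
        add_feat("exon", iv$start - 150L, iv$end + 150L)
        add_feat("three_prime_utr", iv$start - 50L, iv$end + 50L)
      }
    }

    row <- data.frame(id = spec$id, context = ctx,
                      conserved = i %in% conserved_idx,
                      in_existing = i %in% in_existing_idx,
                      chrom = pl$chrom, start = iv$start, end = iv$end,
                      strand = strand, arm5_seq = arms$arm5,
                      loop_seq = loop, arm3_seq = arms$arm3,
                      tail3 = tail3, jitter_prob = jit,
                      nta_A = unname(nta["A"]), nta_U = unname(nta["U"]),
                      switching = i %in% switching_idx,
                      stringsAsFactors = FALSE)
    for (t in tissues) row[[paste0("expr_", t)]] <- unname(expr[t])
    for (t in tissues) row[[paste0("af_", t)]] <- unname(af_t[t])
    plants[[i]] <- row
  }
  plants <- do.call(rbind, plants)

  # distractor transcripts (no plants inside)
  for (k in 1:4) {
    tx_n <- tx_n + 1L
    pl <- .place(1500L, genome, occupied)
    occupied <- pl$occupied
    sd <- sample(c("+", "-"), 1L)
    st <- pl$start
    for (e in 0:2)
      features[[length(features) + 1L]] <- data.frame(
        chrom = pl$chrom, start = st + e * 500L, end = st + e * 500L + 250L,
        strand = sd, type = "exon", transcript_id = sprintf("TX%02d", tx_n),
        gene_id = sprintf("G%02d", tx_n), stringsAsFactors = FALSE)
  }
  # a known-miRNA gene row overlapping an intergenic conserved plant; it must
  # be dropped before context classification (drop_mirna) or the plant would
  # classify as exonic
  p19 <- plants[19, ]
  features[[length(features) + 1L]] <- data.frame(
    chrom = p19$chrom, start = p19$start - 10L, end = p19$end + 10L,
    strand = p19$strand, type = "exon", transcript_id = "known-mir-1-tx",
    gene_id = "known-mir-1", stringsAsFactors = FALSE)
  features <- do.call(rbind, features)

  # piRNA clusters: testis-restricted, first-base-T biased
  pir <- list()
  for (k in 1:2) {
    w <- c(2000L, 2400L)[k]
    pl <- .place(w + 200L, genome, occupied)
    occupied <- pl$occupied
    row <- data.frame(id = paste0("pirna", k), chrom = pl$chrom,
                      start = pl$start + 100L, end = pl$start + 100L + w,
                      strand = c("+", "-")[k], frac_1T = 0.85,
                      stringsAsFactors = FALSE)
    for (t in tissues)
      row[[paste0("expr_", t)]] <- if (t == "testis") 2500 else 0
    pir[[k]] <- row
  }
  pir <- do.call(rbind, pir)

  # multimapping decoy: duplicate a 150 bp tile of cluster 1 into free
  # space, so some piRNA reads map to two loci and exercise count
  # reallocation; the tile is kept short so that unique-mapper density
  # reallocation leaves the copy far below the cluster-calling abundance
  # threshold (repeat-annotation-based suppression of larger duplications
  # is out of scope)
  pl <- .place(150L, genome, occupied)
  occupied <- pl$occupied
  src <- substr(genome[[pir$chrom[1]]], pir$start[1] + 601L, pir$start[1] + 750L)
  substr(genome[[pl$chrom]], pl$start + 1L, pl$start + 150L) <- src

  truth <- list(plants = plants, pirna_clusters = pir, features = features,
                tissues = tissues, bg_frac = bg_frac)

  reads_by_tissue <- lapply(seq_along(tissues), function(ti) {
    simulate_reads(truth, genome, tissues[ti], depth_scale = depth_scale,
                   seed = seed + 100L + ti)
  })
  names(reads_by_tissue) <- tissues

  cons <- plants[plants$conserved, ]
  ref_hairpins <- stats::setNames(
    vapply(seq_len(nrow(cons)), function(k)
      paste0(cons$arm5_seq[k], cons$loop_seq[k], cons$arm3_seq[k]), ""),
    paste0("ref-", cons$id))
  ref_matures <- stats::setNames(
    c(cons$arm5_seq, cons$arm3_seq),
    c(paste0("ref-", cons$id, "-5p"), paste0("ref-", cons$id, "-3p")))
  exist <- plants[plants$in_existing, c("chrom", "start", "end", "strand", "id")]
  exist$type <- "miRNA_primary_transcript"

  out <- list(genome = genome, truth = truth,
              reads_by_tissue = reads_by_tissue,
              ref_hairpins = ref_hairpins, ref_matures = ref_matures,
              existing_annotation = exist)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  gtf = file.path(dir, "annotation.gtf"),
                  ref_hairpins = file.path(dir, "ref_hairpins.fa"),
                  ref_matures = file.path(dir, "ref_matures.fa"),
                  existing = file.path(dir, "existing.gff3"))
    write_fasta(genome, paths$genome)
    write_gtf(features, paths$gtf)
    write_fasta(ref_hairpins, paths$ref_hairpins)
    write_fasta(ref_matures, paths$ref_matures)
    writeLines(to_gff3(exist), paths$existing)
    paths$reads <- character(0)
    for (t in tissues) {
      p <- file.path(dir, paste0("reads_", t, ".fa"))
      write_collapsed(reads_by_tissue[[t]], p)
      paths$reads[t] <- p
    }
    write_truth(truth, dir)
    out$paths <- paths
  }
  out
}
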