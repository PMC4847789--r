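test_that("interval constructors validate their invariants", {
  expect_error(genomic_intervals("chr1", 10, 10), "start < end")
  expect_error(genomic_intervals("chr1", -1, 5), "start < end")
  expect_error(genomic_intervals("chr1", 1, 5, "x"), "strand")
  iv <- genomic_intervals("chr1", 0, 10)
  expect_equal(iv$end - iv$start, 10L)
})

test_that("merge, intersect and subtract satisfy the worked examples", {
  a <- genomic_intervals(c("c", "c"), c(0, 5), c(10, 15))
  m <- merge_intervals(a)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 15L))

  x <- intersect_intervals(genomic_intervals("c", 0, 10),
                           genomic_intervals("c", 8, 20))
  expect_equal(c(x$start, x$end), c(8L, 10L))
  expect_equal(x$end - x$start, 2L)

  s <- subtract_intervals(a, a)
  expect_equal(nrow(s), 0L)
})

test_that("interval operations agree with per-base set arithmetic", {
  set.seed(13)
  for (i in 1:50) {
    n_univ <- 2000L
    mk <- function(k) {
      st <- sample(0:(n_univ - 50L), k)
      genomic_intervals("chr1", st, st + sample(1:50, k, replace = TRUE))
    }
    a <- mk(sample(3:15, 1)); b <- mk(sample(3:15, 1))
    # merge
    got <- merge_intervals(a)
    expect_equal(got[, c("chrom", "start", "end")],
                 runs_to_df(oracle_cover(a, n_univ)),
                 ignore_attr = TRUE)
    # intersect: union of overlap spans equals cover intersection
    got_i <- intersect_intervals(a, b)
    expect_equal(oracle_cover(got_i, n_univ),
                 oracle_cover(a, n_univ) & oracle_cover(b, n_univ))
    # subtract: union of remnants equals cover difference
    got_s <- subtract_intervals(a, b)
    expect_equal(oracle_cover(got_s, n_univ),
                 oracle_cover(a, n_univ) & !oracle_cover(b, n_univ))
  }
})

test_that("introns are the gaps between consecutive exons of a transcript", {
  ft <- data.frame(chrom = "chr1", start = c(100L, 200L), end = c(160L, 260L),
                   strand = "-", type = "exon", transcript_id = "t1",
                   gene_id = "g1", stringsAsFactors = FALSE)
  introns <- derive_introns(ft)
  expect_equal(c(introns$start, introns$end), c(160L, 200L))
  expect_equal(introns$end - introns$start, 40L)
  expect_equal(introns$strand, "-")

  expect_equal(nrow(derive_introns(ft[1, ])), 0L)

  ft3 <- rbind(ft, transform(ft[1, ], start = 300L, end = 350L))
  i3 <- derive_introns(ft3)
  expect_equal(nrow(i3), 2L)
  expect_true(all(diff(i3$start) > 0))

  bad <- transform(ft, start = c(100L, 150L))   # overlapping exons
  expect_error(derive_introns(bad), "overlapping")
})

test_that("genomic classification applies the 15% rule with UTR precedence", {
  ft <- data.frame(
    chrom = "chr1",
    start = c(1000L, 1100L, 2000L, 2400L),
    end = c(1500L, 1300L, 2100L, 2500L),
    strand = "+",
    type = c("exon", "three_prime_utr", "exon", "exon"),
    transcript_id = c("t1", "t1", "t2", "t2"), gene_id = "g",
    stringsAsFactors = FALSE)
  loci <- genomic_intervals("chr1",
                            c(1150L, 2090L, 2150L, 5000L),
                            c(1250L, 2190L, 2250L, 5100L))
  loci$id <- c("in_utr", "exon10pct", "in_intron", "nowhere")
  got <- classify_locus(loci, ft)
  expect_equal(got$category,
               c("UTR", "INTRON", "INTRON", "INTERGENIC"))
  # 10% exon overlap is insufficient for EXON; the intron behind it wins
  expect_equal(got$overlap_fraction[got$id == "in_utr"], 1.0)
  # categories partition the input
  expect_equal(nrow(got), nrow(loci))
})

test_that("miRtron calls respect the intron length and coverage gates", {
  set.seed(17)
  hp <- clean_hairpin(arm_len = 22L, loop_len = 17L)   # 61 nt
  genome <- c(chr1 = paste0(random_dna(500), hp$seq, random_dna(500)))
  iv <- genomic_intervals("chr1", 500L, 500L + nchar(hp$seq), "+")
  iv$id <- "hp1"
  introns <- cbind(iv[, 1:4], transcript_id = "t1")
  reads <- data.frame(id = c("a", "b"), seq = c(hp$arm5, hp$arm3),
                      count = c(60L, 40L))
  calls <- detect_mirtrons(iv, introns, reads, genome)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$end5_offset, 0L)
  expect_equal(calls$end3_offset, 0L)
  expect_gte(calls$intron_coverage, 0.95)

  # intron length outside [50, 120] is never called
  long_intron <- genomic_intervals("chr1", 460L, 581L, "+")  # 121 nt
  long_intron$transcript_id <- "t1"
  expect_equal(nrow(detect_mirtrons(iv, long_intron, reads, genome)), 0L)
  short_intron <- genomic_intervals("chr1", 510L, 559L, "+") # 49 nt
  short_intron$transcript_id <- "t1"
  expect_equal(nrow(detect_mirtrons(iv, short_intron, reads, genome)), 0L)
})
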