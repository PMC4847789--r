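mk_aln <- function(starts, ends, strand = "+", counts = 20L, chrom = "chr1") {
  data.frame(read_id = paste0("r", seq_along(starts)), target = chrom,
             start = as.integer(starts), end = as.integer(ends),
             strand = strand, mismatches = 0L,
             count = rep_len(as.integer(counts), length(starts)),
             stringsAsFactors = FALSE)
}

test_that("read stacks merge within max_gap on one strand only", {
  a <- mk_aln(c(100, 152), c(122, 174))           # 30 nt apart
  expect_equal(nrow(cluster_read_stacks(a, 65)), 1L)

  b <- mk_aln(c(100, 222), c(122, 244))           # 100 nt apart
  expect_equal(nrow(cluster_read_stacks(b, 65)), 2L)

  c2 <- rbind(mk_aln(100, 122, "+"), mk_aln(105, 127, "-"))
  expect_equal(nrow(cluster_read_stacks(c2, 65)), 2L)

  cl <- cluster_read_stacks(a, 65)
  expect_equal(cl$count, sum(a$count))
})

test_that("precursor windows extend, clip and split per the cap rule", {
  genome <- c(chr1 = strrep("ACGT", 2500))
  w1 <- excise_precursors(data.frame(chrom = "chr1", start = 500L, end = 580L,
                                     strand = "+"), genome)
  expect_equal(w1$end - w1$start, 120L)

  w2 <- excise_precursors(data.frame(chrom = "chr1", start = 5L, end = 85L,
                                     strand = "+"), genome)
  expect_equal(w2$start, 0L)

  w3 <- excise_precursors(data.frame(chrom = "chr1", start = 1000L,
                                     end = 1400L, strand = "+"), genome)
  expect_equal(nrow(w3), 2L)
  expect_equal(w3$start[1], 980L)                 # 5'-anchored
  expect_equal(w3$end[2], 1420L)                  # 3'-anchored
  expect_true(all(w3$end - w3$start == 300L))
})

test_that("candidates require a folding duplex with stacks on opposite arms", {
  set.seed(19)
  hp <- clean_hairpin()
  genome <- c(chr1 = paste0(random_dna(600), hp$seq, random_dna(1200)))
  n <- nchar(hp$seq)
  plant_aln <- rbind(
    mk_aln(600, 622, counts = 80L),                       # 5p stack
    mk_aln(600 + n - 22L, 600 + n, counts = 50L))         # 3p stack
  wins <- excise_precursors(cluster_read_stacks(plant_aln, 65)[1, ], genome)
  cands <- propose_candidates(wins, plant_aln, genome)
  expect_equal(nrow(cands), 1L)
  expect_lte(cands$start, 600L)
  expect_gte(cands$end, 600L + n)
  expect_match(cands$id, "^1/")

  # single-arm stack only: rejected
  cands1 <- propose_candidates(wins, plant_aln[1, ], genome)
  expect_equal(nrow(cands1), 0L)

  # degradation-like uniform stacks over a random window: rejected
  bg <- mk_aln(seq(1300, 1420, by = 7), seq(1322, 1442, by = 7), counts = 12L)
  wbg <- excise_precursors(cluster_read_stacks(bg, 65)[1, ], genome)
  expect_equal(nrow(propose_candidates(wbg, bg, genome)), 0L)
})

test_that("candidate-set merging is union-based, idempotent and commutative", {
  a <- data.frame(chrom = "chr1", start = c(100L, 500L), end = c(160L, 560L),
                  strand = "+", source = "DISCOVERY", stringsAsFactors = FALSE)
  b <- data.frame(chrom = "chr1", start = c(100L, 540L, 900L),
                  end = c(160L, 600L, 960L), strand = "+",
                  source = "HOMOLOGY", stringsAsFactors = FALSE)
  m <- merge_candidate_sets(a, b)
  expect_equal(nrow(m), 3L)
  got <- m[m$start == 500L, ]
  expect_equal(got$end, 600L)                     # union span
  expect_match(got$source, "DISCOVERY\\+HOMOLOGY")

  m2 <- merge_candidate_sets(m, m[0, ])
  expect_equal(m2[, c("chrom", "start", "end")], m[, c("chrom", "start", "end")],
               ignore_attr = TRUE)
  m_ba <- merge_candidate_sets(b, a)
  expect_equal(m_ba[, c("chrom", "start", "end")],
               m[, c("chrom", "start", "end")], ignore_attr = TRUE)

  disjoint <- merge_candidate_sets(a, transform(a, start = start + 5000L,
                                                end = end + 5000L))
  expect_equal(nrow(disjoint), 4L)
})
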