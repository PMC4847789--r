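test_that("hairpin mapping retains hits by length and identity", {
  set.seed(23)
  hp70 <- random_dna(70)
  hp59 <- random_dna(59)
  genome <- c(chr1 = paste0(random_dna(400), hp70, random_dna(300),
                            hp59, random_dna(300)))
  hits <- map_hairpins(c(h70 = hp70), genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$alignment_length, 70L)
  expect_equal(substr(genome[[1]], hits$start + 1, hits$end), hp70)

  # 59 nt exact copy falls below the 60 bp retention length
  expect_equal(nrow(map_hairpins(c(h59 = hp59), genome)), 0L)

  # heavy divergence is dropped at min_identity = 0.8
  div <- hp70
  pos <- seq(2, 70, by = 4)
  for (p in pos) substr(div, p, p) <- chartr("ACGT", "GTAC", substr(div, p, p))
  expect_equal(nrow(map_hairpins(c(hdiv = div), genome,
                                 min_identity = 0.8)), 0L)

  # reverse-strand copies are found in forward coordinates
  genome_rc <- c(chr1 = paste0(random_dna(300), rc_chr(hp70), random_dna(300)))
  h2 <- map_hairpins(c(h70 = hp70), genome_rc)
  expect_equal(h2$strand, "-")
  expect_equal(substr(genome_rc[[1]], h2$start + 1, h2$end), rc_chr(hp70))
})

test_that("mature confirmation allows at most one mismatch inside the locus", {
  set.seed(29)
  hp <- random_dna(70)
  mature <- substr(hp, 5, 26)
  genome <- c(chr1 = paste0(random_dna(200), hp, random_dna(200)))
  hits <- map_hairpins(c(h = hp), genome)

  mm <- function(s, k) {
    for (p in utils::head(c(4, 11), k))
      substr(s, p, p) <- chartr("ACGT", "GTAC", substr(s, p, p))
    s
  }
  conf0 <- confirm_mature(hits, c(`h-5p` = mature), genome)
  expect_true(conf0$mature_confirmed)
  expect_equal(conf0$mature_mismatches, 0L)

  conf1 <- confirm_mature(hits, c(`h-5p` = mm(mature, 1)), genome)
  expect_true(conf1$mature_confirmed)
  expect_equal(conf1$mature_mismatches, 1L)

  conf2 <- confirm_mature(hits, c(`h-5p` = mm(mature, 2)), genome)
  expect_false(conf2$mature_confirmed)

  # a mature overhanging the locus edge cannot confirm
  edge <- paste0(substr(genome[[1]], 196, 200), substr(hp, 1, 17))
  confE <- confirm_mature(hits, c(`h-5p` = edge), genome)
  expect_false(confE$mature_confirmed)
})

test_that("known/novel split partitions candidates", {
  cands <- genomic_intervals("chr1", c(100, 300, 500), c(160, 360, 560))
  cands$id <- c("a", "b", "c")
  cons <- genomic_intervals("chr1", c(90, 320), c(150, 380))
  exist <- genomic_intervals("chr1", 90, 150)
  sp <- split_known_novel(cands, cons, exist)
  expect_equal(sp$conserved$id, c("a", "b"))
  expect_equal(sp$novel$id, "c")
  expect_equal(sp$conserved$newly_annotated, c(FALSE, TRUE))
  expect_equal(nrow(sp$conserved) + nrow(sp$novel), nrow(cands))
})

test_that("cross-species search reports context-concordant confirmed homologs", {
  set.seed(31)
  hp <- clean_hairpin(seed = 31)
  # source genome locus and context (intronic)
  src_ft <- data.frame(chrom = "chrA", start = c(1000L, 2000L),
                       end = c(1200L, 2200L), strand = "+", type = "exon",
                       transcript_id = "s1", gene_id = "gs",
                       stringsAsFactors = FALSE)
  src_loci <- genomic_intervals("chrA", 1400L, 1400L + nchar(hp$seq), "+")
  src_loci$id <- "novel1"
  # target genome carries an exact copy inside an intron
  other <- c(chrB = paste0(random_dna(11000), hp$seq, random_dna(2000)))
  oth_ft <- data.frame(chrom = "chrB", start = c(10000L, 14000L),
                       end = c(10500L, 14500L), strand = "+", type = "exon",
                       transcript_id = "o1", gene_id = "go",
                       stringsAsFactors = FALSE)
  tab <- find_cross_species_homologs(
    c(novel1 = hp$seq), src_loci,
    c(`novel1-5p` = hp$arm5, `novel1-3p` = hp$arm3),
    other, oth_ft, src_ft)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$source_context, "INTRON")
  expect_equal(tab$target_context, "INTRON")

  # homolog whose matures carry 2 mismatches is excluded
  rot <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- chartr("ACGT", "GTAC", substr(s, p, p))
    s
  }
  bad5 <- rot(hp$arm5, c(3, 9))
  bad3 <- rot(hp$arm3, c(3, 9))
  tab2 <- find_cross_species_homologs(
    c(novel1 = hp$seq), src_loci,
    c(`novel1-5p` = bad5, `novel1-3p` = bad3),
    other, oth_ft, src_ft)
  expect_lte(nrow(tab2), 0L)

  # genome without a hit yields an empty table
  tab3 <- find_cross_species_homologs(
    c(novel1 = hp$seq), src_loci,
    c(`novel1-5p` = hp$arm5), c(chrC = random_dna(12000)), oth_ft, src_ft)
  expect_equal(nrow(tab3), 0L)
})
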