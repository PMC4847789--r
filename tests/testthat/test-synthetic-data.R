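test_that("toy genomes are deterministic, bounded and GC-controllable", {
  g1 <- make_genome(1, 10000, 0.5, seed = 7)
  g2 <- make_genome(1, 10000, 0.5, seed = 7)
  expect_identical(g1, g2)
  expect_equal(nchar(g1[["chr1"]]), 10000L)
  expect_false(identical(make_genome(1, 10000, 0.5, seed = 1),
                         make_genome(1, 10000, 0.5, seed = 2)))
  expect_false(grepl("[GC]", make_genome(1, 10000, 0, seed = 3)[["chr1"]]))
  expect_error(make_genome(0, 10000, 0.5, 1), "n_chrom")
  expect_error(make_genome(1, 500, 0.5, 1), "length_per_chrom")
})

test_that("plant specifications enforce their invariants", {
  arm5 <- strrep("G", 21)
  expect_error(plant_spec("p", "EXON", arm5, strrep("G", 21), strrep("A", 8),
                          tissue_expression = c(blood = 10)),
               "pair")
  expect_error(plant_spec("p", "EXON", arm5, strrep("C", 21), strrep("A", 8),
                          tissue_expression = c(blood = 10),
                          nta_fractions = c(A = 0.6, U = 0.5)),
               "nta")
  sp <- plant_spec("p", "EXON", arm5, strrep("C", 21), strrep("A", 8),
                   tissue_expression = c(blood = 10))
  expect_s3_class(sp, "plant_spec")
})

test_that("hairpin planting writes arm5+loop+arm3 strand-adjusted", {
  genome <- c(chr1 = strrep("T", 10000))
  sp <- plant_spec("p", "INTERGENIC", strrep("G", 21), strrep("C", 21),
                   strrep("A", 8), strand = "+",
                   tissue_expression = c(blood = 10))
  out <- plant_hairpin(genome, sp, "chr1", 100L)
  written <- substr(out$genome[["chr1"]], 101, 150)
  expect_identical(written, paste0(strrep("G", 21), strrep("A", 8),
                                   strrep("C", 21)))
  expect_equal(out$interval$start, 100L)
  expect_equal(out$interval$end, 150L)

  spm <- plant_spec("p", "INTERGENIC", strrep("G", 21), strrep("C", 21),
                    strrep("A", 8), strand = "-",
                    tissue_expression = c(blood = 10))
  outm <- plant_hairpin(genome, spm, "chr1", 100L)
  expect_identical(substr(outm$genome[["chr1"]], 101, 150),
                   paste0(strrep("G", 21), strrep("T", 8), strrep("C", 21)))

  expect_error(plant_hairpin(out$genome, sp, "chr1", 120L,
                             occupied = out$interval), "placement")
  expect_error(plant_hairpin(genome, sp, "chr1", 9990L), "room")
})

test_that("simulated libraries honour expression, NTA fractions and determinism", {
  set.seed(51)
  hp <- clean_hairpin(seed = 52)
  genome <- c(chr1 = paste0(random_dna(11000), hp$seq, "C", random_dna(3000)))
  n <- nchar(hp$seq)
  plants <- data.frame(
    id = "p1", context = "INTERGENIC", conserved = FALSE, in_existing = FALSE,
    chrom = "chr1", start = 11000L, end = 11000L + n, strand = "+",
    arm5_seq = hp$arm5, loop_seq = hp$loop, arm3_seq = hp$arm3, tail3 = 0L,
    jitter_prob = 0, nta_A = 0, nta_U = 0.5, switching = FALSE,
    expr_blood = 1000, expr_brain = 0, af_blood = 1.0, af_brain = 1.0,
    stringsAsFactors = FALSE)
  truth <- list(plants = plants, pirna_clusters = plants[0, ],
                tissues = c("blood", "brain"), bg_frac = 0)

  reads <- simulate_reads(truth, genome, "blood", seed = 9)
  expect_identical(reads, simulate_reads(truth, genome, "blood", seed = 9))
  expect_error(simulate_reads(truth, genome, "liver", seed = 9), "tissue")

  # zero expression in brain: no reads at all (no background configured)
  expect_equal(nrow(simulate_reads(truth, genome, "brain", seed = 9)), 0L)

  # +U reads within 3 binomial sigmas of n * f_U (arm5_fraction = 1)
  obs_u <- sum(reads$count[reads$seq == paste0(hp$arm5, "T")])
  expect_lt(abs(obs_u - 500), 3 * sqrt(1000 * 0.5 * 0.5))
  expect_equal(sum(reads$count), 1000L)
})

test_that("aggregate library length distribution peaks at 22 nt", {
  ds <- get_fixture()
  h <- length_histogram(do.call(rbind, ds$reads_by_tissue))
  expect_equal(names(h)[which.max(h)], "22")
})

test_that("truth files round-trip and flag miRtrons in GFF3", {
  ds <- get_fixture()
  dir <- withr::local_tempdir()
  write_truth(ds$truth, dir)
  back <- read_truth(dir)
  expect_equal(back$plants, ds$truth$plants, tolerance = 1e-12)
  expect_equal(back$pirna_clusters, ds$truth$pirna_clusters,
               tolerance = 1e-12)
  expect_equal(back$tissues, ds$truth$tissues)
  expect_equal(back$bg_frac, ds$truth$bg_frac)
  gff <- readLines(file.path(dir, "truth.gff3"))
  expect_equal(sum(grepl("mirtron=true", gff)),
               sum(ds$truth$plants$context == "MIRTRON"))

  # empty truth writes valid, re-readable files
  empty <- list(plants = ds$truth$plants[0, ],
                pirna_clusters = ds$truth$pirna_clusters[0, ],
                tissues = ds$truth$tissues, bg_frac = 0.05)
  d2 <- withr::local_tempdir()
  write_truth(empty, d2)
  back2 <- read_truth(d2)
  expect_equal(nrow(back2$plants), 0L)
})

test_that("planted miRtron intron lengths satisfy the length precondition", {
  ds <- get_fixture()
  mt <- ds$truth$plants[ds$truth$plants$context == "MIRTRON", ]
  ilen <- (mt$end - mt$start) + mt$tail3
  expect_true(all(ilen >= 50 & ilen <= 120))
})
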