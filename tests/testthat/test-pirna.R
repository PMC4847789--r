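mk_pir_aln <- function(starts, strand = "+", chrom = "chr1", len = 26L,
                       count = 1L, seq = NULL, read_id = NULL) {
  n <- length(starts)
  data.frame(read_id = read_id %||% paste0("r", seq_len(n)), target = chrom,
             start = as.integer(starts), end = as.integer(starts) + len,
             strand = strand, mismatches = 0L,
             count = rep_len(as.integer(count), n),
             seq = rep_len(seq %||% paste0("T", strrep("A", len - 1L)), n),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("multimapper reallocation follows unique-mapper density", {
  uni <- mk_pir_aln(c(1000, 1100, 3000), count = c(20L, 10L, 10L),
                    read_id = c("u1", "u2", "u3"))
  multi <- mk_pir_aln(c(1050, 30000), count = 8L, read_id = c("m1", "m1"))
  w <- reallocate_counts(rbind(uni, multi), window = 10000)
  expect_equal(w$weight[w$read_id == "u1"], 1)
  m <- w[w$read_id == "m1", ]
  # locus near 40 unique counts vs locus near 0: weights 1 and 0
  expect_equal(sort(m$weight), c(0, 1))

  # proportional split 30 vs 10
  multi2 <- mk_pir_aln(c(1050, 2900), count = 8L, read_id = c("m2", "m2"))
  w2 <- reallocate_counts(rbind(uni, multi2), window = 200)
  m2 <- w2[w2$read_id == "m2", ]
  expect_equal(sort(m2$weight), c(0.25, 0.75))

  # zero density everywhere: uniform fallback
  only <- mk_pir_aln(c(100, 5000), read_id = c("m3", "m3"))
  w3 <- reallocate_counts(only)
  expect_equal(w3$weight, c(0.5, 0.5))

  # conservation: weights per read sum to 1
  set.seed(41)
  rid <- rep(paste0("x", 1:20), times = sample(1:4, 20, replace = TRUE))
  rnd <- mk_pir_aln(sample(1:50000, length(rid)), read_id = rid)
  wr <- reallocate_counts(rnd)
  expect_equal(as.numeric(tapply(wr$weight, wr$read_id, sum)),
               rep(1, 20), tolerance = 1e-12)
})

test_that("the 1T/10A signature is a union over count-weighted reads", {
  expect_equal(signature_frac(c("TAAAAAAAAAA", "TCCCCCCCCCC")), 1)
  # a read with both 1T and 10A counts once
  both <- paste0("T", strrep("C", 8), "A", "CC")
  expect_equal(signature_frac(c(both, strrep("C", 11))), 0.5)
  set.seed(43)
  ten <- c(replicate(6, paste0("T", random_dna(25))),
           replicate(4, paste0("C", strrep("C", 8), "C", random_dna(15))))
  expect_equal(signature_frac(ten), 0.6)
  # short reads leave the denominator
  expect_equal(signature_frac(c("TAAAA", "TAAAAAAAAAA")), 1)
  expect_true(is.nan(signature_frac(character(0))))
})

test_that("cluster calling enforces span, hits, signature and size-fraction", {
  set.seed(47)
  mk_cluster <- function(start, width, n, frac1T = 0.9, chrom = "chr1") {
    st <- sort(sample(start:(start + width - 30L), n, replace = TRUE))
    seqs <- vapply(seq_len(n), function(i) {
      first <- if (stats::runif(1) < frac1T) "T" else "C"
      # tenth base pinned to C so the signature equals the planted 1T rate
      paste0(first, strrep("C", 9), random_dna(16))
    }, "")
    # pin the span ends so the width is exact
    st[1] <- start; st[n] <- start + width - 26L
    mk_pir_aln(st, seq = seqs, read_id = paste0(chrom, "_", seq_len(n)))
  }
  good <- reallocate_counts(mk_cluster(10000, 1500, 60))
  got <- call_clusters(good, "testis")
  expect_equal(nrow(got), 1L)
  expect_gte(got$end - got$start, 1000L)
  expect_equal(got$strand_class, "MONO_PLUS")
  expect_equal(got$tissue, "testis")

  # 800 bp span: rejected on size
  small <- reallocate_counts(mk_cluster(10000, 826, 60))
  expect_equal(nrow(call_clusters(small, "testis")), 0L)

  # signature fraction 0.3: rejected
  weak <- reallocate_counts(mk_cluster(10000, 1500, 60, frac1T = 0.3))
  expect_equal(nrow(call_clusters(weak, "testis")), 0L)

  # a window dominated by miRNA-sized reads: rejected on size fraction
  mixed <- mk_cluster(10000, 1500, 30)
  mirna <- mk_pir_aln(sample(10000:11400, 150), len = 22L,
                      seq = paste0("T", random_dna(21)),
                      read_id = paste0("mi", 1:150))
  both <- reallocate_counts(rbind(mixed, mirna))
  expect_equal(nrow(call_clusters(both, "testis")), 0L)
})

test_that("cross-tissue merging collapses repeated and keeps disjoint clusters", {
  cl <- data.frame(chrom = "chr1", start = c(100L, 150L, 120L, 9000L),
                   end = c(1200L, 1250L, 1220L, 10100L),
                   tissue = c("testis", "ovary", "blood", "testis"),
                   strand_class = c("MONO_PLUS", "MONO_PLUS", "DUAL",
                                    "MONO_MINUS"), stringsAsFactors = FALSE)
  m <- merge_clusters_across_tissues(cl)
  expect_equal(nrow(m), 2L)
  expect_equal(m$start, c(100L, 9000L))
  # merged output is non-overlapping (idempotent under re-merge)
  expect_identical(merge_intervals(m)[, c("start", "end")],
                   m[, c("start", "end")])
  mono <- merge_clusters_across_tissues(cl, mono_only = TRUE)
  expect_equal(nrow(mono), 2L)
})
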