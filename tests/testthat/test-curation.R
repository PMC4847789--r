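# build a profile object for one hairpin from explicit read placements
profile_for <- function(hp_seq, reads_by_tissue) {
  build_profiles(c(hp1 = hp_seq), reads_by_tissue)
}

test_that("profiles record 5'-start counts and conserve aligned counts", {
  hp <- clean_hairpin()
  r5 <- substr(hp$seq, 6, 27)     # one read x10 starting at position 5
  reads <- list(blood = data.frame(id = "a", seq = r5, count = 10L))
  pr <- profile_for(hp$seq, reads)
  p <- pr$profiles$hp1
  expect_equal(p$tissues$blood$start_counts[6], 10L)
  expect_equal(sum(p$tissues$blood$start_counts), 10L)
  # coverage at a position equals summed counts of spanning reads
  expect_equal(p$tissues$blood$coverage[10], 10L)
  expect_equal(p$tissues$blood$coverage[1], 0L)
  # aggregated profile conserves per-tissue totals
  expect_equal(sum(p$agg$start_counts), 10L)
})

test_that("mature calls pick the most abundant distinct read per arm", {
  hp <- clean_hairpin()
  n <- nchar(hp$seq)
  reads <- list(t = data.frame(
    id = c("a", "b", "c"),
    seq = c(hp$arm5, substr(hp$seq, 2, 23), hp$arm3),
    count = c(50L, 20L, 30L)))
  pr <- profile_for(hp$seq, reads)
  fold <- nussinov_fold(hp$seq)
  mt <- call_matures(pr$profiles$hp1, fold)
  expect_equal(mt$mature5$sequence, hp$arm5)
  expect_equal(mt$mature5$start, 0L)
  expect_equal(mt$mature3$sequence, hp$arm3)
  expect_equal(mt$mature3$start, n - 22L)

  # tie: earlier start wins
  tie <- list(t = data.frame(
    id = c("a", "b", "c"),
    seq = c(hp$arm5, substr(hp$seq, 3, 22), hp$arm3),
    count = c(40L, 40L, 30L)))
  pr2 <- profile_for(hp$seq, tie)
  mt2 <- call_matures(pr2$profiles$hp1, fold)
  expect_equal(mt2$mature5$start, 0L)

  # loop-only reads give no calls
  loop_read <- substr(hp$seq, 20, 41)
  pr3 <- profile_for(hp$seq, list(t = data.frame(id = "l", seq = loop_read,
                                                 count = 15L)))
  mt3 <- call_matures(pr3$profiles$hp1, fold)
  expect_null(mt3$mature5)
  expect_null(mt3$mature3)
})

test_that("the two-peak test enforces fraction and count gates per arm", {
  hp <- clean_hairpin()
  n <- nchar(hp$seq)
  fold <- nussinov_fold(hp$seq)
  mk_prof <- function(start_counts) {
    list(agg = list(start_counts = start_counts))
  }
  sc <- integer(n); sc[1] <- 40L; sc[n - 21L] <- 30L
  expect_true(two_peak_test(mk_prof(sc), fold)$overall)

  # uniform starts fail
  un <- integer(n); un[1:20] <- 5L; un[(n - 19L):n] <- 5L
  expect_false(two_peak_test(mk_prof(un), fold)$overall)

  # fraction exactly at the threshold passes (>= semantics)
  sc2 <- integer(n); sc2[1] <- 30L; sc2[10] <- 10L
  sc2[n - 21L] <- 30L; sc2[n - 12L] <- 10L
  tp <- two_peak_test(mk_prof(sc2), fold, min_fraction = 0.75)
  expect_equal(tp$fraction5, 0.75)
  expect_true(tp$overall)

  # invariant under uniform count scaling
  expect_equal(two_peak_test(mk_prof(sc2 * 7L), fold)$overall, tp$overall)

  # an arm under min_count fails that arm
  low <- integer(n); low[1] <- 40L; low[n - 21L] <- 9L
  expect_false(two_peak_test(mk_prof(low), fold)$overall)
})

test_that("confidence classes combine the three criteria", {
  expect_equal(classify_confidence("h", TRUE, TRUE, TRUE)$class, "HIGH")
  expect_equal(classify_confidence("h", FALSE, TRUE, TRUE)$class, "LOW")
  expect_equal(classify_confidence("h", TRUE, FALSE, TRUE)$class, "LOW")
  expect_equal(classify_confidence("h", TRUE, TRUE, FALSE)$class, "LOW")
})

test_that("arm switching requires opposite dominance in qualifying tissues", {
  tb <- data.frame(
    hairpin_id = rep(c("h1", "h2", "h3"), each = 3),
    tissue = rep(c("blood", "brain", "lung"), 3),
    count_5p = c(30L, 40L, 50L,   5L, 45L, 50L,   2L, 45L, 50L),
    count_3p = c(10L, 10L, 10L,  40L, 10L, 10L,  10L, 10L, 10L),
    stringsAsFactors = FALSE)
  sw <- detect_arm_switching(tb, min_total = 20L)
  expect_false(sw$switching[sw$hairpin_id == "h1"])   # 5p everywhere
  expect_true(sw$switching[sw$hairpin_id == "h2"])    # 3p blood, 5p others
  # h3's blood row (total 12) is below min_total and ignored
  expect_false(sw$switching[sw$hairpin_id == "h3"])
})

test_that("5' proportion histogram bins hairpins and conserves totals", {
  tb <- data.frame(hairpin_id = c("a", "b", "c", "d"),
                   tissue = "blood",
                   count_5p = c(100L, 50L, 0L, 0L),
                   count_3p = c(0L, 50L, 80L, 0L), stringsAsFactors = FALSE)
  h <- five_prime_fraction_histogram(tb)
  expect_equal(h["blood", 10], 1L)   # all-5p in the last bin
  expect_equal(h["blood", 6], 1L)    # balanced 50/50 in [0.5, 0.6)
  expect_equal(h["blood", 1], 1L)    # all-3p in the first bin
  expect_equal(sum(h), 3L)           # zero-total hairpin excluded
})
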