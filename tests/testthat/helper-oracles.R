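# Independent oracles used to check the package implementations.

PAIR_OK <- local({
  m <- matrix(FALSE, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T")))
  m["A", "T"] <- m["T", "A"] <- TRUE
  m["G", "C"] <- m["C", "G"] <- TRUE
  m["G", "T"] <- m["T", "G"] <- TRUE
  m
})

# maximum number of nested base pairs by leftmost-position decomposition
# (memoized recursion, independent of the bottom-up end-pairing DP)
oracle_max_pairs <- function(seq, min_loop = 3L) {
  b <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  n <- length(b)
  memo <- matrix(NA_integer_, n + 1L, n + 1L)
  rec <- function(i, j) {
    if (i >= j) return(0L)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- rec(i + 1L, j)                      # i unpaired
    if (j >= i + min_loop + 1L) {
      for (k in (i + min_loop + 1L):j) {
        if (PAIR_OK[b[i], b[k]])
          best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    memo[i, j] <<- best
    best
  }
  rec(1L, n)
}

# naive Hamming scan: all forward placements of q on t with <= k mismatches
oracle_hamming <- function(q, t, k) {
  qv <- strsplit(q, "")[[1]]
  tv <- strsplit(t, "")[[1]]
  m <- length(qv); n <- length(tv)
  if (m > n) return(data.frame(start = integer(0), mismatches = integer(0)))
  mism <- integer(n - m + 1L)
  for (j in seq_len(m))
    mism <- mism + as.integer(tv[j:(j + n - m)] != qv[j])
  hit <- which(mism <= k)
  data.frame(start = hit - 1L, mismatches = mism[hit])
}

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# per-base set arithmetic on a small universe
oracle_cover <- function(x, universe_len) {
  v <- logical(universe_len)
  for (i in seq_len(nrow(x))) {
    if (x$end[i] > x$start[i]) v[(x$start[i] + 1L):x$end[i]] <- TRUE
  }
  v
}

runs_to_df <- function(v, chrom = "chr1") {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

# a deterministic perfect hairpin: 22 nt arms, A/C loop
clean_hairpin <- function(arm_len = 22L, loop_len = 17L, seed = 99L) {
  set.seed(seed)
  repeat {
    arm5 <- random_dna(arm_len)
    if (nrow(nussinov_fold(arm5)$clean_pairs) == 0L) break
  }
  loop <- paste0("C", paste(sample(c("A", "C"), loop_len - 1L, replace = TRUE),
                            collapse = ""))
  list(arm5 = arm5, loop = loop, arm3 = rc_chr(arm5),
       seq = paste0(arm5, loop, rc_chr(arm5)))
}
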