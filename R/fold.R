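# Hairpin secondary-structure prediction by base-pair maximisation and
# stem-loop geometry validation.
#
# The curation criteria downstream consume only stem/loop geometry, so a
# deterministic Nussinov-style dynamic program over canonical pairs
# (A-U, G-C, G-U) replaces thermodynamic minimum-free-energy folding. An
# external MFE folder can be plugged in by supplying a dot-bracket string to
# fold_from_dotbracket().

.PAIRABLE <- local({
  m <- matrix(FALSE, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T")))
  m["A", "T"] <- m["T", "A"] <- TRUE
  m["G", "C"] <- m["C", "G"] <- TRUE
  m["G", "T"] <- m["T", "G"] <- TRUE
  m
})

#' Fold a sequence by base-pair maximisation
#'
#' Nussinov-style dynamic programming over the canonical pair set
#' \{A-U, G-C, G-U\} with a minimum hairpin-loop length. `n_pairs` is always
#' the maximal number of nested pairs; among the (typically many) co-optimal
#' structures the fold deterministically reports one with the maximal number
#' of stacked pairs, so real stems are kept as long helices instead of being
#' fragmented by incidental co-optimal pairings. Remaining ties break to the
#' outermost (smallest-index) pairing partner.
#'
#' @param seq A DNA/RNA sequence (single string; U and T are equivalent).
#' @param min_loop Minimum number of unpaired bases enclosed by a pair.
#' @return A `fold_result`: list with `sequence`, `dot_bracket`, `n_pairs`,
#'   `pairs` (two-column base-pair matrix, 1-based), `loop` (0-based half-open
#'   interval on the sequence), `arms` (list of 5p/3p intervals) and
#'   `paired_fraction_5p` / `paired_fraction_3p`.
#' @export
nussinov_fold <- function(seq, min_loop = 3L) {
  s <- dna_canon(seq)
  check_dna(s, "fold input")
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(b)
  # lexicographic score: pairs * 1024 + stacked pairs (n <= ~300 so the
  # stacking term can never overflow into the pair term)
  PW <- 1024L
  NEG <- -1000000L
  dp_pair <- matrix(NEG, n, n)   # best score with (i,j) forced paired
  dp_free <- matrix(0L, n, n)    # best score for interval [i,j]
  if (n > min_loop + 1L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        if (.PAIRABLE[b[i], b[j]]) {
          inner <- if (j - i - 2L >= min_loop + 1L)
            max(dp_free[i + 1L, j - 1L], dp_pair[i + 1L, j - 1L] + 1L)
          else 0L
          dp_pair[i, j] <- PW + inner
        }
        # decompose by the pairing partner k of j (or j unpaired)
        best <- dp_free[i, j - 1L]
        ks <- i:(j - min_loop - 1L)
        left <- c(0L, dp_free[i, ks[-1] - 1L])
        cand <- left + dp_pair[cbind(ks, j)]
        best <- max(best, cand)
        dp_free[i, j] <- best
      }
    }
  }
  db <- rep(".", n)
  pairs <- matrix(integer(0), ncol = 2)
  descend_pair <- function(i, j) {
    db[i] <<- "("; db[j] <<- ")"
    pairs <<- rbind(pairs, c(i, j))
    if (j - i - 2L < min_loop + 1L) return(invisible())
    inner <- dp_pair[i, j] - PW
    if (.PAIRABLE[b[i + 1L], b[j - 1L]] &&
        dp_pair[i + 1L, j - 1L] + 1L == inner &&
        dp_pair[i + 1L, j - 1L] + 1L >= dp_free[i + 1L, j - 1L]) {
      descend_pair(i + 1L, j - 1L)
    } else {
      process_free(i + 1L, j - 1L)
    }
    invisible()
  }
  process_free <- function(i, j) {
    while (j - i > min_loop && dp_free[i, j] > 0L) {
      best <- dp_free[i, j]
      ks <- i:(j - min_loop - 1L)
      left <- c(0L, dp_free[i, ks[-1] - 1L])
      cand <- left + dp_pair[cbind(ks, j)]
      hit <- which(cand == best)
      if (length(hit)) {
        k <- ks[hit[1]]
        descend_pair(k, j)
        if (k - 1L < i) return(invisible())
        j <- k - 1L
      } else {
        j <- j - 1L                     # j unpaired
      }
    }
    invisible()
  }
  if (n >= 2L) process_free(1L, n)
  .fold_result(s, paste(db, collapse = ""), pairs)
}

#' Build a fold result from an externally supplied dot-bracket structure
#'
#' Adapter slot for plugging a thermodynamic folder: downstream curation only
#' needs the dot-bracket string.
#'
#' @param seq Sequence string.
#' @param dot_bracket Matching dot-bracket string of `(`, `.`, `)`.
#' @return A `fold_result` (see [nussinov_fold()]).
#' @export
fold_from_dotbracket <- function(seq, dot_bracket) {
  s <- dna_canon(seq)
  db <- strsplit(dot_bracket, "", fixed = TRUE)[[1]]
  if (length(db) != nchar(s))
    stop("dot-bracket length must equal sequence length", call. = FALSE)
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(db)) {
    if (db[i] == "(") open <- c(open, i)
    else if (db[i] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket", call. = FALSE)
      pairs <- rbind(pairs, c(open[length(open)], i))
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced dot-bracket", call. = FALSE)
  .fold_result(s, dot_bracket, pairs)
}

# decompose a pair list into stacked helices; returns helix id per pair
.helix_ids <- function(pairs) {
  if (nrow(pairs) == 0L) return(integer(0))
  ord <- order(pairs[, 1])
  key <- paste(pairs[ord, 1], pairs[ord, 2])
  prev <- paste(pairs[ord, 1] - 1L, pairs[ord, 2] + 1L)
  new_helix <- !(prev %in% key)
  ids <- cumsum(new_helix)
  ids[order(ord)]
}

# drop helices with fewer than min_helix stacked pairs; max-pairing folds
# decorate real stems with short helices (incidental loop/arm pairing) that
# carry no structural signal, while genuine stems keep long stacked runs
.prune_pairs <- function(pairs, min_helix = 5L) {
  if (nrow(pairs) == 0L) return(pairs)
  ids <- .helix_ids(pairs)
  keep <- ids %in% which(tabulate(ids) >= min_helix)
  pairs[keep, , drop = FALSE]
}

.pairs_to_db <- function(pairs, n) {
  db <- rep(".", n)
  if (nrow(pairs)) { db[pairs[, 1]] <- "("; db[pairs[, 2]] <- ")" }
  paste(db, collapse = "")
}

.fold_result <- function(seq, dot_bracket, pairs, min_helix = 5L) {
  n <- nchar(seq)
  clean_pairs <- .prune_pairs(pairs, min_helix)
  clean_db <- .pairs_to_db(clean_pairs, n)
  # innermost loops of the cleaned structure; the main (terminal) loop is
  # the longest one
  m <- gregexpr("\\(\\.*\\)", clean_db)[[1]]
  if (m[1] > 0) {
    lens <- attr(m, "match.length") - 2L
    k <- which.max(lens)
    loop <- c(m[k], m[k] + lens[k])                  # 0-based half-open
  } else {
    mid <- n %/% 2L
    loop <- c(mid, mid)
  }
  arm5 <- c(0L, loop[1])
  arm3 <- c(loop[2], n)
  paired <- rep(FALSE, n)
  if (nrow(pairs)) paired[c(pairs[, 1], pairs[, 2])] <- TRUE
  pf5 <- if (arm5[2] > arm5[1]) mean(paired[(arm5[1] + 1L):arm5[2]]) else 0
  pf3 <- if (arm3[2] > arm3[1]) mean(paired[(arm3[1] + 1L):arm3[2]]) else 0
  structure(list(sequence = seq, dot_bracket = dot_bracket,
                 n_pairs = nrow(pairs), pairs = pairs,
                 clean_pairs = clean_pairs, clean_dot_bracket = clean_db,
                 loop = loop,
                 arms = list(arm5 = arm5, arm3 = arm3),
                 paired_fraction_5p = pf5, paired_fraction_3p = pf3),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "  (", x$n_pairs, " pairs)\n", sep = "")
  invisible(x)
}

#' Stem-loop geometry metrics of a fold
#'
#' @param fold A `fold_result`.
#' @return List: `single_stem` (exactly one hairpin loop), `loop_len`,
#'   `max_bulge` (longest unpaired run inside the stem region, loop excluded),
#'   `paired_fraction_5p`, `paired_fraction_3p`, `n_pairs`.
#' @export
hairpin_metrics <- function(fold) {
  db <- fold$clean_dot_bracket %||% fold$dot_bracket
  n_loops <- length(gregexpr("\\(\\.*\\)", db)[[1]])
  if (gregexpr("\\(\\.*\\)", db)[[1]][1] == -1L) n_loops <- 0L
  loop_len <- fold$loop[2] - fold$loop[1]
  # unpaired runs between first "(" and last ")", excluding the loop
  first_open <- regexpr("(", db, fixed = TRUE)
  last_close <- max(gregexpr(")", db, fixed = TRUE)[[1]])
  max_bulge <- 0L
  if (first_open > 0 && last_close > first_open) {
    ch <- strsplit(db, "", fixed = TRUE)[[1]]
    run <- 0L
    for (i in first_open:last_close) {
      in_loop <- i > fold$loop[1] && i <= fold$loop[2]
      if (ch[i] == "." && !in_loop) {
        run <- run + 1L
        max_bulge <- max(max_bulge, run)
      } else run <- 0L
    }
  }
  list(single_stem = n_loops == 1L, loop_len = loop_len, max_bulge = max_bulge,
       paired_fraction_5p = fold$paired_fraction_5p,
       paired_fraction_3p = fold$paired_fraction_3p, n_pairs = fold$n_pairs)
}

#' Validate hairpin geometry against called mature positions
#'
#' Passes when the structure is a single stem-loop, mature5 precedes mature3
#' with at most 4 nt of mutual overlap, and the two matures form a duplex:
#' in the best ungapped antiparallel alignment (offset up to 4 nt, allowing
#' the Dicer 2-nt overhang), at least `min_paired` of each mature's bases
#' pair with the other mature (A-U, G-C and G-U wobble). The direct duplex
#' check is robust to co-optimal rearrangements of the base-pair-maximisation
#' fold, and it subsumes loop-placement tests: a mature lying across the
#' terminal loop cannot be complementary to the opposite mature.
#'
#' @param fold A `fold_result`.
#' @param mature5,mature3 0-based half-open intervals of the 5p and 3p mature
#'   on the precursor sequence (`c(start, end)`), or NULL when an arm has no
#'   call.
#' @param min_paired Minimum paired fraction of mature bases.
#' @return Logical scalar.
#' @export
validate_hairpin <- function(fold, mature5, mature3, min_paired = 0.6) {
  if (is.null(mature5) || is.null(mature3)) return(FALSE)
  met <- hairpin_metrics(fold)
  if (!met$single_stem) return(FALSE)
  n <- nchar(fold$sequence)
  if (mature5[1] < 0 || mature3[2] > n) return(FALSE)
  if (mature3[1] - mature5[2] < -4L) return(FALSE)
  # direct duplex check: best ungapped antiparallel alignment of the matures
  fr <- duplex_fraction(substr(fold$sequence, mature5[1] + 1L, mature5[2]),
                        substr(fold$sequence, mature3[1] + 1L, mature3[2]))
  fr[1] >= min_paired && fr[2] >= min_paired
}

#' Mutual complementarity of two sequences as an antiparallel duplex
#'
#' Best ungapped antiparallel alignment (offset up to `max_offset` nt,
#' accommodating the 2-nt Dicer overhang) counting A-U, G-C and G-U pairs.
#'
#' @param a,b Sequences in 5'->3' orientation.
#' @param max_offset Maximum alignment offset tried in each direction.
#' @return Numeric length 2: the paired fraction of `a` and of `b`.
#' @export
duplex_fraction <- function(a, b, max_offset = 4L) {
  av <- strsplit(dna_canon(a), "", fixed = TRUE)[[1]]
  bv <- rev(strsplit(dna_canon(b), "", fixed = TRUE)[[1]])
  la <- length(av); lb <- length(bv)
  best <- 0L
  for (off in -max_offset:max_offset) {
    i <- seq_len(la)
    j <- i + off
    ok <- j >= 1L & j <= lb
    if (!any(ok)) next
    best <- max(best, sum(.PAIRABLE[cbind(av[i[ok]], bv[j[ok]])]))
  }
  c(best / la, best / lb)
}
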