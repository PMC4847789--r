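# Hairpin curation: per-position read profiles, mature calling, the two-peak
# Dicer/Drosha consistency test, confidence classification, and arm
# dominance / arm-switching analysis.

#' Build per-tissue read profiles over hairpin sequences
#'
#' Reads are aligned to the precursor sequences sense-strand with zero
#' mismatches; each profile records per-position 5'-start counts and coverage
#' depth.
#'
#' @param hairpins Named character vector of precursor sequences.
#' @param reads_by_tissue Named list of collapsed read data.frames.
#' @param rpm_totals Optional named vector of per-tissue genome-matching
#'   totals (RPM scale factors).
#' @return An `arm_profiles` object: per hairpin, per tissue, `start_counts`
#'   and `coverage` integer vectors plus the tissue-aggregated profile and the
#'   per-hairpin alignment table.
#' @export
build_profiles <- function(hairpins, reads_by_tissue, rpm_totals = NULL) {
  n <- nchar(hairpins)
  profs <- lapply(seq_along(hairpins), function(h) {
    list(tissues = list(),
         agg = list(start_counts = integer(n[h]), coverage = integer(n[h])),
         alignments = NULL)
  })
  names(profs) <- names(hairpins)
  for (tissue in names(reads_by_tissue)) {
    reads <- reads_by_tissue[[tissue]]
    if (nrow(reads) == 0L) next
    aln <- align_all(reads, hairpins, max_mismatch = 0L, strands = "forward")
    if (nrow(aln) == 0L) next
    aln$tissue <- tissue
    aln$seq <- reads$seq[match(aln$read_id, reads$id)]
    for (hp in unique(aln$target)) {
      a <- aln[aln$target == hp, , drop = FALSE]
      len <- n[[hp]]
      sc <- integer(len); cov <- integer(len)
      for (k in seq_len(nrow(a))) {
        sc[a$start[k] + 1L] <- sc[a$start[k] + 1L] + a$count[k]
        span <- (a$start[k] + 1L):a$end[k]
        cov[span] <- cov[span] + a$count[k]
      }
      profs[[hp]]$tissues[[tissue]] <- list(start_counts = sc, coverage = cov)
      profs[[hp]]$agg$start_counts <- profs[[hp]]$agg$start_counts + sc
      profs[[hp]]$agg$coverage <- profs[[hp]]$agg$coverage + cov
      profs[[hp]]$alignments <- rbind(profs[[hp]]$alignments, a)
    }
  }
  structure(list(profiles = profs, rpm_totals = rpm_totals),
            class = "arm_profiles")
}

# arm assignment of an alignment: larger overlap with [0, loop_start) vs
# [loop_end, n) decides; ties go to the 5' arm
.assign_arm <- function(starts, ends, loop, n) {
  ov5 <- pmax(0L, pmin(ends, loop[1]) - starts)
  ov3 <- pmax(0L, ends - pmax(starts, loop[2]))
  ifelse(ov5 >= ov3, "5p", "3p")
}

# read-driven boundary between the 5p and 3p arm: midpoint between the modal
# start and the strongest start at least min_sep away. Base-pair-maximisation
# folds can misplace the terminal loop among co-optimal structures, while the
# two dominant read stacks locate the duplex directly; the fold's loop center
# is the fallback when reads are one-sided or sparse.
.arm_boundary <- function(start_counts, fold, min_sep = 15L) {
  pos <- which(start_counts > 0L) - 1L
  if (length(pos) >= 2L) {
    cnt <- start_counts[pos + 1L]
    s1 <- pos[which.max(cnt)]
    far <- pos[abs(pos - s1) >= min_sep]
    if (length(far)) {
      s2 <- far[which.max(start_counts[far + 1L])]
      return((s1 + s2) / 2)
    }
  }
  (fold$loop[1] + fold$loop[2]) / 2
}

#' Call 5p and 3p mature sequences
#'
#' On each arm of the fold, the most abundant distinct aligned read sequence
#' (tissue-aggregated counts) is the mature; ties break to the earlier start,
#' then the lexicographically smaller sequence. Arms without reads yield no
#' call.
#'
#' @param profile One hairpin's entry of an `arm_profiles` object.
#' @param fold The hairpin's `fold_result`.
#' @return List with `mature5` and `mature3`, each NULL or a list
#'   (`sequence`, `start`, `end`, `count`).
#' @export
call_matures <- function(profile, fold) {
  aln <- profile$alignments
  out <- list(mature5 = NULL, mature3 = NULL)
  if (is.null(aln) || nrow(aln) == 0L) return(out)
  n <- nchar(fold$sequence)
  b <- .arm_boundary(profile$agg$start_counts, fold)
  # loop-spanning reads (deeply on both sides of the arm boundary) are not
  # mature candidates
  straddle <- pmin(b - aln$start, aln$end - b) > 4
  aln <- aln[!straddle, , drop = FALSE]
  if (nrow(aln) == 0L) return(out)
  arm <- .assign_arm(aln$start, aln$end, c(b, b), n)
  for (a in c("5p", "3p")) {
    sel <- aln[arm == a, , drop = FALSE]
    if (nrow(sel) == 0L) next
    agg <- stats::aggregate(count ~ seq + start + end, data = sel, FUN = sum)
    agg <- agg[order(-agg$count, agg$start, agg$seq), , drop = FALSE]
    call <- list(sequence = agg$seq[1], start = agg$start[1],
                 end = agg$end[1], count = agg$count[1])
    if (a == "5p") out$mature5 <- call else out$mature3 <- call
  }
  out
}

# two-peak evaluation of a start-count vector split at a loop boundary
.two_peak_arms <- function(start_counts, loop_start, loop_end, window = 2L,
                           min_fraction = 0.75, min_count = 10L) {
  n <- length(start_counts)
  eval_arm <- function(idx) {
    tot <- sum(start_counts[idx])
    if (tot < min_count)
      return(list(pass = FALSE, modal = NA_integer_, fraction = NA_real_))
    modal <- idx[which.max(start_counts[idx])]
    win <- idx[abs(idx - modal) <= window]
    frac <- sum(start_counts[win]) / tot
    list(pass = frac >= min_fraction, modal = modal - 1L, fraction = frac)
  }
  a5 <- eval_arm(seq_len(max(1L, loop_start)))
  a3 <- if (loop_end < n) eval_arm((loop_end + 1L):n)
        else list(pass = FALSE, modal = NA_integer_, fraction = NA_real_)
  list(arm5 = a5$pass, arm3 = a3$pass, overall = a5$pass && a3$pass,
       modal5 = a5$modal, modal3 = a3$modal,
       fraction5 = a5$fraction, fraction3 = a3$fraction)
}

#' Two-peak Dicer/Drosha consistency test
#'
#' Precise processing concentrates read 5' starts at one modal position per
#' arm. Each arm passes when the starts within `window` of the modal start
#' account for at least `min_fraction` of the arm total and the arm total is
#' at least `min_count`; the hairpin passes when both arms do. The test is
#' invariant under uniform count scaling.
#'
#' @param profile One hairpin's entry of an `arm_profiles` object (the
#'   aggregated profile is used).
#' @param fold The hairpin's `fold_result` (arm-split fallback when the read
#'   profile is one-sided; normally the two dominant stacks set the split).
#' @param window Start window (+/- nt) around the modal start.
#' @param min_fraction Minimum in-window fraction of arm starts.
#' @param min_count Minimum read count per arm.
#' @return List: `arm5`, `arm3`, `overall` (logicals), modal starts and
#'   in-window fractions.
#' @export
two_peak_test <- function(profile, fold, window = 2L, min_fraction = 0.75,
                          min_count = 10L) {
  b <- .arm_boundary(profile$agg$start_counts, fold)
  .two_peak_arms(profile$agg$start_counts, floor(b), floor(b),
                 window = window, min_fraction = min_fraction,
                 min_count = min_count)
}

#' Classify a hairpin's confidence
#'
#' HIGH requires all three supports: the two-peak alignment pattern, a valid
#' single stem-loop structure around the called matures, and expression of
#' both arms. Conserved loci failing any criterion are retained as LOW
#' (annotated on similarity and conservation alone); novel candidates must
#' meet the HIGH criteria to be reported at all.
#'
#' @param hairpin_id Hairpin identifier.
#' @param structure_pass Result of [validate_hairpin()].
#' @param two_peak_pass Overall result of [two_peak_test()].
#' @param both_arms_expressed Logical: both arms have called matures.
#' @return data.frame row: `hairpin_id`, `class` (HIGH/LOW), the three flags.
#' @export
classify_confidence <- function(hairpin_id, structure_pass, two_peak_pass,
                                both_arms_expressed) {
  high <- structure_pass && two_peak_pass && both_arms_expressed
  data.frame(hairpin_id = hairpin_id, class = if (high) "HIGH" else "LOW",
             two_peak_pass = two_peak_pass, structure_pass = structure_pass,
             both_arms_expressed = both_arms_expressed,
             stringsAsFactors = FALSE)
}

#' Per-tissue 5p/3p arm abundance table
#'
#' @param profiles An `arm_profiles` object.
#' @param folds Named list of `fold_result`s (one per hairpin).
#' @return data.frame: `hairpin_id`, `tissue`, `count_5p`, `count_3p`.
#' @export
arm_abundance_table <- function(profiles, folds) {
  res <- list()
  for (hp in names(profiles$profiles)) {
    pr <- profiles$profiles[[hp]]
    fold <- folds[[hp]]
    b <- floor(.arm_boundary(pr$agg$start_counts, fold))
    for (tissue in names(pr$tissues)) {
      sc <- pr$tissues[[tissue]]$start_counts
      n <- length(sc)
      c5 <- sum(sc[seq_len(max(1L, b))])
      c3 <- if (b < n) sum(sc[(b + 1L):n]) else 0L
      res[[length(res) + 1L]] <- data.frame(
        hairpin_id = hp, tissue = tissue, count_5p = c5, count_3p = c3,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(hairpin_id = character(0), tissue = character(0),
                      count_5p = integer(0), count_3p = integer(0),
                      stringsAsFactors = FALSE)
  out
}

#' Detect arm switching across tissues
#'
#' For each hairpin, tissues with total arm reads of at least `min_total`
#' vote with the sign of `count_5p - count_3p`; a hairpin is flagged when both
#' signs occur among qualifying tissues.
#'
#' @param table Arm abundance table ([arm_abundance_table()]).
#' @param min_total Minimum 5p+3p count for a tissue to qualify.
#' @return data.frame: `hairpin_id`, `switching`, `n_tissues_5p`,
#'   `n_tissues_3p`.
#' @export
detect_arm_switching <- function(table, min_total = 20L) {
  groups <- split(table, table$hairpin_id)
  res <- lapply(names(groups), function(id) {
    tb <- groups[[id]]
    tb <- tb[tb$count_5p + tb$count_3p >= min_total, , drop = FALSE]
    sgn <- sign(tb$count_5p - tb$count_3p)
    n5 <- sum(sgn > 0); n3 <- sum(sgn < 0)
    data.frame(hairpin_id = id, switching = n5 > 0 && n3 > 0,
               n_tissues_5p = n5, n_tissues_3p = n3, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(hairpin_id = character(0), switching = logical(0),
                      n_tissues_5p = integer(0), n_tissues_3p = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Histogram of per-hairpin 5' read proportions
#'
#' For each tissue, the fraction `5p / (5p + 3p)` of every expressed hairpin
#' is binned into ten intervals `[0, 0.1), ..., [0.9, 1]`. Strong 5'/3' bias
#' shows up as mass in the outer bins.
#'
#' @param table Arm abundance table ([arm_abundance_table()]).
#' @return Matrix: tissues x 10 bins, counts of hairpins.
#' @export
five_prime_fraction_histogram <- function(table) {
  tissues <- sort(unique(table$tissue))
  bins <- paste0("[", seq(0, 0.9, 0.1), ",", seq(0.1, 1, 0.1),
                 c(rep(")", 9), "]"))
  out <- matrix(0L, length(tissues), 10L, dimnames = list(tissues, bins))
  tb <- table[table$count_5p + table$count_3p > 0, , drop = FALSE]
  if (nrow(tb) == 0L) return(out)
  frac <- tb$count_5p / (tb$count_5p + tb$count_3p)
  bin <- pmin(floor(frac * 10) + 1L, 10L)
  for (k in seq_len(nrow(tb)))
    out[tb$tissue[k], bin[k]] <- out[tb$tissue[k], bin[k]] + 1L
  out
}

#' Plot a hairpin expression profile
#'
#' Line plot of per-position 5'-start counts (or coverage) per tissue along
#' the hairpin, the standard visual for judging two-peak processing.
#'
#' @param profiles An `arm_profiles` object.
#' @param hairpin Hairpin name.
#' @param what `"coverage"` or `"start_counts"`.
#' @return Invisibly, the plotted matrix.
#' @export
plot_profile <- function(profiles, hairpin, what = c("coverage",
                                                     "start_counts")) {
  what <- match.arg(what)
  pr <- profiles$profiles[[hairpin]]
  if (is.null(pr)) stop("unknown hairpin: ", hairpin, call. = FALSE)
  tissues <- names(pr$tissues)
  n <- length(pr$agg$start_counts)
  m <- vapply(tissues, function(t) as.numeric(pr$tissues[[t]][[what]]),
              numeric(n))
  if (!length(tissues)) m <- matrix(0, n, 0)
  cols <- grDevices::hcl.colors(max(1L, ncol(m)), "Dark 3")
  graphics::matplot(seq_len(n), m, type = "l", lty = 1, col = cols,
                    xlab = "position on hairpin", ylab = what,
                    main = hairpin)
  if (ncol(m))
    graphics::legend("topright", legend = tissues, col = cols, lty = 1,
                     cex = 0.7, bty = "n")
  invisible(m)
}
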