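# shared internal helpers

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importFrom methods is
NULL

# vectorised reverse complement of character sequences (DNA alphabet)
rc <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# canonicalise sequences: uppercase, RNA U -> DNA T
dna_canon <- function(x) {
  chartr("U", "T", toupper(x))
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(what, " contains non-ACGT/U characters: ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop("'", name, "' must be a single number in [", min, ", ", max, "]",
         call. = FALSE)
  invisible(x)
}
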