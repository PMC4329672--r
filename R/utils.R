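# Internal sequence helpers. Sequences are plain uppercase character strings
# internally (DNA alphabet); Biostrings is used at the I/O boundary and for
# reverse complementation.

normalizeSequence <- function(x) {
  x <- toupper(as.character(x))
  gsub("U", "T", x, fixed = TRUE)
}

# Integer codes 1..4 for A,C,G,T; NA for anything else (N policy handled by
# callers).
seqToCodes <- function(x) {
  match(strsplit(x, "", fixed = TRUE)[[1]], DNA_BASES4)
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stopifnot_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(what, " must be a single finite number", call. = FALSE)
}
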