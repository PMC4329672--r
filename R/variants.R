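# Variant parsing, formatting and application.

#' Construct a VariantRecord
#'
#' @param seqId reference sequence identifier.
#' @param position 1-based first affected reference base (for a pure
#'   insertion: the base after which the insertion occurs).
#' @param refAllele,altAllele reference / alternate alleles; empty string
#'   for pure insertions / deletions respectively.
#' @param notationSource origin of the record.
#' @param originalText text the record was parsed from.
#' @return a \code{\linkS4class{VariantRecord}}.
#' @export
variantRecord <- function(seqId, position, refAllele, altAllele,
                          notationSource = "genomic",
                          originalText = NA_character_) {
  if (is.na(originalText))
    originalText <- sprintf("%s:%d%s>%s", seqId, position, refAllele,
                            altAllele)
  new("VariantRecord", seqId = as.character(seqId),
      position = as.integer(position),
      refAllele = toupper(refAllele), altAllele = toupper(altAllele),
      notationSource = notationSource, originalText = originalText)
}

#' Parse a variant string
#'
#' Accepts g.-style strings (\code{seq:100A>G}, \code{seq:50_52del},
#' \code{seq:50_52delACG}, \code{seq:100_101insTT}, \code{seq:50_52delinsAA})
#' and, when an exon table is supplied, the c. and IVS forms used in the
#' clinical literature (\code{seq:c.X+1G>T}, \code{seq:IVS2-6T>C}, with
#' del/ins/delins variants of the same anchors). c./IVS coordinates are
#' resolved to genomic positions through the exon table at parse time.
#' Formatting a parsed record with \code{\link{formatVariant}} and
#' re-parsing is the identity on canonical forms.
#'
#' @param text the variant string.
#' @param exonTable optional data.frame with columns \code{exon} (1-based
#'   index), \code{start}, \code{end} (1-based inclusive genomic
#'   coordinates), \code{strand}; required for c./IVS input. Only
#'   plus-strand transcripts are supported.
#' @return a \code{\linkS4class{VariantRecord}}.
#' @export
parseVariant <- function(text, exonTable = NULL) {
  text <- trimws(text)
  if (!grepl(":", text, fixed = TRUE))
    stop("variant must be prefixed with a sequence id, e.g. 'chrT:100A>G'")
  seqId <- sub(":.*$", "", text)
  body <- sub("^[^:]+:", "", text)
  body <- sub("^g\\.", "", body)

  if (grepl("^(c\\.|IVS)", body)) {
    if (is.null(exonTable))
      stop("c./IVS notation requires an exon table")
    return(parseTranscriptVariant(seqId, body, exonTable, text))
  }

  m <- regmatches(body, regexec("^(\\d+)([ACGTU])>([ACGTU])$", body))[[1]]
  if (length(m))
    return(variantRecord(seqId, m[2], normalizeSequence(m[3]),
                         normalizeSequence(m[4]), "genomic", text))

  m <- regmatches(body,
    regexec("^(\\d+)(?:_(\\d+))?delins([ACGTU]+)$", body))[[1]]
  if (length(m)) {
    p1 <- as.integer(m[2])
    p2 <- if (nzchar(m[3])) as.integer(m[3]) else p1
    if (p2 < p1) stop("delins end before start in: ", text)
    # reference bases deferred (N placeholder); filled by applyVariant
    return(variantRecord(seqId, p1, strrep("N", p2 - p1 + 1L),
                         normalizeSequence(m[4]), "genomic", text))
  }

  m <- regmatches(body,
    regexec("^(\\d+)(?:_(\\d+))?del([ACGTU]*)$", body))[[1]]
  if (length(m)) {
    p1 <- as.integer(m[2])
    p2 <- if (nzchar(m[3])) as.integer(m[3]) else p1
    if (p2 < p1) stop("deletion end before start in: ", text)
    ref <- normalizeSequence(m[4])
    if (!nzchar(ref)) ref <- strrep("N", p2 - p1 + 1L)
    return(makeDelRecord(seqId, p1, p2, ref, "genomic", text))
  }

  m <- regmatches(body, regexec("^(\\d+)_(\\d+)ins([ACGTU]+)$", body))[[1]]
  if (length(m)) {
    p1 <- as.integer(m[2]); p2 <- as.integer(m[3])
    if (p2 != p1 + 1L)
      stop("insertion positions must be adjacent, e.g. 100_101insTT")
    return(variantRecord(seqId, p1, "", normalizeSequence(m[4]),
                         "genomic", text))
  }
  stop("malformed variant string: ", text)
}

makeDelRecord <- function(seqId, p1, p2, ref, src, text) {
  if (p2 < p1) stop("deletion end before start in: ", text)
  if (nchar(ref) != p2 - p1 + 1L)
    stop("deleted bases do not match the stated interval in: ", text)
  new("VariantRecord", seqId = seqId, position = as.integer(p1),
      refAllele = ref, altAllele = "", notationSource = src,
      originalText = text)
}

# --- c./IVS resolution -----------------------------------------------------

checkExonTable <- function(exonTable) {
  need <- c("exon", "start", "end", "strand")
  if (!all(need %in% names(exonTable)))
    stop("exon table needs columns: ", paste(need, collapse = ", "))
  if (any(exonTable$strand != "+"))
    stop("only plus-strand exon tables are supported")
  exonTable[order(exonTable$exon), , drop = FALSE]
}

# Map a cDNA position (1-based over concatenated exons) plus an intronic
# offset to a genomic coordinate.
cdnaToGenomic <- function(exonTable, pos, offset = 0L) {
  et <- checkExonTable(exonTable)
  lens <- et$end - et$start + 1L
  cum <- cumsum(lens)
  if (pos < 1L || pos > cum[length(cum)])
    stop(sprintf("cDNA position %d outside the transcript (%d nt)",
                 pos, cum[length(cum)]))
  ex <- which(pos <= cum)[1]
  within <- pos - c(0L, cum)[ex]
  g <- et$start[ex] + within - 1L
  if (offset > 0 && within != lens[ex])
    stop("'+' intronic offsets must anchor at the last base of an exon")
  if (offset < 0 && within != 1L)
    stop("'-' intronic offsets must anchor at the first base of an exon")
  g + as.integer(offset)
}

# IVSn+k: k-th intronic base after exon n; IVSn-k: k-th base before exon n+1.
ivsToGenomic <- function(exonTable, intron, offset) {
  et <- checkExonTable(exonTable)
  if (intron < 1L || intron >= nrow(et))
    stop(sprintf("intron %d does not exist (transcript has %d exons)",
                 intron, nrow(et)))
  if (offset > 0) et$end[intron] + as.integer(offset)
  else if (offset < 0) et$start[intron + 1L] + as.integer(offset)
  else stop("IVS offset cannot be zero")
}

parseTranscriptVariant <- function(seqId, body, exonTable, text) {
  src <- if (startsWith(body, "c.")) "cdna" else "ivs"
  anchor <- "^c\\.(\\d+)([+-]\\d+)?"
  if (src == "ivs") anchor <- "^IVS(\\d+)([+-]\\d+)"
  m <- regmatches(body, regexec(anchor, body))[[1]]
  if (!length(m)) stop("malformed c./IVS variant: ", text)
  idx <- as.integer(m[2])
  off <- if (length(m) >= 3 && nzchar(m[3])) as.integer(m[3]) else 0L
  g <- if (src == "cdna") cdnaToGenomic(exonTable, idx, off)
       else ivsToGenomic(exonTable, idx, off)
  rest <- sub(anchor, "", body)

  mm <- regmatches(rest, regexec("^([ACGTU])>([ACGTU])$", rest))[[1]]
  if (length(mm)) {
    v <- variantRecord(seqId, g, normalizeSequence(mm[2]),
                       normalizeSequence(mm[3]), src, text)
    return(v)
  }
  mm <- regmatches(rest, regexec("^del([ACGTU]+)$", rest))[[1]]
  if (length(mm))
    return(makeDelRecord(seqId, g, g + nchar(mm[2]) - 1L,
                         normalizeSequence(mm[2]), src, text))
  mm <- regmatches(rest, regexec("^ins([ACGTU]+)$", rest))[[1]]
  if (length(mm))
    return(variantRecord(seqId, g, "", normalizeSequence(mm[2]), src, text))
  stop("unsupported c./IVS variant form: ", text)
}

#' Format a VariantRecord as a canonical g.-style string
#'
#' @param v a \code{\linkS4class{VariantRecord}}.
#' @return character, e.g. \code{"chrT:100A>G"}, \code{"chrT:50_52delACG"},
#'   \code{"chrT:100_101insTT"}, \code{"chrT:50_52delinsAA"}.
#' @export
formatVariant <- function(v) {
  stopifnot(is(v, "VariantRecord"))
  ref <- v@refAllele; alt <- v@altAllele; p <- v@position
  if (nchar(ref) == 1L && nchar(alt) == 1L)
    return(sprintf("%s:%d%s>%s", v@seqId, p, ref, alt))
  if (nchar(alt) == 0L) {
    if (nchar(ref) == 1L)
      return(sprintf("%s:%ddel%s", v@seqId, p, ref))
    return(sprintf("%s:%d_%ddel%s", v@seqId, p, p + nchar(ref) - 1L, ref))
  }
  if (nchar(ref) == 0L)
    return(sprintf("%s:%d_%dins%s", v@seqId, p, p + 1L, alt))
  sprintf("%s:%d_%ddelins%s", v@seqId, p, p + nchar(ref) - 1L, alt)
}

setMethod("show", "VariantRecord", function(object) {
  cat(sprintf("VariantRecord %s (%s)\n", formatVariant(object),
              object@notationSource))
})

#' Apply a variant to a reference sequence
#'
#' Validates the reference allele against the sequence (a mismatch is
#' rejected naming expected vs observed -- the wrong-isoform guard), builds
#' the mutated sequence, and returns a monotone coordinate map from old to
#' new 1-based positions. Positions inside a deletion map to \code{NA};
#' substitutions have the identity map.
#'
#' @param reference the reference sequence (character or DNAString).
#' @param v a \code{\linkS4class{VariantRecord}}.
#' @return list with \code{sequence} (mutated), \code{coordMap} (integer
#'   vector of length \code{nchar(reference)}), and \code{v} (the record,
#'   with any deferred reference bases filled in).
#' @export
applyVariant <- function(reference, v) {
  stopifnot(is(v, "VariantRecord"))
  reference <- normalizeSequence(reference)
  n <- nchar(reference)
  refLen <- nchar(v@refAllele)
  p <- v@position
  if (p > n || (refLen > 0 && p + refLen - 1L > n))
    stop(sprintf("variant at %d outside reference of length %d", p, n))
  if (refLen > 0) {
    observed <- substr(reference, p, p + refLen - 1L)
    if (grepl("N", v@refAllele, fixed = TRUE)) {
      v@refAllele <- observed  # deferred ref (bare del / delins)
    } else if (observed != v@refAllele) {
      stop(sprintf(
        "reference mismatch at %s:%d: expected '%s', sequence has '%s'",
        v@seqId, p, v@refAllele, observed))
    }
  }
  altLen <- nchar(v@altAllele)
  pre <- if (refLen > 0) substr(reference, 1, p - 1L)
         else substr(reference, 1, p)
  post <- if (refLen > 0) substr(reference, p + refLen, n)
          else substr(reference, p + 1L, n)
  mutated <- paste0(pre, v@altAllele, post)

  shift <- altLen - refLen
  coordMap <- seq_len(n)
  if (refLen > 0) {
    if (altLen > 0) {
      # delins/substitution: affected bases map into the replacement,
      # truncated if the replacement is shorter
      inside <- seq.int(p, p + refLen - 1L)
      coordMap[inside] <- ifelse(seq_along(inside) <= altLen,
                                 p + seq_along(inside) - 1L, NA_integer_)
    } else {
      coordMap[seq.int(p, p + refLen - 1L)] <- NA_integer_
    }
    if (p + refLen <= n)
      coordMap[seq.int(p + refLen, n)] <-
        coordMap[seq.int(p + refLen, n)] + shift
  } else if (p + 1L <= n) {
    coordMap[seq.int(p + 1L, n)] <- coordMap[seq.int(p + 1L, n)] + altLen
  }
  list(sequence = mutated, coordMap = coordMap, v = v)
}

#' Invert a variant
#'
#' Returns the record that exactly undoes \code{v} on the mutated sequence;
#' applying a variant and then its inverse restores the reference and all
#' site strengths.
#'
#' @param v a \code{\linkS4class{VariantRecord}} with a concrete reference
#'   allele.
#' @return a \code{\linkS4class{VariantRecord}}.
#' @export
invertVariant <- function(v) {
  stopifnot(is(v, "VariantRecord"))
  ref <- v@refAllele; alt <- v@altAllele
  if (nchar(alt) == 0L) {
    # deletion at p..p+r-1 is undone by inserting after p-1
    return(variantRecord(v@seqId, v@position - 1L, "", ref,
                         v@notationSource))
  }
  if (nchar(ref) == 0L) {
    # insertion after p is undone by deleting p+1..p+a
    return(variantRecord(v@seqId, v@position + 1L, alt, "",
                         v@notationSource))
  }
  variantRecord(v@seqId, v@position, alt, ref, v@notationSource)
}
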