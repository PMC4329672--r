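#' Build an individual-information model from aligned binding sites
#'
#' Estimates per-position base frequencies from equal-length aligned
#' training sequences and converts them to weights in bits,
#' \eqn{w(b,l) = 2 + \log_2[(n_{b,l} + p)/(n + 4p)]} where \eqn{p} is the
#' pseudocount. With \code{pseudocount = 0} a base never observed at a
#' position receives the finite sentinel \code{floorBits} instead of
#' \eqn{-\infty}. The model's \code{rSequence} is the mean individual
#' information of the training sequences under the fitted weights (exactly
#' the average information \eqn{\sum_l 2 - H(l)} when \code{pseudocount = 0}
#' and no correction is applied).
#'
#' Sequences containing ambiguous bases (N) are dropped with a warning,
#' since counting them as missing data would bias the frequencies. U is
#' mapped to T on input.
#'
#' @param trainingSeqs character vector (or DNAStringSet) of equal-length
#'   site sequences.
#' @param offsetStart,offsetEnd inclusive window offsets relative to the
#'   model zero point (first intronic base for donors, last intronic base
#'   for acceptors). Window length must equal the sequence length.
#' @param pseudocount per-base pseudocount; default 0.5. Use 0 for the exact
#'   identity between \code{rSequence} and the training-set mean.
#' @param applyCorrection subtract the first-order small-sample bias
#'   \eqn{3L/(2 n \ln 2)} bits from \code{rSequence} (individual weights are
#'   never corrected). Default \code{FALSE}.
#' @param name,siteKind model label and site kind.
#' @param floorBits sentinel weight for unobserved bases at pseudocount 0.
#' @return an \code{\linkS4class{InfoModel}}.
#' @examples
#' m <- buildInfoModel(c("ACGT", "ACGA", "ACGT"), offsetStart = -1,
#'                     offsetEnd = 2, pseudocount = 0)
#' rSequence(m)
#' @export
buildInfoModel <- function(trainingSeqs, offsetStart, offsetEnd,
                           pseudocount = 0.5, applyCorrection = FALSE,
                           name = "model", siteKind = "donor",
                           floorBits = -20) {
  trainingSeqs <- vapply(as.character(trainingSeqs), normalizeSequence, "")
  if (length(trainingSeqs) == 0L)
    stop("at least one training sequence is required")
  offsetStart <- as.integer(offsetStart)
  offsetEnd <- as.integer(offsetEnd)
  L <- offsetEnd - offsetStart + 1L
  lens <- nchar(trainingSeqs)
  bad <- which(lens != L)
  if (length(bad))
    stop(sprintf(
      "training sequence %d has length %d; window [%d, %d] requires %d",
      bad[1], lens[bad[1]], offsetStart, offsetEnd, L))
  if (any(grepl("[^ACGTN]", trainingSeqs)))
    stop("training sequences must use the alphabet A, C, G, T, U, N")
  hasN <- grepl("N", trainingSeqs, fixed = TRUE)
  if (any(hasN)) {
    warning(sprintf("dropped %d training sequence(s) containing N",
                    sum(hasN)))
    trainingSeqs <- trainingSeqs[!hasN]
    if (length(trainingSeqs) == 0L)
      stop("no training sequences left after dropping records with N")
  }
  n <- length(trainingSeqs)

  codeMat <- t(vapply(trainingSeqs, seqToCodes, integer(L)))
  if (L == 1L) codeMat <- matrix(as.integer(codeMat), ncol = 1L)
  counts <- vapply(seq_len(L), function(l)
    tabulate(codeMat[, l], nbins = 4L), numeric(4))
  dimnames(counts) <- list(DNA_BASES4, as.character(offsetStart:offsetEnd))

  freqs <- (counts + pseudocount) / (n + 4 * pseudocount)
  weights <- 2 + log2(freqs)
  if (pseudocount == 0)
    weights[counts == 0] <- floorBits

  model <- new("InfoModel",
    name = name, siteKind = siteKind,
    offsetStart = offsetStart, offsetEnd = offsetEnd,
    weights = weights, freqs = freqs, nSites = n,
    rSequence = 0, rSequenceSD = 0,
    pseudocount = pseudocount, correctionApplied = applyCorrection,
    floorBits = floorBits)

  ri <- vapply(trainingSeqs, function(s) scoreWindow(model, s)$rI, 0)
  rSeq <- mean(ri)
  if (applyCorrection)
    rSeq <- rSeq - smallSampleCorrection(n, L)
  model@rSequence <- rSeq
  model@rSequenceSD <- if (n > 1) stats::sd(ri) else 0
  model
}

# First-order bias of the plug-in entropy estimator, summed over positions:
# (k - 1) / (2 n ln 2) bits per position with k = 4 bases.
smallSampleCorrection <- function(n, L) {
  L * 3 / (2 * n * log(2))
}

#' Construct an InfoModel directly from a frequency matrix
#'
#' Used for generating models (synthetic-data oracles) and for loading
#' externally derived matrices. Frequencies at each position must sum to 1.
#'
#' @param freqs 4 x L matrix (rows A,C,G,T) of base frequencies; columns are
#'   window positions.
#' @param offsetStart first window offset (the last is implied by L).
#' @param name,siteKind,floorBits,nSites see
#'   \code{\link{buildInfoModel}}; \code{nSites} records the (nominal) size
#'   of the set the frequencies came from.
#' @return an \code{\linkS4class{InfoModel}} with \code{pseudocount = 0};
#'   \code{rSequence} is the expected information
#'   \eqn{\sum_l (2 - H(l))} of the frequency matrix.
#' @export
infoModelFromFrequencies <- function(freqs, offsetStart,
                                     name = "model", siteKind = "donor",
                                     floorBits = -20, nSites = 0L) {
  freqs <- as.matrix(freqs)
  if (nrow(freqs) != 4L)
    stop("frequency matrix must have 4 rows (A, C, G, T)")
  rownames(freqs) <- DNA_BASES4
  sums <- colSums(freqs)
  if (any(abs(sums - 1) > 1e-9) || any(freqs < 0))
    stop("frequencies at each position must be non-negative and sum to 1")
  offsetStart <- as.integer(offsetStart)
  offsetEnd <- offsetStart + ncol(freqs) - 1L
  colnames(freqs) <- as.character(offsetStart:offsetEnd)
  weights <- 2 + log2(freqs)
  weights[freqs == 0] <- floorBits
  perPos <- 2 + colSums(ifelse(freqs > 0, freqs * log2(freqs), 0))
  # sd of R_i under independent positions: sum of per-position variances
  perPosVar <- vapply(seq_len(ncol(freqs)), function(l) {
    f <- freqs[, l]
    w <- ifelse(f > 0, 2 + log2(f), 0)
    sum(f * w^2) - sum(f * w)^2
  }, 0)
  new("InfoModel",
    name = name, siteKind = siteKind,
    offsetStart = offsetStart, offsetEnd = offsetEnd,
    weights = weights, freqs = freqs, nSites = as.integer(nSites),
    rSequence = sum(perPos), rSequenceSD = sqrt(sum(perPosVar)),
    pseudocount = 0, correctionApplied = FALSE, floorBits = floorBits)
}

#' Per-position average information and its total
#'
#' Returns for each position the average information \eqn{2 - H(l)} (H the
#' Shannon entropy of the base distribution at that position, in bits) and
#' the total over positions. The total equals \code{rSequence(model)} when
#' the model was built with pseudocount 0 and no correction.
#'
#' @param model an \code{\linkS4class{InfoModel}}.
#' @return list with \code{profile} (named numeric, bits per position) and
#'   \code{total} (bits).
#' @export
averageInformation <- function(model) {
  stopifnot(is(model, "InfoModel"))
  f <- model@freqs
  profile <- 2 + colSums(ifelse(f > 0, f * log2(f), 0))
  names(profile) <- colnames(model@weights)
  list(profile = profile, total = sum(profile))
}

#' Sequence-logo data for an InfoModel
#'
#' Base heights for a sequence logo: at each position, the height of base b
#' is its frequency times the position's average information, so the heights
#' at a position stack to the position's information contribution. Bases are
#' ranked by descending frequency within each position.
#'
#' @param model an \code{\linkS4class{InfoModel}}.
#' @return data.frame with columns \code{offset}, \code{base}, \code{freq},
#'   \code{height} (bits), \code{rank}.
#' @export
logoData <- function(model) {
  stopifnot(is(model, "InfoModel"))
  info <- averageInformation(model)$profile
  offs <- as.integer(colnames(model@weights))
  out <- do.call(rbind, lapply(seq_along(offs), function(l) {
    f <- model@freqs[, l]
    ord <- order(f, decreasing = TRUE)
    data.frame(offset = offs[l], base = DNA_BASES4[ord], freq = f[ord],
               height = f[ord] * info[l], rank = seq_len(4),
               row.names = NULL)
  }))
  out
}

#' @describeIn InfoModel-accessors average information of the training set
#'   (bits)
#' @export
rSequence <- function(model) model@rSequence

#' Accessors for InfoModel
#'
#' @param model an \code{\linkS4class{InfoModel}}.
#' @name InfoModel-accessors
#' @export
modelWeights <- function(model) model@weights

#' @describeIn InfoModel-accessors inclusive window offsets
#' @export
modelOffsets <- function(model) c(model@offsetStart, model@offsetEnd)

#' @describeIn InfoModel-accessors window length in nt
#' @export
modelWindowLength <- function(model) model@offsetEnd - model@offsetStart + 1L

#' @describeIn InfoModel-accessors site kind
#' @export
siteKind <- function(model) model@siteKind

#' @describeIn InfoModel-accessors number of training sites
#' @export
nSites <- function(model) model@nSites

#' @describeIn InfoModel-accessors per-position argmax (consensus) sequence
#' @export
consensusSequence <- function(model) {
  paste(DNA_BASES4[apply(model@weights, 2, which.max)], collapse = "")
}

#' @describeIn InfoModel-accessors maximum attainable R_i (consensus score)
#' @export
maxScore <- function(model) sum(apply(model@weights, 2, max))

setMethod("show", "InfoModel", function(object) {
  cat(sprintf(
    "InfoModel '%s' (%s), window [%d, %+d] (%d nt)\n",
    object@name, object@siteKind, object@offsetStart, object@offsetEnd,
    modelWindowLength(object)))
  cat(sprintf(
    "  n = %d sites; R_sequence = %.2f +/- %.2f bits; pseudocount = %g%s\n",
    object@nSites, object@rSequence, object@rSequenceSD, object@pseudocount,
    if (object@correctionApplied) " (small-sample corrected)" else ""))
  cat(sprintf("  consensus: %s (max R_i = %.2f bits)\n",
              consensusSequence(object), maxScore(object)))
})
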