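# Scoring: individual information of single placements, exhaustive window
# scanning, and sequence-walker decompositions.

# Score a bare window string against a model: per-position contributions,
# ambiguous bases contribute 0 bits (conservative N policy) and are flagged.
scoreWindow <- function(model, windowSeq) {
  codes <- seqToCodes(windowSeq)
  L <- modelWindowLength(model)
  if (length(codes) != L)
    stop(sprintf("window has %d nt; model requires %d", length(codes), L))
  contrib <- numeric(L)
  ok <- !is.na(codes)
  contrib[ok] <- model@weights[cbind(codes[ok], which(ok))]
  names(contrib) <- colnames(model@weights)
  list(rI = sum(contrib), contributions = contrib, hasN = any(!ok))
}

#' Score one site placement
#'
#' Computes the individual information \eqn{R_i} of the model placed with
#' its zero point at \code{zeroCoord} (1-based) on \code{sequence}. For
#' \code{strand = "-"} the window is read off the reverse complement:
#' plus-strand positions \code{zeroCoord - offsetEnd} through
#' \code{zeroCoord - offsetStart}, reverse-complemented, so that
#' \code{zeroCoord} is the model zero point on the minus strand.
#'
#' Ambiguous bases (N) in the window contribute 0 bits and set the
#' \code{hasN} flag -- a conservative choice that neither rewards nor
#' penalizes unknown sequence.
#'
#' @param model an \code{\linkS4class{InfoModel}}.
#' @param sequence character (or DNAString) to score on.
#' @param zeroCoord 1-based coordinate of the model zero point.
#' @param strand \code{"+"} (default) or \code{"-"}.
#' @return a \code{\linkS4class{ScoredSite}}.
#' @export
scoreSite <- function(model, sequence, zeroCoord, strand = "+") {
  stopifnot(is(model, "InfoModel"))
  sequence <- normalizeSequence(sequence)
  zeroCoord <- as.integer(zeroCoord)
  n <- nchar(sequence)
  if (strand == "+") {
    from <- zeroCoord + model@offsetStart
    to <- zeroCoord + model@offsetEnd
  } else if (strand == "-") {
    from <- zeroCoord - model@offsetEnd
    to <- zeroCoord - model@offsetStart
  } else stop("strand must be '+' or '-'")
  if (from < 1L || to > n)
    stop(sprintf(
      "window [%d, %d] outside sequence of length %d (pad by %d nt)",
      from, to, n, max(1L - from, to - n)))
  win <- substr(sequence, from, to)
  if (strand == "-") win <- revComp(win)
  sc <- scoreWindow(model, win)
  new("ScoredSite",
    modelName = model@name, siteKind = model@siteKind,
    zeroCoord = zeroCoord, strand = strand,
    rI = sc$rI, contributions = sc$contributions,
    windowSeq = win, hasN = sc$hasN)
}

#' Scan a sequence for candidate sites
#'
#' Scores every placement of the model whose window lies inside
#' \code{region} and returns those with \eqn{R_i \ge} \code{minRi}, sorted
#' by coordinate (ties in ranked reports break to the lower coordinate).
#' The result is identical to exhaustive per-offset \code{\link{scoreSite}}.
#'
#' @param model an \code{\linkS4class{InfoModel}}.
#' @param sequence sequence to scan.
#' @param minRi minimum reported \eqn{R_i} in bits; default \code{-Inf}
#'   reports every placement.
#' @param region 1-based inclusive \code{c(start, end)} interval restricting
#'   the window placements; default the whole sequence.
#' @param strand \code{"+"} or \code{"-"}.
#' @return data.frame with columns \code{zeroCoord}, \code{strand},
#'   \code{siteKind}, \code{modelName}, \code{rI}, \code{windowSeq},
#'   \code{hasN}.
#' @export
scanSites <- function(model, sequence, minRi = -Inf, region = NULL,
                      strand = "+") {
  stopifnot(is(model, "InfoModel"))
  sequence <- normalizeSequence(sequence)
  n <- nchar(sequence)
  if (strand == "-") {
    # scan the reverse complement on + and mirror the coordinates
    rc <- revComp(sequence)
    rcRegion <- if (is.null(region)) NULL else
      c(n + 1L - as.integer(region[2]), n + 1L - as.integer(region[1]))
    hits <- scanSites(model, rc, minRi, rcRegion, "+")
    hits$zeroCoord <- n + 1L - hits$zeroCoord
    hits$strand <- rep("-", nrow(hits))
    hits <- hits[order(hits$zeroCoord), , drop = FALSE]
    rownames(hits) <- NULL
    return(hits)
  }
  if (is.null(region)) region <- c(1L, n)
  region <- as.integer(region)
  if (region[1] < 1L || region[2] > n || region[1] > region[2])
    return(emptyScan())
  L <- modelWindowLength(model)
  if (region[2] - region[1] + 1L < L) return(emptyScan())
  starts <- region[1]:(region[2] - L + 1L)

  codes <- seqToCodes(sequence)
  # sliding scores: score[i] = sum_j w[code[i+j-1], j]; N positions add 0
  sc <- numeric(length(starts))
  hasN <- logical(length(starts))
  w <- model@weights
  for (j in seq_len(L)) {
    cj <- codes[starts + j - 1L]
    miss <- is.na(cj)
    add <- numeric(length(cj))
    add[!miss] <- w[cbind(cj[!miss], j)]
    sc <- sc + add
    hasN <- hasN | miss
  }
  zero <- starts - model@offsetStart
  idx <- which(sc >= minRi)
  if (!length(idx)) return(emptyScan())
  data.frame(
    zeroCoord = zero[idx], strand = rep("+", length(idx)),
    siteKind = rep(model@siteKind, length(idx)),
    modelName = rep(model@name, length(idx)),
    rI = sc[idx],
    windowSeq = substring(sequence, starts[idx], starts[idx] + L - 1L),
    hasN = hasN[idx],
    stringsAsFactors = FALSE)
}

emptyScan <- function() {
  data.frame(zeroCoord = integer(), strand = character(),
             siteKind = character(), modelName = character(),
             rI = numeric(), windowSeq = character(), hasN = logical(),
             stringsAsFactors = FALSE)
}

#' Sequence-walker report for a scored site
#'
#' Per-position decomposition of a site's \eqn{R_i}: the base at each
#' offset, its bit contribution, and whether the contribution argues
#' against binding (negative). Contributions sum to \code{rI(site)}.
#'
#' @param site a \code{\linkS4class{ScoredSite}}.
#' @return data.frame with columns \code{offset}, \code{base},
#'   \code{contribution}, \code{negative}.
#' @export
walkerTable <- function(site) {
  stopifnot(is(site, "ScoredSite"))
  data.frame(
    offset = as.integer(names(site@contributions)),
    base = strsplit(site@windowSeq, "")[[1]],
    contribution = unname(site@contributions),
    negative = unname(site@contributions < 0),
    stringsAsFactors = FALSE)
}

#' @describeIn scoreSite individual information of a ScoredSite, in bits
#' @param site a \code{\linkS4class{ScoredSite}}.
#' @export
rI <- function(site) site@rI

#' @describeIn scoreSite zero-point coordinate of a ScoredSite (1-based)
#' @export
zeroCoord <- function(site) site@zeroCoord

setMethod("show", "ScoredSite", function(object) {
  cat(sprintf(
    "ScoredSite: %s (%s) at %d (%s), R_i = %.2f bits%s\n  window: %s\n",
    object@modelName, object@siteKind, object@zeroCoord, object@strand,
    object@rI, if (object@hasN) " [contains N]" else "", object@windowSeq))
})
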