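# Variant interpretation: site deltas, fold changes, residual strength,
# severity bins.

#' Minimum fold change in binding affinity for an information change
#'
#' The minimum fold change in spliceosome binding affinity implied by a
#' change of \eqn{\Delta R_i} bits is \eqn{2^{|\Delta R_i|}}; the direction
#' records whether it is a reduction (\eqn{\Delta R_i < 0}) or an increase.
#' A 7.0-bit weakening is therefore at least a 128-fold reduction in
#' affinity.
#'
#' @param deltaRi change in individual information, bits.
#' @return numeric fold change (\eqn{\ge 1}) with attribute
#'   \code{direction} (\code{"reduction"}, \code{"increase"} or
#'   \code{"none"}).
#' @examples
#' foldChange(-7)   # 128-fold reduction
#' foldChange(9.1)  # >= 549-fold increase
#' @export
foldChange <- function(deltaRi) {
  stopifnot_scalar_number(deltaRi, "deltaRi")
  fold <- 2^abs(deltaRi)
  attr(fold, "direction") <-
    if (deltaRi < 0) "reduction" else if (deltaRi > 0) "increase" else "none"
  fold
}

#' Residual binding strength as a percentage
#'
#' The residual strength of a weakened site on the bit scale:
#' \eqn{100 \times R_{i,final} / R_{i,initial}} with
#' \eqn{R_{i,initial} = R_{i,final} - \Delta R_i}. Reported alongside the
#' affinity fold change (\code{\link{foldChange}}) because the two are often
#' confused: a site at 5.4 bits after a -2.6 bit change retains 67.5% of its
#' information but at most \eqn{2^{-2.6} \approx 16\%} of its binding
#' affinity.
#'
#' @param rIFinal final site strength, bits.
#' @param deltaRi change in strength, bits.
#' @return percent (numeric), or \code{NA} with attribute
#'   \code{undefined = TRUE} when the initial strength is not positive.
#' @export
residualStrength <- function(rIFinal, deltaRi) {
  stopifnot_scalar_number(rIFinal, "rIFinal")
  stopifnot_scalar_number(deltaRi, "deltaRi")
  rIInitial <- rIFinal - deltaRi
  if (rIInitial <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  100 * rIFinal / rIInitial
}

#' Severity bin for a natural-site information change
#'
#' Classifies \eqn{\Delta R_i} at a natural splice site into the empirical
#' severity bins used for reported substitutions: sites weakened by more
#' than 7.0 bits are deleterious; by 4.0 to 7.0 bits probably deleterious;
#' by 1.0 to 4.0 bits leaky; smaller changes benign (probable
#' polymorphism). The printed bins share endpoints; they are resolved as
#' half-open intervals with each boundary assigned to the less severe bin
#' ("more than 7.0 bits" is strict).
#'
#' @param deltaRi change in individual information, bits (finite;
#'   vectorized).
#' @return factor with levels \code{deleterious},
#'   \code{probably_deleterious}, \code{leaky}, \code{benign}.
#' @examples
#' classifySMC(c(-7.5, -5, -2, -0.5, 0.3))
#' @export
classifySMC <- function(deltaRi) {
  if (any(!is.finite(deltaRi))) stop("deltaRi must be finite")
  bins <- cut(deltaRi, breaks = c(-Inf, -7, -4, -1, Inf), right = FALSE,
              labels = c("deleterious", "probably_deleterious", "leaky",
                         "benign"))
  bins
}

# Map a pre-variant coordinate through a coordinate map; positions deleted
# by the variant re-anchor to the nearest surviving position downstream
# (falling back upstream at the 3' end).
mapCoord <- function(coordMap, pos) {
  n <- length(coordMap)
  if (pos < 1L || pos > n) return(NA_integer_)
  if (!is.na(coordMap[pos])) return(coordMap[pos])
  after <- which(!is.na(coordMap[pos:n]))
  if (length(after)) return(coordMap[pos + after[1] - 1L])
  before <- which(!is.na(coordMap[1:pos]))
  if (length(before)) return(coordMap[before[length(before)]])
  NA_integer_
}

SITE_CATEGORIES <- c("unchanged_above_min", "unchanged_below_min",
                     "abolished", "leaky", "natural_strengthened",
                     "cryptic_created", "cryptic_strengthened",
                     "cryptic_weakened")

#' Analyze a variant against a set of information models
#'
#' Scores every placement of every model whose window overlaps the variant
#' within the analysis window (default 54 nt circumscribing the mutation),
#' before and after applying the variant, and reports the per-site deltas:
#' \eqn{R_{i,initial}}, \eqn{R_{i,final}}, \eqn{\Delta R_i}, minimum fold
#' change, residual strength, category and (for natural sites) the severity
#' bin.
#'
#' Categories: an annotated natural site whose final strength falls below
#' \code{riMin} with a significant weakening is \code{abolished}; weakened
#' significantly but remaining above \code{riMin} is \code{leaky};
#' strengthened significantly is \code{natural_strengthened}. A non-natural
#' placement crossing \code{riMin} upward with a significant gain is
#' \code{cryptic_created}; otherwise significant gains / losses are
#' \code{cryptic_strengthened} / \code{cryptic_weakened}. Everything else is
#' \code{unchanged_above_min} or \code{unchanged_below_min} by its final
#' strength. Sites whose windows span a deletion are re-anchored through the
#' coordinate map and rescored on the mutated sequence, not masked.
#'
#' @param reference the reference sequence.
#' @param v a \code{\linkS4class{VariantRecord}}.
#' @param models list of \code{\linkS4class{InfoModel}}s.
#' @param naturalSites data.frame of annotated sites with columns
#'   \code{kind}, \code{zeroCoord}, \code{strand} (may be empty).
#' @param windowNt analysis window around the variant, nt (default 54; must
#'   be at least the largest model window).
#' @param riMin minimum functional site strength, bits: 1.6 for genome-wide
#'   style models (default), 2.4 for the legacy models.
#' @param significanceBits threshold for calling a change (default 1.0 bit;
#'   smaller changes are not reliably detected experimentally).
#' @param strand strand(s) to report: \code{"+"} (default, the annotated
#'   gene strand), \code{"-"}, or \code{"both"}.
#' @return data.frame with one row per scored placement: \code{modelName},
#'   \code{siteKind}, \code{zeroCoord}, \code{zeroCoordPost},
#'   \code{strand}, \code{isNatural}, \code{rIInitial}, \code{rIFinal},
#'   \code{deltaRi}, \code{minFoldChange}, \code{foldDirection},
#'   \code{residualPct}, \code{category}, \code{smcBin}.
#' @export
analyzeVariant <- function(reference, v, models, naturalSites = NULL,
                           windowNt = 54, riMin = 1.6,
                           significanceBits = 1.0, strand = "+") {
  reference <- normalizeSequence(reference)
  if (is(models, "InfoModel")) models <- list(models)
  maxWin <- max(vapply(models, modelWindowLength, 0L))
  if (windowNt < maxWin)
    stop(sprintf("windowNt (%d) must be at least the largest model window (%d)",
                 as.integer(windowNt), maxWin))
  strands <- switch(strand, "+" = "+", "-" = "-", both = c("+", "-"),
                    stop("strand must be '+', '-' or 'both'"))
  app <- applyVariant(reference, v)
  v <- app$v
  n <- nchar(reference)
  varStart <- v@position
  # insertions affect the junction between position and position + 1
  varEnd <- if (nchar(v@refAllele) == 0L) v@position + 1L
            else v@position + nchar(v@refAllele) - 1L
  half <- floor(windowNt / 2)
  lo <- max(1L, varStart - half)
  hi <- min(n, varEnd + half)

  rows <- list()
  for (model in models) {
    os <- model@offsetStart; oe <- model@offsetEnd
    for (st in strands) {
      # zero coords whose window intersects the affected bases, clipped to
      # the analysis window and the sequence
      if (st == "+") {
        zmin <- max(varStart - oe, lo - oe, 1L - os)
        zmax <- min(varEnd - os, hi - os, n - oe)
      } else {
        zmin <- max(varStart + os, lo + os, 1L + oe)
        zmax <- min(varEnd + oe, hi + oe, n + os)
      }
      if (zmin > zmax) next
      for (z in seq.int(zmin, zmax)) {
        pre <- scoreSite(model, reference, z, st)
        zPost <- mapCoord(app$coordMap, z)
        post <- tryCatch(
          if (is.na(zPost)) NULL
          else scoreSite(model, app$sequence, zPost, st),
          error = function(e) NULL)
        if (is.null(post)) next
        isNat <- !is.null(naturalSites) && nrow(naturalSites) > 0 &&
          any(naturalSites$kind == model@siteKind &
              naturalSites$zeroCoord == z &
              naturalSites$strand == st)
        d <- post@rI - pre@rI
        fold <- foldChange(d)
        res <- residualStrength(post@rI, d)
        cat_ <- categorizeDelta(pre@rI, post@rI, d, isNat, riMin,
                                significanceBits)
        rows[[length(rows) + 1L]] <- data.frame(
          modelName = model@name, siteKind = model@siteKind,
          zeroCoord = z, zeroCoordPost = zPost, strand = st,
          isNatural = isNat, rIInitial = pre@rI, rIFinal = post@rI,
          deltaRi = d, minFoldChange = as.numeric(fold),
          foldDirection = attr(fold, "direction"),
          residualPct = as.numeric(res),
          category = cat_,
          smcBin = if (isNat) as.character(classifySMC(d)) else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    message("no model placement overlaps the variant within the window")
    return(emptyDeltas())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

categorizeDelta <- function(rIInitial, rIFinal, d, isNatural, riMin,
                            significanceBits) {
  sig <- abs(d) >= significanceBits
  if (isNatural) {
    if (sig && d < 0 && rIFinal < riMin) return("abolished")
    if (sig && d < 0) return("leaky")
    if (sig && d > 0) return("natural_strengthened")
  } else if (sig) {
    if (d > 0 && rIInitial < riMin && rIFinal >= riMin)
      return("cryptic_created")
    if (d > 0) return("cryptic_strengthened")
    return("cryptic_weakened")
  }
  if (rIFinal >= riMin) "unchanged_above_min" else "unchanged_below_min"
}

emptyDeltas <- function() {
  data.frame(modelName = character(), siteKind = character(),
             zeroCoord = integer(), zeroCoordPost = integer(),
             strand = character(), isNatural = logical(),
             rIInitial = numeric(), rIFinal = numeric(),
             deltaRi = numeric(), minFoldChange = numeric(),
             foldDirection = character(), residualPct = numeric(),
             category = character(), smcBin = character(),
             stringsAsFactors = FALSE)
}

#' Direct severity lookup for a substitution at a model offset
#'
#' The change in information for a substitution at one model offset is the
#' weight difference at that offset, independent of sequence context:
#' \eqn{\Delta R_i = w(alt, l) - w(ref, l)}.
#'
#' @param model an \code{\linkS4class{InfoModel}}.
#' @param offset integer model offset (within the window).
#' @param refBase,altBase single bases.
#' @return list with \code{deltaRi}, \code{minFoldChange},
#'   \code{foldDirection} and \code{smcBin}.
#' @export
calcDeltaRi <- function(model, offset, refBase, altBase) {
  stopifnot(is(model, "InfoModel"))
  offs <- as.integer(colnames(model@weights))
  l <- match(as.integer(offset), offs)
  if (is.na(l))
    stop(sprintf("offset %d outside model window [%d, %d]",
                 as.integer(offset), model@offsetStart, model@offsetEnd))
  refBase <- normalizeSequence(refBase); altBase <- normalizeSequence(altBase)
  ib <- match(refBase, DNA_BASES4); ia <- match(altBase, DNA_BASES4)
  if (is.na(ib) || is.na(ia)) stop("bases must be A, C, G, T or U")
  d <- model@weights[ia, l] - model@weights[ib, l]
  fold <- foldChange(d)
  list(deltaRi = unname(d), minFoldChange = as.numeric(fold),
       foldDirection = attr(fold, "direction"),
       smcBin = as.character(classifySMC(d)))
}
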