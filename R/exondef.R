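# Exon definition: gap surprisal, total exon information, isoform ranking,
# branch-point scanning.

#' Construct a gap-surprisal model
#'
#' @param edges increasing integer upper bin edges (nt); bin i covers
#'   (edges[i-1], edges[i]], the first bin starts at 1.
#' @param probs bin probabilities summing to 1.
#' @param kind \code{"exon_length"} or \code{"regulatory_distance"}.
#' @param tailPolicy beyond the last edge: \code{"floor"} (default, the
#'   floor probability) or \code{"last"} (the last bin's probability).
#' @param floorProb probability for empty bins and the floor tail
#'   (default \code{2^-20}).
#' @return a \code{\linkS4class{GapSurprisalModel}}.
#' @export
gapSurprisalModel <- function(edges, probs, kind = "exon_length",
                              tailPolicy = "floor", floorProb = 2^-20) {
  new("GapSurprisalModel", kind = kind, edges = as.integer(edges),
      probs = as.numeric(probs), tailPolicy = tailPolicy,
      floorProb = floorProb)
}

#' Gap surprisal of a length
#'
#' Self-information of the bin containing \code{length}:
#' \eqn{-\log_2 P(\mathrm{bin}(L))} bits. Uncommon lengths fall in
#' low-probability bins and yield large surprisal terms, which reduce the
#' total exon information \eqn{R_{i,total}}.
#'
#' @param model a \code{\linkS4class{GapSurprisalModel}}.
#' @param length length (or distance) in nt, >= 1; vectorized.
#' @return surprisal in bits (>= 0).
#' @export
gapSurprisal <- function(model, length) {
  stopifnot(is(model, "GapSurprisalModel"))
  if (any(length < 1)) stop("length must be >= 1 nt")
  p <- vapply(length, function(L) {
    i <- which(L <= model@edges)[1]
    if (is.na(i)) {
      if (model@tailPolicy == "floor") model@floorProb
      else model@probs[length(model@probs)]
    } else {
      max(model@probs[i], model@floorProb * (model@probs[i] == 0))
    }
  }, 0)
  p[p == 0] <- model@floorProb
  -log2(p)
}

#' Default exon-length distribution
#'
#' A bundled synthetic stand-in for the genome-wide distribution of
#' constitutive exon lengths: a log-normal with median 120 nt
#' (\eqn{\sigma_{\log} = 0.6}) integrated over 16 log-spaced bins covering
#' 1--10,000 nt. Substitute an empirical table (via
#' \code{\link{readLengthDistribution}}) for production use.
#'
#' @return a \code{\linkS4class{GapSurprisalModel}}.
#' @export
defaultExonLengthModel <- function() {
  edges <- unique(as.integer(round(10^seq(0, 4, length.out = 17))))[-1]
  lower <- c(0L, edges[-length(edges)])
  p <- stats::plnorm(edges, meanlog = log(120), sdlog = 0.6) -
       stats::plnorm(lower, meanlog = log(120), sdlog = 0.6)
  p <- p / sum(p)
  gapSurprisalModel(edges, p, kind = "exon_length")
}

#' Default regulatory-distance distribution
#'
#' Distances from a regulatory element to the nearest natural splice site,
#' concentrated within 10 nt of the site with a monotonically increasing
#' penalty at larger distances (geometric decay over 8 bins to 500 nt).
#'
#' @return a \code{\linkS4class{GapSurprisalModel}}.
#' @export
defaultRegulatoryDistanceModel <- function() {
  edges <- c(10L, 20L, 40L, 80L, 160L, 250L, 400L, 500L)
  p <- 0.5^seq_along(edges)
  p <- p / sum(p)
  gapSurprisalModel(edges, p, kind = "regulatory_distance")
}

#' Total exon information for an acceptor/donor pair
#'
#' \eqn{R_{i,total} = R_{i,acceptor} + R_{i,donor} - GS(L)}, optionally plus
#' a regulatory term \eqn{R_{i,reg} - GS_2(d)} where \eqn{d} is the distance
#' from the regulatory site's zero point to the nearest of the two natural
#' splice-site zero points. When several regulatory sites of one factor are
#' supplied the strongest is used.
#'
#' The exon runs from the first exonic base after the acceptor zero point
#' (last intronic base) through the last exonic base before the donor zero
#' point (first intronic base), so its length is
#' \code{zeroCoord(donor) - zeroCoord(acceptor) - 1}.
#'
#' @param acceptor,donor \code{\linkS4class{ScoredSite}}s on the same
#'   strand, donor downstream of the acceptor.
#' @param gsModel exon-length \code{\linkS4class{GapSurprisalModel}}.
#' @param regulatory optional list with \code{sites} (list of
#'   \code{ScoredSite}s for one factor) and \code{distanceModel} (a
#'   regulatory-distance \code{GapSurprisalModel}).
#' @param isWildType flag the annotated exon.
#' @return an \code{\linkS4class{ExonCandidate}}.
#' @export
exonTotal <- function(acceptor, donor, gsModel, regulatory = NULL,
                      isWildType = FALSE) {
  stopifnot(is(acceptor, "ScoredSite"), is(donor, "ScoredSite"))
  if (acceptor@siteKind != "acceptor" || donor@siteKind != "donor")
    stop("exonTotal needs an acceptor site and a donor site")
  if (donor@zeroCoord <= acceptor@zeroCoord)
    stop("donor must lie downstream of the acceptor")
  len <- donor@zeroCoord - acceptor@zeroCoord - 1L
  gs <- gapSurprisal(gsModel, len)
  regTerm <- list()
  total <- acceptor@rI + donor@rI - gs
  if (!is.null(regulatory)) {
    sites <- regulatory$sites
    if (is(sites, "ScoredSite")) sites <- list(sites)
    best <- sites[[which.max(vapply(sites, function(s) s@rI, 0))]]
    dist <- min(abs(best@zeroCoord - acceptor@zeroCoord),
                abs(best@zeroCoord - donor@zeroCoord))
    gs2 <- gapSurprisal(regulatory$distanceModel, max(dist, 1L))
    regTerm <- list(factor = best@modelName, rI = best@rI,
                    distance = dist, surprisal = gs2)
    total <- total + best@rI - gs2
  }
  new("ExonCandidate", acceptor = acceptor, donor = donor,
      length = len, gapSurprisal = gs, regulatoryTerm = regTerm,
      rITotal = total, isWildType = isWildType)
}

#' @describeIn exonTotal total exon information of an ExonCandidate, bits
#' @param candidate an \code{\linkS4class{ExonCandidate}}.
#' @export
rITotal <- function(candidate) candidate@rITotal

setMethod("show", "ExonCandidate", function(object) {
  cat(sprintf(
    "ExonCandidate [%d, %d], length %d nt%s\n",
    object@acceptor@zeroCoord + 1L, object@donor@zeroCoord - 1L,
    object@length, if (object@isWildType) " (wild type)" else ""))
  cat(sprintf(
    "  acceptor %.2f + donor %.2f - gap surprisal %.2f%s = R_i,total %.2f bits\n",
    object@acceptor@rI, object@donor@rI, object@gapSurprisal,
    if (length(object@regulatoryTerm))
      sprintf(" + %s %.2f - %.2f", object@regulatoryTerm$factor,
              object@regulatoryTerm$rI, object@regulatoryTerm$surprisal)
    else "",
    object@rITotal))
})

#' Rank candidate isoforms for an exon before and after a variant
#'
#' Enumerates candidate exons from all acceptor/donor site pairs within the
#' analysis window around the affected exon (sites with
#' \eqn{R_i \ge riMin}, plus the annotated natural pair), computes
#' \eqn{R_{i,total}} for each pre- and post-variant, and ranks the
#' post-variant candidates by \eqn{R_{i,total}} (ties: shorter exon, then
#' lower coordinate). When the variant weakens a natural site of the exon by
#' at least \code{skipThresholdBits} (default 7.0 bits, i.e. at least
#' 128-fold), the exon-skipping isoform is inserted at the top of the
#' post-variant ranking; if no viable exon remains post-variant, skipping is
#' returned alone.
#'
#' @param reference the reference sequence.
#' @param v a \code{\linkS4class{VariantRecord}}.
#' @param models named list with elements \code{acceptor} and \code{donor}
#'   (\code{\linkS4class{InfoModel}}s).
#' @param exon list or one-row data.frame with \code{acceptorZero} and
#'   \code{donorZero}: the annotated natural pair of the affected exon.
#' @param gsModel exon-length \code{\linkS4class{GapSurprisalModel}}.
#' @param riMin minimum site strength for candidate sites (bits).
#' @param skipThresholdBits natural-site drop that triggers the skipping
#'   isoform (default 7.0).
#' @param windowNt how far beyond the annotated exon to search for
#'   candidate sites (default 54 nt each side).
#' @return data.frame of isoforms (pre and post), columns \code{phase},
#'   \code{isoform} (\code{wild_type}/\code{cryptic}/\code{skipping}),
#'   \code{acceptorZero}, \code{donorZero}, \code{length},
#'   \code{rIAcceptor}, \code{rIDonor}, \code{gapSurprisal},
#'   \code{rITotal}, \code{rank}.
#' @export
rankIsoforms <- function(reference, v, models, exon, gsModel,
                         riMin = 1.6, skipThresholdBits = 7.0,
                         windowNt = 54) {
  reference <- normalizeSequence(reference)
  accZ <- as.integer(exon$acceptorZero)
  donZ <- as.integer(exon$donorZero)
  app <- applyVariant(reference, v)
  lo <- max(1L, accZ - windowNt)
  hi <- min(nchar(reference), donZ + windowNt)

  candidates <- function(sequence, accZero, donZero, offset = 0L) {
    reg <- c(max(1L, lo + offset), min(nchar(sequence), hi + offset))
    acc <- scanSites(models$acceptor, sequence, minRi = riMin, region = reg)
    don <- scanSites(models$donor, sequence, minRi = riMin, region = reg)
    addNat <- function(df, model, z) {
      if (!is.na(z) && !z %in% df$zeroCoord) {
        s <- tryCatch(scoreSite(model, sequence, z), error = function(e) NULL)
        if (!is.null(s))
          df <- rbind(df, data.frame(
            zeroCoord = z, strand = "+", siteKind = model@siteKind,
            modelName = model@name, rI = s@rI, windowSeq = s@windowSeq,
            hasN = s@hasN, stringsAsFactors = FALSE))
      }
      df
    }
    acc <- addNat(acc, models$acceptor, accZero)
    don <- addNat(don, models$donor, donZero)
    out <- list()
    for (i in seq_len(nrow(acc))) for (j in seq_len(nrow(don))) {
      len <- don$zeroCoord[j] - acc$zeroCoord[i] - 1L
      if (len < 1L) next
      gs <- gapSurprisal(gsModel, len)
      out[[length(out) + 1L]] <- data.frame(
        acceptorZero = acc$zeroCoord[i], donorZero = don$zeroCoord[j],
        length = len, rIAcceptor = acc$rI[i], rIDonor = don$rI[j],
        gapSurprisal = gs,
        rITotal = acc$rI[i] + don$rI[j] - gs,
        stringsAsFactors = FALSE)
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }

  rankDf <- function(df, natAccZ, natDonZ, phase) {
    if (is.null(df)) return(NULL)
    df$isoform <- ifelse(df$acceptorZero == natAccZ &
                           df$donorZero == natDonZ, "wild_type", "cryptic")
    ord <- order(-df$rITotal, df$length, df$acceptorZero)
    df <- df[ord, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    df$phase <- phase
    df
  }

  pre <- rankDf(candidates(reference, accZ, donZ), accZ, donZ, "pre")

  accZPost <- mapCoord(app$coordMap, accZ)
  donZPost <- mapCoord(app$coordMap, donZ)
  post <- rankDf(candidates(app$sequence, accZPost, donZPost,
                            offset = nchar(app$sequence) - nchar(reference)),
                 accZPost, donZPost, "post")

  # natural-site drop decides whether skipping leads the post ranking
  natDrop <- 0
  for (side in list(c("acceptor", accZ, accZPost),
                    c("donor", donZ, donZPost))) {
    m <- models[[side[1]]]
    z0 <- as.integer(side[2]); z1 <- as.integer(side[3])
    preRI <- tryCatch(scoreSite(m, reference, z0)@rI, error = function(e) NA)
    postRI <- tryCatch(
      if (is.na(z1)) NA else scoreSite(m, app$sequence, z1)@rI,
      error = function(e) NA)
    if (!is.na(preRI) && !is.na(postRI))
      natDrop <- min(natDrop, postRI - preRI)
    else if (!is.na(preRI) && is.na(postRI))
      natDrop <- -Inf  # site deleted outright
  }

  skipRow <- data.frame(
    acceptorZero = NA_integer_, donorZero = NA_integer_,
    length = NA_integer_, rIAcceptor = NA_real_, rIDonor = NA_real_,
    gapSurprisal = NA_real_, rITotal = NA_real_, isoform = "skipping",
    rank = NA_integer_, phase = "post", stringsAsFactors = FALSE)

  if (is.null(post)) {
    skipRow$rank <- 1L
    post <- skipRow
  } else if (natDrop <= -skipThresholdBits) {
    skipRow$rank <- 1L
    post$rank <- post$rank + 1L
    post <- rbind(skipRow, post)
  }
  out <- rbind(pre, post)
  rownames(out) <- NULL
  out[, c("phase", "isoform", "acceptorZero", "donorZero", "length",
          "rIAcceptor", "rIDonor", "gapSurprisal", "rITotal", "rank")]
}

#' Scan for branch-point sites upstream of an acceptor
#'
#' Scores the branch-point model over the region upstream of the acceptor
#' and reports hits with \eqn{R_i \ge 0} within \code{searchNt} of the
#' acceptor zero point (never beyond \code{hardMaxNt}; the branch point is
#' typically within 40 nt of the 3' splice site but cases up to ~400 nt are
#' known). Hits whose windows overlap an annotated donor window are flagged
#' \code{contextOk = FALSE} -- motif look-alikes inside donor sites are a
#' known false-positive mode of branch-point prediction.
#'
#' @param bpsModel branch-point \code{\linkS4class{InfoModel}} (zero point
#'   at the branch adenosine).
#' @param sequence the sequence.
#' @param acceptorZero acceptor zero coordinate (last intronic base).
#' @param searchNt reported search range upstream of the acceptor (default
#'   100 nt), capped at \code{hardMaxNt}.
#' @param hardMaxNt absolute maximum distance (default 400 nt).
#' @param donorWindows optional data.frame of annotated donor windows with
#'   columns \code{start}, \code{end} (1-based inclusive).
#' @param minRi minimum reported strength (default 0 bits).
#' @return data.frame with \code{zeroCoord}, \code{rI},
#'   \code{distanceToAcceptor}, \code{contextOk}.
#' @export
findBranchpoints <- function(bpsModel, sequence, acceptorZero,
                             searchNt = 100L, hardMaxNt = 400L,
                             donorWindows = NULL, minRi = 0) {
  stopifnot(is(bpsModel, "InfoModel"))
  sequence <- normalizeSequence(sequence)
  acceptorZero <- as.integer(acceptorZero)
  span <- min(as.integer(searchNt), as.integer(hardMaxNt))
  lo <- max(1L, acceptorZero - span + bpsModel@offsetStart)
  hi <- min(nchar(sequence), acceptorZero)
  hits <- scanSites(bpsModel, sequence, minRi = minRi, region = c(lo, hi))
  if (nrow(hits) == 0)
    return(data.frame(zeroCoord = integer(), rI = numeric(),
                      distanceToAcceptor = integer(), contextOk = logical()))
  dist <- acceptorZero - hits$zeroCoord
  keep <- dist >= 0L & dist <= span
  hits <- hits[keep, , drop = FALSE]
  dist <- dist[keep]
  ctxOk <- rep(TRUE, nrow(hits))
  if (!is.null(donorWindows) && nrow(donorWindows) > 0) {
    ws <- hits$zeroCoord + bpsModel@offsetStart
    we <- hits$zeroCoord + bpsModel@offsetEnd
    for (k in seq_len(nrow(donorWindows)))
      ctxOk <- ctxOk & !(ws <= donorWindows$end[k] &
                           we >= donorWindows$start[k])
  }
  data.frame(zeroCoord = hits$zeroCoord, rI = hits$rI,
             distanceToAcceptor = as.integer(dist), contextOk = ctxOk)
}
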