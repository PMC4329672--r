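# Cryptic splice-site activation: event typing, activation calls,
# pipeline flagging, strength-differential statistics.

#' Type a cryptic splice-site activation event
#'
#' Classifies a (natural, cryptic) pair of site deltas into the three
#' activation modes:
#' \itemize{
#' \item Type 1: the cryptic site is strengthened or created
#'   (\eqn{\Delta R_i \ge} significance) while the natural site is intact
#'   (\eqn{|\Delta R_i| <} significance);
#' \item Type 2: one variant simultaneously weakens the natural site and
#'   strengthens/creates the cryptic site (shared footprint);
#' \item Type 3: the natural site is weakened and a pre-existing cryptic
#'   site (\eqn{R_{i,initial} \ge riMin}) is itself unchanged.
#' }
#' Every pair maps to exactly one of type1/type2/type3/none. When both
#' sites change but the variant's edited positions do not intersect both
#' windows (\code{sharedFootprint = FALSE}), the event is typed by the
#' natural-site rule (type 3) and the distant cryptic change should be
#' reported separately.
#'
#' @param natural,cryptic one-row data.frames from
#'   \code{\link{analyzeVariant}} (fields \code{siteKind}, \code{zeroCoord},
#'   \code{rIInitial}, \code{rIFinal}, \code{deltaRi}).
#' @param significanceBits threshold for calling a change (default 1.0).
#' @param riMin minimum functional strength (default 1.6 bits).
#' @param sharedFootprint whether the variant's edited positions intersect
#'   both site windows (default \code{TRUE}).
#' @return a \code{\linkS4class{CrypticEvent}}.
#' @export
classifyCrypticEvent <- function(natural, cryptic, significanceBits = 1.0,
                                 riMin = 1.6, sharedFootprint = TRUE) {
  natural <- as.data.frame(natural)[1, , drop = FALSE]
  cryptic <- as.data.frame(cryptic)[1, , drop = FALSE]
  if (natural$siteKind != cryptic$siteKind)
    stop("natural and cryptic deltas must have the same polarity (site kind)")
  natWeak <- natural$deltaRi <= -significanceBits
  natIntact <- abs(natural$deltaRi) < significanceBits
  cryUp <- cryptic$deltaRi >= significanceBits
  cryIntact <- abs(cryptic$deltaRi) < significanceBits
  cryPre <- cryptic$rIInitial >= riMin

  type <-
    if (cryUp && natIntact) "type1"
    else if (natWeak && cryUp && sharedFootprint) "type2"
    else if (natWeak && cryIntact && cryPre) "type3"
    else if (natWeak && cryUp) "type3"  # distant independent change
    else "none"

  new("CrypticEvent",
    eventType = type, natural = natural, cryptic = cryptic,
    distanceNt = as.integer(cryptic$zeroCoord - natural$zeroCoord),
    samePolarity = TRUE,
    competitionMargin = cryptic$rIFinal - natural$rIFinal)
}

setMethod("show", "CrypticEvent", function(object) {
  cat(sprintf(
    "CrypticEvent %s (%s): natural %.2f -> %.2f, cryptic %.2f -> %.2f bits\n",
    object@eventType, object@natural$siteKind,
    object@natural$rIInitial, object@natural$rIFinal,
    object@cryptic$rIInitial, object@cryptic$rIFinal))
  cat(sprintf("  distance %+d nt, competition margin %.2f bits\n",
              object@distanceNt, object@competitionMargin))
})

#' Predict whether a typed cryptic event is likely to be activated
#'
#' A cryptic site is called likely to be used when it is functional
#' (\eqn{R_{i,final} \ge riMin}) and comparable to or exceeding the
#' competing natural site (\eqn{R_{i,final}} within \code{slackBits} of the
#' natural site's final strength), unless it lies too far from the natural
#' site (distant sites, beyond \code{distanceCutoffNt}, are less likely to
#' be recognized).
#'
#' @param event a \code{\linkS4class{CrypticEvent}} with
#'   \code{eventType != "none"}.
#' @param slackBits how much weaker than the natural site a cryptic site may
#'   be and still count as comparable (default 1.0 bit).
#' @param riMin minimum functional strength (default 1.6 bits).
#' @param distanceCutoffNt distance beyond which activation is downgraded
#'   (default 400 nt).
#' @return list with \code{call} (\code{"likely"}/\code{"unlikely"}) and
#'   \code{rationale}.
#' @export
predictActivation <- function(event, slackBits = 1.0, riMin = 1.6,
                              distanceCutoffNt = 400L) {
  stopifnot(is(event, "CrypticEvent"))
  if (event@eventType == "none")
    stop("predictActivation requires a typed event")
  cryFinal <- event@cryptic$rIFinal
  natFinal <- event@natural$rIFinal
  if (cryFinal < riMin)
    return(list(call = "unlikely",
                rationale = sprintf(
                  "cryptic site below r_i_min (%.2f < %.2f bits)",
                  cryFinal, riMin)))
  if (cryFinal < natFinal - slackBits)
    return(list(call = "unlikely",
                rationale = sprintf(
                  "cryptic site %.2f bits weaker than the natural site (slack %.1f)",
                  natFinal - cryFinal, slackBits)))
  if (abs(event@distanceNt) > distanceCutoffNt)
    return(list(call = "unlikely",
                rationale = sprintf(
                  "cryptic site %d nt from the natural site (cutoff %d)",
                  abs(event@distanceNt), as.integer(distanceCutoffNt))))
  list(call = "likely",
       rationale = sprintf(
         "cryptic site functional and competitive (margin %+.2f bits, %d nt)",
         event@competitionMargin, event@distanceNt))
}

#' Flag and prioritize site deltas the way a genome pipeline does
#'
#' Retains deltas where \eqn{R_{i,initial}} or \eqn{R_{i,final}} is at least
#' 0 bits and \eqn{|\Delta R_i| \ge 1.0} bits, then prioritizes (1) weakened
#' natural sites, (2) cryptic sites passing \code{\link{predictActivation}}
#' against the nearest natural site of the same polarity, and (3)
#' strengthened natural sites (retained but unlikely to be deleterious).
#' Everything else is dropped with a reason code. The operation is
#' idempotent and order-independent.
#'
#' @param deltas data.frame from \code{\link{analyzeVariant}} (or the same
#'   columns); natural rows are identified by \code{isNatural}.
#' @param riMin,slackBits,distanceCutoffNt,significanceBits see
#'   \code{\link{predictActivation}} / \code{\link{analyzeVariant}}.
#' @return the input with added columns \code{flagged}, \code{priority}
#'   (1 best; NA when dropped) and \code{reason}.
#' @export
pipelineFlag <- function(deltas, riMin = 1.6, slackBits = 1.0,
                         distanceCutoffNt = 400L, significanceBits = 1.0) {
  n <- nrow(deltas)
  flagged <- logical(n)
  priority <- rep(NA_integer_, n)
  reason <- character(n)
  naturals <- deltas[deltas$isNatural, , drop = FALSE]

  neg <- deltas$rIInitial < 0 & deltas$rIFinal < 0
  insig <- !neg & abs(deltas$deltaRi) < significanceBits
  reason[neg] <- "negative_strength"
  reason[insig] <- "below_significance"

  natWeak <- !neg & !insig & deltas$isNatural & deltas$deltaRi < 0
  natUp <- !neg & !insig & deltas$isNatural & deltas$deltaRi >= 0
  flagged[natWeak] <- TRUE; priority[natWeak] <- 1L
  reason[natWeak] <- "natural_weakened"
  flagged[natUp] <- TRUE; priority[natUp] <- 3L
  reason[natUp] <- "natural_strengthened_low_priority"

  cryDown <- !neg & !insig & !deltas$isNatural & deltas$deltaRi < 0
  reason[cryDown] <- "cryptic_weakened"

  # only significant cryptic gains need the per-site activation assessment
  for (i in which(!neg & !insig & !deltas$isNatural & deltas$deltaRi >= 0)) {
    d <- deltas[i, ]
    sameKind <- naturals[naturals$siteKind == d$siteKind &
                           naturals$strand == d$strand, , drop = FALSE]
    if (nrow(sameKind) == 0) {
      reason[i] <- "no_natural_site_of_same_polarity"
      next
    }
    nearest <- sameKind[which.min(abs(sameKind$zeroCoord - d$zeroCoord)), ]
    ev <- classifyCrypticEvent(nearest, d,
                               significanceBits = significanceBits,
                               riMin = riMin)
    act <- if (ev@eventType == "none")
      list(call = "unlikely", rationale = "untyped event")
    else predictActivation(ev, slackBits = slackBits, riMin = riMin,
                           distanceCutoffNt = distanceCutoffNt)
    if (act$call == "likely") {
      flagged[i] <- TRUE; priority[i] <- 2L
      reason[i] <- "cryptic_activation_likely"
    } else {
      reason[i] <- paste0("activation_unlikely: ", act$rationale)
    }
  }
  deltas$flagged <- flagged
  deltas$priority <- priority
  deltas$reason <- reason
  deltas
}

#' Strength differentials of validated cryptic events, by type and location
#'
#' Arithmetic mean and sample standard deviation of the competition margin
#' (cryptic \eqn{R_{i,final}} minus natural \eqn{R_{i,final}}) per (event
#' type, location) stratum. Strata with fewer than 2 events report
#' \code{NA} for the SD; empty strata are omitted with a notice.
#'
#' @param events data.frame with columns \code{eventType}
#'   (\code{type1/type2/type3}), \code{location} (\code{intronic} /
#'   \code{exonic}) and \code{margin} (bits). A list of
#'   \code{\linkS4class{CrypticEvent}}s plus a \code{location} vector is
#'   also accepted.
#' @param location optional location labels when \code{events} is a list.
#' @return data.frame with \code{eventType}, \code{location}, \code{mean},
#'   \code{sd}, \code{n}.
#' @export
strengthDifferentialStats <- function(events, location = NULL) {
  if (is.list(events) && !is.data.frame(events)) {
    events <- data.frame(
      eventType = vapply(events, function(e) e@eventType, ""),
      location = location,
      margin = vapply(events, function(e) e@competitionMargin, 0),
      stringsAsFactors = FALSE)
  }
  need <- c("eventType", "location", "margin")
  if (!all(need %in% names(events)))
    stop("events need columns: ", paste(need, collapse = ", "))
  strata <- expand.grid(
    eventType = c("type1", "type2", "type3"),
    location = c("intronic", "exonic"),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(strata)), function(k) {
    sel <- events$eventType == strata$eventType[k] &
      events$location == strata$location[k]
    m <- events$margin[sel]
    if (!length(m)) return(NULL)
    data.frame(eventType = strata$eventType[k],
               location = strata$location[k],
               mean = mean(m),
               sd = if (length(m) > 1) stats::sd(m) else NA_real_,
               n = length(m), stringsAsFactors = FALSE)
  })
  empty <- vapply(rows, is.null, TRUE)
  if (any(empty))
    message(sum(empty), " empty stratum/strata omitted")
  out <- do.call(rbind, rows[!empty])
  rownames(out) <- NULL
  out
}
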