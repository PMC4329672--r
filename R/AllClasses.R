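#' @import methods
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

SITE_KINDS <- c("donor", "acceptor", "branchpoint", "regulatory")

#' InfoModel: an individual-information weight matrix
#'
#' An \code{InfoModel} holds the per-position, per-base weights (in bits) of
#' one binding-site model -- a donor, acceptor, branch-point or regulatory
#' ribl -- together with the window offsets relative to the model zero point
#' and summary statistics of the training set. The weight of base \eqn{b} at
#' position \eqn{l} is \eqn{2 + \log_2 f(b,l)} (with optional pseudocount),
#' so that the dot product with a one-hot encoded window gives the site's
#' individual information \eqn{R_i} in bits.
#'
#' For donor sites the zero point is the first intronic base and the default
#' window is [-3, +6]; for acceptors the zero point is the last intronic base
#' and the window is [-25, +2]. Position zero is a real position, not skipped.
#'
#' @slot name label, e.g. \code{"donor"}.
#' @slot siteKind one of \code{"donor"}, \code{"acceptor"},
#'   \code{"branchpoint"}, \code{"regulatory"}.
#' @slot offsetStart,offsetEnd inclusive window offsets relative to the zero
#'   point.
#' @slot weights 4 x L numeric matrix of weights in bits, rows A,C,G,T,
#'   columns named by offset.
#' @slot freqs 4 x L matrix of the base frequencies the weights derive from.
#' @slot nSites number of training sequences.
#' @slot rSequence average information of the training set, in bits.
#' @slot rSequenceSD standard deviation of training-set \eqn{R_i}, in bits.
#' @slot pseudocount pseudocount added per base when estimating frequencies.
#' @slot correctionApplied whether the small-sample correction was subtracted
#'   from \code{rSequence}.
#' @slot floorBits finite sentinel weight used for bases never observed when
#'   \code{pseudocount = 0}.
#' @export
setClass("InfoModel",
  representation(
    name = "character",
    siteKind = "character",
    offsetStart = "integer",
    offsetEnd = "integer",
    weights = "matrix",
    freqs = "matrix",
    nSites = "integer",
    rSequence = "numeric",
    rSequenceSD = "numeric",
    pseudocount = "numeric",
    correctionApplied = "logical",
    floorBits = "numeric"
  )
)

setValidity("InfoModel", function(object) {
  msgs <- character()
  L <- object@offsetEnd - object@offsetStart + 1L
  if (L < 1L) msgs <- c(msgs, "offsetEnd must be >= offsetStart")
  if (!identical(rownames(object@weights), DNA_BASES4))
    msgs <- c(msgs, "weights rows must be A, C, G, T")
  if (ncol(object@weights) != L)
    msgs <- c(msgs, sprintf("weights must have %d columns (window length)", L))
  if (!all(dim(object@freqs) == dim(object@weights)))
    msgs <- c(msgs, "freqs must have the same dimensions as weights")
  if (!object@siteKind %in% SITE_KINDS)
    msgs <- c(msgs, sprintf("siteKind must be one of: %s",
                            paste(SITE_KINDS, collapse = ", ")))
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    msgs <- c(msgs, "pseudocount must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

#' ScoredSite: a located, scored binding site
#'
#' A single placement of an \code{\linkS4class{InfoModel}} on a sequence:
#' the coordinate of the model zero point, the strand, the individual
#' information \eqn{R_i} and the per-position bit contributions (the
#' sequence-walker data). \code{r_i} always equals the sum of the
#' contributions.
#'
#' @slot modelName name of the scoring model.
#' @slot siteKind site kind of the scoring model.
#' @slot zeroCoord 1-based position of the model zero point in the scanned
#'   sequence (plus-strand coordinates, also for minus-strand sites).
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot rI individual information in bits.
#' @slot contributions per-position bit values, named by offset.
#' @slot windowSeq the window sequence as scored (reverse-complemented for
#'   minus-strand sites).
#' @slot hasN whether any window position was an ambiguous base (scored 0).
#' @export
setClass("ScoredSite",
  representation(
    modelName = "character",
    siteKind = "character",
    zeroCoord = "integer",
    strand = "character",
    rI = "numeric",
    contributions = "numeric",
    windowSeq = "character",
    hasN = "logical"
  )
)

setValidity("ScoredSite", function(object) {
  msgs <- character()
  if (!object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (nchar(object@windowSeq) != length(object@contributions))
    msgs <- c(msgs, "windowSeq length must equal number of contributions")
  if (abs(object@rI - sum(object@contributions)) > 1e-9)
    msgs <- c(msgs, "rI must equal the sum of contributions")
  if (length(msgs)) msgs else TRUE
})

#' VariantRecord: one sequence change
#'
#' A substitution, insertion, deletion or combined change in 1-based
#' genomic coordinates. \code{position} is the first affected reference
#' base; for a pure insertion it is the base after which the insertion
#' occurs and \code{refAllele} is empty. For a pure deletion
#' \code{altAllele} is empty. Records parsed from c./IVS notation keep the
#' original text and are resolved to genomic coordinates through an exon
#' table at parse time.
#'
#' @slot seqId reference sequence identifier.
#' @slot position 1-based position (see above).
#' @slot refAllele reference allele (may be empty for insertions).
#' @slot altAllele alternate allele (may be empty for deletions).
#' @slot notationSource one of \code{"genomic"}, \code{"cdna"}, \code{"ivs"}.
#' @slot originalText the text the record was parsed from.
#' @export
setClass("VariantRecord",
  representation(
    seqId = "character",
    position = "integer",
    refAllele = "character",
    altAllele = "character",
    notationSource = "character",
    originalText = "character"
  )
)

setValidity("VariantRecord", function(object) {
  msgs <- character()
  if (nchar(object@refAllele) == 0L && nchar(object@altAllele) == 0L)
    msgs <- c(msgs, "ref and alt alleles cannot both be empty")
  # position 0 is allowed only for an insertion before the first base
  if (object@position < 1L &&
      !(object@position == 0L && nchar(object@refAllele) == 0L))
    msgs <- c(msgs, "position must be >= 1")
  if (!object@notationSource %in% c("genomic", "cdna", "ivs"))
    msgs <- c(msgs, "notationSource must be genomic, cdna or ivs")
  # N in refAllele marks bases deferred to application (bare del / delins)
  if (grepl("[^ACGTN]", object@refAllele) || grepl("[^ACGT]", object@altAllele))
    msgs <- c(msgs, "alleles must contain only A, C, G, T")
  if (length(msgs)) msgs else TRUE
})

#' GapSurprisalModel: a binned length (or distance) distribution
#'
#' Self-information of exon lengths or regulatory-site distances: the gap
#' surprisal of a length L is \eqn{-\log_2 P(\mathrm{bin}(L))}. Bins are
#' right-closed intervals with upper edges \code{edges}; lengths beyond the
#' last edge are handled by \code{tailPolicy} (\code{"floor"}: the floor
#' probability; \code{"last"}: the last bin's probability).
#'
#' @slot kind \code{"exon_length"} or \code{"regulatory_distance"}.
#' @slot edges strictly increasing integer upper bin edges (nt).
#' @slot probs bin probabilities, non-negative, summing to 1.
#' @slot tailPolicy \code{"floor"} or \code{"last"}.
#' @slot floorProb probability assigned to empty bins / floor tail.
#' @export
setClass("GapSurprisalModel",
  representation(
    kind = "character",
    edges = "integer",
    probs = "numeric",
    tailPolicy = "character",
    floorProb = "numeric"
  )
)

setValidity("GapSurprisalModel", function(object) {
  msgs <- character()
  if (!object@kind %in% c("exon_length", "regulatory_distance"))
    msgs <- c(msgs, "kind must be exon_length or regulatory_distance")
  if (length(object@edges) != length(object@probs))
    msgs <- c(msgs, "edges and probs must have equal length")
  if (any(diff(object@edges) <= 0))
    msgs <- c(msgs, "edges must be strictly increasing")
  if (any(object@probs < 0))
    msgs <- c(msgs, "probabilities must be non-negative")
  if (abs(sum(object@probs) - 1) > 1e-9)
    msgs <- c(msgs, "probabilities must sum to 1 (tolerance 1e-9)")
  if (!object@tailPolicy %in% c("floor", "last"))
    msgs <- c(msgs, "tailPolicy must be 'floor' or 'last'")
  if (length(msgs)) msgs else TRUE
})

#' ExonCandidate: an acceptor/donor pair with total exon information
#'
#' Total exon information is
#' \eqn{R_{i,total} = R_{i,acceptor} + R_{i,donor} - GS(L)} with an optional
#' regulatory term \eqn{+ R_{i,reg} - GS_2(d)}. Exon length L runs from the
#' first exonic base after the acceptor zero point (last intronic base) to
#' the last exonic base before the donor zero point (first intronic base).
#'
#' @slot acceptor,donor the component \code{\linkS4class{ScoredSite}}s.
#' @slot length exon length in nt.
#' @slot gapSurprisal gap surprisal of the length, bits.
#' @slot regulatoryTerm list with elements \code{factor}, \code{rI},
#'   \code{distance}, \code{surprisal}, or empty list when absent.
#' @slot rITotal total exon information, bits.
#' @slot isWildType whether this is the annotated (wild-type) exon.
#' @export
setClass("ExonCandidate",
  representation(
    acceptor = "ScoredSite",
    donor = "ScoredSite",
    length = "integer",
    gapSurprisal = "numeric",
    regulatoryTerm = "list",
    rITotal = "numeric",
    isWildType = "logical"
  )
)

setValidity("ExonCandidate", function(object) {
  msgs <- character()
  if (object@length < 1L)
    msgs <- c(msgs, "exon length must be >= 1 nt")
  if (object@donor@zeroCoord <= object@acceptor@zeroCoord)
    msgs <- c(msgs, "donor must lie downstream of the acceptor")
  reg <- object@regulatoryTerm
  expected <- object@acceptor@rI + object@donor@rI - object@gapSurprisal
  if (length(reg)) expected <- expected + reg$rI - reg$surprisal
  if (abs(object@rITotal - expected) > 1e-9)
    msgs <- c(msgs, "rITotal inconsistent with its components")
  if (length(msgs)) msgs else TRUE
})

#' CrypticEvent: a typed cryptic splice-site activation event
#'
#' Pairs the variant-induced change at a natural site with the change at a
#' candidate cryptic site of the same polarity, typed per the three
#' activation modes: Type 1 (cryptic strengthened or created, natural
#' intact), Type 2 (one variant simultaneously weakens the natural site and
#' strengthens/creates the cryptic), Type 3 (natural weakened, pre-existing
#' cryptic unchanged).
#'
#' @slot eventType \code{"type1"}, \code{"type2"}, \code{"type3"} or
#'   \code{"none"}.
#' @slot natural,cryptic one-row site-delta data.frames (see
#'   \code{\link{analyzeVariant}}).
#' @slot distanceNt signed distance, cryptic zero minus natural zero.
#' @slot samePolarity whether both sites are the same kind.
#' @slot competitionMargin cryptic \eqn{R_{i,final}} minus natural
#'   \eqn{R_{i,final}}, bits.
#' @export
setClass("CrypticEvent",
  representation(
    eventType = "character",
    natural = "data.frame",
    cryptic = "data.frame",
    distanceNt = "integer",
    samePolarity = "logical",
    competitionMargin = "numeric"
  )
)

setValidity("CrypticEvent", function(object) {
  msgs <- character()
  if (!object@eventType %in% c("type1", "type2", "type3", "none"))
    msgs <- c(msgs, "eventType must be type1, type2, type3 or none")
  if (object@eventType != "none" && !object@samePolarity)
    msgs <- c(msgs, "typed events require matching site polarity")
  if (length(msgs)) msgs else TRUE
})

#' ToyGene: a synthetic gene with planted splice sites
#'
#' @slot sequence the gene sequence (character).
#' @slot exons data.frame of 1-based inclusive exon intervals
#'   (\code{start}, \code{end}).
#' @slot registry data.frame of planted features: \code{kind},
#'   \code{zeroCoord}, \code{target} (bits), \code{rI} (achieved, bits),
#'   \code{role} (\code{"natural"}, \code{"latent"}, \code{"decoy"},
#'   \code{"overlap_decoy"}).
#' @slot seed the seed the gene was generated from.
#' @export
setClass("ToyGene",
  representation(
    sequence = "character",
    exons = "data.frame",
    registry = "data.frame",
    seed = "integer"
  )
)

setValidity("ToyGene", function(object) {
  msgs <- character()
  n <- nchar(object@sequence)
  if (nrow(object@exons) &&
      (any(object@exons$start < 1) || any(object@exons$end > n)))
    msgs <- c(msgs, "exon annotations outside sequence")
  if (length(msgs)) msgs else TRUE
})
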