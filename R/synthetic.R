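# Synthetic data: generating frequency matrices, site samples, toy genes
# with planted (and latent) splice sites, and engineered variant panels
# with ground-truth labels.

# run code with a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Generating frequency matrices for synthetic splice-site models
#'
#' Frequency matrices emulating the canonical human donor (window [-3, +6],
#' zero = first intronic base; average information around 8 bits), acceptor
#' (window [-25, +2], zero = last intronic base; polypyrimidine tract and
#' invariant AG) and branch-point (window [-4, +2], zero = the branch
#' adenosine) motifs. These are synthetic stand-ins for genome-derived
#' models, used as generating truths for sampling and parameter-recovery
#' checks; any real matrix in the model format can be substituted.
#'
#' @return 4 x L numeric matrix, rows A, C, G, T, columns window offsets.
#' @export
donorFrequencyMatrix <- function() {
  m <- cbind(
    `-3` = c(0.33, 0.37, 0.17, 0.13),
    `-2` = c(0.61, 0.12, 0.14, 0.13),
    `-1` = c(0.09, 0.04, 0.80, 0.07),
    `0`  = c(0.001, 0.001, 0.997, 0.001),
    `1`  = c(0.001, 0.007, 0.002, 0.990),
    `2`  = c(0.60, 0.02, 0.35, 0.03),
    `3`  = c(0.70, 0.08, 0.12, 0.10),
    `4`  = c(0.07, 0.05, 0.82, 0.06),
    `5`  = c(0.16, 0.16, 0.21, 0.47),
    `6`  = c(0.26, 0.24, 0.25, 0.25))
  rownames(m) <- DNA_BASES4
  m
}

#' @rdname donorFrequencyMatrix
#' @export
acceptorFrequencyMatrix <- function() {
  tract <- c(0.12, 0.30, 0.13, 0.45)  # polypyrimidine tract
  m <- matrix(rep(tract, 21), nrow = 4,
              dimnames = list(DNA_BASES4, as.character(-25:-5)))
  tail <- cbind(
    `-4` = c(0.10, 0.35, 0.10, 0.45),
    `-3` = c(0.05, 0.65, 0.05, 0.25),
    `-2` = c(0.10, 0.40, 0.05, 0.45),
    `-1` = c(0.94, 0.02, 0.01, 0.03),
    `0`  = c(0.001, 0.001, 0.997, 0.001),
    `1`  = c(0.25, 0.12, 0.50, 0.13),
    `2`  = c(0.27, 0.23, 0.27, 0.23))
  rownames(tail) <- DNA_BASES4
  cbind(m, tail)
}

#' @rdname donorFrequencyMatrix
#' @export
branchpointFrequencyMatrix <- function() {
  m <- cbind(
    `-4` = c(0.10, 0.30, 0.10, 0.50),
    `-3` = c(0.55, 0.15, 0.15, 0.15),
    `-2` = c(0.05, 0.70, 0.05, 0.20),
    `-1` = c(0.05, 0.05, 0.05, 0.85),
    `0`  = c(0.95, 0.02, 0.02, 0.01),
    `1`  = c(0.40, 0.30, 0.10, 0.20),
    `2`  = c(0.10, 0.40, 0.10, 0.40))
  rownames(m) <- DNA_BASES4
  m
}

#' Default synthetic donor/acceptor/branch-point models
#'
#' \code{\link{infoModelFromFrequencies}} applied to the bundled generating
#' matrices.
#'
#' @return named list of \code{\linkS4class{InfoModel}}s (\code{donor},
#'   \code{acceptor}, \code{branchpoint}).
#' @export
defaultModels <- function() {
  list(
    donor = infoModelFromFrequencies(donorFrequencyMatrix(), -3L,
                                     name = "donor", siteKind = "donor"),
    acceptor = infoModelFromFrequencies(acceptorFrequencyMatrix(), -25L,
                                        name = "acceptor",
                                        siteKind = "acceptor"),
    branchpoint = infoModelFromFrequencies(branchpointFrequencyMatrix(), -4L,
                                           name = "branchpoint",
                                           siteKind = "branchpoint"))
}

#' Sample aligned binding-site sequences from a frequency matrix
#'
#' Draws \code{n} sequences with positions sampled independently from the
#' per-position base frequencies; reproducible for a given seed.
#'
#' @param freqs 4 x L frequency matrix (rows A, C, G, T; columns sum to 1).
#' @param n number of sequences.
#' @param seed RNG seed.
#' @return character vector of \code{n} sequences of length L.
#' @export
sampleSites <- function(freqs, n, seed = 1L) {
  freqs <- as.matrix(freqs)
  if (nrow(freqs) != 4L || any(freqs < 0) ||
      any(abs(colSums(freqs) - 1) > 1e-9))
    stop("freqs must be a 4 x L matrix with columns summing to 1")
  n <- as.integer(n)
  if (n == 0L) return(character(0))
  withSeed(seed, {
    L <- ncol(freqs)
    mat <- vapply(seq_len(L), function(l)
      sample(DNA_BASES4, n, replace = TRUE, prob = freqs[, l]),
      character(n))
    if (n == 1L) mat <- matrix(mat, nrow = 1L)
    apply(mat, 1, paste, collapse = "")
  })
}

randomBackground <- function(n, gcBias = 0) {
  p <- c(0.25 - gcBias / 2, 0.25 + gcBias / 2,
         0.25 + gcBias / 2, 0.25 - gcBias / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

replaceAt <- function(sequence, pos, replacement) {
  paste0(substr(sequence, 1, pos - 1L), replacement,
         substr(sequence, pos + nchar(replacement), nchar(sequence)))
}

# Greedy window design: start from the consensus and apply the single-base
# change that brings R_i closest to the target until within tol. Positions
# where the consensus base towers over the runner-up by more than
# protectGapBits (the invariant GT/AG cores) are kept consensus unless the
# target is unreachable otherwise.
plantWindow <- function(model, target, tol = 0.5, protectGapBits = 3,
                        freezeOffsets = integer()) {
  mx <- maxScore(model)
  if (target > mx + tol)
    stop(sprintf("target %.2f bits unreachable: model maximum is %.2f bits",
                 target, mx))
  w <- model@weights
  win <- strsplit(consensusSequence(model), "")[[1]]
  frozen <- as.integer(colnames(w)) %in% freezeOffsets
  gaps <- vapply(seq_along(win), function(l) {
    sw <- sort(w[, l], decreasing = TRUE)
    sw[1] - sw[2]
  }, 0)
  cur <- mx
  # maxStep spreads the degradation over many positions (one big hit would
  # leave long homogeneous stretches intact and shift-invariant)
  pass <- function(allowed, maxStep) {
    repeat {
      if (abs(cur - target) <= tol) return(TRUE)
      best <- NULL; bestDiff <- abs(cur - target)
      for (l in which(allowed)) for (b in DNA_BASES4) {
        if (b == win[l]) next
        step <- w[b, l] - w[win[l], l]
        if (step < -maxStep) next
        cand <- cur + step
        if (abs(cand - target) < bestDiff - 1e-12) {
          best <- c(l, b); bestDiff <- abs(cand - target)
        }
      }
      if (is.null(best)) return(FALSE)
      l <- as.integer(best[1]); b <- best[2]
      cur <<- cur - w[win[l], l] + w[b, l]
      win[l] <<- b
    }
  }
  ok <- pass(gaps <= protectGapBits & !frozen, 2.5)
  if (!ok) ok <- pass(gaps <= protectGapBits & !frozen, Inf)
  if (!ok) ok <- pass(!frozen, Inf)
  if (!ok)
    stop(sprintf("could not plant a window within %.1f bits of %.2f", tol,
                 target))
  list(window = paste(win, collapse = ""), rI = cur)
}

writeWindow <- function(sequence, model, zero, window) {
  replaceAt(sequence, zero + model@offsetStart, window)
}

#' Generate a toy gene with planted splice sites
#'
#' Builds a uniform-background gene with \code{nExons} exons, plants
#' acceptor/donor windows whose \eqn{R_i} lies within +/- 0.5 bits of the
#' requested targets, and (by default) plants three deliberate decoy
#' contexts that make the cryptic-activation effects of
#' \code{\link{makeVariantPanel}} constructible: a latent donor one
#' substitution away from a strong site, a pre-existing strong intronic
#' donor decoy, and a donor decoy overlapping the last donor's window.
#' Backgrounds are re-drawn (bounded attempts) if an accidental same-kind
#' site stronger than a planted natural site arises within 100 nt of it.
#'
#' @param nExons number of exons (default 4).
#' @param exonLengths,intronLengths integer vectors (recycled) of exon and
#'   intron lengths, nt.
#' @param siteStrengthTargets named numeric: target \eqn{R_i} in bits for
#'   \code{donor} and \code{acceptor} natural sites.
#' @param models named list with \code{donor} and \code{acceptor}
#'   \code{\linkS4class{InfoModel}}s (default \code{\link{defaultModels}}).
#' @param seed RNG seed.
#' @param flankNt flanking background on each side (default 150 nt).
#' @param gcBias background GC skew in [-0.5, 0.5]; 0 = uniform.
#' @param plantDecoys plant the three decoy contexts (default TRUE).
#' @param riMin functional threshold used when shaping the latent decoy.
#' @param maxAttempts background re-draws before giving up.
#' @return a \code{\linkS4class{ToyGene}}.
#' @export
makeToyGene <- function(nExons = 4L, exonLengths = c(120L, 110L, 130L, 100L),
                        intronLengths = 250L,
                        siteStrengthTargets = c(donor = 8, acceptor = 9.5),
                        models = defaultModels(), seed = 1L,
                        flankNt = 150L, gcBias = 0, plantDecoys = TRUE,
                        riMin = 1.6, maxAttempts = 20L) {
  nExons <- as.integer(nExons)
  stopifnot(nExons >= 2L)
  exonLengths <- as.integer(rep_len(exonLengths, nExons))
  intronLengths <- as.integer(rep_len(intronLengths, nExons - 1L))
  if (any(intronLengths < 60L))
    stop("introns must be at least 60 nt to hold the site windows")
  don <- models$donor; acc <- models$acceptor

  for (attempt in seq_len(maxAttempts)) {
    gene <- withSeed(seed * 1000L + attempt,
                     buildToyGeneOnce(nExons, exonLengths, intronLengths,
                                      siteStrengthTargets, don, acc,
                                      flankNt, gcBias, plantDecoys, riMin))
    if (noAccidentalSites(gene, don, acc, riMin)) {
      gene@seed <- as.integer(seed)
      return(gene)
    }
  }
  stop("could not generate a gene without accidental competing sites in ",
       maxAttempts, " attempts")
}

buildToyGeneOnce <- function(nExons, exonLengths, intronLengths, targets,
                             don, acc, flankNt, gcBias, plantDecoys, riMin) {
  total <- 2L * flankNt + sum(exonLengths) + sum(intronLengths)
  sequence <- randomBackground(total, gcBias)

  starts <- integer(nExons); ends <- integer(nExons)
  pos <- flankNt + 1L
  for (i in seq_len(nExons)) {
    starts[i] <- pos
    ends[i] <- pos + exonLengths[i] - 1L
    pos <- ends[i] + 1L + if (i < nExons) intronLengths[i] else 0L
  }

  reg <- list()
  addReg <- function(kind, zero, target, role)
    reg[[length(reg) + 1L]] <<- data.frame(
      kind = kind, zeroCoord = zero, target = target, rI = NA_real_,
      role = role, stringsAsFactors = FALSE)

  for (i in seq_len(nExons - 1L)) {      # donors: exon i / intron i boundary
    z <- ends[i] + 1L
    # the last donor hosts the overlapping type-2 decoy: keep +4/+5 (the
    # decoy's GT core) at consensus
    freeze <- if (plantDecoys && i == nExons - 1L) c(4L, 5L) else integer()
    pw <- plantWindow(don, targets[["donor"]], freezeOffsets = freeze)
    sequence <- writeWindow(sequence, don, z, pw$window)
    addReg("donor", z, targets[["donor"]], "natural")
  }
  for (i in seq.int(2L, nExons)) {       # acceptors: last intronic base
    z <- starts[i] - 1L
    pw <- plantWindow(acc, targets[["acceptor"]])
    sequence <- writeWindow(sequence, acc, z, pw$window)
    addReg("acceptor", z, targets[["acceptor"]], "natural")
  }

  donors <- vapply(reg, function(r) r$kind == "donor", TRUE)
  donorZeros <- vapply(reg[donors], function(r) r$zeroCoord, 0)

  if (plantDecoys && nExons >= 4L) {
    # latent donor: strong window broken at its most informative position;
    # one substitution restores it (Type 1 material), intron 2
    zLat <- ends[2] + 1L + 60L
    pw <- plantWindow(don, targets[["donor"]] - 0.5)
    win <- strsplit(pw$window, "")[[1]]
    drop <- pw$rI - riMin + 1.5   # required weakening to sit below riMin
    cand <- expand.grid(l = seq_along(win), b = DNA_BASES4,
                        stringsAsFactors = FALSE)
    cand$delta <- mapply(function(l, b)
      don@weights[b, l] - don@weights[win[l], l], cand$l, cand$b)
    ok <- cand[cand$delta <= -drop, , drop = FALSE]
    if (nrow(ok) == 0) stop("cannot shape a latent donor decoy")
    pick <- ok[which.max(ok$delta), ]      # smallest adequate weakening
    win[pick$l] <- pick$b
    sequence <- writeWindow(sequence, don, zLat, paste(win, collapse = ""))
    addReg("donor", zLat, pw$rI + pick$delta, "latent")

    # pre-existing strong donor decoy 50 nt into intron 1 (Type 3 material)
    zDec <- ends[1] + 1L + 50L
    pw <- plantWindow(don, targets[["donor"]] - 1)
    sequence <- writeWindow(sequence, don, zDec, pw$window)
    addReg("donor", zDec, targets[["donor"]] - 1, "decoy")

    # donor decoy overlapping the last natural donor, zero 4 nt downstream
    # (Type 2 material): its +2..+6 offsets lie outside the natural window
    zNat <- ends[nExons - 1L] + 1L
    zOv <- zNat + 4L
    consOv <- strsplit(consensusSequence(don), "")[[1]]
    offs <- as.integer(colnames(don@weights))
    for (k in seq_along(offs)) {
      p <- zOv + offs[k]
      if (p > zNat + don@offsetEnd)   # leave the natural window untouched
        sequence <- replaceAt(sequence, p, consOv[k])
    }
    addReg("donor", zOv, NA_real_, "overlap_decoy")
  }

  registry <- do.call(rbind, reg)
  sequence <- cleanupAccidentalSites(sequence, registry, don, acc)
  for (k in seq_len(nrow(registry))) {
    m <- if (registry$kind[k] == "donor") don else acc
    registry$rI[k] <- scoreSite(m, sequence, registry$zeroCoord[k])@rI
  }
  new("ToyGene", sequence = sequence,
      exons = data.frame(start = starts, end = ends),
      registry = registry, seed = 0L)
}

# 1-based inclusive windows of all registered sites
registeredWindows <- function(registry, don, acc) {
  m <- lapply(registry$kind, function(k) if (k == "donor") don else acc)
  data.frame(
    start = registry$zeroCoord +
      vapply(m, function(x) x@offsetStart, 0L),
    end = registry$zeroCoord + vapply(m, function(x) x@offsetEnd, 0L))
}

# accidental competing placements near the naturals: same-kind unregistered
# hits within 2 bits of a natural site and within 100 nt of it, excluding
# hits whose windows overlap a registered (deliberate) decoy context
accidentalHits <- function(sequence, registry, don, acc) {
  wins <- registeredWindows(registry, don, acc)
  nat <- registry[registry$role == "natural", , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(nat))) {
    m <- if (nat$kind[k] == "donor") don else acc
    z <- nat$zeroCoord[k]
    hits <- scanSites(m, sequence, minRi = nat$rI[k] - 2,
                      region = c(max(1L, z - 100L - modelWindowLength(m)),
                                 min(nchar(sequence),
                                     z + 100L + modelWindowLength(m))))
    hits <- hits[abs(hits$zeroCoord - z) <= 100L &
                   !hits$zeroCoord %in%
                     registry$zeroCoord[registry$kind == nat$kind[k]], ,
                 drop = FALSE]
    if (!nrow(hits)) next
    hs <- hits$zeroCoord + m@offsetStart
    he <- hits$zeroCoord + m@offsetEnd
    overlapsReg <- vapply(seq_len(nrow(hits)), function(i)
      any(hs[i] <= wins$end & he[i] >= wins$start), TRUE)
    hits <- hits[!overlapsReg, , drop = FALSE]
    if (nrow(hits)) out[[length(out) + 1L]] <- cbind(hits, kind = nat$kind[k])
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# destroy accidental placements by mutating one free position (outside every
# registered window) in the offending window to the score-minimizing base
cleanupAccidentalSites <- function(sequence, registry, don, acc,
                                   maxIter = 60L) {
  wins <- registeredWindows(registry, don, acc)
  for (iter in seq_len(maxIter)) {
    hits <- accidentalHits(sequence, registry, don, acc)
    if (is.null(hits)) return(sequence)
    hit <- hits[which.max(hits$rI), ]
    m <- if (hit$kind == "donor") don else acc
    offs <- as.integer(colnames(m@weights))
    poss <- hit$zeroCoord + offs
    free <- !vapply(poss, function(p)
      any(p >= wins$start & p <= wins$end), TRUE)
    if (!any(free)) return(sequence)  # resampling will handle it
    best <- NULL; bestScore <- Inf
    for (i in which(free)) {
      cur <- substr(sequence, poss[i], poss[i])
      for (b in setdiff(DNA_BASES4, cur)) {
        newScore <- hit$rI - m@weights[cur, i] + m@weights[b, i]
        if (newScore < bestScore) {
          bestScore <- newScore; best <- c(poss[i], b)
        }
      }
    }
    sequence <- replaceAt(sequence, as.integer(best[1]), best[2])
  }
  sequence
}

# TRUE when no unregistered same-kind placement within 100 nt of a natural
# site comes within 2 bits of that site's strength (deliberate decoy
# contexts excepted). Weak decoys are left in place on purpose: genomes are
# replete with them; only near-competitive accidental sites would make the
# planted ground truth ambiguous.
noAccidentalSites <- function(gene, don, acc, riMin = 1.6) {
  is.null(accidentalHits(gene@sequence, gene@registry, don, acc))
}

setMethod("show", "ToyGene", function(object) {
  cat(sprintf("ToyGene: %d nt, %d exons, %d registered sites (seed %d)\n",
              nchar(object@sequence), nrow(object@exons),
              nrow(object@registry), object@seed))
})

#' Engineer a labelled variant panel on a toy gene
#'
#' For each requested effect, searches the substitutions allowed by weight
#' arithmetic at the relevant planted context for one that achieves the
#' intended outcome, then verifies the label end-to-end with
#' \code{\link{evaluatePanel}}'s classification chain before accepting it.
#' Effects that cannot be realized on the gene are skipped with a notice.
#'
#' Effects and their planted contexts (see \code{\link{makeToyGene}}):
#' \describe{
#' \item{abolish_natural}{weakens a natural donor below \code{riMin} by
#'   at least 7 bits (label \code{abolished});}
#' \item{leaky_natural}{weakens a natural acceptor by 1--4 bits, staying
#'   above \code{riMin} (label \code{leaky});}
#' \item{neutral}{a background substitution changing no site with
#'   \eqn{R_i \ge 0} by 1 bit or more (label \code{neutral});}
#' \item{type1}{restores the latent donor decoy (cryptic created, natural
#'   intact);}
#' \item{type2}{a substitution in the shared footprint of the last natural
#'   donor and its overlapping decoy, weakening one and strengthening the
#'   other;}
#' \item{type3}{abolishes the first natural donor, exposing the
#'   pre-existing strong decoy.}
#' }
#'
#' @param gene a \code{\linkS4class{ToyGene}} built with
#'   \code{plantDecoys = TRUE}.
#' @param effects character vector of intended effects (default: all six).
#' @param models named list with \code{donor} and \code{acceptor} models.
#' @param seed RNG seed (neutral-position search order).
#' @param riMin,significanceBits thresholds used for engineering and
#'   verification.
#' @return data.frame: \code{effect}, \code{seqId}, \code{position},
#'   \code{ref}, \code{alt}, \code{variantText}, \code{targetKind},
#'   \code{naturalZero}, \code{crypticZero}, \code{label}.
#' @export
makeVariantPanel <- function(gene,
                             effects = c("abolish_natural", "leaky_natural",
                                         "neutral", "type1", "type2",
                                         "type3"),
                             models = defaultModels(), seed = 1L,
                             riMin = 1.6, significanceBits = 1.0) {
  stopifnot(is(gene, "ToyGene"))
  reg <- gene@registry
  seqn <- gene@sequence
  don <- models$donor; acc <- models$acceptor
  natOf <- function(kind) reg[reg$role == "natural" & reg$kind == kind, ]
  roleZero <- function(role) {
    r <- reg[reg$role == role, ]
    if (nrow(r)) r$zeroCoord[1] else NA_integer_
  }

  rows <- list()
  addRow <- function(effect, pos, alt, targetKind, natZero, cryZero, label) {
    ref <- substr(seqn, pos, pos)
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = effect, seqId = "toygene", position = as.integer(pos),
      ref = ref, alt = alt,
      variantText = sprintf("toygene:%d%s>%s", pos, ref, alt),
      targetKind = targetKind, naturalZero = as.integer(natZero),
      crypticZero = as.integer(cryZero), label = label,
      stringsAsFactors = FALSE)
  }

  # candidate substitutions over a model window, with their weight deltas
  windowCandidates <- function(model, zero) {
    offs <- as.integer(colnames(model@weights))
    out <- expand.grid(off = offs, alt = DNA_BASES4,
                       stringsAsFactors = FALSE)
    out$pos <- zero + out$off
    out$ref <- substring(seqn, out$pos, out$pos)
    out <- out[out$ref != out$alt, , drop = FALSE]
    out$delta <- mapply(function(off, ref, alt) {
      l <- match(off, offs)
      model@weights[alt, l] - model@weights[ref, l]
    }, out$off, out$ref, out$alt)
    out
  }

  verify <- function(pos, alt, expected, natZero, cryZero) {
    v <- variantRecord("toygene", pos, substr(seqn, pos, pos), alt)
    pred <- classifyPanelVariant(seqn, v, models, reg, riMin,
                                 significanceBits)
    identical(pred, expected)
  }

  tryEffect <- function(effect) {
    switch(effect,
      abolish_natural = {
        nat <- natOf("donor")
        nat <- nat[order(-nat$zeroCoord), ][2, ]  # middle donor (D2)
        cand <- windowCandidates(don, nat$zeroCoord)
        cand <- cand[cand$delta <= -7 &
                       nat$rI + cand$delta < riMin, , drop = FALSE]
        cand <- cand[order(cand$delta), , drop = FALSE]
        for (k in seq_len(nrow(cand)))
          if (verify(cand$pos[k], cand$alt[k], "abolished", NA, NA)) {
            addRow(effect, cand$pos[k], cand$alt[k], "donor",
                   nat$zeroCoord, NA, "abolished")
            return(TRUE)
          }
        FALSE
      },
      leaky_natural = {
        nat <- natOf("acceptor")[1, ]
        cand <- windowCandidates(acc, nat$zeroCoord)
        cand <- cand[cand$delta <= -significanceBits & cand$delta > -4 &
                       nat$rI + cand$delta >= riMin + 0.25, , drop = FALSE]
        cand <- cand[order(abs(cand$delta + 2.5)), , drop = FALSE]
        for (k in seq_len(nrow(cand)))
          if (verify(cand$pos[k], cand$alt[k], "leaky", NA, NA)) {
            addRow(effect, cand$pos[k], cand$alt[k], "acceptor",
                   nat$zeroCoord, NA, "leaky")
            return(TRUE)
          }
        FALSE
      },
      neutral = {
        # deep in the last intron, away from every registered window
        iv <- c(gene@exons$end[nrow(gene@exons) - 1L] + 60L,
                gene@exons$start[nrow(gene@exons)] - 60L)
        positions <- withSeed(seed, sample(seq.int(iv[1], iv[2])))
        for (pos in positions) {
          if (min(abs(pos - reg$zeroCoord)) < 40L) next
          for (alt in setdiff(DNA_BASES4, substr(seqn, pos, pos)))
            if (verify(pos, alt, "neutral", NA, NA)) {
              addRow(effect, pos, alt, "none", NA, NA, "neutral")
              return(TRUE)
            }
        }
        FALSE
      },
      type1 = {
        zLat <- roleZero("latent")
        if (is.na(zLat)) return(FALSE)
        cand <- windowCandidates(don, zLat)
        pre <- scoreSite(don, seqn, zLat)@rI
        cand <- cand[cand$delta >= significanceBits &
                       pre + cand$delta >= riMin, , drop = FALSE]
        cand <- cand[order(-cand$delta), , drop = FALSE]
        for (k in seq_len(nrow(cand)))
          if (verify(cand$pos[k], cand$alt[k], "type1", NA, zLat)) {
            addRow(effect, cand$pos[k], cand$alt[k], "donor",
                   nearestNatural(reg, "donor", zLat), zLat, "type1")
            return(TRUE)
          }
        FALSE
      },
      type2 = {
        zOv <- roleZero("overlap_decoy")
        if (is.na(zOv)) return(FALSE)
        zNat <- nearestNatural(reg, "donor", zOv)
        natPre <- scoreSite(don, seqn, zNat)@rI
        ovPre <- scoreSite(don, seqn, zOv)@rI
        cand <- windowCandidates(don, zNat)
        # restrict to the shared footprint of the two windows
        cand <- cand[cand$pos >= zOv + don@offsetStart &
                       cand$pos <= zNat + don@offsetEnd, , drop = FALSE]
        cand$ovDelta <- vapply(seq_len(nrow(cand)), function(k) {
          l <- match(cand$pos[k] - zOv, as.integer(colnames(don@weights)))
          don@weights[cand$alt[k], l] - don@weights[cand$ref[k], l]
        }, 0)
        cand <- cand[cand$delta <= -significanceBits &
                       cand$ovDelta >= significanceBits &
                       ovPre + cand$ovDelta >= riMin, , drop = FALSE]
        cand <- cand[order(cand$delta), , drop = FALSE]
        for (k in seq_len(nrow(cand)))
          if (verify(cand$pos[k], cand$alt[k], "type2", zNat, zOv)) {
            addRow(effect, cand$pos[k], cand$alt[k], "donor", zNat, zOv,
                   "type2")
            return(TRUE)
          }
        FALSE
      },
      type3 = {
        zDec <- roleZero("decoy")
        if (is.na(zDec)) return(FALSE)
        zNat <- nearestNatural(reg, "donor", zDec)
        natPre <- scoreSite(don, seqn, zNat)@rI
        cand <- windowCandidates(don, zNat)
        cand <- cand[cand$delta <= -7 &
                       natPre + cand$delta < riMin, , drop = FALSE]
        cand <- cand[order(cand$delta), , drop = FALSE]
        for (k in seq_len(nrow(cand)))
          if (verify(cand$pos[k], cand$alt[k], "type3", zNat, zDec)) {
            addRow(effect, cand$pos[k], cand$alt[k], "donor", zNat, zDec,
                   "type3")
            return(TRUE)
          }
        FALSE
      },
      stop("unknown effect: ", effect))
  }

  for (effect in effects)
    if (!tryEffect(effect))
      message("effect not achievable on this gene, skipped: ", effect)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

nearestNatural <- function(registry, kind, zero) {
  nat <- registry[registry$role == "natural" & registry$kind == kind, ]
  nat$zeroCoord[which.min(abs(nat$zeroCoord - zero))]
}

# One-variant classification chain shared by makeVariantPanel verification
# and evaluatePanel: label in {neutral, abolished, leaky, natural_strengthened,
# type1, type2, type3, cryptic_change}.
classifyPanelVariant <- function(reference, v, models, registry, riMin,
                                 significanceBits) {
  deltas <- suppressMessages(analyzeVariant(
    reference, v, models[c("donor", "acceptor")],
    naturalSites = registry[registry$role == "natural",
                            c("kind", "zeroCoord")] |>
      transform(strand = "+"),
    riMin = riMin, significanceBits = significanceBits))
  if (nrow(deltas) == 0) return("neutral")

  relevant <- deltas[(deltas$rIInitial >= 0 | deltas$rIFinal >= 0) &
                       abs(deltas$deltaRi) >= significanceBits, ,
                     drop = FALSE]
  if (nrow(relevant) == 0) return("neutral")

  cry <- relevant[!relevant$isNatural & relevant$deltaRi > 0 &
                    relevant$rIFinal >= riMin, , drop = FALSE]
  nat <- relevant[relevant$isNatural, , drop = FALSE]

  if (nrow(cry)) {
    cry <- cry[which.max(cry$rIFinal), ]
    natZ <- nearestNatural(registry, cry$siteKind, cry$zeroCoord)
    natRow <- nat[nat$siteKind == cry$siteKind & nat$zeroCoord == natZ, ,
                  drop = FALSE]
    if (nrow(natRow) == 0) {
      # natural site outside the variant window: score it directly
      m <- models[[cry$siteKind]]
      app <- applyVariant(reference, v)
      preRI <- scoreSite(m, reference, natZ)@rI
      postRI <- scoreSite(m, app$sequence, mapCoord(app$coordMap, natZ))@rI
      natRow <- data.frame(siteKind = cry$siteKind, zeroCoord = natZ,
                           rIInitial = preRI, rIFinal = postRI,
                           deltaRi = postRI - preRI)
    }
    shared <- abs(cry$zeroCoord - natRow$zeroCoord) <
      modelWindowLength(models[[cry$siteKind]])
    ev <- classifyCrypticEvent(natRow, cry,
                               significanceBits = significanceBits,
                               riMin = riMin, sharedFootprint = shared)
    if (ev@eventType != "none") return(ev@eventType)
  }

  if (nrow(nat)) {
    nat <- nat[which.min(nat$deltaRi), ]
    if (nat$deltaRi <= -significanceBits) {
      if (nat$rIFinal < riMin) {
        # abolished natural: an untouched pre-existing cryptic nearby that
        # is competitive with the original natural site (within 1.5 bits)
        # makes this a Type 3 activation; weak background decoys do not
        m <- models[[nat$siteKind]]
        near <- scanSites(m, reference,
                          minRi = max(riMin, nat$rIInitial - 1.5),
                          region = c(max(1L, nat$zeroCoord - 100L -
                                           modelWindowLength(m)),
                                     min(nchar(reference),
                                         nat$zeroCoord + 100L +
                                           modelWindowLength(m))))
        near <- near[abs(near$zeroCoord - nat$zeroCoord) <= 100L &
                       near$zeroCoord != nat$zeroCoord, , drop = FALSE]
        natZs <- registry$zeroCoord[registry$role == "natural" &
                                      registry$kind == nat$siteKind]
        near <- near[!near$zeroCoord %in% natZs, , drop = FALSE]
        touched <- near$zeroCoord %in% relevant$zeroCoord
        if (any(!touched)) return("type3")
        return("abolished")
      }
      return("leaky")
    }
    if (nat$deltaRi >= significanceBits) return("natural_strengthened")
  }
  "cryptic_change"
}

#' Run the end-to-end classification chain over a variant panel
#'
#' Applies each panel variant to the gene, analyzes it against the models,
#' and classifies the outcome (abolished / leaky / neutral / type1 / type2 /
#' type3), returning the predictions next to the planted labels.
#'
#' @param gene a \code{\linkS4class{ToyGene}}.
#' @param panel data.frame from \code{\link{makeVariantPanel}}.
#' @param models named list with \code{donor} and \code{acceptor} models.
#' @param riMin,significanceBits classification thresholds.
#' @return the panel with a \code{predicted} column and \code{agree}
#'   (logical).
#' @export
evaluatePanel <- function(gene, panel, models = defaultModels(),
                          riMin = 1.6, significanceBits = 1.0) {
  stopifnot(is(gene, "ToyGene"))
  panel$predicted <- vapply(seq_len(nrow(panel)), function(i) {
    v <- variantRecord(panel$seqId[i], panel$position[i], panel$ref[i],
                       panel$alt[i])
    classifyPanelVariant(gene@sequence, v, models, gene@registry,
                         riMin, significanceBits)
  }, "")
  panel$agree <- panel$predicted == panel$label
  panel
}
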