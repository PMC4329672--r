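test_that("gap surprisal is the self-information of the length bin", {
  gm <- gapSurprisalModel(edges = c(10, 20, 40), probs = c(1, 0, 0))
  expect_equal(gapSurprisal(gm, 5), 0)
  gm2 <- gapSurprisalModel(edges = c(10, 20, 40, 80),
                           probs = c(0.125, 0.5, 0.25, 0.125))
  expect_equal(gapSurprisal(gm2, 3), 3)        # -log2(1/8)
  expect_equal(gapSurprisal(gm2, 15), 1)
  # rarer bins always cost more than the modal bin
  expect_gt(gapSurprisal(gm2, 35), gapSurprisal(gm2, 15))
  # tail policies beyond the last edge
  expect_equal(gapSurprisal(gm2, 500), 20)     # floor 2^-20
  gmLast <- gapSurprisalModel(edges = c(10, 20, 40, 80),
                              probs = c(0.125, 0.5, 0.25, 0.125),
                              tailPolicy = "last")
  expect_equal(gapSurprisal(gmLast, 500), 3)
  expect_error(gapSurprisal(gm2, 0), ">= 1")
  expect_error(gapSurprisalModel(c(10, 20), c(0.6, 0.6)), "sum to 1")
})

test_that("default exon-length model is a proper distribution peaked near 120 nt", {
  gm <- defaultExonLengthModel()
  expect_equal(sum(gm@probs), 1, tolerance = 1e-12)
  lens <- c(10, 50, 120, 400, 3000, 9000)
  gs <- gapSurprisal(gm, lens)
  expect_true(all(gs >= 0))
  expect_equal(which.min(gapSurprisal(gm, c(10, 120, 5000))), 2L)
})

mkSite <- function(kind, zero, ri, L = 4L) {
  new("ScoredSite", modelName = kind, siteKind = kind,
      zeroCoord = as.integer(zero), strand = "+", rI = ri,
      contributions = c(ri, rep(0, L - 1L)), windowSeq = strrep("A", L),
      hasN = FALSE)
}

test_that("total exon information follows the stated algebra", {
  gm <- gapSurprisalModel(edges = c(50, 150, 500),
                          probs = c(0.25, 0.5, 0.25))
  acc <- mkSite("acceptor", 100, 10)
  don <- mkSite("donor", 220, 8)    # exon length 119 -> modal bin, 1 bit
  ec <- exonTotal(acc, don, gm)
  expect_equal(ec@length, 119L)
  expect_equal(ec@gapSurprisal, 1)
  expect_equal(rITotal(ec), 10 + 8 - 1)
  # zero surprisal: total = acceptor + donor
  gm0 <- gapSurprisalModel(edges = c(1000), probs = 1)
  expect_equal(rITotal(exonTotal(acc, don, gm0)), 18)
  expect_error(exonTotal(acc, mkSite("donor", 50, 8), gm), "downstream")
})

test_that("the regulatory term adds rI minus its distance surprisal", {
  gm <- gapSurprisalModel(edges = c(1000), probs = 1)
  dm <- defaultRegulatoryDistanceModel()
  acc <- mkSite("acceptor", 100, 10)
  don <- mkSite("donor", 220, 8)
  reg <- mkSite("regulatory", 108, 5)   # 8 nt from the acceptor (modal bin)
  s <- gapSurprisal(dm, 8)
  ec <- exonTotal(acc, don, gm, regulatory = list(sites = reg,
                                                  distanceModel = dm))
  expect_equal(rITotal(ec), 18 + 5 - s)
  # the strongest of several same-factor sites is used
  reg2 <- mkSite("regulatory", 109, 7)
  ec2 <- exonTotal(acc, don, gm,
                   regulatory = list(sites = list(reg, reg2),
                                     distanceModel = dm))
  expect_equal(ec2@regulatoryTerm$rI, 7)
  # the regulatory term never changes the component site strengths
  expect_equal(ec2@acceptor@rI, 10)
  expect_equal(ec2@donor@rI, 8)
  # monotone penalty: farther regulatory site, lower total
  regFar <- mkSite("regulatory", 100 - 300, 5)
  ecFar <- exonTotal(acc, don, gm,
                     regulatory = list(sites = regFar, distanceModel = dm))
  expect_lt(rITotal(ecFar), rITotal(ec))
})

test_that("rITotal decreases when length moves to a rarer bin", {
  gm <- gapSurprisalModel(edges = c(50, 150, 500, 5000),
                          probs = c(0.2, 0.6, 0.15, 0.05))
  acc <- mkSite("acceptor", 100, 10)
  totals <- vapply(c(120, 400, 3000), function(L)
    rITotal(exonTotal(acc, mkSite("donor", 100 + L + 1L, 8), gm)), 0)
  expect_true(all(diff(totals) < 0))
})

test_that("isoform ranking responds to natural-site loss", {
  ms <- defaultModels()
  g <- makeToyGene(models = ms, seed = 2)
  nat <- g@registry[g@registry$role == "natural", ]
  exon2 <- list(acceptorZero = nat$zeroCoord[nat$kind == "acceptor"][1],
                donorZero = nat$zeroCoord[nat$kind == "donor"][2])
  gm <- defaultExonLengthModel()
  # a no-op variant (ref == alt is not allowed; neutral deep-intron change)
  pos <- exon2$donorZero + 120L
  vNeutral <- variantRecord("g", pos, substr(g@sequence, pos, pos),
                            setdiff(c("A", "C", "G", "T"),
                                    substr(g@sequence, pos, pos))[1])
  iso <- rankIsoforms(g@sequence, vNeutral, ms, exon2, gm)
  pre <- iso[iso$phase == "pre", ]
  post <- iso[iso$phase == "post", ]
  expect_equal(pre$isoform[pre$rank == 1], "wild_type")
  expect_equal(post[, names(post) != "phase"],
               pre[, names(pre) != "phase"], ignore_attr = TRUE)
  # abolishing the donor inserts the skipping isoform at the top
  z <- exon2$donorZero
  vKill <- variantRecord("g", z, substr(g@sequence, z, z), "C")
  iso2 <- rankIsoforms(g@sequence, vKill, ms, exon2, gm)
  post2 <- iso2[iso2$phase == "post", ]
  expect_equal(post2$isoform[post2$rank == 1], "skipping")
  expect_equal(iso2[iso2$phase == "pre", "isoform"][1], "wild_type")
})

test_that("a planted strong cryptic exon outranks the weakened natural exon", {
  ms <- defaultModels()
  g <- makeToyGene(models = ms, seed = 2)
  nat <- g@registry[g@registry$role == "natural", ]
  accZ <- nat$zeroCoord[nat$kind == "acceptor"][1]
  donZ <- nat$zeroCoord[nat$kind == "donor"][2]
  gm <- defaultExonLengthModel()
  # plant a consensus donor 30 nt inside the exon, then weaken the natural
  # donor by ~3 bits: the cryptic exon pairs the same acceptor with a
  # stronger donor at a similar length
  don <- ms$donor
  zCry <- donZ - 30L
  seq2 <- paste0(substr(g@sequence, 1, zCry - 4L), consensusSequence(don),
                 substr(g@sequence, zCry + 7L, nchar(g@sequence)))
  cand <- expand.grid(off = -3:6, alt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  w <- modelWeights(don)
  pick <- NULL
  for (k in seq_len(nrow(cand))) {
    pos <- donZ + cand$off[k]
    ref <- substr(seq2, pos, pos)
    if (ref == cand$alt[k]) next
    d <- w[cand$alt[k], as.character(cand$off[k])] -
      w[ref, as.character(cand$off[k])]
    if (d < -2.5 && d > -4.5 && abs(pos - zCry) > 8) { pick <- k; break }
  }
  expect_false(is.null(pick))  # deterministic under the fixed models/seed
  pos <- donZ + cand$off[pick]
  v <- variantRecord("g", pos, substr(seq2, pos, pos), cand$alt[pick])
  iso <- rankIsoforms(seq2, v, ms, list(acceptorZero = accZ, donorZero = donZ),
                      gm, skipThresholdBits = 7)
  post <- iso[iso$phase == "post", ]
  top <- post[post$rank == 1, ]
  expect_equal(top$isoform, "cryptic")
  expect_equal(top$donorZero, zCry)
})

test_that("branch-point scan respects distance windows and donor context", {
  ms <- defaultModels()
  bps <- ms$branchpoint
  set.seed(53)
  bg <- randomSeq(700)
  accZ <- 650L
  cons <- consensusSequence(bps)
  # plant the consensus 30 nt upstream of the acceptor
  z30 <- accZ - 30L
  s <- paste0(substr(bg, 1, z30 - 5L), cons, substr(bg, z30 + 3L, nchar(bg)))
  hits <- findBranchpoints(bps, s, accZ)
  expect_true(z30 %in% hits$zeroCoord)
  h <- hits[hits$zeroCoord == z30, ]
  expect_equal(h$distanceToAcceptor, 30L)
  expect_true(h$contextOk)
  # a motif inside an annotated donor window is flagged contextOk = FALSE
  dw <- data.frame(start = z30 - 4L, end = z30 + 5L)
  hits2 <- findBranchpoints(bps, s, accZ, donorWindows = dw)
  expect_false(hits2$contextOk[hits2$zeroCoord == z30])
  # a motif 500 nt upstream is beyond the hard maximum
  z500 <- accZ - 500L
  s3 <- paste0(substr(bg, 1, z500 - 5L), cons,
               substr(bg, z500 + 3L, nchar(bg)))
  hits3 <- findBranchpoints(bps, s3, accZ, searchNt = 600, hardMaxNt = 400)
  expect_false(z500 %in% hits3$zeroCoord)
  expect_true(all(hits3$distanceToAcceptor <= 400))
})
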