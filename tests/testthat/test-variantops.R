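test_that("variant strings parse and round-trip through the canonical form", {
  v <- parseVariant("chrT:100A>G")
  expect_equal(v@position, 100L)
  expect_equal(v@refAllele, "A")
  expect_equal(v@altAllele, "G")
  for (txt in c("chrT:100A>G", "chrT:50_52delACG", "chrT:100_101insTT",
                "chrT:50_52delinsAA", "chrT:7delC")) {
    v <- parseVariant(txt)
    expect_identical(formatVariant(parseVariant(formatVariant(v))),
                     formatVariant(v))
  }
  expect_error(parseVariant("chrT:100A>"), "malformed")
  expect_error(parseVariant("100A>G"), "sequence id")
  expect_error(parseVariant("chrT:52_50del"), "before start")
  expect_error(parseVariant("chrT:100_105insTT"), "adjacent")
})

test_that("c. and IVS notation resolve through the exon table", {
  # two-exon transcript: exon 1 = 11..100, exon 2 = 201..300
  et <- data.frame(exon = 1:2, start = c(11L, 201L), end = c(100L, 300L),
                   strand = "+")
  expect_error(parseVariant("chrT:c.90+1G>T"), "exon table")
  # c.90 is the 90th transcript base = genomic 100 (end of exon 1);
  # c.90+1 is the first intronic base = genomic 101
  v <- parseVariant("chrT:c.90+1G>T", et)
  expect_equal(v@position, 101L)
  expect_equal(v@notationSource, "cdna")
  # c.91 is the first base of exon 2 = genomic 201; c.91-2 = 199
  expect_equal(parseVariant("chrT:c.91-2A>G", et)@position, 199L)
  # IVS1+5 = genomic 105; IVS1-1 = genomic 200
  expect_equal(parseVariant("chrT:IVS1+5T>C", et)@position, 105L)
  expect_equal(parseVariant("chrT:IVS1-1G>A", et)@position, 200L)
  expect_error(parseVariant("chrT:c.90+1G>T",
                            transform(et, strand = "-")), "plus-strand")
  expect_error(parseVariant("chrT:c.50+1A>G", et), "anchor")
})

test_that("applyVariant mutates and maps coordinates correctly", {
  ref <- "AACCGGTTAACCGGTTAACC"
  # substitution: identity map, one base changed
  sub <- applyVariant(ref, variantRecord("s", 5, "G", "T"))
  expect_equal(nchar(sub$sequence), nchar(ref))
  expect_equal(substr(sub$sequence, 5, 5), "T")
  expect_identical(sub$coordMap, 1:20)
  expect_equal(sum(strsplit(ref, "")[[1]] !=
                     strsplit(sub$sequence, "")[[1]]), 1L)
  # 3-nt deletion: length shrinks, downstream coordinates shift by -3
  del <- applyVariant(ref, variantRecord("s", 5, "GGT", ""))
  expect_equal(nchar(del$sequence), 17L)
  expect_true(all(is.na(del$coordMap[5:7])))
  expect_equal(del$coordMap[8:20], 5:17)
  # insertion after position 5
  ins <- applyVariant(ref, variantRecord("s", 5, "", "TTT"))
  expect_equal(nchar(ins$sequence), 23L)
  expect_equal(ins$coordMap[6:20], 9:23)
  expect_equal(substr(ins$sequence, 6, 8), "TTT")
  # ref mismatch names expected vs observed
  expect_error(applyVariant(ref, variantRecord("s", 5, "A", "T")),
               "expected 'A', sequence has 'G'")
})

test_that("composite delins matches a hand-built expected sequence", {
  ref <- paste0("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG",
                "TTTTTTTTTT", "ACGTACGTAC", "GTACGTACGT")
  v <- parseVariant("s:11_20delinsTG")
  out <- applyVariant(ref, v)
  expect_equal(out$sequence,
               paste0("AAAAAAAAAA", "TG", "GGGGGGGGGG",
                      "TTTTTTTTTT", "ACGTACGTAC", "GTACGTACGT"))
  expect_equal(out$coordMap[21], 13L)
})

test_that("deleting then re-inserting the deleted bases restores reference", {
  set.seed(31)
  ref <- randomSeq(60)
  v <- variantRecord("s", 20, substr(ref, 20, 24), "")
  mut <- applyVariant(ref, v)
  back <- applyVariant(mut$sequence, invertVariant(mut$v))
  expect_identical(back$sequence, ref)
})

test_that("fold change is the exponential affinity relation", {
  expect_equal(as.numeric(foldChange(-7)), 128)
  expect_equal(attr(foldChange(-7), "direction"), "reduction")
  expect_equal(ceiling(as.numeric(foldChange(9.1))), 549)
  expect_equal(as.numeric(foldChange(9.6 - 6.6)), 8)
  expect_gte(foldChange(-(9.1 - 5.6)), 11)
  expect_equal(as.numeric(foldChange(0)), 1)
  # multiplicativity for same-sign changes
  for (pair in list(c(-1.2, -3.4), c(0.5, 2.5), c(-7, -0.1)))
    expect_equal(as.numeric(foldChange(sum(pair))),
                 as.numeric(foldChange(pair[1])) *
                   as.numeric(foldChange(pair[2])))
})

test_that("residual strength is the bit ratio, undefined at non-positive", {
  expect_equal(residualStrength(5.4, -2.6), 67.5)
  expect_equal(residualStrength(8, 0), 100)
  expect_equal(residualStrength(5, -5), 50)
  out <- residualStrength(2, 5)  # initial would be -3
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
})

test_that("severity bins partition the line with boundaries to the less severe bin", {
  expect_equal(as.character(classifySMC(c(-7.5, -5, -2, -0.5))),
               c("deleterious", "probably_deleterious", "leaky", "benign"))
  expect_equal(as.character(classifySMC(c(-7, -4, -1))),
               c("probably_deleterious", "leaky", "benign"))
  grid <- seq(-12, 4, by = 0.125)
  bins <- classifySMC(grid)
  expect_false(anyNA(bins))          # total
  expect_true(all(table(bins) > 0))  # each bin reachable
  expect_error(classifySMC(NA_real_), "finite")
})

test_that("calcDeltaRi is the weight difference at the offset", {
  m <- toyModel()
  res <- calcDeltaRi(m, -1, "A", "G")
  expect_equal(res$deltaRi,
               modelWeights(m)["G", 1] - modelWeights(m)["A", 1])
  expect_equal(res$minFoldChange, 2^abs(res$deltaRi))
  expect_error(calcDeltaRi(m, 5, "A", "G"), "outside model window")
})

test_that("analyzeVariant categorizes natural and cryptic changes", {
  ms <- defaultModels()
  g <- makeToyGene(models = ms, seed = 3)
  nat <- g@registry[g@registry$role == "natural", ]
  natSites <- data.frame(kind = nat$kind, zeroCoord = nat$zeroCoord,
                         strand = "+")
  donorZ <- nat$zeroCoord[nat$kind == "donor"][1]
  # abolish the invariant GT: natural category abolished, large fold change
  v <- variantRecord("g", donorZ, substr(g@sequence, donorZ, donorZ), "C")
  d <- analyzeVariant(g@sequence, v, ms[c("donor", "acceptor")], natSites)
  natRow <- d[d$isNatural & d$zeroCoord == donorZ, ]
  expect_equal(nrow(natRow), 1L)
  expect_equal(natRow$category, "abolished")
  expect_equal(natRow$smcBin, "deleterious")
  expect_equal(natRow$minFoldChange, 2^abs(natRow$deltaRi))
  expect_equal(natRow$deltaRi, natRow$rIFinal - natRow$rIInitial)
  # ref = alt is rejected at the record level; a no-change position far from
  # any model window yields only unchanged categories
  bg <- which.max(vapply(seq_len(nchar(g@sequence)), function(p)
    min(abs(p - g@registry$zeroCoord)), 0))
  vN <- variantRecord("g", bg, substr(g@sequence, bg, bg),
                      setdiff(c("A", "C", "G", "T"),
                              substr(g@sequence, bg, bg))[1])
  dN <- analyzeVariant(g@sequence, vN, ms[c("donor", "acceptor")], natSites)
  expect_true(all(!dN$isNatural))
})

test_that("windows spanning a deletion are rescored, not masked", {
  ms <- defaultModels()
  g <- makeToyGene(models = ms, seed = 4)
  nat <- g@registry[g@registry$role == "natural", ]
  donorZ <- nat$zeroCoord[nat$kind == "donor"][1]
  natSites <- data.frame(kind = nat$kind, zeroCoord = nat$zeroCoord,
                         strand = "+")
  # delete the GT core: the donor window re-anchors and is rescored
  v <- variantRecord("g", donorZ, substr(g@sequence, donorZ, donorZ + 1L), "")
  d <- analyzeVariant(g@sequence, v, ms["donor"], natSites)
  natRow <- d[d$isNatural, ]
  expect_equal(nrow(natRow), 1L)
  expect_true(is.finite(natRow$rIFinal))
  expect_equal(natRow$category, "abolished")
})

test_that("applying a variant and its inverse restores all site scores", {
  ms <- defaultModels()
  g <- makeToyGene(models = ms, seed = 5)
  don <- ms$donor
  donorZ <- g@registry$zeroCoord[g@registry$kind == "donor" &
                                   g@registry$role == "natural"][1]
  v <- variantRecord("g", donorZ + 3L,
                     substr(g@sequence, donorZ + 3L, donorZ + 3L), "C")
  mut <- applyVariant(g@sequence, v)
  back <- applyVariant(mut$sequence, invertVariant(mut$v))
  expect_identical(back$sequence, g@sequence)
  expect_equal(rI(scoreSite(don, back$sequence, donorZ)),
               rI(scoreSite(don, g@sequence, donorZ)))
})

test_that("position spectrum correlates counts with information", {
  m <- defaultModels()$donor
  prof <- averageInformation(m)$profile
  offs <- as.integer(names(prof))
  # counts exactly proportional to the profile -> r = 1
  counts <- round(100 * prof / max(prof)) + 1L
  tab <- data.frame(offset = rep(offs, counts), deleterious = TRUE)
  ps <- positionSpectrum(tab, m)
  expect_equal(unname(ps$counts), unname(counts), ignore_attr = TRUE)
  expect_equal(ps$r, 1, tolerance = 0.02)
  # Poisson counts with rate proportional to the profile: strong correlation
  set.seed(41)
  lam <- 500 * pmax(prof, 0) / sum(pmax(prof, 0))
  sim <- stats::rpois(length(lam), lam)
  tab2 <- data.frame(offset = rep(offs, sim), deleterious = TRUE)
  expect_gte(positionSpectrum(tab2, m)$r, 0.8)
  # too few distinct positions -> undefined
  tab3 <- data.frame(offset = c(0L, 1L), deleterious = TRUE)
  expect_true(is.na(positionSpectrum(tab3, m)$r))
  expect_error(positionSpectrum(data.frame(offset = 99L, deleterious = TRUE),
                                m), "outside the model window")
})

test_that("concordance labelling follows the validation criteria", {
  rec <- data.frame(
    predicted = c("abolished", "abolished", "abolished", "leaky", "leaky",
                  "leaky", "strengthened", "cryptic", "cryptic", "cryptic",
                  "regulatory", "abolished"),
    observed_splicing_loss = c(TRUE, TRUE, FALSE, NA, NA, NA, NA, NA, NA,
                               NA, NA, TRUE),
    observed_residual_splicing = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
                                   NA, NA, NA, NA, NA, FALSE),
    rtpcr_heterozygote = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                           FALSE, FALSE, FALSE, FALSE, FALSE),
    stronger_cryptic_activated = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                                   FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    cryptic_observed = c(NA, NA, NA, NA, NA, NA, NA, TRUE, TRUE, FALSE, NA,
                         NA),
    cryptic_top_ranked = c(NA, NA, NA, NA, NA, NA, NA, TRUE, FALSE, NA, NA,
                           NA),
    wildtype_level = c(NA, NA, NA, NA, NA, NA, "normal", NA, NA, NA, NA, NA),
    binding_concordant = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, TRUE, NA),
    uninformative = c(rep(FALSE, 11), TRUE))
  res <- assessConcordance(rec)
  expect_equal(res$labels, c(
    "concordant",      # a: abolished, no residual
    "concordant",      # a: residual excused by RT-PCR heterozygote
    "discordant",      # a: residual splicing observed
    "concordant",      # b: leaky with residual splicing
    "concordant",      # b: excused by stronger cryptic
    "discordant",      # b: no residual splicing
    "concordant",      # c: strengthened, normal wild-type level
    "concordant",      # d: cryptic observed and top-ranked
    "partial",         # d: cryptic observed, not top-ranked
    "discordant",      # d: cryptic not observed
    "concordant",      # e: binding assay concordant
    "uninformative"))  # flagged out
  expect_equal(res$nInformative, 11L)
  expect_equal(res$nPartial, 1L)
  expect_equal(res$nConcordant, 8L)
  expect_equal(res$percentConcordant, 100 * 8 / 11)
})
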