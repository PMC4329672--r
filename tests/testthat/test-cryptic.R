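mkDelta <- function(kind, zero, ri0, ri1, natural = FALSE) {
  data.frame(modelName = kind, siteKind = kind, zeroCoord = as.integer(zero),
             zeroCoordPost = as.integer(zero), strand = "+",
             isNatural = natural, rIInitial = ri0, rIFinal = ri1,
             deltaRi = ri1 - ri0, minFoldChange = 2^abs(ri1 - ri0),
             foldDirection = if (ri1 < ri0) "reduction" else "increase",
             residualPct = NA_real_, category = "unchanged_above_min",
             smcBin = NA_character_, stringsAsFactors = FALSE)
}

test_that("cryptic events are typed per the three activation modes", {
  nat <- mkDelta("donor", 100, 9, 9, natural = TRUE)
  # Type 1: cryptic created from 0 to 6 bits, natural untouched
  ev1 <- classifyCrypticEvent(nat, mkDelta("donor", 160, 0, 6))
  expect_equal(ev1@eventType, "type1")
  expect_equal(ev1@distanceNt, 60L)
  expect_equal(ev1@competitionMargin, -3)
  # Type 2: one variant weakens the natural (9 -> 1) and strengthens the
  # overlapping cryptic (2 -> 8)
  ev2 <- classifyCrypticEvent(mkDelta("donor", 100, 9, 1, TRUE),
                              mkDelta("donor", 104, 2, 8),
                              sharedFootprint = TRUE)
  expect_equal(ev2@eventType, "type2")
  # Type 3: natural weakened, pre-existing 7-bit cryptic untouched
  ev3 <- classifyCrypticEvent(mkDelta("donor", 100, 9, 1, TRUE),
                              mkDelta("donor", 150, 7, 7))
  expect_equal(ev3@eventType, "type3")
  # distant independent change is typed by the natural-site rule
  evD <- classifyCrypticEvent(mkDelta("donor", 100, 9, 1, TRUE),
                              mkDelta("donor", 900, 2, 8),
                              sharedFootprint = FALSE)
  expect_equal(evD@eventType, "type3")
  expect_error(classifyCrypticEvent(nat, mkDelta("acceptor", 160, 0, 6)),
               "polarity")
})

test_that("event typing is a partition over delta combinations", {
  vals <- c(-8, -2, 0, 2, 8)
  for (nd in vals) for (cd in vals) for (c0 in c(0, 3)) {
    ev <- classifyCrypticEvent(mkDelta("donor", 100, 9, 9 + nd, TRUE),
                               mkDelta("donor", 150, c0, c0 + cd))
    expect_true(ev@eventType %in% c("type1", "type2", "type3", "none"))
  }
  # sub-significance drift on both sides is not an event
  ev0 <- classifyCrypticEvent(mkDelta("donor", 100, 9, 8.5, TRUE),
                              mkDelta("donor", 150, 3, 3.4))
  expect_equal(ev0@eventType, "none")
})

test_that("activation calls require strength, competitiveness and proximity", {
  natWeak <- mkDelta("donor", 100, 9, 1, TRUE)
  # cryptic 9.1 bits weaker than the natural site -> unlikely
  natStrong <- mkDelta("donor", 100, 12, 12, TRUE)
  evWeak <- classifyCrypticEvent(natStrong, mkDelta("donor", 150, 0, 2.9))
  act <- predictActivation(evWeak)
  expect_equal(act$call, "unlikely")
  expect_match(act$rationale, "weaker")
  # equal strength but 450 nt away -> unlikely at the 400 nt cutoff
  evFar <- classifyCrypticEvent(natWeak, mkDelta("donor", 550, 7, 7))
  expect_equal(predictActivation(evFar)$call, "unlikely")
  expect_match(predictActivation(evFar)$rationale, "nt from")
  expect_equal(predictActivation(evFar, distanceCutoffNt = 500)$call,
               "likely")
  # exceeds the natural site by 2 bits at 20 nt -> likely
  evNear <- classifyCrypticEvent(natWeak, mkDelta("donor", 120, 3, 3),
                                 riMin = 1.6)
  expect_equal(predictActivation(evNear)$call, "likely")
  # below riMin -> unlikely no matter the margin
  evLow <- classifyCrypticEvent(mkDelta("donor", 100, 2, 0.5, TRUE),
                                mkDelta("donor", 120, 2.0, 2.0))
  expect_equal(predictActivation(evLow, riMin = 2.4)$call, "unlikely")
  expect_match(predictActivation(evLow, riMin = 2.4)$rationale, "r_i_min")
})

test_that("activation is monotone in cryptic strength", {
  natWeak <- mkDelta("donor", 100, 9, 1, TRUE)
  calls <- vapply(seq(0, 12, by = 0.5), function(ri) {
    ev <- classifyCrypticEvent(natWeak, mkDelta("donor", 150, ri, ri))
    if (ev@eventType == "none") return("none")
    predictActivation(ev)$call
  }, "")
  likely <- calls == "likely"
  # once likely, always likely as cryptic strength grows
  if (any(likely))
    expect_true(all(likely[seq(which(likely)[1], length(likely))]))
  expect_true(any(likely))
})

test_that("pipeline flagging applies the information-change rules", {
  rows <- rbind(
    mkDelta("donor", 100, 9, 2, natural = TRUE),    # weakened natural
    mkDelta("donor", 300, 6, 8, natural = TRUE),    # strengthened natural
    mkDelta("donor", 140, 5, 5.5),                  # below 1-bit rule
    mkDelta("donor", 150, -6, -4),                  # both strengths < 0
    mkDelta("donor", 118, 2, 8),                    # activatable cryptic
    mkDelta("donor", 700, 2, 8))                    # distant cryptic
  out <- pipelineFlag(rows)
  expect_equal(out$flagged, c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$priority, c(1L, 3L, NA, NA, 2L, NA))
  expect_equal(out$reason[3], "below_significance")
  expect_equal(out$reason[4], "negative_strength")
  expect_match(out$reason[6], "activation_unlikely")
  # idempotent and order-independent
  again <- pipelineFlag(out[, seq_len(ncol(rows))])
  expect_equal(again$flagged, out$flagged)
  perm <- sample(nrow(rows))
  shuffled <- pipelineFlag(rows[perm, ])
  expect_equal(shuffled$flagged, out$flagged[perm])
})

test_that("planted qualifying events are recovered from a large neutral batch", {
  set.seed(61)
  n <- 10000
  ri0 <- runif(n, -5, 12)
  neutral <- mkDelta("donor", 100, 0, 0)[rep(1, n), ]
  neutral$zeroCoord <- sample.int(5000, n, replace = TRUE)
  neutral$rIInitial <- ri0
  neutral$rIFinal <- ri0 + runif(n, -0.9, 0.9)
  neutral$deltaRi <- neutral$rIFinal - neutral$rIInitial
  planted <- rbind(
    mkDelta("donor", 5100, 9, 1.5, natural = TRUE),
    mkDelta("donor", 5120, 3, 9),
    mkDelta("donor", 5130, 2, 7.5),
    mkDelta("acceptor", 6000, 10, 2, natural = TRUE),
    mkDelta("acceptor", 6040, 4, 9.5))
  out <- pipelineFlag(rbind(neutral, planted))
  expect_equal(sum(out$flagged), 5L)
  expect_true(all(out$flagged[(n + 1):(n + 5)]))
})

test_that("strength differentials reproduce mean and SD per stratum", {
  ev <- data.frame(eventType = c("type1", "type1", "type3", "type3",
                                 "type3", "type2"),
                   location = c("exonic", "exonic", "intronic", "intronic",
                                "intronic", "intronic"),
                   margin = c(2, 4, 6, 6, 6, 1))
  expect_message(res <- strengthDifferentialStats(ev), "omitted")
  t1 <- res[res$eventType == "type1" & res$location == "exonic", ]
  expect_equal(t1$mean, 3)
  expect_equal(t1$sd, sqrt(2))
  expect_equal(t1$n, 2L)
  t3 <- res[res$eventType == "type3" & res$location == "intronic", ]
  expect_equal(t3$sd, 0)   # equal margins
  # seeded margins at the published Type 3 intronic moments
  set.seed(71)
  sim <- data.frame(eventType = "type3", location = "intronic",
                    margin = rnorm(104, mean = 6.3, sd = 4.9))
  res2 <- suppressMessages(strengthDifferentialStats(sim))
  expect_lt(abs(res2$mean - 6.3), 1.0)
  expect_equal(res2$n, 104L)
})
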