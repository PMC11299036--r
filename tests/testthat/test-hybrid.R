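test_that("site-pattern counting matches hand-built tallies", {
  aln <- c(o  = "AAAAACGN",
           p1 = "AAACACGA",
           h  = "AACCACGA",
           p2 = "AACAACTA")
  roles <- list(outgroup = "o", p1 = "p1", hybrid = "h", p2 = "p2")
  spc <- countSitePatterns(aln, roles)
  # columns: AAAA, AAAA, AACC (AABB), ACCA (ABBA), AAAA, CCCC,
  #          GGGT (xP2), xxxN (skipped)
  cc <- spc@counts
  expect_equal(spc@nSkipped, 1)
  expect_equal(sum(cc), 7)
  expect_equal(unname(cc[["monomorphic"]]), 4)
  expect_equal(unname(cc[["ABBA"]]), 1)
  expect_equal(unname(cc[["AABB"]]), 1)
  expect_equal(unname(cc[["xP2"]]), 1)
  expect_equal(unname(cc[["other"]]), 0)

  # 4 identical sequences: everything monomorphic
  same <- setNames(rep("ACGTACGT", 4), c("o", "p1", "h", "p2"))
  cc2 <- countSitePatterns(same, roles)@counts
  expect_equal(unname(cc2[["monomorphic"]]), 8)
  expect_equal(sum(cc2), 8)

  expect_error(countSitePatterns(aln, list(outgroup = "o", p1 = "p1",
                                           hybrid = "h")), "p2")
  expect_error(hydeGammaTest(countSitePatterns(same, roles)), "degenerate")
})

test_that("gamma test hits the boundaries and is orientation-symmetric", {
  # hybrid identical to P1, P2 divergent -> gamma ~ 1
  set.seed(41)
  p1 <- paste0(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  p2 <- strsplit(p1, "")[[1]]
  flip <- sample(3000, 600)
  for (i in flip) p2[i] <- sample(setdiff(c("A", "C", "G", "T"), p2[i]), 1)
  p2 <- paste0(p2, collapse = "")
  o <- strsplit(p1, "")[[1]]
  oflip <- sample(3000, 600)
  for (i in oflip) o[i] <- sample(setdiff(c("A", "C", "G", "T"), o[i]), 1)
  o <- paste0(o, collapse = "")
  aln <- c(o = o, p1 = p1, h = p1, p2 = p2)
  res <- hydeGammaTest(countSitePatterns(
    aln, list(outgroup = "o", p1 = "p1", hybrid = "h", p2 = "p2")))
  expect_gte(res@gammaHat, 0.95)

  # swapping the parental roles maps gamma to 1 - gamma
  net <- quartetNetwork(0.3)
  sm <- simulateSupermatrix(net, 120, 400, seed = 42)
  r1 <- hydeGammaTest(countSitePatterns(sm, list(
    outgroup = c("out1", "sel1"), p1 = "A", hybrid = "B", p2 = "C")))
  r2 <- hydeGammaTest(countSitePatterns(sm, list(
    outgroup = c("out1", "sel1"), p1 = "C", hybrid = "B", p2 = "A")))
  expect_equal(r1@gammaHat, 1 - r2@gammaHat, tolerance = 1e-9)
})

test_that("gamma recovery and type-I behaviour at reduced scale", {
  # recovery: median error over datasets with gamma drawn in [0.1, 0.9]
  errs <- vapply(1:8, function(i) {
    g <- 0.1 + 0.8 * (i - 1) / 7
    sm <- simulateSupermatrix(quartetNetwork(g), 150, 400, seed = 500 + i)
    realized <- mean(attr(sm, "routing") == "parent1")
    r <- hydeGammaTest(countSitePatterns(sm, list(
      outgroup = c("out1", "sel1"), p1 = "A", hybrid = "B", p2 = "C")))
    abs(r@gammaHat - realized)
  }, 1)
  expect_lte(median(errs), 0.05)

  # tree-like data (gamma = 0): few false positives
  fp <- vapply(1:40, function(i) {
    sm <- simulateSupermatrix(quartetNetwork(0), 40, 300, seed = 900 + i)
    r <- hydeGammaTest(countSitePatterns(sm, list(
      outgroup = c("out1", "sel1"), p1 = "A", hybrid = "B", p2 = "C")))
    r@significant
  }, TRUE)
  expect_lte(mean(fp), 0.125)
})

test_that("D statistic arithmetic and jackknife calibration", {
  # constructed counts: 150 ABBA, 50 BABA columns (+ mono filler)
  abba <- c(o = "A", p1 = "A", h = "B", p2 = "B")
  baba <- c(o = "A", p1 = "B", h = "A", p2 = "B")
  mono <- c(o = "A", p1 = "A", h = "A", p2 = "A")
  cols <- cbind(matrix(rep(abba, 150), 4), matrix(rep(baba, 50), 4),
                matrix(rep(mono, 800), 4))
  cols[cols == "B"] <- "C"
  set.seed(1)
  cols <- cols[, sample(ncol(cols))]
  rownames(cols) <- c("o", "p1", "h", "p2")
  cols[cols == "A"] <- "A"
  roles <- list(outgroup = "o", p1 = "p1", hybrid = "h", p2 = "p2")
  d <- dStatistic(cols, roles, blockSize = 100)
  expect_equal(d$nABBA, 150)
  expect_equal(d$nBABA, 50)
  expect_equal(d$D, 0.5)

  # symmetric counts give D = 0
  cols0 <- cbind(matrix(rep(abba, 100), 4), matrix(rep(baba, 100), 4))
  cols0[cols0 == "B"] <- "G"
  rownames(cols0) <- c("o", "p1", "h", "p2")
  d0 <- dStatistic(cols0, roles, blockSize = 50)
  expect_equal(d0$D, 0)

  expect_error(dStatistic(matrix("A", 4, 10,
    dimnames = list(c("o", "p1", "h", "p2"), NULL)), roles),
    "informative")

  # no-flow simulations (H truly sister to P1): |Z| <= 2 in most replicates
  zs <- vapply(1:60, function(i) {
    sm <- simulateSupermatrix(quartetNetwork(1), 30, 300, seed = 2000 + i)
    dStatistic(sm, list(outgroup = "out1", p1 = "A", hybrid = "B",
                        p2 = "C"), blockSize = 300)$Z
  }, 1)
  expect_gte(mean(abs(zs) <= 2), 0.90)
})

test_that("individual bootstrap reuses counts and is reproducible", {
  net <- caseStudyNetwork()
  set.seed(55)
  trs <- paleohybrid:::.simulateMscNoSeed(net, 150)
  class(trs) <- "multiPhylo"
  trs <- scaleToSubstitutions(trs, 0.02)
  alns <- lapply(trs, function(t) paleohybrid:::.simAlignmentNoSeed(t, 500))
  sm <- concatenateAlignments(setNames(alns, sprintf("l%03d", 1:150)))
  spc <- countSitePatterns(sm, list(outgroup = c("out1", "sel1"),
                                    p1 = c("A1", "A2"),
                                    hybrid = c("B1", "B2", "B3"),
                                    p2 = c("C1", "C2")))
  b1 <- bootstrapHybridTest(spc, nReps = 100, seed = 8)
  b2 <- bootstrapHybridTest(spc, nReps = 100, seed = 8)
  expect_identical(b1@gammaSamples, b2@gammaSamples)
  expect_true(all(b1@gammaSamples >= 0 & b1@gammaSamples <= 1))
  expect_gte(b1@fractionSignificant, 0.9)  # strong signal at gamma 0.45

  expect_error(bootstrapHybridTest(spc, nReps = 0, seed = 1), "nReps")
})

test_that("triplet model probabilities are a simplex and the fit behaves", {
  for (g in seq(0, 1, by = 0.25))
    for (tA in c(0, 0.5, 2, 10))
      for (tC in c(0, 1, 5))
        expect_equal(sum(tripletModelProbs(g, tA, tC)), 1, tolerance = 1e-12)

  # boundary: every locus AB|C
  tc <- new("TripletCounts", nAB = 500, nAC = 0, nBC = 0,
            nUnclassified = 0, groups = c("A", "B", "C"))
  fit <- fitTripletNetwork(tc)
  expect_gte(fit@gammaHat, 0.999)

  # symmetric counts: flat likelihood, not identifiable
  tc0 <- new("TripletCounts", nAB = 100, nAC = 100, nBC = 100,
             nUnclassified = 0, groups = c("A", "B", "C"))
  expect_false(fitTripletNetwork(tc0)@identifiable)

  expect_error(fitTripletNetwork(new("TripletCounts", nAB = -1, nAC = 1,
                                     nBC = 1, nUnclassified = 0,
                                     groups = c("A", "B", "C"))),
               "negative")

  # orientation symmetry: swapping A and C maps gamma to 1 - gamma
  tc1 <- new("TripletCounts", nAB = 420, nAC = 120, nBC = 460,
             nUnclassified = 0, groups = c("A", "B", "C"))
  tc2 <- new("TripletCounts", nAB = 460, nAC = 120, nBC = 420,
             nUnclassified = 0, groups = c("C", "B", "A"))
  f1 <- fitTripletNetwork(tc1); f2 <- fitTripletNetwork(tc2)
  expect_equal(f1@gammaHat, 1 - f2@gammaHat, tolerance = 1e-6)
})

test_that("triplet fit recovers gamma from model draws", {
  set.seed(77)
  errs <- vapply(1:20, function(i) {
    g <- runif(1, 0.1, 0.9)
    p <- tripletModelProbs(g, 1, 1)
    n <- as.integer(rmultinom(1, 5000, p))
    tc <- new("TripletCounts", nAB = n[1], nBC = n[2], nAC = n[3],
              nUnclassified = 0, groups = c("A", "B", "C"))
    abs(fitTripletNetwork(tc)@gammaHat - g)
  }, 1)
  expect_lte(median(errs), 0.03)
})
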