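test_that("NG86 matches the hand-counted toy pairs", {
  # 4 identical AAA codons + one synonymous third-position change
  p <- codonPair(paste0(c(rep("AAA", 4), "AAG"), collapse = ""),
                 strrep("AAA", 5))
  e <- ng86Ks(p)
  expect_equal(e@sSites, 5 / 3, tolerance = 1e-12)
  expect_equal(e@ks, -0.75 * log(0.2), tolerance = 1e-12)
  expect_equal(round(e@ks, 4), 1.2071)
  expect_equal(e@ka, 0)

  # one nonsynonymous change instead
  p2 <- codonPair(paste0(c(rep("AAA", 4), "AAC"), collapse = ""),
                  strrep("AAA", 5))
  e2 <- ng86Ks(p2)
  expect_equal(e2@nSites, 40 / 3, tolerance = 1e-9)
  expect_equal(e2@ka, -0.75 * log(0.9), tolerance = 1e-12)
  expect_equal(round(e2@ka, 4), 0.079)
  expect_equal(e2@ks, 0)

  # identical sequences
  e3 <- ng86Ks(codonPair(strrep("GATTCA", 5), strrep("GATTCA", 5)))
  expect_equal(e3@ks, 0)
  expect_equal(e3@ka, 0)
})

test_that("NG86 equals the exhaustive-pathway oracle on random pairs", {
  set.seed(1234)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (i in 1:500) {
    c1 <- sample(sense, 30, replace = TRUE)
    c2 <- c1
    nmut <- sample(1:25, 1)
    pos <- sample(90, nmut)
    s2 <- strsplit(paste0(c2, collapse = ""), "")[[1]]
    for (p in pos) s2[p] <- sample(c("A", "C", "G", "T"), 1)
    s2 <- paste0(s2, collapse = "")
    # skip draws that created in-frame stops
    cods2 <- substring(s2, seq(1, 88, 3), seq(3, 90, 3))
    if (any(gc[cods2] == "*")) next
    s1 <- paste0(c1, collapse = "")
    mine <- ng86Ks(codonPair(s1, s2))
    orc <- oracleNg86(s1, s2)
    expect_equal(mine@sSites, orc$S, tolerance = 1e-12)
    expect_equal(mine@nSites, orc$N, tolerance = 1e-12)
    if (is.na(orc$ks)) expect_true(mine@saturated) else
      expect_equal(mine@ks, orc$ks, tolerance = 1e-12)
    if (!is.na(orc$ka)) expect_equal(mine@ka, orc$ka, tolerance = 1e-12)
    # symmetry
    rev <- ng86Ks(codonPair(s2, s1))
    if (!is.na(mine@ks)) expect_equal(rev@ks, mine@ks, tolerance = 1e-9)
  }
})

test_that("codon-aware pairwise alignment back-threads proteins onto codons", {
  cds <- randomCds(20, seed = 3)
  al <- codonAlignPair(cds, cds)
  expect_equal(al@identity, 1)
  expect_false(grepl("-", al@aln1))

  # a single-codon insertion produces one whole-codon gap
  ins <- paste0(substr(cds, 1, 30), "GGA", substr(cds, 31, 60))
  al2 <- codonAlignPair(ins, cds)
  expect_equal(nchar(al2@aln1), 63)
  expect_equal(vapply(seq(1, 63, 3), function(i) substr(al2@aln2, i, i + 2),
                      "")[11] == "---" ||
               grepl("---", al2@aln2), TRUE)
  expect_false(grepl("(^|[^-])-{1,2}([^-]|$)", al2@aln2))  # gaps in triplets

  expect_error(codonAlignPair(paste0("ATG", "TAA", "GGA"), cds,
                              id1 = "bad"), "stop codon")
})

test_that("the identity cutoff removes only high-identity pairs", {
  df <- data.frame(pair_id = c("a", "b", "c"), ks = c(0.1, 1.4, 3.2),
                   identity = c(0.95, 0.91, 0.85))
  out <- identityCutoffFilter(df, 0.90)
  expect_equal(out$pair_id, "c")
  expect_equal(attr(out, "removed"), 2)
  expect_true(all(out$identity <= 0.90))
  # survivors unchanged
  expect_equal(out$ks, 3.2)
  expect_error(identityCutoffFilter(df, 1.5), "threshold")
})

test_that("mixture peak fitting recovers single and double peaks", {
  set.seed(9)
  one <- rnorm(3000, 3.0, 0.3)
  m1 <- fitKsPeaks(one, seed = 1)
  expect_lt(abs(m1@labels[["Ks1"]] - 3.0), 0.05)

  two <- c(rnorm(2500, 1.5, 0.15), rnorm(2500, 3.0, 0.3))
  m2 <- fitKsPeaks(two, seed = 1)
  expect_gte(length(m2@means), 2)
  expect_lt(abs(m2@labels[["Ks1"]] - 3.0), 0.1)
  expect_lt(abs(m2@labels[["Ks2"]] - 1.5), 0.1)
  expect_equal(sum(m2@weights), 1, tolerance = 1e-6)

  expect_error(fitKsPeaks(rep(2, 100), seed = 1), "degenerate")
  expect_error(fitKsPeaks(rnorm(10, 2, 0.1), seed = 1), "too few")
})

test_that("rate calibration rescales by the reference mode", {
  set.seed(10)
  ref <- rnorm(2000, 2.0, 0.1)
  other <- rnorm(2000, 1.0, 0.1)
  out <- calibrateKs(list(ref = ref, other = other), "ref", 3.0)
  f <- attr(out, "factor")
  expect_equal(f, 3.0 / paleohybrid:::.densityMode(ref), tolerance = 1e-9)
  expect_equal(out$other, other * f)
  # reference mode maps exactly to the reference value
  expect_equal(paleohybrid:::.densityMode(ref) * f, 3.0, tolerance = 1e-9)
  # self-calibration with own mode is the identity
  md <- paleohybrid:::.densityMode(ref)
  self <- calibrateKs(list(ref = ref), "ref", md)
  expect_equal(self$ref, ref, tolerance = 1e-9)

  expect_error(calibrateKs(list(a = ref), "b", 1), "not among")
})

test_that("best-hit pairing picks top local-alignment scores with tie rule", {
  target <- Biostrings::AAStringSet(c(
    t1 = "MKLVVLLAIVSSA", t2 = "MGGTRRSSPPLLK", t3 = "MKLVVLAAIVSSA"))
  query <- Biostrings::AAStringSet(c(q1 = "MKLVVLLAIVSSA"))
  hits <- bestHitPairs(query, target)
  expect_equal(hits$target, "t1")
  expect_true(hits$reciprocal)

  # equal-scoring targets: lexicographically smaller id wins
  target2 <- Biostrings::AAStringSet(c(zz = "MKLVVLLAIVSSA",
                                       aa = "MKLVVLLAIVSSA"))
  hits2 <- bestHitPairs(query, target2)
  expect_equal(hits2$target, "aa")

  # score floor leaves queries unpaired
  query3 <- Biostrings::AAStringSet(c(q1 = "WWWWCCCHHH"))
  hits3 <- bestHitPairs(query3, target, minScore = 25)
  expect_equal(nrow(hits3), 0)
  expect_equal(attr(hits3, "unpaired"), "q1")

  expect_error(bestHitPairs(query, Biostrings::AAStringSet()), "empty")
})

test_that("contamination distorts the Ks mixture and the cutoff repairs it", {
  prs <- simulateParalogPairs(700, contaminationFraction = 0.3, seed = 77)
  tab <- ksTable(prs)
  # spurious low-Ks mass before filtering
  pre <- fitKsPeaks(tab$ks, kRange = 1:4, seed = 2)
  expect_true(min(pre@means) < 0.7)
  post_tab <- identityCutoffFilter(tab, 0.90)
  truth <- attr(prs, "truth")
  expect_equal(attr(post_tab, "removed"),
               sum(truth$class == "contaminant"))
  post <- fitKsPeaks(post_tab$ks, kRange = 1:4, seed = 2)
  expect_lt(abs(post@labels[["Ks1"]] - 3.0), 0.1)
  expect_lt(abs(post@labels[["Ks2"]] - 1.5), 0.1)
})
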