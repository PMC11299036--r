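test_that("strict-clock dating is exact on clock trees", {
  # depths in substitutions/site; root at 0.370 calibrated to 370 Ma
  tr <- parseNewick(paste0(
    "(((A:0.248,B:0.248):0.020,C:0.268):0.102,O:0.370);"))
  ch <- strictClockDates(tr, list(calibration(c("A", "B", "C", "O"), 370)))
  expect_equal(ch@rate, 0.001, tolerance = 1e-12)
  expect_equal(splitTime(ch, "A", "B"), 248, tolerance = 1e-9)
  expect_equal(splitTime(ch, c("A", "B"), "C"), 268, tolerance = 1e-9)
  expect_equal(splitTime(ch, "A", "O"), 370, tolerance = 1e-9)
  # ultrametric output
  d <- ape::node.depth.edgelength(ch@tree)
  expect_lt(diff(range(d[seq_along(ch@tree$tip.label)])), 1e-9)

  # star-like tree with equal tip branches
  star <- parseNewick("((a:0.1,b:0.1):0.1,(c:0.15,d:0.15):0.05);")
  ch2 <- strictClockDates(star, list(calibration(letters[1:4], 100)))
  expect_equal(splitTime(ch2, "a", "b"), 50, tolerance = 1e-9)
  expect_equal(splitTime(ch2, "c", "d"), 75, tolerance = 1e-9)

  # two mutually consistent calibrations reproduce both node ages
  ch3 <- strictClockDates(tr, list(
    calibration(c("A", "B", "C", "O"), 370),
    calibration(c("A", "B", "C"), 268)))
  expect_equal(splitTime(ch3, "A", "O"), 370, tolerance = 1e-9)
  expect_equal(splitTime(ch3, c("A", "B"), "C"), 268, tolerance = 1e-9)

  # calibration clade must be monophyletic
  expect_error(strictClockDates(tr, list(calibration(c("A", "C"), 100))),
               "monophyletic")
  zero <- parseNewick("((A:0,B:0):0,O:0);")
  expect_error(strictClockDates(zero, list(calibration(c("A", "B", "O"),
                                                       10))), "depth")
})

test_that("split times read MRCA ages from constructed chronograms", {
  tr <- parseNewick("(((A:0.1,B:0.1):0.1,C:0.2):0.1,O:0.3);")
  ch <- strictClockDates(tr, list(calibration(c("A", "B", "C", "O"), 300)))
  expect_equal(splitTime(ch, "A", "B"), 100, tolerance = 1e-9)
  expect_equal(splitTime(ch, "B", "C"), 200, tolerance = 1e-9)
  expect_equal(splitTime(ch, c("A", "B"), "O"), 300, tolerance = 1e-9)
  expect_error(splitTime(ch, "A", "zz"), "absent")
  expect_error(splitTime(ch, character(0), "A"), "nonempty")
})

test_that("the concordance diagnostic reproduces the published reading", {
  sch <- new("GroupScheme", outgroup = "O", focal = "B",
             parent1 = c("A1", "A2"), parent2 = c("C1", "C2"),
             other = character(0))
  mkChrono <- function(topology, tHyb, tPar) {
    # build a clock tree with the requested split depths (rate 0.001)
    r <- 0.001
    if (topology == "B_with_A") {
      txt <- sprintf(
        "(((B:%g,(A1:%g,A2:%g):%g):%g,(C1:%g,C2:%g):%g):%g,O:%g);",
        tHyb * r, 150 * r, 150 * r, (tHyb - 150) * r, (tPar - tHyb) * r,
        150 * r, 150 * r, (tPar - 150) * r, (370 - tPar) * r, 370 * r)
    } else {
      txt <- sprintf(
        "(((B:%g,(C1:%g,C2:%g):%g):%g,(A1:%g,A2:%g):%g):%g,O:%g);",
        tHyb * r, 150 * r, 150 * r, (tHyb - 150) * r, (tPar - tHyb) * r,
        150 * r, 150 * r, (tPar - 150) * r, (370 - tPar) * r, 370 * r)
    }
    strictClockDates(parseNewick(txt),
                     list(calibration(c("B", "A1", "A2", "C1", "C2", "O"),
                                      370)))
  }
  # the published ages: 267/268 parental, 247/248 hybrid splits
  chB <- mkChrono("B_with_A", 247, 267)
  chC <- mkChrono("B_with_C", 248, 268)
  rep1 <- hybridTimeConsistency(chB, chC, sch)
  expect_equal(verdict(rep1), "hybridization_consistent")
  st <- splitAges(rep1)
  expect_equal(unname(st["parentalSplitB"]), 267, tolerance = 1e-6)
  expect_equal(unname(st["parentalSplitC"]), 268, tolerance = 1e-6)
  expect_equal(unname(st["hybridSplitB"]), 247, tolerance = 1e-6)
  expect_equal(unname(st["hybridSplitC"]), 248, tolerance = 1e-6)
  expect_equal(rep1@hybridAgeDiff, 1, tolerance = 1e-6)

  # a clearly different parental split suggests ILS
  chC2 <- mkChrono("B_with_C", 248, 310)
  expect_equal(verdict(hybridTimeConsistency(chB, chC2, sch)),
               "ILS_suspected")

  # zero tolerance rejects any nonzero difference
  expect_false(verdict(hybridTimeConsistency(chB, chC, sch,
                                             tolerance = 0)) ==
                 "hybridization_consistent")
})

test_that("dating the conflicting gene sets of one case study is concordant", {
  cs <- buildCaseStudy(caseStudyConfig(seed = 19, nLoci = 90,
                                       sitesPerLocus = 600, nKsPairs = 0))
  sch <- cs$scheme
  dateSet <- function(cls) {
    ids <- names(cs$classes)[cs$classes == cls]
    sm <- concatenateAlignments(cs$loci[ids])
    tr <- rerootOutgroup(neighborJoining(jcDistanceMatrix(sm)), "out1")
    tr <- ape::drop.tip(tr, "out1")
    strictClockDates(tr, list(calibration(setdiff(tr$tip.label, "out1"),
                                          304)))
  }
  chB <- dateSet("parent1"); chC <- dateSet("parent2")
  rep <- hybridTimeConsistency(chB, chC, sch, tolerance = 0.05)
  st <- splitAges(rep)
  # both hybrid-split estimates close to each other relative to the true age
  expect_lte(abs(st[["hybridSplitB"]] - st[["hybridSplitC"]]) / 248, 0.10)
  expect_equal(verdict(rep), "hybridization_consistent")
})
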