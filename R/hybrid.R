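#' Tally quartet site patterns for the hybridization test
#'
#' Columns are classified over the ordered roles (outgroup, P1, hybrid,
#' P2) into collapsed classes: `monomorphic`; the three two-pair classes
#' `AABB` (outgroup pairs with P1, hybrid with P2), `ABBA` (P1 with
#' hybrid), `ABAB` (P1 with P2); singleton classes `xO`, `xP1`, `xH`,
#' `xP2` (exactly one role differs); and `other` (three or four states).
#' With several individuals per role, counts are summed over all
#' role-respecting individual quartets (`"all_quartets"`) or taken from
#' the first individual of each role (`"representative"`).  Columns with a
#' gap or ambiguity in any role are skipped.  Counts are also recorded per
#' contiguous site block (the alignment's `partition_map` genes when
#' present, otherwise `blockSize` columns) for block-jackknife standard
#' errors that respect the shared gene tree within a locus.
#'
#' @param alignment `DNAStringSet`, matrix or named character vector.
#' @param roleMap named list with character vectors `outgroup`, `p1`,
#'   `hybrid`, `p2` (sequence names).
#' @param policy `"all_quartets"` or `"representative"`.
#' @param blockSize fallback block length in columns when the alignment
#'   has no partition map.
#' @return a [SitePatternCounts-class].
#' @export
countSitePatterns <- function(alignment, roleMap,
                              policy = c("all_quartets", "representative"),
                              blockSize = 500) {
  policy <- match.arg(policy)
  m <- .alnMatrix(alignment)
  pm <- .partitionMap(alignment)
  roles <- c("outgroup", "p1", "hybrid", "p2")
  for (r in roles) {
    if (is.null(roleMap[[r]]) || length(roleMap[[r]]) == 0)
      stop("role '", r, "' has no sequence")
    if (!all(roleMap[[r]] %in% rownames(m)))
      stop("role '", r, "' names sequences absent from the alignment")
  }
  if (policy == "representative")
    roleMap <- lapply(roleMap[roles], function(x) x[1])
  quartets <- expand.grid(o = roleMap$outgroup, p1 = roleMap$p1,
                          h = roleMap$hybrid, p2 = roleMap$p2,
                          stringsAsFactors = FALSE)
  classes <- c("monomorphic", "AABB", "ABBA", "ABAB",
               "xO", "xP1", "xH", "xP2", "other")
  blocks <- if (!is.null(pm)) {
    rep.int(seq_len(nrow(pm)), pm$end - pm$start)
  } else {
    ceiling(seq_len(ncol(m)) / blockSize)
  }
  nb <- max(blocks)
  qbc <- array(0, dim = c(nrow(quartets), nb, length(classes)),
               dimnames = list(NULL, NULL, classes))
  nSkip <- 0
  acgt <- c("A", "C", "G", "T")
  for (qi in seq_len(nrow(quartets))) {
    o <- m[quartets$o[qi], ]; a <- m[quartets$p1[qi], ]
    h <- m[quartets$h[qi], ]; b <- m[quartets$p2[qi], ]
    use <- o %in% acgt & a %in% acgt & h %in% acgt & b %in% acgt
    nSkip <- nSkip + sum(!use)
    eq_oa <- o == a; eq_oh <- o == h; eq_ob <- o == b
    eq_ah <- a == h; eq_ab <- a == b; eq_hb <- h == b
    cls <- integer(length(o))  # 0 = unused
    cls[use & eq_oa & eq_oh & eq_ob] <- 1L
    cls[use & eq_oa & eq_hb & !eq_oh] <- 2L
    cls[use & eq_ob & eq_ah & !eq_oa] <- 3L
    cls[use & eq_oh & eq_ab & !eq_oa] <- 4L
    cls[use & eq_ah & eq_ab & !eq_oa] <- 5L
    cls[use & eq_oh & eq_ob & !eq_oa] <- 6L
    cls[use & eq_oa & eq_ob & !eq_oh] <- 7L
    cls[use & eq_oa & eq_oh & !eq_ob] <- 8L
    cls[use & cls == 0L] <- 9L
    tb <- table(factor(blocks[cls > 0], levels = seq_len(nb)),
                factor(cls[cls > 0], levels = 1:9))
    qbc[qi, , ] <- as.matrix(tb)
  }
  counts <- apply(qbc, 3, sum)
  names(counts) <- classes
  new("SitePatternCounts", counts = counts,
      nUsed = sum(counts), nSkipped = nSkip,
      quartetCounts = apply(qbc, c(1, 3), sum), quartetIndex = quartets,
      blockArray = qbc)
}

# jackknife-based intersection-union test on block x class count matrix
.iuTestFromBlocks <- function(blockCounts) {
  tot <- colSums(blockCounts)
  t1 <- tot[["ABBA"]] - tot[["ABAB"]]
  t2 <- tot[["AABB"]] - tot[["ABAB"]]
  nb <- nrow(blockCounts)
  if (nb < 2) return(list(t1 = t1, t2 = t2, se1 = NA_real_, se2 = NA_real_))
  l1 <- t1 - (blockCounts[, "ABBA"] - blockCounts[, "ABAB"])
  l2 <- t2 - (blockCounts[, "AABB"] - blockCounts[, "ABAB"])
  se1 <- sqrt((nb - 1) / nb * sum((l1 - mean(l1))^2))
  se2 <- sqrt((nb - 1) / nb * sum((l2 - mean(l2))^2))
  list(t1 = t1, t2 = t2, se1 = se1, se2 = se2)
}

#' Invariant-based hybridization test with gamma estimation
#'
#' Under the coalescent mixture model of hybrid origin (the hybrid lineage
#' traces to the P1 side with probability gamma, to the P2 side with
#' 1-gamma), each parental displayed tree contributes equally to its two
#' discordant two-pair site-pattern classes, so the excesses
#' `ABBA - ABAB` and `AABB - ABAB` are proportional to gamma and 1-gamma.
#' The estimator is `gamma_hat = (ABBA - ABAB) / (ABBA + AABB - 2 ABAB)`,
#' clamped to \[0,1\].  The tree null (gamma = 0 or 1) predicts one excess
#' to vanish; the test is intersection-union: Z is the smaller of the two
#' excesses standardized by their block-jackknife standard errors (blocks
#' respect loci, so the shared gene tree within a locus does not deflate
#' the variance), and the one-sided p-value is its upper normal tail.
#'
#' @param counts a [SitePatternCounts-class].
#' @param alpha significance level.
#' @return a [HybridTestResult-class].
#' @export
hydeGammaTest <- function(counts, alpha = 0.05) {
  stopifnot(is(counts, "SitePatternCounts"))
  cc <- counts@counts
  n_abba <- cc[["ABBA"]]; n_aabb <- cc[["AABB"]]; n_abab <- cc[["ABAB"]]
  if (n_abba + n_aabb + n_abab == 0)
    stop("degenerate counts: no two-pair site patterns")
  den <- n_abba + n_aabb - 2 * n_abab
  g <- if (den == 0) 0.5 else (n_abba - n_abab) / den
  g <- min(1, max(0, g))
  blockCounts <- apply(counts@blockArray, c(2, 3), sum)
  iu <- .iuTestFromBlocks(blockCounts)
  z1 <- if (is.na(iu$se1) || iu$se1 == 0)
    iu$t1 / sqrt(max(n_abba + n_abab, 1)) else iu$t1 / iu$se1
  z2 <- if (is.na(iu$se2) || iu$se2 == 0)
    iu$t2 / sqrt(max(n_aabb + n_abab, 1)) else iu$t2 / iu$se2
  z <- min(z1, z2)
  p <- stats::pnorm(z, lower.tail = FALSE)
  sig <- (p < alpha) && g > 0 && g < 1
  new("HybridTestResult", gammaHat = g, zScore = z, pValue = p,
      significant = sig, alpha = alpha)
}

#' ABBA-BABA D-statistic with block-jackknife Z
#'
#' For the quartet (((P1, H), P2), outgroup) with outgroup polarization:
#' ABBA columns have the derived allele shared by H and P2, BABA columns
#' shared by P1 and P2.  `D = (nABBA - nBABA) / (nABBA + nBABA)`; the Z
#' score uses the block-jackknife standard error over contiguous site
#' blocks.  Columns where the outgroup individuals disagree are skipped.
#'
#' @param alignment `DNAStringSet`, matrix or named character vector.
#' @param roleMap as in [countSitePatterns()].
#' @param blockSize contiguous sites per jackknife block (default 500).
#' @return list `D`, `Z`, `p` (two-sided), `nABBA`, `nBABA`, `nBlocks`.
#' @export
dStatistic <- function(alignment, roleMap, blockSize = 500) {
  m <- .alnMatrix(alignment)
  roles <- c("outgroup", "p1", "hybrid", "p2")
  for (r in roles)
    if (is.null(roleMap[[r]]) || !all(roleMap[[r]] %in% rownames(m)))
      stop("role '", r, "' missing or absent from the alignment")
  acgt <- c("A", "C", "G", "T")
  og <- m[roleMap$outgroup, , drop = FALSE]
  ogOK <- colSums(matrix(og %in% acgt, nrow(og))) == nrow(og) &
    apply(og, 2, function(x) length(unique(x)) == 1)
  o <- og[1, ]
  a <- m[roleMap$p1[1], ]; h <- m[roleMap$hybrid[1], ]; b <- m[roleMap$p2[1], ]
  use <- ogOK & a %in% acgt & h %in% acgt & b %in% acgt
  abba <- use & a == o & h == b & h != o
  baba <- use & h == o & a == b & a != o
  nA <- sum(abba); nB <- sum(baba)
  if (nA + nB == 0) stop("no informative (ABBA/BABA) sites")
  D <- (nA - nB) / (nA + nB)
  blocks <- ceiling(seq_along(o) / blockSize)
  nBlocks <- length(unique(blocks))
  if (nBlocks < 2) {
    warning("fewer than 2 jackknife blocks; Z unavailable")
    return(list(D = D, Z = NA_real_, p = NA_real_, nABBA = nA, nBABA = nB,
                nBlocks = nBlocks))
  }
  ba <- tapply(abba, blocks, sum); bb <- tapply(baba, blocks, sum)
  loo <- (nA - ba - (nB - bb)) / pmax(nA - ba + nB - bb, 1)
  mj <- mean(loo)
  vj <- (nBlocks - 1) / nBlocks * sum((loo - mj)^2)
  se <- sqrt(vj)
  Z <- if (se == 0) 0 else D / se
  list(D = D, Z = Z, p = 2 * stats::pnorm(abs(Z), lower.tail = FALSE),
       nABBA = nA, nBABA = nB, nBlocks = nBlocks)
}

#' Individual bootstrap of the hybridization test
#'
#' Individuals within each ingroup role (P1, hybrid, P2) are resampled
#' with replacement and the test rerun per replicate.  Because per-quartet
#' site-pattern counts are additive, each replicate reweights the stored
#' quartet-by-block count array of `counts` — no realignment or
#' recounting.
#'
#' @param counts a [SitePatternCounts-class] from [countSitePatterns()]
#'   with `policy = "all_quartets"`.
#' @param nReps number of replicates (>= 1).
#' @param seed mandatory RNG seed.
#' @param alpha significance level per replicate.
#' @return a [BootstrapResult-class].
#' @export
bootstrapHybridTest <- function(counts, nReps = 1000, seed, alpha = 0.05) {
  stopifnot(is(counts, "SitePatternCounts"))
  if (nReps < 1) stop("nReps must be >= 1")
  .assertSeed(seed)
  qi <- counts@quartetIndex
  ind <- lapply(c(p1 = "p1", h = "h", p2 = "p2"), function(r) unique(qi[[r]]))
  if (all(lengths(ind) == 1))
    warning("single individual per ingroup role: bootstrap is degenerate")
  qbc <- counts@blockArray
  nq <- dim(qbc)[1]
  flat <- matrix(qbc, nrow = nq)   # quartet x (block*class)
  nb <- dim(qbc)[2]; ncl <- dim(qbc)[3]
  gam <- numeric(nReps); sig <- logical(nReps)
  for (rp in seq_len(nReps)) {
    draw <- lapply(ind, function(x) sample(x, length(x), replace = TRUE))
    tb1 <- table(draw$p1); tb2 <- table(draw$h); tb3 <- table(draw$p2)
    m1 <- tb1[qi$p1]; m2 <- tb2[qi$h]; m3 <- tb3[qi$p2]
    m1[is.na(m1)] <- 0; m2[is.na(m2)] <- 0; m3[is.na(m3)] <- 0
    w <- as.numeric(m1) * as.numeric(m2) * as.numeric(m3)
    bc <- matrix(colSums(flat * w), nb, ncl,
                 dimnames = list(NULL, dimnames(qbc)[[3]]))
    tot <- colSums(bc)
    den <- tot[["ABBA"]] + tot[["AABB"]] - 2 * tot[["ABAB"]]
    g <- if (den == 0) 0.5 else (tot[["ABBA"]] - tot[["ABAB"]]) / den
    g <- min(1, max(0, g))
    iu <- .iuTestFromBlocks(bc)
    z <- min(iu$t1 / max(iu$se1, 1e-12), iu$t2 / max(iu$se2, 1e-12))
    p <- stats::pnorm(z, lower.tail = FALSE)
    gam[rp] <- g
    sig[rp] <- (p < alpha) && g > 0 && g < 1
  }
  new("BootstrapResult", gammaSamples = gam,
      fractionSignificant = mean(sig), gammaRange = range(gam))
}
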