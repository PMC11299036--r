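#' Simulate coding-sequence paralog pairs with a target Ks distribution
#'
#' Clean pairs: a random ancestor CDS receives a number of synonymous
#' single-nucleotide differences chosen so the Nei-Gojobori proportion of
#' synonymous differences matches the Jukes-Cantor expectation
#' `ps = (3/4)(1 - exp(-4 Ks/3))` for a Ks value drawn from the given
#' Gaussian mixture (plus a small nonsynonymous load, `kaKsRatio`), so the
#' realized estimator output is distributed around the drawn mixture value.
#' Contaminated pairs emulate redundant transcripts (splice forms, assembly
#' artifacts): a near-identical copy with 2-9.5% random differences, hence
#' nucleotide identity >= 0.90 by construction and a spurious low-Ks mass.
#'
#' @param nPairs number of pairs (0 returns an empty list).
#' @param ksMixture data.frame with columns `mean`, `sd`, `weight`.
#' @param contaminationFraction probability a pair is a redundant
#'   near-identical copy, in \[0,1\].
#' @param seed mandatory RNG seed.
#' @param nCodons codons per sequence.
#' @param kaKsRatio Ka drawn as this fraction of the pair's Ks.
#' @return list of [CodonPairAlignment-class]; attribute `"truth"` is a
#'   data.frame with `pair_id`, `class` (`clean`/`contaminant`) and
#'   `ks_true`.
#' @export
simulateParalogPairs <- function(nPairs, ksMixture = data.frame(
                                   mean = c(1.5, 3.0), sd = c(0.15, 0.3),
                                   weight = c(0.5, 0.5)),
                                 contaminationFraction = 0, seed,
                                 nCodons = 900, kaKsRatio = 0.05) {
  if (nPairs == 0) return(list())
  if (contaminationFraction < 0 || contaminationFraction > 1)
    stop("contaminationFraction must be in [0, 1]")
  if (any(ksMixture$mean <= 0) || any(ksMixture$sd <= 0) ||
      any(ksMixture$weight < 0) || sum(ksMixture$weight) <= 0)
    stop("invalid Ks mixture")
  .assertSeed(seed)
  tab <- .codonTables()
  # ancestors for clean pairs are drawn from codons offering site-preserving
  # synonymous and nonsynonymous changes, so ps and pn hit their targets
  pool <- tab$sense[vapply(tab$spSyn, length, 1L) > 0 &
                    vapply(tab$spNsyn, length, 1L) > 0]
  pairs <- vector("list", nPairs)
  truth <- data.frame(pair_id = character(nPairs), class = character(nPairs),
                      ks_true = numeric(nPairs))
  wts <- ksMixture$weight / sum(ksMixture$weight)
  for (i in seq_len(nPairs)) {
    contaminated <- stats::runif(1) < contaminationFraction
    if (contaminated) {
      anc <- sample(tab$sense, nCodons, replace = TRUE)
      der <- .mutateAnywhere(anc, round(stats::runif(1, 0.02, 0.095) *
                                          3 * nCodons), tab)
      ksTrue <- NA_real_
    } else {
      comp <- sample.int(nrow(ksMixture), 1, prob = wts)
      ksTrue <- max(0.05, min(4.2, stats::rnorm(1, ksMixture$mean[comp],
                                                ksMixture$sd[comp])))
      kaTrue <- kaKsRatio * ksTrue
      # ancestor drawn from codons with at least one synonymous option, so
      # synonymous capacity is ample
      anc <- sample(pool, nCodons, replace = TRUE)
      S <- sum(tab$S[anc])
      psT <- 0.75 * (1 - exp(-4 * ksTrue / 3))
      pnT <- 0.75 * (1 - exp(-4 * kaTrue / 3))
      kS <- min(round(psT * S), floor(0.745 * S))
      kN <- round(pnT * (3 * nCodons - S))
      if (kS + kN > nCodons)
        stop("nCodons too small for the requested divergence")
      idx <- sample.int(nCodons, kS + kN)
      der <- anc
      for (j in idx[seq_len(kS)]) {
        op <- tab$spSyn[[der[j]]]
        pick <- op[[sample.int(length(op), 1)]]
        cd <- der[j]; substr(cd, as.integer(pick["pos"]),
                             as.integer(pick["pos"])) <- pick["base"]
        der[j] <- cd
      }
      if (kN > 0) for (j in idx[kS + seq_len(kN)]) {
        op <- tab$spNsyn[[der[j]]]
        pick <- op[[sample.int(length(op), 1)]]
        cd <- der[j]; substr(cd, as.integer(pick["pos"]),
                             as.integer(pick["pos"])) <- pick["base"]
        der[j] <- cd
      }
    }
    id1 <- sprintf("pair%04d_a", i); id2 <- sprintf("pair%04d_b", i)
    pairs[[i]] <- codonPair(paste0(anc, collapse = ""),
                            paste0(der, collapse = ""), id1 = id1, id2 = id2)
    truth$pair_id[i] <- sprintf("pair%04d", i)
    truth$class[i] <- if (contaminated) "contaminant" else "clean"
    truth$ks_true[i] <- ksTrue
  }
  attr(pairs, "truth") <- truth
  pairs
}

# scatter n random non-stop single-base changes over a codon vector
.mutateAnywhere <- function(cods, n, tab) {
  bases <- c("A", "C", "G", "T")
  L <- length(cods)
  pos <- sample.int(3L * L, min(n, 3L * L))
  for (p in pos) {
    ci <- (p - 1L) %/% 3L + 1L
    off <- (p - 1L) %% 3L + 1L
    old <- substr(cods[ci], off, off)
    for (b in sample(setdiff(bases, old))) {
      cand <- cods[ci]
      substr(cand, off, off) <- b
      if (tab$geneticCode[cand] != "*") { cods[ci] <- cand; break }
    }
  }
  cods
}
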