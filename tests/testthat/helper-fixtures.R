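# shared fixtures and small independent oracles

# random gap-free DNA alignment as named character vector
randomAlignment <- function(nseq = 4, len = 100, seed = 1) {
  set.seed(seed)
  x <- vapply(seq_len(nseq), function(i)
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
  names(x) <- paste0("s", seq_len(nseq))
  x
}

# random sense-codon CDS string
randomCds <- function(nCodons = 30, seed = 1) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste0(sample(sense, nCodons, replace = TRUE), collapse = "")
}

# 4-taxon one-reticulation network used across hybrid tests:
# parental split at 13.4 CU, reticulation at 12.4 (tA = tC = 1.0)
quartetNetwork <- function(gamma = 0.4511) {
  speciesNetwork("(((A:13.4,C:13.4):1.8,sel1:15.2):3.3,out1:18.5);", "B",
                 parent1Clade = "A", parent2Clade = "C",
                 parent1Height = 12.4, parent2Height = 12.4, gamma = gamma)
}

quartetScheme <- function() {
  new("GroupScheme", outgroup = "out1", focal = "B", parent1 = "A",
      parent2 = "C", other = "sel1")
}

# simulate a concatenated alignment from a network (one individual/species)
simulateSupermatrix <- function(network, nLoci, sitesPerLocus, seed,
                                clockRate = 0.02) {
  set.seed(seed)
  trs <- paleohybrid:::.simulateMscNoSeed(network, nLoci)
  class(trs) <- "multiPhylo"
  trs <- scaleToSubstitutions(trs, clockRate)
  alns <- lapply(trs, function(t)
    paleohybrid:::.simAlignmentNoSeed(t, sitesPerLocus))
  names(alns) <- sprintf("locus%04d", seq_along(alns))
  structure(concatenateAlignments(alns), routing = attr(trs, "routing"))
}

# ---------------------------------------------------------------------------
# independent brute-force NG86 oracle: explicit per-codon site fractions and
# exhaustive pathway enumeration, sharing no code with the implementation
oracleNg86 <- function(s1, s2) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  codons2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  synFrac <- function(cod) {
    tot <- 0
    for (pos in 1:3) {
      syn <- 0; cnt <- 0
      for (b in setdiff(bases, substr(cod, pos, pos))) {
        mut <- cod
        substr(mut, pos, pos) <- b
        if (gc[[mut]] == "*") next
        cnt <- cnt + 1
        if (gc[[mut]] == gc[[cod]]) syn <- syn + 1
      }
      if (cnt > 0) tot <- tot + syn / cnt
    }
    tot
  }
  permsOf <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in permsOf(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (k in seq_along(codons1)) {
    c1 <- codons1[k]; c2 <- codons2[k]
    S <- S + (synFrac(c1) + synFrac(c2)) / 2
    dif <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(dif) == 0) next
    paths <- permsOf(dif)
    res <- NULL
    for (p in paths) {
      cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
      for (pos in p) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (gc[[nxt]] == "*") { blocked <- TRUE; nd <- nd + 1 }
        else if (!blocked && gc[[nxt]] == gc[[cur]]) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      res <- rbind(res, c(sd, nd, blocked))
    }
    ok <- res[, 3] == 0
    if (!any(ok)) ok <- rep(TRUE, nrow(res))
    Sd <- Sd + mean(res[ok, 1]); Nd <- Nd + mean(res[ok, 2])
  }
  N <- 3 * length(codons1) - S
  ps <- Sd / S; pn <- Nd / N
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       ks = if (ps >= 0.75) NA_real_ else -0.75 * log(1 - 4 * ps / 3),
       ka = if (pn >= 0.75) NA_real_ else -0.75 * log(1 - 4 * pn / 3))
}

# random resolved tree with given tip labels and exponential branch lengths
randomPhylo <- function(ntips, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntips)
  tr$tip.label <- paste0("t", seq_len(ntips))
  tr
}
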