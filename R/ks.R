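#' Construct a codon pair alignment from pre-aligned coding strings
#'
#' @param aln1,aln2 aligned coding strings (equal length, multiple of 3,
#'   gaps `-` in whole codons).
#' @param id1,id2 sequence identifiers.
#' @return a [CodonPairAlignment-class].
#' @export
codonPair <- function(aln1, aln2, id1 = "seq1", id2 = "seq2") {
  aln1 <- toupper(aln1); aln2 <- toupper(aln2)
  obj <- new("CodonPairAlignment", id1 = id1, id2 = id2,
             aln1 = aln1, aln2 = aln2,
             identity = .pairIdentity(aln1, aln2))
  validObject(obj)
  obj
}

# identity over ungapped nucleotide columns
.pairIdentity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  use <- x != "-" & y != "-"
  if (!any(use)) return(NA_real_)
  mean(x[use] == y[use])
}

.translateCds <- function(s, id = "sequence") {
  tab <- .codonTables()
  cods <- .toCodons(s)
  aa <- tab$geneticCode[cods]
  if (anyNA(aa)) stop("untranslatable codon in ", id, " at codon ",
                      which(is.na(aa))[1])
  internal <- which(aa == "*")
  internal <- internal[internal < length(aa)]
  if (length(internal))
    stop("internal stop codon in ", id, " at codon position ", internal[1])
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]  # trim terminal stop
  paste0(aa, collapse = "")
}

#' Protein-guided pairwise codon alignment
#'
#' Translates both coding sequences, aligns the proteins globally
#' (BLOSUM62) and back-threads the alignment onto codons, so gap columns
#' are whole codons.  Incomplete terminal codons and a terminal stop are
#' trimmed; an internal stop is an error naming its position.
#'
#' @param cds1,cds2 coding sequences (character or `DNAString(Set)`).
#' @param id1,id2 identifiers.
#' @return a [CodonPairAlignment-class].
#' @export
codonAlignPair <- function(cds1, cds2, id1 = "seq1", id2 = "seq2") {
  s1 <- toupper(as.character(cds1)); s2 <- toupper(as.character(cds2))
  s1 <- substr(s1, 1, 3 * (nchar(s1) %/% 3))
  s2 <- substr(s2, 1, 3 * (nchar(s2) %/% 3))
  p1 <- .translateCds(s1, id1); p2 <- .translateCds(s2, id2)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  a1 <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  cods1 <- .toCodons(s1); cods2 <- .toCodons(s2)
  i1 <- i2 <- 0L
  out1 <- out2 <- character(length(a1))
  for (k in seq_along(a1)) {
    if (a1[k] == "-") out1[k] <- "---" else { i1 <- i1 + 1L; out1[k] <- cods1[i1] }
    if (a2[k] == "-") out2[k] <- "---" else { i2 <- i2 + 1L; out2[k] <- cods2[i2] }
  }
  codonPair(paste0(out1, collapse = ""), paste0(out2, collapse = ""),
            id1 = id1, id2 = id2)
}

#' Nei-Gojobori (1986) synonymous and nonsynonymous divergence
#'
#' Fractional synonymous sites per codon come from the fraction of
#' synonymous single-nucleotide changes per position (changes into stop
#' codons are not countable); observed differences in multi-hit codons are
#' averaged over all minimal stop-free mutational pathways with equal
#' weights.  Proportions are Jukes-Cantor corrected:
#' `Ks = -(3/4) log(1 - (4/3) ps)` and likewise Ka.  `ps >= 3/4` (or
#' `pn >= 3/4`) sets the saturated flag and `NA` for the affected rate.
#'
#' @param pair a [CodonPairAlignment-class] (see [codonAlignPair()]).
#' @return a [KsEstimate-class].
#' @export
ng86Ks <- function(pair) {
  stopifnot(is(pair, "CodonPairAlignment"))
  tab <- .codonTables()
  c1 <- .toCodons(pair@aln1); c2 <- .toCodons(pair@aln2)
  keep <- !grepl("-", c1, fixed = TRUE) & !grepl("-", c2, fixed = TRUE)
  c1 <- c1[keep]; c2 <- c2[keep]
  known <- c1 %in% tab$sense & c2 %in% tab$sense
  bad1 <- which(!c1 %in% tab$sense & c1 %in% names(tab$geneticCode))
  if (length(bad1) && any(tab$geneticCode[c1[bad1]] == "*"))
    stop("in-frame stop codon in ungapped alignment position")
  bad2 <- which(!c2 %in% tab$sense & c2 %in% names(tab$geneticCode))
  if (length(bad2) && any(tab$geneticCode[c2[bad2]] == "*"))
    stop("in-frame stop codon in ungapped alignment position")
  c1 <- c1[known]; c2 <- c2[known]
  if (length(c1) < 1) stop("no ungapped codon columns")
  Stot <- sum((tab$S[c1] + tab$S[c2]) / 2)
  Ntot <- 3 * length(c1) - Stot
  if (Stot <= 0) stop("zero synonymous sites")
  i1 <- match(c1, tab$sense); i2 <- match(c2, tab$sense)
  Sd <- sum(tab$Sd[cbind(i1, i2)])
  Nd <- sum(tab$Nd[cbind(i1, i2)])
  ps <- Sd / Stot
  pn <- Nd / Ntot
  sat_s <- ps >= 0.75; sat_n <- pn >= 0.75
  ks <- if (sat_s) NA_real_ else -0.75 * log(1 - 4 * ps / 3)
  ka <- if (sat_n) NA_real_ else -0.75 * log(1 - 4 * pn / 3)
  new("KsEstimate", ks = ks, ka = ka, sSites = Stot, nSites = Ntot,
      identity = pair@identity, saturated = sat_s || sat_n)
}

#' Best-hit pairing of sequences by local alignment score
#'
#' One best target per query by Smith-Waterman score (ties broken by the
#' lexicographically smaller target id); queries scoring below `minScore`
#' are left unpaired.  The reciprocal-best subset is flagged.
#'
#' @param query,target `AAStringSet` or `DNAStringSet`.
#' @param minScore score floor below which a query is unpaired.
#' @return data.frame `query`, `target`, `score`, `reciprocal`; unpaired
#'   query ids in attribute `"unpaired"`.
#' @export
bestHitPairs <- function(query, target, minScore = 0) {
  if (length(target) == 0) stop("empty target set")
  if (is.null(names(query)) || is.null(names(target)))
    stop("query and target must be named")
  isAA <- methods::is(query, "AAStringSet")
  scoreRow <- function(q, set) {
    if (isAA)
      Biostrings::pairwiseAlignment(rep(Biostrings::AAStringSet(as.character(q)),
                                        length(set)), set,
                                    type = "local",
                                    substitutionMatrix = "BLOSUM62",
                                    gapOpening = 10, gapExtension = 0.5,
                                    scoreOnly = TRUE)
    else
      Biostrings::pairwiseAlignment(rep(Biostrings::DNAStringSet(as.character(q)),
                                        length(set)), set,
                                    type = "local",
                                    gapOpening = 10, gapExtension = 0.5,
                                    scoreOnly = TRUE)
  }
  bestOf <- function(scores, ids) {
    top <- max(scores)
    cand <- sort(ids[scores == top])
    list(id = cand[1], score = top)
  }
  hits <- data.frame(query = character(), target = character(),
                     score = numeric())
  unpaired <- character()
  for (qi in seq_along(query)) {
    sc <- scoreRow(query[[qi]], target)
    b <- bestOf(sc, names(target))
    if (b$score < minScore) unpaired <- c(unpaired, names(query)[qi])
    else hits <- rbind(hits, data.frame(query = names(query)[qi],
                                        target = b$id, score = b$score))
  }
  if (nrow(hits) == 0) {
    hits$reciprocal <- logical(0)
    attr(hits, "unpaired") <- unpaired
    return(hits)
  }
  hits$reciprocal <- FALSE
  for (tg in unique(hits$target)) {
    sc <- scoreRow(target[[tg]], query)
    b <- bestOf(sc, names(query))
    hits$reciprocal[hits$target == tg & hits$query == b$id] <- TRUE
  }
  attr(hits, "unpaired") <- unpaired
  hits
}

#' Remove near-identical pairs before Ks peak fitting
#'
#' Drops pairs whose nucleotide identity exceeds `threshold` (redundant
#' transcripts, alternative splice forms, assembly artifacts); survivors
#' are returned unchanged.
#'
#' @param pairs data.frame with an `identity` column, or a list of
#'   [CodonPairAlignment-class] / [KsEstimate-class] objects.
#' @param threshold identity cutoff in (0, 1); default 0.90.
#' @return same container as `pairs`, filtered; attribute `"removed"`
#'   gives the removed count.
#' @export
identityCutoffFilter <- function(pairs, threshold = 0.90) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  idn <- if (is.data.frame(pairs)) pairs$identity
         else vapply(pairs, function(p) p@identity, 1)
  keep <- !(idn > threshold)
  out <- if (is.data.frame(pairs)) pairs[keep, , drop = FALSE] else pairs[keep]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Fit Gaussian-mixture peaks to a Ks distribution
#'
#' Values inside `ksWindow` are fitted with unequal-variance Gaussian
#' mixtures over the component numbers in `kRange`; the model is selected
#' by BIC ([mclust::Mclust()]).  The labels `Ks1` (largest mean) and `Ks2`
#' (second largest) name the focal peaks.
#'
#' @param ks numeric vector of Ks values.
#' @param kRange candidate numbers of components.
#' @param ksWindow inclusive window of usable Ks values.
#' @param seed RNG seed (mixture initialisation).
#' @param minN minimum number of values inside the window.
#' @return a [KsPeakModel-class].
#' @export
fitKsPeaks <- function(ks, kRange = 1:3, ksWindow = c(0.05, 5), seed = 1,
                       minN = 50) {
  ks <- ks[is.finite(ks) & ks >= ksWindow[1] & ks <= ksWindow[2]]
  if (length(ks) < minN)
    stop("too few Ks values inside the window (", length(ks), " < ", minN, ")")
  if (stats::sd(ks) < 1e-8) stop("degenerate variance in Ks values")
  .assertSeed(seed)
  fit <- mclust::Mclust(ks, G = kRange, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  ord <- order(fit$parameters$mean)
  means <- as.numeric(fit$parameters$mean[ord])
  sds <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sds) == 1) sds <- rep(sds, length(means)) else sds <- sds[ord]
  wts <- as.numeric(fit$parameters$pro[ord])
  labs <- c(Ks1 = means[length(means)])
  if (length(means) >= 2) labs <- c(labs, Ks2 = means[length(means) - 1])
  new("KsPeakModel", means = means, sds = sds, weights = wts,
      bic = as.numeric(fit$bic), n = length(ks), labels = labs)
}

#' Calibrate Ks distributions against a reference pair
#'
#' Every distribution is rescaled by `referenceValue / mode(reference)`,
#' where the mode is the argmax of a kernel density estimate (Silverman
#' bandwidth, 512-point grid), so the reference distribution's mode maps
#' exactly to `referenceValue`.
#'
#' @param ksList named list of numeric Ks vectors, one per species pair.
#' @param referencePair name of the reference distribution in `ksList`.
#' @param referenceValue target Ks for the reference mode.
#' @return named list of rescaled vectors; attribute `"factor"` is the
#'   scaling factor applied.
#' @export
calibrateKs <- function(ksList, referencePair, referenceValue) {
  if (!referencePair %in% names(ksList))
    stop("reference pair '", referencePair, "' not among the distributions")
  md <- .densityMode(ksList[[referencePair]])
  if (!is.finite(md) || md <= 0) stop("reference mode is zero")
  f <- referenceValue / md
  out <- lapply(ksList, function(x) x * f)
  attr(out, "factor") <- f
  out
}

.densityMode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  d <- stats::density(x, bw = "nrd0", n = 512)
  d$x[which.max(d$y)]
}

#' Ks/Ka table for a list of codon pairs
#'
#' Convenience wrapper running [ng86Ks()] over a list of pairs.
#'
#' @param pairs list of [CodonPairAlignment-class].
#' @return data.frame `pair_id`, `ks`, `ka`, `identity`, `saturated`.
#' @export
ksTable <- function(pairs) {
  rows <- lapply(seq_along(pairs), function(i) {
    e <- ng86Ks(pairs[[i]])
    data.frame(pair_id = paste(pairs[[i]]@id1, pairs[[i]]@id2, sep = "|"),
               ks = e@ks, ka = e@ka, identity = e@identity,
               saturated = e@saturated)
  })
  do.call(rbind, rows)
}
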