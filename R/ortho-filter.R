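#' Greedy redundancy clustering of transcripts
#'
#' Longest-first greedy clustering: a sequence joins the first existing
#' cluster whose representative it matches with global-alignment identity
#' at or above `identityThreshold` (identity = matches / alignment columns
#' excluding terminal gaps); otherwise it founds a new cluster.
#' Representatives are the longest member of each cluster (ties broken
#' lexicographically by id).
#'
#' @param seqs named `DNAStringSet` (or named character vector).
#' @param identityThreshold identity threshold in (0, 1\].
#' @return list with `representatives` (`DNAStringSet`) and `clusters`
#'   (named character vector mapping every sequence id to its
#'   representative's id).
#' @export
clusterRedundant <- function(seqs, identityThreshold = 0.98) {
  if (identityThreshold <= 0 || identityThreshold > 1)
    stop("identityThreshold must be in (0, 1]")
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (length(seqs) == 0) stop("empty input")
  if (is.null(names(seqs))) stop("sequences must be named")
  ord <- order(-Biostrings::width(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- integer(0)            # indices into seqs
  assign <- character(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (r in reps) {
      if (.globalIdentity(seqs[[r]], seqs[[i]]) >= identityThreshold) {
        assign[i] <- names(seqs)[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- names(seqs)[i]
    }
  }
  names(assign) <- names(seqs)
  list(representatives = seqs[reps], clusters = assign)
}

# global alignment identity over columns excluding terminal gaps
.globalIdentity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(as.character(a)),
    Biostrings::DNAStringSet(as.character(b)),
    type = "overlap", gapOpening = 10, gapExtension = 0.5)
  x <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  y <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ng <- x != "-" | y != "-"
  # trim terminal gap runs
  core <- which(x != "-" & y != "-")
  if (length(core) == 0) return(0)
  span <- core[1]:core[length(core)]
  mean(x[span] == y[span])
}

#' Two-step ortholog filtering of homolog groups
#'
#' A group passes iff (i) every required species has at least one member,
#' (ii) every reference clade is monophyletic in the group's tree and
#' (iii), in the second pass only, the aligned length is at least
#' `minAlignedLength`.  Reports list every failed criterion per group.
#'
#' @param groups list of [HomologGroup-class].
#' @param stage `"first_pass"` (representative species) or `"second_pass"`
#'   (all species; adds the aligned-length criterion).
#' @param speciesRequired character vector of required species.
#' @param referenceClades named list of species sets required monophyletic
#'   in each group's tree.
#' @param minAlignedLength minimum aligned length (default 1000),
#'   second pass only.
#' @param missingCladePolicy `"fail"` (default): a reference clade with
#'   taxa absent from the tree counts as non-monophyletic; `"skip"`:
#'   such clades are ignored.
#' @return list with `kept` (passing groups) and `reports` (data.frame
#'   `group_id`, `passed`, `failed_criteria`).
#' @export
filterOrthologs <- function(groups, stage = c("first_pass", "second_pass"),
                            speciesRequired, referenceClades = list(),
                            minAlignedLength = 1000,
                            missingCladePolicy = c("fail", "skip")) {
  stage <- match.arg(stage)
  missingCladePolicy <- match.arg(missingCladePolicy)
  reports <- data.frame(group_id = character(), passed = logical(),
                        failed_criteria = character())
  kept <- list()
  for (g in groups) {
    fails <- character()
    have <- names(g@members)[vapply(g@members, length, 1L) > 0]
    if (!all(speciesRequired %in% have)) fails <- c(fails, "missing_species")
    if (length(referenceClades)) {
      if (is.null(g@tree)) {
        fails <- c(fails, "non_monophyletic_reference_clade")
      } else {
        for (cl in referenceClades) {
          pres <- intersect(cl, g@tree$tip.label)
          if (length(pres) < length(cl)) {
            if (missingCladePolicy == "fail") {
              fails <- c(fails, "non_monophyletic_reference_clade"); break
            } else next
          }
          if (length(pres) >= 2 && !ape::is.monophyletic(g@tree, pres)) {
            fails <- c(fails, "non_monophyletic_reference_clade"); break
          }
        }
      }
    }
    if (stage == "second_pass") {
      len <- if (is.null(g@alignment)) 0L else
        unique(Biostrings::width(g@alignment))[1]
      if (len < minAlignedLength) fails <- c(fails, "short_alignment")
    }
    passed <- length(fails) == 0
    reports <- rbind(reports, data.frame(
      group_id = g@groupId, passed = passed,
      failed_criteria = paste(fails, collapse = ",")))
    if (passed) kept <- c(kept, list(g))
  }
  list(kept = kept, reports = reports)
}

#' Entropy-based substitution-saturation screen
#'
#' The index `iss` is the mean per-site Shannon entropy of the alignment
#' divided by the expected mean entropy under full saturation (sites drawn
#' independently from the observed base composition).  The critical value
#' is the 5th percentile of the index over fully randomized alignments of
#' the same dimensions; an alignment whose index reaches that null lower
#' tail is flagged saturated.
#'
#' @param alignment nucleotide alignment (>= 4 sequences).
#' @param nRandomizations randomized alignments for the null (default 1000).
#' @param seed mandatory RNG seed.
#' @return a [SaturationReport-class].
#' @export
saturationIndex <- function(alignment, nRandomizations = 1000, seed) {
  m <- .alnMatrix(alignment)
  if (nrow(m) < 4) stop("need at least 4 sequences")
  bases <- c("A", "C", "G", "T")
  keep <- colSums(matrix(m %in% bases, nrow(m))) == nrow(m)
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0) stop("alignment has no usable columns")
  .assertSeed(seed)
  comp <- table(factor(m, levels = bases))
  comp <- as.numeric(comp) / sum(comp)
  obs <- .meanColEntropy(m, bases)
  nullIdx <- vapply(seq_len(nRandomizations), function(i) {
    r <- matrix(sample(bases, length(m), replace = TRUE, prob = comp),
                nrow(m))
    .meanColEntropy(r, bases)
  }, 1)
  expFull <- mean(nullIdx)
  if (expFull <= 0) stop("degenerate base composition")
  iss <- obs / expFull
  issCrit <- as.numeric(stats::quantile(nullIdx / expFull, 0.05))
  new("SaturationReport", iss = iss, issCritical = issCrit,
      saturated = iss >= issCrit)
}

.meanColEntropy <- function(m, bases) {
  tab <- apply(m, 2, function(col) tabulate(match(col, bases), 4))
  p <- t(tab) / colSums(tab)
  h <- -rowSums(ifelse(p > 0, p * log(p), 0))
  mean(h)
}
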