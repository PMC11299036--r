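#' Simulate a nucleotide alignment along a gene tree
#'
#' Sites evolve independently under JC69 or HKY85 (via
#' [phangorn::simSeq()]); the root sequence is drawn from the stationary
#' base frequencies.  Branch lengths must already be in expected
#' substitutions per site (apply the clock rate first, see
#' [scaleToSubstitutions()]).
#'
#' @param tree `phylo` with branch lengths in substitutions/site.
#' @param nSites number of sites (> 0).
#' @param seed mandatory RNG seed.
#' @param model `"JC69"` or `"HKY85"`.
#' @param kappa transition/transversion rate ratio (HKY85).
#' @param baseFreq stationary base frequencies in A,C,G,T order (HKY85).
#' @return `DNAStringSet` alignment, one sequence per tip.
#' @export
simulateAlignment <- function(tree, nSites, seed, model = c("JC69", "HKY85"),
                              kappa = 2, baseFreq = rep(0.25, 4)) {
  model <- match.arg(model)
  if (nSites < 1) stop("nSites must be positive")
  .assertSeed(seed)
  .simAlignmentNoSeed(tree, nSites, model, kappa, baseFreq)
}

# internal: no seeding, for callers managing the RNG stream themselves
.simAlignmentNoSeed <- function(tree, nSites, model = "JC69", kappa = 2,
                                baseFreq = rep(0.25, 4)) {
  if (model == "JC69") {
    dat <- phangorn::simSeq(tree, l = nSites)
  } else {
    # phangorn Q order: a<->c, a<->g, a<->t, c<->g, c<->t, g<->t
    Q <- c(1, kappa, 1, 1, kappa, 1)
    dat <- phangorn::simSeq(tree, l = nSites, Q = Q, bf = baseFreq)
  }
  m <- toupper(as.character(dat))
  .matrixToDNAStringSet(m)
}

#' Rescale coalescent-unit branch lengths to substitutions per site
#'
#' @param tree `phylo` (or `multiPhylo`) with coalescent-unit lengths.
#' @param clockRate substitutions/site per coalescent unit.
#' @return tree(s) with rescaled branch lengths.
#' @export
scaleToSubstitutions <- function(tree, clockRate) {
  if (clockRate <= 0) stop("clockRate must be positive")
  if (inherits(tree, "multiPhylo")) {
    out <- lapply(tree, scaleToSubstitutions, clockRate = clockRate)
    class(out) <- "multiPhylo"
    for (a in names(attributes(tree)))
      if (!a %in% c("class", "names")) attr(out, a) <- attr(tree, a)
    return(out)
  }
  tree$edge.length <- tree$edge.length * clockRate
  tree
}
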