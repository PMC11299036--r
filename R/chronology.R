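#' Create a fossil calibration
#'
#' @param clade taxon set whose MRCA is given the fixed age.
#' @param ageMa age in Ma.
#' @return a [Calibration-class].
#' @export
calibration <- function(clade, ageMa) new("Calibration", clade = clade,
                                          ageMa = ageMa)

#' Strict-clock dating by mean path lengths with fixed calibrations
#'
#' Node depth is the mean path length (substitutions/site) from the node
#' to its descendant tips; the clock rate is the least-squares fit through
#' the origin of depth against age over the calibrated nodes; every node
#' age is depth/rate, with child ages clamped below their parent so the
#' chronogram is ultrametric and monotone.
#'
#' @param tree rooted `phylo` with branch lengths in substitutions/site.
#' @param calibrations list of [Calibration-class]; each clade must be
#'   monophyletic in `tree`.
#' @return a [Chronogram-class].
#' @export
strictClockDates <- function(tree, calibrations) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (length(calibrations) < 1) stop("at least one calibration required")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  dm <- ape::dist.nodes(tree)
  depth <- numeric(nn)
  for (v in (ntip + 1L):nn) depth[v] <- mean(dm[v, .descTips(tree, v)])
  calNodes <- integer(0); calAges <- numeric(0)
  for (cal in calibrations) {
    if (!all(cal@clade %in% tree$tip.label))
      stop("calibration clade taxa absent from tree")
    if (length(cal@clade) >= 2 && !ape::is.monophyletic(tree, cal@clade))
      stop("calibration clade not monophyletic: ",
           paste(utils::head(cal@clade, 3), collapse = ","), "...")
    calNodes <- c(calNodes, .mrcaNode(tree, cal@clade))
    calAges <- c(calAges, cal@ageMa)
  }
  d <- depth[calNodes]
  if (all(d <= 0)) stop("zero depth at every calibrated node")
  rate <- sum(d * calAges) / sum(calAges^2)
  if (rate <= 0) stop("nonpositive clock rate")
  ages <- depth / rate
  # clamp children below parents, preorder (cladewise edges visit a parent
  # before any edge inside its clade)
  cw <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(cw$edge))) {
    par <- cw$edge[e, 1]; ch <- cw$edge[e, 2]
    if (ages[ch] > ages[par]) ages[ch] <- ages[par]
  }
  ages[seq_len(ntip)] <- 0
  out <- tree
  out$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  new("Chronogram", tree = out, rate = rate, ages = ages)
}

.descTips <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  match(.tipsBelow(phy, node), phy$tip.label)
}

#' Age of the split between two taxon sets
#'
#' Returns the age (Ma) of the most recent common ancestor of `X` and `Y`
#' in a dated tree.
#'
#' @param chronogram a [Chronogram-class].
#' @param X,Y nonempty taxon sets present in the tree.
#' @return age in Ma.
#' @export
splitTime <- function(chronogram, X, Y) {
  stopifnot(is(chronogram, "Chronogram"))
  if (length(X) == 0 || length(Y) == 0) stop("X and Y must be nonempty")
  tr <- chronogram@tree
  missing <- setdiff(c(X, Y), tr$tip.label)
  if (length(missing)) stop("taxa absent from chronogram: ",
                            paste(missing, collapse = ", "))
  node <- .mrcaNode(tr, union(X, Y))
  chronogram@ages[node]
}

#' Split-time concordance diagnostic for hybrid origin
#'
#' Extracts the parental-superclade split and the focal-clade divergence
#' from the two gene-set chronograms: the gene-set-B chronogram (focal
#' clade sister to superclade A) yields the A-C split and the focal-vs-A
#' age; the gene-set-C chronogram yields the A-C split and the
#' focal-vs-C age.  If the focal clade arose by hybridization between the
#' two superclade ancestors, both pairs of ages agree; a clearly different
#' parental split instead points to incomplete lineage sorting.
#'
#' @param chronoB,chronoC [Chronogram-class] objects dated from gene sets
#'   B and C.
#' @param scheme a [GroupScheme-class].
#' @param tolerance maximum relative difference (of the pair mean) still
#'   called concordant; default 0.05.
#' @return a [ConsistencyReport-class] (slot `splitTimes` holds the named
#'   ages).
#' @export
hybridTimeConsistency <- function(chronoB, chronoC, scheme,
                                  tolerance = 0.05) {
  for (ch in list(chronoB, chronoC)) {
    tr <- ch@tree
    B <- intersect(scheme@focal, tr$tip.label)
    if (length(B) >= 2 && !ape::is.monophyletic(tr, B))
      stop("focal clade not monophyletic in a chronogram")
  }
  pB <- splitTime(chronoB, scheme@parent1, scheme@parent2)
  hB <- splitTime(chronoB, scheme@focal, scheme@parent1)
  pC <- splitTime(chronoC, scheme@parent1, scheme@parent2)
  hC <- splitTime(chronoC, scheme@focal, scheme@parent2)
  st <- new("SplitTimes", ages = c(parentalSplitB = pB, parentalSplitC = pC,
                                   hybridSplitB = hB, hybridSplitC = hC))
  pd <- abs(pB - pC); hd <- abs(hB - hC)
  relP <- if ((pB + pC) == 0) 0 else pd / mean(c(pB, pC))
  relH <- if ((hB + hC) == 0) 0 else hd / mean(c(hB, hC))
  verdict <- if (relP <= tolerance && relH <= tolerance)
    "hybridization_consistent"
  else if (relP > tolerance) "ILS_suspected"
  else "inconclusive"
  new("ConsistencyReport", parentalSplitDiff = pd, hybridAgeDiff = hd,
      relParental = relP, relHybrid = relH, verdict = verdict,
      splitTimes = st)
}
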