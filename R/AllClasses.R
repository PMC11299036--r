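setOldClass("phylo")
setOldClass("multiPhylo")

#' One-reticulation species network
#'
#' A rooted ultrametric species tree (the backbone, heights in coalescent
#' units) plus a single hybrid clade whose stem attaches to two parental
#' edges with inheritance probability `gamma` for the parent-1 side.
#' Simulation ground truth for the multispecies coalescent.
#'
#' @slot backbone ultrametric `phylo` (coalescent units) without the hybrid taxa.
#' @slot hybridTree ultrametric `phylo` for the hybrid clade, or `NULL` when
#'   the hybrid is a single tip.
#' @slot hybridTips character, tip labels of the hybrid clade.
#' @slot parent1Clade,parent2Clade character, tip sets of the backbone
#'   defining the two parental attachment edges (the clade stems).
#' @slot parent1Height,parent2Height attachment heights (coalescent units);
#'   must lie on the respective stem edges.
#' @slot gamma probability that a lineage entering the reticulation follows
#'   the parent-1 side.
#' @exportClass SpeciesNetwork
setClass("SpeciesNetwork", representation(
  backbone = "phylo", hybridTree = "ANY", hybridTips = "character",
  parent1Clade = "character", parent2Clade = "character",
  parent1Height = "numeric", parent2Height = "numeric", gamma = "numeric"))

setValidity("SpeciesNetwork", function(object) {
  msg <- character()
  if (length(object@gamma) != 1 || is.na(object@gamma) ||
      object@gamma < 0 || object@gamma > 1)
    msg <- c(msg, "gamma must be a single value in [0, 1]")
  if (length(object@hybridTips) < 1) msg <- c(msg, "at least one hybrid tip")
  if (any(object@hybridTips %in% object@backbone$tip.label))
    msg <- c(msg, "hybrid tips must not appear in the backbone")
  h <- .nodeHeights(object@backbone)
  for (side in 1:2) {
    cl <- slot(object, paste0("parent", side, "Clade"))
    ah <- slot(object, paste0("parent", side, "Height"))
    if (!all(cl %in% object@backbone$tip.label)) {
      msg <- c(msg, sprintf("parent%dClade taxa missing from backbone", side))
      next
    }
    mr <- if (length(cl) == 1L) match(cl, object@backbone$tip.label) else
      ape::getMRCA(object@backbone, cl)
    par <- object@backbone$edge[object@backbone$edge[, 2] == mr, 1]
    if (length(par) == 1L && !(ah > h[mr] && ah < h[par]))
      msg <- c(msg, sprintf("parent%dHeight not on the clade's stem edge", side))
  }
  hr <- .hybridRootHeight(object)
  if (hr >= min(object@parent1Height, object@parent2Height))
    msg <- c(msg, "hybrid clade root must be younger than both attachments")
  if (length(msg)) msg else TRUE
})

#' Taxon-group scheme for classification and gene-flow tests
#'
#' @slot outgroup,focal,parent1,parent2,other character vectors of taxon
#'   names; pairwise disjoint, `other` may be empty.
#' @exportClass GroupScheme
setClass("GroupScheme", representation(
  outgroup = "character", focal = "character",
  parent1 = "character", parent2 = "character", other = "character"))

setValidity("GroupScheme", function(object) {
  sets <- list(object@outgroup, object@focal, object@parent1, object@parent2,
               object@other)
  nonopt <- sets[1:4]
  if (any(vapply(nonopt, length, 1L) == 0))
    return("outgroup, focal, parent1 and parent2 must be nonempty")
  all_t <- unlist(sets)
  if (anyDuplicated(all_t)) return("taxon groups must be pairwise disjoint")
  TRUE
})

#' A homologous gene group
#'
#' @slot groupId identifier.
#' @slot members named list (species -> `DNAStringSet`) of member sequences.
#' @slot alignment optional `DNAStringSet` alignment (equal widths) or `NULL`.
#' @slot tree optional gene tree (`phylo`) or `NULL`.
#' @exportClass HomologGroup
setClass("HomologGroup", representation(
  groupId = "character", members = "list", alignment = "ANY", tree = "ANY"))

setValidity("HomologGroup", function(object) {
  if (length(object@members) < 1) return("at least one species required")
  ids <- unlist(lapply(object@members, names))
  if (anyDuplicated(ids)) return("member sequence ids must be unique")
  TRUE
})

#' Substitution-saturation screen result
#'
#' @slot iss observed entropy-based saturation index (0 = invariant,
#'   about 1 = fully saturated).
#' @slot issCritical randomization-null critical value (5th percentile of
#'   the full-saturation null).
#' @slot saturated logical, `iss >= issCritical`.
#' @exportClass SaturationReport
setClass("SaturationReport", representation(
  iss = "numeric", issCritical = "numeric", saturated = "logical"))

#' Partition of loci into topology-defined gene sets
#'
#' @slot counts named integer: `sister_to_both`, `sister_to_A`,
#'   `sister_to_C`, `unresolved`.
#' @slot assignments named character, locus -> class.
#' @slot percentages shares of the three resolved classes (percent, 2 dp).
#' @slot warning logical flag set when no tree could be resolved.
#' @exportClass GeneSetPartition
setClass("GeneSetPartition", representation(
  counts = "integer", assignments = "character", percentages = "numeric",
  warning = "logical"))

#' Rooted-triplet topology counts for three taxon groups
#'
#' @slot nAB,nAC,nBC counts of the three resolved rooted triplets
#'   (which pair of groups is sister).
#' @slot nUnclassified trees where a group was not monophyletic.
#' @slot groups character(3), the group names in order (A, B, C).
#' @exportClass TripletCounts
setClass("TripletCounts", representation(
  nAB = "numeric", nAC = "numeric", nBC = "numeric",
  nUnclassified = "numeric", groups = "character"))

#' Pairwise codon alignment
#'
#' @slot id1,id2 sequence identifiers.
#' @slot aln1,aln2 aligned codon strings (equal length, multiple of 3,
#'   gaps in whole codons).
#' @slot identity fraction of identical ungapped nucleotide columns.
#' @exportClass CodonPairAlignment
setClass("CodonPairAlignment", representation(
  id1 = "character", id2 = "character",
  aln1 = "character", aln2 = "character", identity = "numeric"))

setValidity("CodonPairAlignment", function(object) {
  n1 <- nchar(object@aln1); n2 <- nchar(object@aln2)
  if (n1 != n2) return("aligned strings must have equal length")
  if (n1 %% 3 != 0) return("alignment length must be a multiple of 3")
  TRUE
})

#' Nei-Gojobori Ks/Ka estimate for one pair
#'
#' @slot ks,ka synonymous / nonsynonymous substitutions per site
#'   (`NA` when saturated).
#' @slot sSites,nSites fractional synonymous / nonsynonymous site counts.
#' @slot identity nucleotide identity of the pair alignment.
#' @slot saturated logical, proportion of differences >= 3/4.
#' @exportClass KsEstimate
setClass("KsEstimate", representation(
  ks = "numeric", ka = "numeric", sSites = "numeric", nSites = "numeric",
  identity = "numeric", saturated = "logical"))

#' Fitted Gaussian-mixture model of a Ks distribution
#'
#' @slot means,sds,weights component parameters, sorted by increasing mean.
#' @slot bic BIC of the selected model.
#' @slot n number of Ks values used.
#' @slot labels named numeric: `Ks1` (largest mean) and, when at least two
#'   components were fitted, `Ks2` (second largest).
#' @exportClass KsPeakModel
setClass("KsPeakModel", representation(
  means = "numeric", sds = "numeric", weights = "numeric",
  bic = "numeric", n = "integer", labels = "numeric"))

#' Quartet site-pattern tallies
#'
#' Counts of collapsed site-pattern classes over the ordered roles
#' (outgroup, P1, hybrid, P2): `AABB` (hybrid pairs with P2), `ABBA`
#' (hybrid pairs with P1), `ABAB` (P1 pairs with P2; discordant),
#' singleton classes, `monomorphic` and `other`.
#'
#' @slot counts named numeric vector of class counts.
#' @slot nUsed,nSkipped columns used / skipped (gap or ambiguity in a role).
#' @slot quartetCounts per-individual-quartet count matrix (rows =
#'   quartets), used for individual bootstrap.
#' @slot quartetIndex data.frame mapping quartet rows to individuals.
#' @slot blockArray quartet x block x class count array (blocks follow the
#'   alignment's partition map), used for jackknife standard errors and
#'   the individual bootstrap.
#' @exportClass SitePatternCounts
setClass("SitePatternCounts", representation(
  counts = "numeric", nUsed = "numeric", nSkipped = "numeric",
  quartetCounts = "matrix", quartetIndex = "data.frame",
  blockArray = "array"))

#' Result of the invariant-based hybridization test
#'
#' @slot gammaHat estimated inheritance probability from the P1 side, in \[0,1\].
#' @slot zScore intersection-union Z statistic against the tree null.
#' @slot pValue one-sided p-value.
#' @slot significant logical at level `alpha` (requires gammaHat strictly
#'   inside (0,1)).
#' @slot alpha test level.
#' @exportClass HybridTestResult
setClass("HybridTestResult", representation(
  gammaHat = "numeric", zScore = "numeric", pValue = "numeric",
  significant = "logical", alpha = "numeric"))

#' Individual-bootstrap summary of the hybridization test
#'
#' @slot gammaSamples per-replicate gamma estimates.
#' @slot fractionSignificant share of replicates detecting hybridization.
#' @slot gammaRange min and max of the gamma samples.
#' @exportClass BootstrapResult
setClass("BootstrapResult", representation(
  gammaSamples = "numeric", fractionSignificant = "numeric",
  gammaRange = "numeric"))

#' One-reticulation triplet pseudo-likelihood fit
#'
#' @slot gammaHat inheritance probability from the A (P1) side.
#' @slot tA,tC internal branch lengths (coalescent units).
#' @slot logPL maximized log pseudo-likelihood.
#' @slot identifiable FALSE when the profile likelihood over gamma is flat
#'   within tolerance.
#' @slot equalDepths whether the fit constrained tA == tC.
#' @exportClass NetworkFit
setClass("NetworkFit", representation(
  gammaHat = "numeric", tA = "numeric", tC = "numeric", logPL = "numeric",
  identifiable = "logical", equalDepths = "logical"))

#' A fossil calibration applied as a fixed node age
#'
#' @slot clade taxon set whose MRCA is calibrated.
#' @slot ageMa age in Ma (> 0).
#' @exportClass Calibration
setClass("Calibration", representation(clade = "character", ageMa = "numeric"))

setValidity("Calibration", function(object)
  if (length(object@ageMa) != 1 || object@ageMa <= 0)
    "ageMa must be a single positive value" else TRUE)

#' Dated ultrametric tree
#'
#' @slot tree rooted ultrametric `phylo`, branch lengths in Ma.
#' @slot rate fitted clock rate (substitutions/site/Ma).
#' @slot ages node ages in Ma, indexed by node number.
#' @exportClass Chronogram
setClass("Chronogram", representation(
  tree = "phylo", rate = "numeric", ages = "numeric"))

#' Named divergence times extracted from gene-set chronograms
#'
#' `parentalSplitB`/`parentalSplitC`: age of the A-C superclade split in the
#' gene-set-B / gene-set-C chronogram; `hybridSplitB`: focal clade vs
#' superclade A (gene set B); `hybridSplitC`: focal clade vs superclade C
#' (gene set C).  All in Ma.
#'
#' @slot ages named numeric vector of divergence times.
#' @exportClass SplitTimes
setClass("SplitTimes", representation(ages = "numeric"))

#' Split-time concordance diagnostic
#'
#' @slot parentalSplitDiff,hybridAgeDiff absolute differences (Ma).
#' @slot relParental,relHybrid differences relative to the pair means.
#' @slot verdict one of `hybridization_consistent`, `ILS_suspected`,
#'   `inconclusive`.
#' @slot splitTimes the underlying [SplitTimes-class] object.
#' @exportClass ConsistencyReport
setClass("ConsistencyReport", representation(
  parentalSplitDiff = "numeric", hybridAgeDiff = "numeric",
  relParental = "numeric", relHybrid = "numeric", verdict = "character",
  splitTimes = "ANY"))
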