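#' Root a gene tree with an outgroup
#'
#' Places the root on the edge separating the smallest clade containing all
#' outgroup taxa present in the tree from the remaining taxa; the branch
#' length of that edge is split equally across the new root.
#'
#' @param tree `phylo`.
#' @param outgroupTaxa character; at least one must be present.
#' @return rooted `phylo`; if the outgroup taxa do not form a clade after
#'   rooting, the attribute `"unrooted_ambiguous"` is set to `TRUE`.
#' @export
rerootOutgroup <- function(tree, outgroupTaxa) {
  present <- intersect(outgroupTaxa, tree$tip.label)
  if (length(present) == 0) stop("no outgroup taxon present in the tree")
  if (length(present) == length(tree$tip.label))
    stop("outgroup covers the whole tree")
  # already rooted with the outgroup on one side of the root: keep as is,
  # so internal (support) labels are untouched
  if (ape::is.rooted(tree)) {
    rootNode <- length(tree$tip.label) + 1L
    kids <- tree$edge[tree$edge[, 1] == rootNode, 2]
    sides <- lapply(kids, .tipsBelow, phy = tree)
    if (any(vapply(sides, function(s) setequal(s, present), TRUE)))
      return(tree)
  }
  rooted <- ape::root(tree, outgroup = present, resolve.root = TRUE,
                      edgelabel = TRUE)
  # split the divided edge equally across the new root
  rootNode <- length(rooted$tip.label) + 1L
  re <- which(rooted$edge[, 1] == rootNode)
  if (length(re) == 2) {
    tot <- sum(rooted$edge.length[re])
    rooted$edge.length[re] <- tot / 2
  }
  if (!ape::is.monophyletic(rooted, present))
    attr(rooted, "unrooted_ambiguous") <- TRUE
  rooted
}

#' Classify the focal clade's position in one rooted gene tree
#'
#' The tree is pruned to the scheme's parent1 (A), focal (B) and parent2
#' (C) taxa.  B must be monophyletic; the taxon content S of B's sister
#' clade decides the class: S intersecting both A and C gives
#' `sister_to_both`, S within A gives `sister_to_A`, S within C gives
#' `sister_to_C`.  Anything else — B non-monophyletic, or the support of
#' the bipartition uniting B with its sister below `supportThreshold` — is
#' `unresolved`.
#'
#' @param tree rooted `phylo` (see [rerootOutgroup()]).
#' @param scheme a [GroupScheme-class].
#' @param supportThreshold minimum support of the defining bipartition
#'   (internal node labels); default 0 uses the tree as given.
#' @return one of `"sister_to_both"`, `"sister_to_A"`, `"sister_to_C"`,
#'   `"unresolved"`.
#' @export
classifyFocalPosition <- function(tree, scheme, supportThreshold = 0) {
  A <- intersect(scheme@parent1, tree$tip.label)
  B <- intersect(scheme@focal, tree$tip.label)
  C <- intersect(scheme@parent2, tree$tip.label)
  if (length(A) == 0 || length(B) == 0 || length(C) == 0)
    stop("tree shares no taxa with one of the groups A, B, C")
  tr <- ape::keep.tip(tree, c(A, B, C))
  if (!ape::is.monophyletic(tr, B)) return("unresolved")
  node <- .mrcaNode(tr, B)
  parent <- tr$edge[tr$edge[, 2] == node, 1]
  if (length(parent) != 1) return("unresolved")  # B spans the root
  sibs <- setdiff(tr$edge[tr$edge[, 1] == parent, 2], node)
  S <- unlist(lapply(sibs, .tipsBelow, phy = tr))
  if (supportThreshold > 0) {
    # read support off the original (unpruned) tree: the smallest clade
    # containing B and its sister content carries the defining bipartition
    node0 <- .mrcaNode(tree, c(B, S))
    supp <- .nodeSupport(tree, node0)
    if (is.finite(supp) && supp < supportThreshold) return("unresolved")
  }
  inA <- any(S %in% A); inC <- any(S %in% C)
  if (any(!S %in% c(A, C))) return("unresolved")
  if (inA && inC) "sister_to_both"
  else if (inA) "sister_to_A"
  else if (inC) "sister_to_C"
  else "unresolved"
}

.nodeSupport <- function(phy, node) {
  if (is.null(phy$node.label)) return(NA_real_)
  lab <- phy$node.label[node - length(phy$tip.label)]
  suppressWarnings(as.numeric(lab))
}

#' Partition gene trees into the three topology-defined gene sets
#'
#' Applies [classifyFocalPosition()] to every tree and reports counts,
#' per-locus assignments and percentage shares of the three resolved
#' classes (rounded to 2 decimals).
#'
#' @param trees `multiPhylo` or list of rooted `phylo`; names become locus
#'   ids.
#' @param scheme a [GroupScheme-class].
#' @param supportThreshold passed to [classifyFocalPosition()].
#' @return a [GeneSetPartition-class].
#' @export
partitionGeneSets <- function(trees, scheme, supportThreshold = 0) {
  if (length(trees) == 0) stop("no trees given")
  ids <- names(trees)
  if (is.null(ids)) ids <- sprintf("locus%04d", seq_along(trees))
  cls <- vapply(trees, classifyFocalPosition, "", scheme = scheme,
                supportThreshold = supportThreshold)
  names(cls) <- ids
  lev <- c("sister_to_both", "sister_to_A", "sister_to_C", "unresolved")
  counts <- table(factor(cls, levels = lev))
  counts <- setNames(as.integer(counts), lev)
  resolved <- counts[1:3]
  warn <- sum(resolved) == 0
  pct <- if (warn) setNames(rep(NA_real_, 3), names(resolved)) else
    round(100 * resolved / sum(resolved), 2)
  if (warn) warning("all trees unresolved")
  new("GeneSetPartition", counts = counts, assignments = cls,
      percentages = pct, warning = warn)
}

#' Rooted-triplet topology frequencies for three taxon groups
#'
#' Each tree is pruned to the three groups; when every group is
#' monophyletic in the pruned tree, the sister pair is tallied, otherwise
#' the tree is unclassified.
#'
#' @param trees rooted trees (`multiPhylo` or list).
#' @param groups named list of three character vectors (taxon sets).
#' @return a [TripletCounts-class]; slot order follows `names(groups)` as
#'   (A, B, C) with `nAB`, `nAC`, `nBC`.
#' @export
tripletFrequencies <- function(trees, groups) {
  stopifnot(length(groups) == 3)
  gn <- names(groups)
  if (is.null(gn)) { gn <- c("A", "B", "C"); names(groups) <- gn }
  all_t <- unlist(lapply(trees, function(t) t$tip.label))
  for (g in gn)
    if (!any(groups[[g]] %in% all_t))
      stop("group '", g, "' absent from all trees")
  n <- c(AB = 0, AC = 0, BC = 0); nun <- 0
  for (tr in trees) {
    keep <- intersect(tr$tip.label, unlist(groups))
    pt <- ape::keep.tip(tr, keep)
    gs <- lapply(groups, intersect, x = pt$tip.label)
    if (any(lengths(gs) == 0)) { nun <- nun + 1; next }
    mono <- vapply(gs, function(g)
      length(g) == 1 || ape::is.monophyletic(pt, g), TRUE)
    if (!all(mono)) { nun <- nun + 1; next }
    sis <- .sisterPair(pt, gs)
    if (is.null(sis)) { nun <- nun + 1; next }
    n[sis] <- n[sis] + 1
  }
  new("TripletCounts", nAB = n[["AB"]], nAC = n[["AC"]], nBC = n[["BC"]],
      nUnclassified = nun, groups = gn)
}

# which pair of the three (monophyletic) groups is sister in the pruned tree
.sisterPair <- function(pt, gs) {
  pairs <- list(AB = c(1, 2), AC = c(1, 3), BC = c(2, 3))
  for (nm in names(pairs)) {
    tips <- c(gs[[pairs[[nm]][1]]], gs[[pairs[[nm]][2]]])
    mr <- .mrcaNode(pt, tips)
    below <- .tipsBelow(pt, mr)
    if (setequal(below, tips)) return(nm)
  }
  NULL
}

#' ILS-vs-hybridization pattern diagnostic on three topology counts
#'
#' Under incomplete lineage sorting the two minority topologies are
#' expected to be nearly equal in frequency while the majority stands out;
#' under hybridization two topologies have similar (high) frequencies and
#' one is clearly the least frequent.  With sorted counts n1 >= n2 >= n3,
#' exact two-sided binomial tests of 50:50 are applied to (n1, n2) and to
#' (n2, n3): `ILS_like` iff the first differs significantly and the second
#' does not; `hybrid_like` iff the first does not and the second does;
#' anything else is `ambiguous`.
#'
#' @param counts three nonnegative topology counts.
#' @param alpha test level (default 0.05).
#' @return list with `verdict`, `p_top` (n1 vs n2), `p_minor` (n2 vs n3)
#'   and the sorted counts.
#' @export
ilsVsHybridPattern <- function(counts, alpha = 0.05) {
  if (length(counts) != 3 || any(counts < 0)) stop("need three nonnegative counts")
  if (sum(counts) < 1) stop("counts sum to zero")
  s <- sort(counts, decreasing = TRUE)
  p_top <- stats::binom.test(s[1], s[1] + s[2], p = 0.5)$p.value
  p_minor <- if (s[2] + s[3] == 0) 1 else
    stats::binom.test(s[2], s[2] + s[3], p = 0.5)$p.value
  verdict <- if (p_top < alpha && p_minor >= alpha) "ILS_like"
    else if (p_top >= alpha && p_minor < alpha) "hybrid_like"
    else "ambiguous"
  list(verdict = verdict, p_top = p_top, p_minor = p_minor,
       counts_sorted = s)
}
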