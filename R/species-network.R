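#' Construct a one-reticulation species network
#'
#' The backbone is an ultrametric species tree (heights in coalescent
#' units) that does not contain the hybrid taxa.  The hybrid clade attaches
#' by its stem to two parental edges, identified as the stem edges of
#' `parent1Clade` and `parent2Clade`, at heights `parent1Height` and
#' `parent2Height`.  A gene lineage reaching the reticulation follows the
#' parent-1 side with probability `gamma`.
#'
#' @param backbone `phylo` or newick string; rooted, ultrametric,
#'   coalescent-unit branch lengths.
#' @param hybrid `phylo`, newick string or a single tip name for the hybrid
#'   clade.
#' @param parent1Clade,parent2Clade character; backbone tip sets whose stem
#'   edges carry the attachments.
#' @param parent1Height,parent2Height attachment heights (coalescent units).
#' @param gamma inheritance probability of the parent-1 side, in \[0,1\].
#' @return a [SpeciesNetwork-class] object.
#' @export
speciesNetwork <- function(backbone, hybrid, parent1Clade, parent2Clade,
                           parent1Height, parent2Height, gamma) {
  if (is.character(backbone)) backbone <- parseNewick(backbone)
  hybridTree <- NULL
  if (is.character(hybrid) && length(hybrid) == 1 && grepl(";", hybrid))
    hybrid <- parseNewick(hybrid)
  if (inherits(hybrid, "phylo")) {
    hybridTree <- hybrid
    hybridTips <- hybrid$tip.label
  } else {
    hybridTips <- as.character(hybrid)
    if (length(hybridTips) != 1)
      stop("multiple hybrid tips must be given as a tree")
  }
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  obj <- new("SpeciesNetwork", backbone = backbone, hybridTree = hybridTree,
             hybridTips = hybridTips, parent1Clade = parent1Clade,
             parent2Clade = parent2Clade,
             parent1Height = parent1Height, parent2Height = parent2Height,
             gamma = gamma)
  validObject(obj)
  obj
}

#' The packaged nine-taxon case-study network
#'
#' A synthetic scenario mirroring an ancient allopolyploid origin of a
#' focal clade (tips `B1`-`B3`) from the common ancestors of two parental
#' superclades (`A1`,`A2` and `C1`,`C2`), with an early-diverging lineage
#' (`sel1`) and a distant outgroup (`out1`).  Node heights follow the dated
#' scenario (root 370 Ma, earliest split 304 Ma, parental split 268 Ma,
#' hybridization 248 Ma) on a scale of 20 Ma per coalescent unit; see the
#' methods vignette.
#'
#' @param gamma inheritance probability from the A side (default 0.4511).
#' @return a [SpeciesNetwork-class] object.
#' @export
caseStudyNetwork <- function(gamma = 0.4511) {
  speciesNetwork(
    backbone = "((((A1:7.5,A2:7.5):5.9,(C1:7.5,C2:7.5):5.9):1.8,sel1:15.2):3.3,out1:18.5);",
    hybrid = "((B1:2,B2:2):2,B3:4);",
    parent1Clade = c("A1", "A2"), parent2Clade = c("C1", "C2"),
    parent1Height = 12.4, parent2Height = 12.4, gamma = gamma)
}

#' Taxon groups of the case-study network
#'
#' @return a [GroupScheme-class] matching [caseStudyNetwork()].
#' @export
caseStudyScheme <- function() {
  new("GroupScheme", outgroup = "out1", focal = c("B1", "B2", "B3"),
      parent1 = c("A1", "A2"), parent2 = c("C1", "C2"), other = "sel1")
}

# ---------------------------------------------------------------------------
# multispecies coalescent on the network
#
# Lineages are newick fragments carrying their current height.  Coalescence
# within a population of k lineages occurs at rate k(k-1)/2 per coalescent
# unit.  At the reticulation each surviving hybrid-stem lineage picks the
# parent-1 side with probability gamma, then continues in the chosen
# parental edge of the backbone.

# coalesce lineages (list of list(frag=, h=)) between h0 and h1 (h1 may be Inf)
.coalesceSegment <- function(lineages, h0, h1) {
  h <- h0
  while (length(lineages) >= 2) {
    k <- length(lineages)
    dt <- stats::rexp(1, rate = k * (k - 1) / 2)
    if (h + dt > h1) break
    h <- h + dt
    pair <- sample.int(k, 2)
    a <- lineages[[pair[1]]]; b <- lineages[[pair[2]]]
    merged <- list(
      frag = sprintf("(%s:%.10g,%s:%.10g)", a$frag, h - a$h, b$frag, h - b$h),
      h = h)
    lineages <- c(lineages[-pair], list(merged))
  }
  lineages
}

# internal per-locus simulation; returns phylo (coalescent-unit lengths)
# plus the routing of the hybrid lineages
.simLocus <- function(plan, gamma, forceSide = "random") {
  # 1. hybrid clade internal coalescent (if any)
  if (!is.null(plan$hybrid)) {
    hl <- .simulateOnTreeTable(plan$hybrid)
  } else {
    hl <- list(list(frag = plan$hybridTip, h = 0))
  }
  # hybrid stem up to the reticulation
  T0 <- min(plan$h1, plan$h2)
  hl <- .coalesceSegment(hl, plan$hybridRootHeight, T0)
  # 2. route
  if (forceSide == "both") {
    sides <- rep(3L, length(hl))
  } else if (forceSide == "parent1") {
    sides <- rep(1L, length(hl))
  } else if (forceSide == "parent2") {
    sides <- rep(2L, length(hl))
  } else {
    sides <- ifelse(stats::runif(length(hl)) < gamma, 1L, 2L)
  }
  # continue each side separately up to its attachment height
  inject <- list()
  g1 <- hl[sides == 1L]; g2 <- hl[sides == 2L]; g3 <- hl[sides == 3L]
  if (length(g1)) {
    g1 <- .coalesceSegment(g1, T0, plan$h1)
    inject <- c(inject, lapply(g1, function(l)
      list(edge = plan$edge1, h = plan$h1, lin = list(frag = l$frag, h = l$h))))
  }
  if (length(g2)) {
    g2 <- .coalesceSegment(g2, T0, plan$h2)
    inject <- c(inject, lapply(g2, function(l)
      list(edge = plan$edge2, h = plan$h2, lin = list(frag = l$frag, h = l$h))))
  }
  if (length(g3)) {
    inject <- c(inject, lapply(g3, function(l)
      list(edge = plan$edgeBoth, h = plan$hBoth,
           lin = list(frag = l$frag, h = l$h))))
  }
  # 3. backbone structured coalescent with injections
  root_lin <- .simulateOnTreeTable(plan$backbone, inject)
  root_lin <- .coalesceSegment(root_lin, plan$rootHeight, Inf)
  txt <- paste0(root_lin[[1]]$frag, ";")
  tr <- ape::read.tree(text = txt)
  attr(tr, "routing") <- c("parent1", "parent2", "both")[sides]
  tr
}

# build a population-table "plan" once per network (or plain tree)
.mscPlan <- function(net) {
  if (inherits(net, "phylo")) {
    bb <- net
    plan <- list(backbone = .treeTable(bb), rootHeight = max(.nodeHeights(bb)),
                 hybrid = NULL, hybridTip = NULL)
    plan$plain <- TRUE
    return(plan)
  }
  stopifnot(is(net, "SpeciesNetwork"))
  bb <- net@backbone
  h <- .nodeHeights(bb)
  tt <- .treeTable(bb)
  e1 <- .stemEdgeId(bb, net@parent1Clade)
  e2 <- .stemEdgeId(bb, net@parent2Clade)
  # "both" injection: population directly above the mrca of both parental clades
  mrca12 <- .mrcaNode(bb, union(net@parent1Clade, net@parent2Clade))
  eBoth <- which(bb$edge[, 2] == mrca12)
  hBoth <- h[mrca12]
  if (length(eBoth) == 0) { eBoth <- 0L }  # mrca is the root: root population
  list(backbone = tt, rootHeight = max(h),
       hybrid = if (is.null(net@hybridTree)) NULL else .treeTable(net@hybridTree),
       hybridTip = if (is.null(net@hybridTree)) net@hybridTips else NULL,
       hybridRootHeight = .hybridRootHeight(net),
       h1 = net@parent1Height, h2 = net@parent2Height,
       edge1 = e1, edge2 = e2, edgeBoth = eBoth, hBoth = hBoth,
       plain = FALSE)
}

.stemEdgeId <- function(phy, clade) {
  node <- .mrcaNode(phy, clade)
  id <- which(phy$edge[, 2] == node)
  if (length(id) != 1) stop("clade has no stem edge (is it the root?)")
  id
}

# tree table: postorder list of populations (edges) with bottom/top heights
.treeTable <- function(phy) {
  h <- .nodeHeights(phy)
  n <- length(phy$tip.label)
  root <- n + 1L
  # children of each node
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  order_nodes <- order(h[as.integer(names(kids))])  # process low to high
  list(phy = phy, heights = h, ntip = n, root = root,
       kids = kids, node_order = as.integer(names(kids))[order_nodes])
}

# run the structured coalescent over a tree table; injections is a list of
# list(edge = edge id (0 = root population), h = height, lin = lineage)
# returns lineages surviving at the root node height (root population itself
# is NOT run here so callers can pool further injections)
.simulateOnTreeTable <- function(tt, injections = list()) {
  phy <- tt$phy; h <- tt$heights
  inj_edges <- vapply(injections, function(x) x$edge, 1L)
  lin_at <- vector("list", tt$ntip + phy$Nnode)
  for (i in seq_len(tt$ntip))
    lin_at[[i]] <- list(list(frag = phy$tip.label[i], h = h[i]))
  for (node in tt$node_order) {
    lineages <- list()
    for (child in tt$kids[[as.character(node)]]) {
      eid <- which(phy$edge[, 2] == child)
      lins <- lin_at[[child]]
      inj_here <- injections[inj_edges == eid]
      if (length(inj_here)) {
        # coalesce in sub-segments split at injection heights
        evs <- sort(vapply(inj_here, function(x) x$h, 1))
        cur_h <- h[child]
        for (eh in evs) {
          lins <- .coalesceSegment(lins, cur_h, eh)
          add <- inj_here[vapply(inj_here, function(x) x$h, 1) == eh]
          lins <- c(lins, lapply(add, function(x) x$lin))
          cur_h <- eh
        }
        lins <- .coalesceSegment(lins, cur_h, h[node])
      } else {
        lins <- .coalesceSegment(lins, h[child], h[node])
      }
      lineages <- c(lineages, lins)
    }
    lin_at[[node]] <- lineages
  }
  root_l <- lin_at[[tt$root]]
  root_inj <- injections[inj_edges == 0L]
  if (length(root_inj)) root_l <- c(root_l, lapply(root_inj, function(x) x$lin))
  lapply(root_l, function(l) { l$h <- max(l$h, 0); l })
}

# minimal topology check used by the generator's class conditioning:
# position of the hybrid group relative to the two parental clades,
# computed directly on the (ultrametric, coalescent-unit) gene tree
.truePosition <- function(tree, focal, p1, p2) {
  keep <- intersect(tree$tip.label, c(focal, p1, p2))
  tr <- ape::keep.tip(tree, keep)
  foc <- intersect(focal, tr$tip.label)
  if (!ape::is.monophyletic(tr, foc)) return("other")
  node <- .mrcaNode(tr, foc)
  parent <- tr$edge[tr$edge[, 2] == node, 1]
  if (length(parent) != 1) return("other")
  sibs <- setdiff(tr$edge[tr$edge[, 1] == parent, 2], node)
  stips <- unlist(lapply(sibs, .tipsBelow, phy = tr))
  inA <- any(stips %in% p1); inC <- any(stips %in% p2)
  if (any(stips %in% focal)) return("other")
  if (inA && inC) "sister_to_both" else if (inA) "sister_to_A"
  else if (inC) "sister_to_C" else "other"
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Draws gene trees on a one-reticulation [SpeciesNetwork-class] (or a
#' plain ultrametric species tree).  Every gene lineage entering the
#' reticulation independently follows the parent-1 side with probability
#' `gamma`; lineages coalesce within populations at rate `choose(k,2)` per
#' coalescent unit.  Branch lengths of the returned trees are coalescent
#' units.
#'
#' @param network a [SpeciesNetwork-class] or ultrametric `phylo`
#'   (coalescent units).
#' @param nLoci number of gene trees.
#' @param seed mandatory RNG seed.
#' @param forceSide `"random"` (route by gamma), `"parent1"`, `"parent2"`,
#'   or `"both"` (inject the hybrid lineage above the parental split; used
#'   for the both-alleles-retained locus class).
#' @param conditionOn optional topology class
#'   (`"sister_to_A"`, `"sister_to_C"`, `"sister_to_both"`); draws are
#'   rejected until the realized backbone position matches.
#' @param maxTries rejection-sampling cap per locus.
#' @return a `multiPhylo`; attribute `"routing"` is a character vector of
#'   per-locus routing (`parent1`/`parent2`/`both`/`mixed`; `tree` for a
#'   plain species tree).
#' @export
simulateMscGeneTrees <- function(network, nLoci, seed,
                                 forceSide = c("random", "parent1",
                                               "parent2", "both"),
                                 conditionOn = NULL, maxTries = 1000) {
  forceSide <- match.arg(forceSide)
  if (nLoci < 1) stop("nLoci must be >= 1")
  .assertSeed(seed)
  .simulateMscNoSeed(network, nLoci, forceSide, conditionOn, maxTries)
}

# internal workhorse drawing from the current RNG stream
.simulateMscNoSeed <- function(network, nLoci, forceSide = "random",
                               conditionOn = NULL, maxTries = 1000) {
  plan <- .mscPlan(network)
  plain <- isTRUE(plan$plain)
  if (plain && forceSide != "random")
    stop("forceSide requires a SpeciesNetwork")
  gamma <- if (plain) NA_real_ else network@gamma
  trees <- vector("list", nLoci)
  routing <- character(nLoci)
  for (i in seq_len(nLoci)) {
    tries <- 0
    repeat {
      tries <- tries + 1
      if (plain) {
        root_l <- .simulateOnTreeTable(plan$backbone)
        root_l <- .coalesceSegment(root_l, plan$rootHeight, Inf)
        tr <- ape::read.tree(text = paste0(root_l[[1]]$frag, ";"))
        attr(tr, "routing") <- "tree"
      } else {
        tr <- .simLocus(plan, gamma, forceSide)
      }
      if (is.null(conditionOn)) break
      pos <- .truePosition(tr, .hybridTipsOf(network),
                           network@parent1Clade, network@parent2Clade)
      if (pos == conditionOn) break
      if (tries >= maxTries)
        stop("could not realize topology class '", conditionOn,
             "' in ", maxTries, " tries")
    }
    trees[[i]] <- tr
    r <- attr(tr, "routing")
    routing[i] <- if (identical(r, "tree")) "tree"
      else if (length(unique(r)) == 1) unique(r) else "mixed"
  }
  class(trees) <- "multiPhylo"
  attr(trees, "routing") <- routing
  trees
}

.hybridTipsOf <- function(net) net@hybridTips
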