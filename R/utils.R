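# internal helpers shared across modules

# node heights (time above the tips) for an ultrametric rooted phylo;
# tolerates small numerical noise in tip depths
.nodeHeights <- function(phy) {
  depths <- ape::node.depth.edgelength(phy)
  max(depths) - depths
}

.hybridRootHeight <- function(net) {
  if (is.null(net@hybridTree)) 0 else max(.nodeHeights(net@hybridTree))
}

# MRCA that also works for a single tip
.mrcaNode <- function(phy, tips) {
  idx <- match(tips, phy$tip.label)
  if (anyNA(idx)) stop("taxa absent from tree: ",
                       paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) idx else ape::getMRCA(phy, idx)
}

.assertSeed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a seed is required for stochastic operations")
  set.seed(as.integer(seed))
}

# descendant tip labels of a node
.tipsBelow <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(phy$tip.label[node])
  ape::extract.clade(phy, node)$tip.label
}

# alignment container helpers -------------------------------------------------

# coerce character matrix / DNAStringSet to an upper-case character matrix
# (rows = sequences)
.alnMatrix <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else if (methods::is(x, "XStringSet")) {
    if (length(unique(Biostrings::width(x))) != 1)
      stop("sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(as.character(x)), ""))
    rownames(m) <- names(x)
  } else if (is.character(x)) {
    if (length(unique(nchar(x))) != 1)
      stop("sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  } else stop("unsupported alignment container: ", class(x)[1])
  m
}

.matrixToDNAStringSet <- function(m) {
  s <- Biostrings::DNAStringSet(apply(m, 1, paste0, collapse = ""))
  names(s) <- rownames(m)
  s
}

# partition map: data.frame(name, start, end), 0-based half-open columns
.partitionMap <- function(x) attr(x, "partition_map")
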