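#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] enforcing the
#' pipeline's conventions: ids are the header up to the first whitespace,
#' residues are upper-cased, record order is preserved, duplicate ids and
#' empty records are errors.
#'
#' @param path file path.
#' @param type `"DNA"` or `"AA"`.
#' @return a `DNAStringSet` (or `AAStringSet`) with unique names.
#' @export
readFasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  if (length(x) == 0) stop("no FASTA records in ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence id in ", path, ": ",
         names(x)[duplicated(names(x))][1])
  if (any(Biostrings::width(x) == 0)) stop("empty FASTA record in ", path)
  # normalize case
  if (type == "DNA") Biostrings::DNAStringSet(toupper(as.character(x))) else
    Biostrings::AAStringSet(toupper(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs named `XStringSet` or named character vector.
#' @param path output path.
#' @param width line width for residue folding (> 0).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 60) {
  if (width < 1) stop("width must be positive")
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (length(seqs) == 0) stop("no sequences to write")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  Biostrings::writeXStringSet(seqs, path, width = as.integer(width))
  invisible(path)
}

#' Parse a newick string into a tree
#'
#' Dialect: unquoted labels, `:`-prefixed branch lengths, internal-node
#' labels read as support values (numeric when possible).
#'
#' @param text newick text ending in `;`.
#' @return a `phylo` object.
#' @export
parseNewick <- function(text) {
  text <- trimws(text)
  no_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  no_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (no_open != no_close)
    stop("unbalanced parentheses in newick (", no_open, " '(' vs ",
         no_close, " ')')")
  if (!grepl(";\\s*$", text)) stop("newick must terminate with ';'")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("newick parse error: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("newick parse error: unreadable tree")
  phy
}

#' Write a tree as newick text
#'
#' @param tree a `phylo` object.
#' @param digits precision for branch lengths.
#' @return single newick string.
#' @export
writeNewick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Jukes-Cantor distance matrix
#'
#' Pairwise proportions of mismatching sites over ungapped, unambiguous
#' shared columns (pairwise deletion), corrected as
#' `d = -(3/4) log(1 - (4/3) p)`.  Pairs with `p >= 3/4` are saturated:
#' depending on `saturated`, they raise an error or become `Inf`.
#'
#' @param alignment nucleotide alignment (`DNAStringSet`, character matrix
#'   or named character vector of equal-length strings).
#' @param saturated `"infinite"` (default) or `"error"`.
#' @return symmetric numeric matrix with taxon dimnames; attribute
#'   `"saturated"` is a logical matrix flagging saturated pairs.
#' @export
jcDistanceMatrix <- function(alignment, saturated = c("infinite", "error")) {
  saturated <- match.arg(saturated)
  m <- .alnMatrix(alignment)
  if (nrow(m) < 2) stop("need at least two sequences")
  n <- nrow(m)
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  p <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- ok[i, ] & ok[j, ]
    if (!any(use)) stop("no shared ungapped columns for pair ",
                        rownames(m)[i], "/", rownames(m)[j])
    p[i, j] <- p[j, i] <- mean(m[i, use] != m[j, use])
  }
  sat <- p >= 0.75
  diag(sat) <- FALSE
  if (any(sat) && saturated == "error")
    stop("saturated pair (p >= 0.75) in alignment")
  d <- ifelse(sat, Inf, -0.75 * log(pmax(1 - 4 * p / 3, .Machine$double.xmin)))
  diag(d) <- 0
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' [ape::nj()] with negative branch-length estimates clamped to zero.
#' Exact (topology and lengths) on additive matrices.
#'
#' @param dm symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return unrooted `phylo`.
#' @export
neighborJoining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(dm))) stop("distance matrix contains non-finite entries")
  phy <- ape::nj(dm)
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Concatenate gene alignments into a supermatrix
#'
#' Taxa missing from a gene are filled with gaps.  The returned alignment
#' carries a `partition_map` attribute (`data.frame(name, start, end)`,
#' 0-based half-open column ranges tiling the supermatrix).
#'
#' @param alignments named list of alignments (each a `DNAStringSet`,
#'   matrix or named character vector).
#' @return `DNAStringSet` supermatrix with attribute `partition_map`.
#' @export
concatenateAlignments <- function(alignments) {
  if (length(alignments) == 0) stop("no alignments given")
  if (is.null(names(alignments)) || anyDuplicated(names(alignments)))
    stop("alignments must have unique names (duplicate gene name?)")
  mats <- lapply(alignments, .alnMatrix)
  for (nm in names(mats)) {
    ids <- rownames(mats[[nm]])
    if (is.null(ids)) stop("alignment '", nm, "' has unnamed sequences")
    if (anyDuplicated(ids)) {
      dup <- ids[duplicated(ids)][1]
      rows <- mats[[nm]][ids == dup, , drop = FALSE]
      if (nrow(unique(rows)) > 1)
        stop("conflicting residues for duplicate taxon '", dup,
             "' in gene '", nm, "'")
      mats[[nm]] <- mats[[nm]][!duplicated(ids), , drop = FALSE]
    }
  }
  taxa <- Reduce(union, lapply(mats, rownames))
  lens <- vapply(mats, ncol, 1L)
  total <- sum(lens)
  out <- matrix("-", length(taxa), total, dimnames = list(taxa, NULL))
  at <- 0L
  pm <- data.frame(name = names(mats), start = integer(length(mats)),
                   end = integer(length(mats)))
  for (k in seq_along(mats)) {
    cols <- (at + 1L):(at + lens[k])
    out[rownames(mats[[k]]), cols] <- mats[[k]]
    pm$start[k] <- at
    pm$end[k] <- at + lens[k]
    at <- at + lens[k]
  }
  res <- .matrixToDNAStringSet(out)
  attr(res, "partition_map") <- pm
  res
}
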