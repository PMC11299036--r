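#' Default configuration for the packaged case study
#'
#' Study conditions of the packaged allopolyploidization scenario: 347
#' loci split over the three locus classes with the proportions
#' both-retained 0.3746, parent-1-retained 0.2334, parent-2-retained
#' 0.3919 (applied by exact quota by default), inheritance probability
#' gamma = 0.4511, a clock of 0.001 substitutions/site/Ma on a scale of
#' 20 Ma per coalescent unit, and 1200-bp loci.  Ks paralog pairs carry
#' two peaks at Ks 1.5 and 3.0 with 30% near-identical contamination.
#'
#' @param seed RNG seed.
#' @param nLoci number of loci.
#' @param sitesPerLocus alignment columns per locus.
#' @param gamma inheritance probability from the A side.
#' @param classMix named proportions (`both`, `parent1`, `parent2`).
#' @param quota apply the mix by exact quota (largest remainder); when
#'   `FALSE`, classes are drawn multinomially.
#' @param clockRate substitutions/site per coalescent unit.
#' @param maPerCoalUnit Ma per coalescent unit (for truth ages).
#' @param nKsPairs number of paralog pairs for the Ks stage.
#' @param ksContamination contamination fraction of the Ks pairs.
#' @return named list of configuration values.
#' @export
caseStudyConfig <- function(seed = 1, nLoci = 347, sitesPerLocus = 1200,
                            gamma = 0.4511,
                            classMix = c(both = 0.3746, parent1 = 0.2334,
                                         parent2 = 0.3919),
                            quota = TRUE, clockRate = 0.02,
                            maPerCoalUnit = 20, nKsPairs = 600,
                            ksContamination = 0.3) {
  classMix <- unlist(classMix)
  if (abs(sum(classMix) - 1) > 0.01)
    stop("classMix proportions must sum to 1")
  classMix <- classMix / sum(classMix)
  list(seed = seed, nLoci = nLoci, sitesPerLocus = sitesPerLocus,
       gamma = gamma, classMix = classMix, quota = quota,
       clockRate = clockRate, maPerCoalUnit = maPerCoalUnit,
       nKsPairs = nKsPairs, ksContamination = ksContamination)
}

# largest-remainder quota split of n into length(props) classes
.quotaCounts <- function(n, props) {
  raw <- n * props / sum(props)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Build the packaged synthetic case study
#'
#' Generates the complete input set for every pipeline stage: per-locus
#' alignments and true gene trees drawn from the multispecies coalescent
#' on the one-reticulation case-study network, the taxon-group scheme,
#' coding-sequence paralog pairs for the Ks stage, and a machine-readable
#' truth log (true gamma, per-locus classes, true node ages in Ma).
#' Locus classes are realized-topology classes: parent-1-retained loci are
#' routed to the A side and conditioned to show the focal clade sister to
#' superclade A (likewise for the other classes), mirroring how the
#' empirical gene sets are observed-topology partitions.
#'
#' @param config see [caseStudyConfig()].
#' @param dir optional output directory; when given, writes
#'   `loci/<locus>.fasta`, `trees/<locus>.nwk` (substitutions/site),
#'   `groups.yaml`, `ks_pairs.fasta` and `truth.json`.
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, a list with `loci` (named list of `DNAStringSet`),
#'   `trees` (true gene trees, substitutions/site), `cuTrees` (coalescent
#'   units), `classes`, `scheme`, `network`, `ksPairs`, `ksTruth` and
#'   `truth`.
#' @export
buildCaseStudy <- function(config = caseStudyConfig(), dir = NULL,
                           overwrite = FALSE) {
  if (!is.null(dir) && dir.exists(dir) && !overwrite &&
      length(list.files(dir)) > 0)
    stop("output directory exists; use overwrite = TRUE")
  .assertSeed(config$seed)
  network <- caseStudyNetwork(gamma = config$gamma)
  scheme <- caseStudyScheme()
  mix <- config$classMix[c("both", "parent1", "parent2")]
  classes <- if (isTRUE(config$quota)) {
    rep(names(mix), .quotaCounts(config$nLoci, mix))
  } else {
    as.character(sample(names(mix), config$nLoci, replace = TRUE,
                        prob = mix))
  }
  sideOf <- c(both = "both", parent1 = "parent1", parent2 = "parent2")
  condOf <- c(both = "sister_to_both", parent1 = "sister_to_A",
              parent2 = "sister_to_C")
  cuTrees <- vector("list", config$nLoci)
  loci <- vector("list", config$nLoci)
  ids <- sprintf("locus%04d", seq_len(config$nLoci))
  for (i in seq_len(config$nLoci)) {
    cl <- classes[i]
    tr <- .simulateMscNoSeed(network, 1, forceSide = sideOf[[cl]],
                             conditionOn = condOf[[cl]])[[1]]
    cuTrees[[i]] <- tr
    loci[[i]] <- .simAlignmentNoSeed(
      scaleToSubstitutions(tr, config$clockRate), config$sitesPerLocus)
  }
  names(cuTrees) <- names(loci) <- ids
  trees <- lapply(cuTrees, scaleToSubstitutions,
                  clockRate = config$clockRate)
  class(trees) <- "multiPhylo"
  class(cuTrees) <- "multiPhylo"
  ksPairs <- simulateParalogPairs(
    config$nKsPairs, contaminationFraction = config$ksContamination,
    seed = config$seed + 1)
  truth <- list(
    gamma = config$gamma, classes = stats::setNames(classes, ids),
    node_ages_ma = list(root = 18.5 * config$maPerCoalUnit,
                        earliest_split = 15.2 * config$maPerCoalUnit,
                        parental_split = 13.4 * config$maPerCoalUnit,
                        hybridization = 12.4 * config$maPerCoalUnit),
    clock_rate_per_cu = config$clockRate,
    ma_per_coal_unit = config$maPerCoalUnit,
    rate_per_ma = config$clockRate / config$maPerCoalUnit,
    seed = config$seed, config = config[setdiff(names(config), "classMix")],
    class_mix = as.list(config$classMix))
  out <- list(loci = loci, trees = trees, cuTrees = cuTrees,
              classes = stats::setNames(classes, ids), scheme = scheme,
              network = network, ksPairs = ksPairs,
              ksTruth = attr(ksPairs, "truth"), truth = truth)
  if (!is.null(dir)) .writeCaseStudy(out, dir)
  invisible(out)
}

.writeCaseStudy <- function(cs, dir) {
  dir.create(file.path(dir, "loci"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "trees"), showWarnings = FALSE)
  for (id in names(cs$loci)) {
    writeFasta(cs$loci[[id]], file.path(dir, "loci", paste0(id, ".fasta")))
    cat(writeNewick(cs$trees[[id]]), "\n", sep = "",
        file = file.path(dir, "trees", paste0(id, ".nwk")))
  }
  sch <- cs$scheme
  yaml::write_yaml(list(outgroup = as.list(sch@outgroup),
                        focal = as.list(sch@focal),
                        parent1 = as.list(sch@parent1),
                        parent2 = as.list(sch@parent2),
                        other = as.list(sch@other)),
                   file.path(dir, "groups.yaml"))
  if (length(cs$ksPairs)) {
    seqs <- unlist(lapply(cs$ksPairs, function(p)
      stats::setNames(c(p@aln1, p@aln2), c(p@id1, p@id2))))
    writeFasta(Biostrings::DNAStringSet(seqs),
               file.path(dir, "ks_pairs.fasta"))
  }
  jsonlite::write_json(cs$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a taxon-group scheme from a groups.yaml file
#'
#' @param path YAML file with keys `outgroup`, `focal`, `parent1`,
#'   `parent2` and optional `other`.
#' @return a [GroupScheme-class].
#' @export
readGroupScheme <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in c("outgroup", "focal", "parent1", "parent2"))
    if (is.null(y[[k]])) stop("groups file lacks '", k, "'")
  new("GroupScheme", outgroup = unlist(y$outgroup), focal = unlist(y$focal),
      parent1 = unlist(y$parent1), parent2 = unlist(y$parent2),
      other = if (is.null(y$other)) character(0) else unlist(y$other))
}
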