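#' Run the full inference pipeline
#'
#' Executes, in order: input generation or loading, ortholog filtering,
#' gene-set partitioning, Ks estimation with the redundancy cutoff and
#' peak fitting, the site-pattern hybridization test with individual
#' bootstrap, the triplet network fit, strict-clock dating of the two
#' conflicting gene sets and the split-time concordance diagnostic.  Any
#' stage failure aborts with the stage name and cause.
#'
#' @param config a configuration list or path to a YAML file.  Either
#'   `case_study:` (arguments of [caseStudyConfig()]) or `input_dir:` (a
#'   directory laid out like [buildCaseStudy()] output) must be present.
#'   Optional keys: `trees` (`"given"` to use the input gene trees,
#'   `"nj"` to re-estimate them by neighbor joining from the locus
#'   alignments; default `"auto"` uses input trees when present),
#'   `thresholds`
#'   (`ks_identity_cutoff`, `min_aligned_length`, `alpha`,
#'   `consistency_tolerance`, `support`), `bootstrap_reps`,
#'   `calibrations` (list of `{clade:, age_ma:}` where `clade` is a taxon
#'   vector or `"root"`/`"ingroup"`).
#' @param outDir optional output directory for `report.json` and
#'   per-stage TSVs.
#' @return the analysis report (list), invisibly when `outDir` is given.
#' @export
runFullAnalysis <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .normalizeConfig(config)
  log <- function(stage, fmt, ...) message(sprintf("[%s] %s", stage,
                                                   sprintf(fmt, ...)))
  run <- function(stage, expr) tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))

  # ---- inputs ---------------------------------------------------------
  cs <- run("inputs", {
    if (!is.null(cfg$input_dir)) .readInputs(cfg$input_dir)
    else do.call(caseStudyConfig, cfg$case_study) |> buildCaseStudy()
  })
  scheme <- cs$scheme
  log("inputs", "%d loci, %d Ks pairs", length(cs$loci),
      length(cs$ksPairs))

  # ---- gene trees -----------------------------------------------------
  treeMode <- cfg$trees
  if (treeMode == "auto")
    treeMode <- if (is.null(cs$trees)) "nj" else "given"
  usedTrees <- run("trees", {
    if (treeMode == "nj") {
      lapply(cs$loci, function(aln)
        neighborJoining(jcDistanceMatrix(aln)))
    } else {
      if (is.null(cs$trees)) stop("no input trees available")
      cs$trees
    }
  })
  rooted <- run("trees", lapply(usedTrees, rerootOutgroup,
                                outgroupTaxa = scheme@outgroup))
  log("trees", "%d gene trees (%s)", length(rooted), treeMode)

  # ---- ortholog filter ------------------------------------------------
  filt <- run("filter", {
    groups <- lapply(names(cs$loci), function(id) {
      aln <- cs$loci[[id]]
      members <- lapply(stats::setNames(nm = names(aln)), function(sp)
        stats::setNames(Biostrings::DNAStringSet(
          gsub("-", "", as.character(aln[sp]))), sp))
      new("HomologGroup", groupId = id, members = members,
          alignment = aln, tree = rooted[[id]])
    })
    filterOrthologs(groups, stage = "second_pass",
                    speciesRequired = c(scheme@outgroup, scheme@focal,
                                        scheme@parent1, scheme@parent2),
                    referenceClades = list(parent1 = scheme@parent1,
                                           parent2 = scheme@parent2,
                                           focal = scheme@focal),
                    minAlignedLength = cfg$thresholds$min_aligned_length)
  })
  keptIds <- vapply(filt$kept, function(g) g@groupId, "")
  log("filter", "%d of %d loci pass", length(keptIds), length(cs$loci))
  if (length(keptIds) == 0) stop("stage 'filter' failed: no locus passed")

  # ---- gene-set partition --------------------------------------------
  part <- run("sort", partitionGeneSets(rooted[keptIds], scheme,
                                        cfg$thresholds$support))
  log("sort", "counts %s", paste(part@counts, collapse = "/"))
  pattern <- run("sort", ilsVsHybridPattern(part@counts[1:3],
                                            cfg$thresholds$alpha))

  # ---- Ks -------------------------------------------------------------
  ksRes <- run("ks", {
    if (length(cs$ksPairs) == 0) NULL else {
      tabAll <- ksTable(cs$ksPairs)
      kept <- identityCutoffFilter(tabAll, cfg$thresholds$ks_identity_cutoff)
      peaks <- fitKsPeaks(kept$ks, seed = cfg$seed)
      list(table = tabAll, kept = kept, removed = attr(kept, "removed"),
           peaks = peaks)
    }
  })
  if (!is.null(ksRes))
    log("ks", "%d pairs, %d removed by cutoff, Ks1 = %.3f",
        nrow(ksRes$table), ksRes$removed, ksRes$peaks@labels[["Ks1"]])

  # ---- hybridization test --------------------------------------------
  hyde <- run("hyde", {
    supermatrix <- concatenateAlignments(cs$loci[keptIds])
    roleMap <- list(outgroup = c(scheme@outgroup, scheme@other),
                    p1 = scheme@parent1, hybrid = scheme@focal,
                    p2 = scheme@parent2)
    spc <- countSitePatterns(supermatrix, roleMap)
    test <- hydeGammaTest(spc, alpha = cfg$thresholds$alpha)
    boot <- bootstrapHybridTest(spc, nReps = cfg$bootstrap_reps,
                                seed = cfg$seed + 2,
                                alpha = cfg$thresholds$alpha)
    list(counts = spc, test = test, boot = boot)
  })
  log("hyde", "gamma = %.4f, Z = %.2f", hyde$test@gammaHat,
      hyde$test@zScore)

  # ---- network fit ----------------------------------------------------
  netfit <- run("netfit", {
    tc <- tripletFrequencies(rooted[keptIds],
                             list(A = scheme@parent1, B = scheme@focal,
                                  C = scheme@parent2))
    fitTripletNetwork(tc)
  })
  log("netfit", "gamma = %.4f", netfit@gammaHat)

  # ---- dating ---------------------------------------------------------
  dating <- run("date", {
    cls <- part@assignments[keptIds]
    lociB <- keptIds[cls == "sister_to_A"]
    lociC <- keptIds[cls == "sister_to_C"]
    if (length(lociB) < 2 || length(lociC) < 2)
      stop("too few loci in a gene set for dating")
    dateSet <- function(ids) {
      sm <- concatenateAlignments(cs$loci[ids])
      tr <- rerootOutgroup(neighborJoining(jcDistanceMatrix(sm)),
                           scheme@outgroup)
      # the root position along the outgroup branch is not identifiable
      # without a clock, so dating uses the ingroup tree only, with the
      # deepest retained split calibrated
      tr <- ape::drop.tip(tr, intersect(scheme@outgroup, tr$tip.label))
      strictClockDates(tr, .resolveCalibrations(cfg$calibrations, scheme))
    }
    chB <- dateSet(lociB); chC <- dateSet(lociC)
    cons <- hybridTimeConsistency(chB, chC, scheme,
                                  cfg$thresholds$consistency_tolerance)
    list(chronoB = chB, chronoC = chC, consistency = cons)
  })
  log("date", "verdict: %s", dating$consistency@verdict)

  # ---- report ---------------------------------------------------------
  report <- .assembleReport(cfg, part, pattern, ksRes, hyde, netfit, dating)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(
      data.frame(locus = names(part@assignments),
                 class = unname(part@assignments)),
      file.path(outDir, "gene_sets.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (!is.null(ksRes))
      utils::write.table(ksRes$table, file.path(outDir, "ks_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(filt$reports, file.path(outDir, "filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(report))
  }
  report
}

.normalizeConfig <- function(config) {
  if (is.null(config$case_study) && is.null(config$input_dir))
    stop("config needs either 'case_study' or 'input_dir'")
  if (!is.null(config$input_dir) &&
      !file.exists(file.path(config$input_dir, "groups.yaml")))
    stop("input_dir lacks groups.yaml")
  th <- config$thresholds
  defaults <- list(redundancy_identity = 0.98, ks_identity_cutoff = 0.90,
                   min_aligned_length = 1000, alpha = 0.05,
                   consistency_tolerance = 0.05, support = 0)
  for (k in names(defaults)) if (is.null(th[[k]])) th[[k]] <- defaults[[k]]
  seed <- config$seed
  if (is.null(seed)) seed <- config$case_study$seed
  if (is.null(seed)) stop("config must set a seed")
  if (!is.null(config$case_study) && is.null(config$case_study$seed))
    config$case_study$seed <- seed
  list(case_study = config$case_study, input_dir = config$input_dir,
       trees = if (is.null(config$trees)) "auto" else config$trees,
       thresholds = th,
       bootstrap_reps = if (is.null(config$bootstrap_reps)) 200
         else config$bootstrap_reps,
       calibrations = config$calibrations, seed = seed)
}

.resolveCalibrations <- function(cals, scheme) {
  allTaxa <- c(scheme@outgroup, scheme@other, scheme@focal,
               scheme@parent1, scheme@parent2)
  ingroup <- setdiff(allTaxa, scheme@outgroup)
  if (is.null(cals))
    cals <- list(list(clade = "ingroup", age_ma = 304))
  lapply(cals, function(cl) {
    clade <- cl$clade
    if (identical(clade, "root")) clade <- allTaxa
    else if (identical(clade, "ingroup")) clade <- ingroup
    calibration(unlist(clade), cl$age_ma)
  })
}

.readInputs <- function(dir) {
  scheme <- readGroupScheme(file.path(dir, "groups.yaml"))
  lf <- sort(list.files(file.path(dir, "loci"), pattern = "\\.fasta$",
                        full.names = TRUE))
  if (length(lf) == 0) stop("no loci found under ", dir)
  loci <- lapply(lf, readFasta)
  names(loci) <- sub("\\.fasta$", "", basename(lf))
  tf <- file.path(dir, "trees", paste0(names(loci), ".nwk"))
  trees <- NULL
  if (all(file.exists(tf))) {
    trees <- lapply(tf, function(f) parseNewick(readLines(f, warn = FALSE)))
    names(trees) <- names(loci)
    class(trees) <- "multiPhylo"
  }
  ksPairs <- list()
  kf <- file.path(dir, "ks_pairs.fasta")
  if (file.exists(kf)) {
    seqs <- readFasta(kf)
    stems <- unique(sub("_[ab]$", "", names(seqs)))
    ksPairs <- lapply(stems, function(s)
      codonPair(as.character(seqs[[paste0(s, "_a")]]),
                as.character(seqs[[paste0(s, "_b")]]),
                id1 = paste0(s, "_a"), id2 = paste0(s, "_b")))
  }
  list(loci = loci, trees = trees, scheme = scheme, ksPairs = ksPairs)
}

.assembleReport <- function(cfg, part, pattern, ksRes, hyde, netfit,
                            dating) {
  cfgJson <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfgJson, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  st <- dating$consistency@splitTimes@ages
  list(
    provenance = list(package_version =
                        as.character(utils::packageVersion("paleohybrid")),
                      seed = cfg$seed, config_md5 = hash),
    gene_sets = list(counts = as.list(part@counts),
                     percentages = as.list(part@percentages),
                     pattern_verdict = pattern$verdict),
    ks = if (is.null(ksRes)) "skipped" else list(
      n_pairs = nrow(ksRes$table), removed_by_cutoff = ksRes$removed,
      peaks = list(means = ksRes$peaks@means, sds = ksRes$peaks@sds,
                   weights = ksRes$peaks@weights,
                   labels = as.list(ksRes$peaks@labels))),
    hybrid_test = list(gamma = hyde$test@gammaHat, z = hyde$test@zScore,
                       p = hyde$test@pValue,
                       significant = hyde$test@significant,
                       bootstrap = list(
                         fraction_significant =
                           hyde$boot@fractionSignificant,
                         gamma_min = hyde$boot@gammaRange[1],
                         gamma_max = hyde$boot@gammaRange[2])),
    network_fit = list(gamma = netfit@gammaHat, tA = netfit@tA,
                       tC = netfit@tC,
                       identifiable = netfit@identifiable),
    chronology = list(split_times_ma = as.list(st),
                      parental_split_diff = dating$consistency@parentalSplitDiff,
                      hybrid_age_diff = dating$consistency@hybridAgeDiff,
                      verdict = dating$consistency@verdict))
}
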