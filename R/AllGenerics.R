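#' Accessors for paleohybrid result objects
#'
#' Small accessor generics so user code never reaches into slots:
#' `gammaHat()` returns the estimated inheritance probability,
#' `classCounts()` the gene-set or triplet counts, `ksPeaks()` the fitted
#' mixture component table, `verdict()` the diagnostic verdict and
#' `splitAges()` the named divergence times.
#'
#' @param object a paleohybrid result object.
#' @return The accessed component (numeric, named numeric or data.frame).
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("gammaHat", function(object) standardGeneric("gammaHat"))

#' @rdname accessors
#' @export
setGeneric("classCounts", function(object) standardGeneric("classCounts"))

#' @rdname accessors
#' @export
setGeneric("ksPeaks", function(object) standardGeneric("ksPeaks"))

#' @rdname accessors
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setGeneric("splitAges", function(object) standardGeneric("splitAges"))

#' @rdname accessors
#' @export
setMethod("gammaHat", "HybridTestResult", function(object) object@gammaHat)

#' @rdname accessors
#' @export
setMethod("gammaHat", "NetworkFit", function(object) object@gammaHat)

#' @rdname accessors
#' @export
setMethod("gammaHat", "BootstrapResult", function(object) object@gammaSamples)

#' @rdname accessors
#' @export
setMethod("gammaHat", "SpeciesNetwork", function(object) object@gamma)

#' @rdname accessors
#' @export
setMethod("classCounts", "GeneSetPartition", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("classCounts", "TripletCounts", function(object)
  c(AB = object@nAB, AC = object@nAC, BC = object@nBC,
    unclassified = object@nUnclassified))

#' @rdname accessors
#' @export
setMethod("ksPeaks", "KsPeakModel", function(object)
  data.frame(mean = object@means, sd = object@sds, weight = object@weights))

#' @rdname accessors
#' @export
setMethod("verdict", "ConsistencyReport", function(object) object@verdict)

#' @rdname accessors
#' @export
setMethod("splitAges", "SplitTimes", function(object) object@ages)

#' @rdname accessors
#' @export
setMethod("splitAges", "ConsistencyReport", function(object)
  object@splitTimes@ages)

setMethod("show", "SpeciesNetwork", function(object) {
  cat("SpeciesNetwork:", length(object@backbone$tip.label), "backbone taxa,",
      length(object@hybridTips), "hybrid taxa\n")
  cat("  gamma =", object@gamma,
      sprintf("(P1 side: %s)\n", paste(object@parent1Clade, collapse = ",")))
  cat("  attachment heights:", object@parent1Height, "/",
      object@parent2Height, "coalescent units\n")
})

setMethod("show", "GroupScheme", function(object) {
  cat("GroupScheme\n")
  cat("  outgroup:", paste(object@outgroup, collapse = ", "), "\n")
  cat("  focal   :", paste(object@focal, collapse = ", "), "\n")
  cat("  parent1 :", paste(object@parent1, collapse = ", "), "\n")
  cat("  parent2 :", paste(object@parent2, collapse = ", "), "\n")
  if (length(object@other))
    cat("  other   :", paste(object@other, collapse = ", "), "\n")
})

setMethod("show", "GeneSetPartition", function(object) {
  cat("GeneSetPartition over", sum(object@counts), "trees\n")
  print(object@counts)
  cat("resolved-class percentages:\n")
  print(object@percentages)
})

setMethod("show", "TripletCounts", function(object) {
  g <- object@groups
  cat(sprintf("TripletCounts (%s): %s|%s=%d  %s|%s=%d  %s|%s=%d  unclassified=%d\n",
              paste(g, collapse = ","), g[1], g[2], as.integer(object@nAB),
              g[1], g[3], as.integer(object@nAC),
              g[2], g[3], as.integer(object@nBC),
              as.integer(object@nUnclassified)))
})

setMethod("show", "KsEstimate", function(object) {
  cat(sprintf("KsEstimate: Ks=%s Ka=%s (S=%.2f, N=%.2f, identity=%.3f%s)\n",
              format(object@ks, digits = 4), format(object@ka, digits = 4),
              object@sSites, object@nSites, object@identity,
              if (isTRUE(object@saturated)) ", saturated" else ""))
})

setMethod("show", "KsPeakModel", function(object) {
  cat("KsPeakModel:", length(object@means), "component(s), BIC =",
      round(object@bic, 2), "on n =", object@n, "\n")
  print(ksPeaks(object))
  if (length(object@labels)) print(round(object@labels, 4))
})

setMethod("show", "HybridTestResult", function(object) {
  cat(sprintf("Hybridization test: gamma = %.4f, Z = %.4f, p = %.4g (%s at alpha=%g)\n",
              object@gammaHat, object@zScore, object@pValue,
              if (object@significant) "significant" else "not significant",
              object@alpha))
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("Bootstrap: %d replicates, %.1f%% significant, gamma in [%.4f, %.4f]\n",
              length(object@gammaSamples), 100 * object@fractionSignificant,
              object@gammaRange[1], object@gammaRange[2]))
})

setMethod("show", "NetworkFit", function(object) {
  cat(sprintf("NetworkFit: gamma = %.4f, tA = %.3f, tC = %.3f, logPL = %.2f%s%s\n",
              object@gammaHat, object@tA, object@tC, object@logPL,
              if (object@equalDepths) " (equal depths)" else "",
              if (!object@identifiable) " [NOT identifiable]" else ""))
})

setMethod("show", "Chronogram", function(object) {
  cat(sprintf("Chronogram: %d tips, root age %.2f Ma, rate %.6f subst/site/Ma\n",
              length(object@tree$tip.label), max(object@ages), object@rate))
})

setMethod("show", "SplitTimes", function(object) {
  cat("SplitTimes (Ma):\n"); print(round(object@ages, 2))
})

setMethod("show", "ConsistencyReport", function(object) {
  cat(sprintf("ConsistencyReport: verdict = %s\n", object@verdict))
  cat(sprintf("  parental split diff %.2f Ma (rel %.3f); hybrid age diff %.2f Ma (rel %.3f)\n",
              object@parentalSplitDiff, object@relParental,
              object@hybridAgeDiff, object@relHybrid))
})

setMethod("show", "SaturationReport", function(object) {
  cat(sprintf("SaturationReport: iss = %.4f, critical = %.4f -> %s\n",
              object@iss, object@issCritical,
              if (object@saturated) "saturated" else "not saturated"))
})

setMethod("show", "SitePatternCounts", function(object) {
  cat("SitePatternCounts:", object@nUsed, "sites used,",
      object@nSkipped, "skipped\n")
  print(object@counts)
})
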