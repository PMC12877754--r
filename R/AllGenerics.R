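#' @name accessors
#' @title Accessors for GaudiHiC classes
#' @param x an object.
#' @description Slot accessors; user code should use these rather than `@`.
NULL

#' @rdname accessors
#' @export
setGeneric("regionOf", function(x) standardGeneric("regionOf"))
#' @rdname accessors
#' @export
setGeneric("regionChrom", function(x) standardGeneric("regionChrom"))
#' @rdname accessors
#' @export
setGeneric("regionStart", function(x) standardGeneric("regionStart"))
#' @rdname accessors
#' @export
setGeneric("regionEnd", function(x) standardGeneric("regionEnd"))
#' @rdname accessors
#' @export
setGeneric("regionWidth", function(x) standardGeneric("regionWidth"))
#' @rdname accessors
#' @export
setGeneric("binResolution", function(x) standardGeneric("binResolution"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("binStarts", function(x) standardGeneric("binStarts"))
#' @rdname accessors
#' @export
setGeneric("contactValues", function(x) standardGeneric("contactValues"))
#' @rdname accessors
#' @export
setGeneric("isBalanced", function(x) standardGeneric("isBalanced"))
#' @rdname accessors
#' @export
setGeneric("binBiases", function(x) standardGeneric("binBiases"))
#' @rdname accessors
#' @export
setGeneric("maskedBins", function(x) standardGeneric("maskedBins"))
#' @rdname accessors
#' @export
setGeneric("layoutCoords", function(x) standardGeneric("layoutCoords"))
#' @rdname accessors
#' @export
setGeneric("meanInterbin", function(x) standardGeneric("meanInterbin"))
#' @rdname accessors
#' @export
setGeneric("layoutStress", function(x) standardGeneric("layoutStress"))
#' @rdname accessors
#' @export
setGeneric("occupancyPolygons", function(x) standardGeneric("occupancyPolygons"))
#' @rdname accessors
#' @export
setGeneric("polygonAreas", function(x) standardGeneric("polygonAreas"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("memberBins", function(x) standardGeneric("memberBins"))
#' @rdname accessors
#' @export
setGeneric("memberRegions", function(x) standardGeneric("memberRegions"))
#' @rdname accessors
#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))
#' @rdname accessors
#' @export
setGeneric("motifMatrix", function(x) standardGeneric("motifMatrix"))
#' @rdname accessors
#' @export
setGeneric("motifBackground", function(x) standardGeneric("motifBackground"))
#' @rdname accessors
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))
#' @rdname accessors
#' @export
setGeneric("motifConsensus", function(x) standardGeneric("motifConsensus"))
#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

setMethod("regionOf", "GenomicRegion", function(x) x)
setMethod("regionOf", "BinGrid", function(x) x@region)
setMethod("regionOf", "SignalTrack", function(x) x@region)
setMethod("regionOf", "ContactMatrix", function(x) x@grid@region)
setMethod("regionOf", "SpatialLayout", function(x) x@grid@region)

setMethod("regionChrom", "GenomicRegion", function(x) x@chrom)
setMethod("regionStart", "GenomicRegion", function(x) x@start)
setMethod("regionEnd", "GenomicRegion", function(x) x@end)
setMethod("regionWidth", "GenomicRegion", function(x) x@end - x@start)

setMethod("binResolution", "BinGrid", function(x) x@resolution)
setMethod("binResolution", "ContactMatrix", function(x) x@grid@resolution)
setMethod("nBins", "BinGrid", function(x) length(x@binStarts))
setMethod("nBins", "ContactMatrix", function(x) length(x@grid@binStarts))
setMethod("nBins", "SpatialLayout", function(x) length(x@grid@binStarts))
setMethod("binStarts", "BinGrid", function(x) x@binStarts)
setMethod("binStarts", "ContactMatrix", function(x) x@grid@binStarts)

setMethod("contactValues", "ContactMatrix", function(x) x@values)
setMethod("isBalanced", "ContactMatrix", function(x) x@balanced)
setMethod("binBiases", "ContactMatrix", function(x) x@biases)
setMethod("maskedBins", "ContactMatrix", function(x) x@masked)
setMethod("maskedBins", "SpatialLayout", function(x) x@masked)
setMethod("maskedBins", "InteractionGraph", function(x) x@masked)

setMethod("layoutCoords", "SpatialLayout", function(x) x@xy)
setMethod("layoutCoords", "GaudiPlot", function(x) x@layout@xy)
setMethod("meanInterbin", "SpatialLayout", function(x) x@meanInterbin)
setMethod("meanInterbin", "GaudiPlot", function(x) x@layout@meanInterbin)
setMethod("layoutStress", "SpatialLayout", function(x) x@stress)

setMethod("occupancyPolygons", "GaudiPlot", function(x) x@polygons)
setMethod("polygonAreas", "GaudiPlot", function(x) x@areas)
setMethod("graphEdges", "InteractionGraph", function(x) x@edges)

setMethod("memberBins", "NeighborhoodSelection", function(x) x@memberBins)
setMethod("memberRegions", "NeighborhoodSelection", function(x) x@memberRegions)

setMethod("motifName", "PWMotif", function(x) x@name)
setMethod("motifMatrix", "PWMotif", function(x) x@matrix)
setMethod("motifBackground", "PWMotif", function(x) x@background)
setMethod("motifLength", "PWMotif", function(x) ncol(x@matrix))
setMethod("motifConsensus", "PWMotif", function(x) {
  paste(rownames(x@matrix)[apply(x@matrix, 2L, which.max)], collapse = "")
})

setMethod("trackValues", "SignalTrack", function(x) {
  data.frame(start = x@starts, end = x@ends, value = x@values)
})

setMethod("show", "GenomicRegion", function(object) {
  cat("GenomicRegion ", formatRegion(object),
      " (0-based half-open, width ", format(regionWidth(object), big.mark = ","),
      " bp)\n", sep = "")
})

setMethod("show", "BinGrid", function(object) {
  cat("BinGrid over ", formatRegion(object@region), ": ",
      nBins(object), " bins of ", object@resolution, " bp\n", sep = "")
})

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack over ", formatRegion(object@region), ": ",
      length(object@starts), " intervals\n", sep = "")
})

setMethod("show", "PWMotif", function(object) {
  cat("PWMotif ", object@name, " (", ncol(object@matrix),
      " bp, consensus ", motifConsensus(object), ")\n", sep = "")
})

setMethod("show", "ContactMatrix", function(object) {
  cat("ContactMatrix: ", nBins(object), " x ", nBins(object), " bins (",
      object@grid@resolution, " bp), ",
      if (object@balanced) "balanced" else "raw", ", ",
      sum(object@masked), " masked\n", sep = "")
})

setMethod("show", "InteractionGraph", function(object) {
  cat("InteractionGraph: ", object@nNodes, " nodes, ",
      sum(!object@edges$backbone), " selected + ",
      sum(object@edges$backbone), " backbone edges\n", sep = "")
})

setMethod("show", "SpatialLayout", function(object) {
  cat("SpatialLayout: ", sum(!object@masked), " bins embedded, stress ",
      signif(object@stress, 4), ", mean interbin distance ",
      signif(object@meanInterbin, 4), "\n", sep = "")
})

setMethod("show", "GaudiPlot", function(object) {
  cat("GaudiPlot: ", length(object@polygons),
      " occupancy polygons, buffer radius ",
      signif(object@bufferRadius, 4), "\n", sep = "")
})

setMethod("show", "NeighborhoodSelection", function(object) {
  cat("NeighborhoodSelection: TSS bin ", object@tssBin, ", radius ",
      signif(object@radius, 4), ", ", length(object@memberBins),
      " member bins\n", sep = "")
})

setMethod("show", "GaudiConfig", function(object) {
  cat("GaudiConfig:\n",
      "  resolution           ", object@resolution, " bp\n",
      "  topFraction          ", object@topFraction, "\n",
      "  bufferFactor         ", object@bufferFactor, "\n",
      "  neighborhoodFactor   ", object@neighborhoodFactor, "\n",
      "  contributionQuantile ", object@contributionQuantile, "\n",
      "  pwmScoreFraction     ", object@pwmScoreFraction, "\n",
      "  seed                 ", object@seed, "\n", sep = "")
})
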