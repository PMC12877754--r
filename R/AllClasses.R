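#' @import methods
#' @importFrom stats quantile setNames median fisher.test p.adjust rnorm rpois runif cmdscale dist optim
#' @importFrom utils read.table write.table packageVersion head tail
NULL

#' GenomicRegion: a half-open genomic interval
#'
#' Coordinates are 0-based, half-open (`[start, end)`), the convention of
#' BED/bedGraph and of binned Hi-C matrix tooling. All package functions use
#' this convention; use [asGRanges()] to convert to the 1-based closed
#' convention of \pkg{GenomicRanges}.
#'
#' @slot chrom chromosome name.
#' @slot start 0-based inclusive start.
#' @slot end exclusive end; must exceed `start`.
#' @export
setClass("GenomicRegion",
  representation(chrom = "character", start = "numeric", end = "numeric"))

setValidity("GenomicRegion", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L || is.na(object@chrom) || !nzchar(object@chrom))
    msg <- c(msg, "'chrom' must be a single non-empty string")
  if (length(object@start) != 1L || length(object@end) != 1L)
    msg <- c(msg, "'start' and 'end' must be single numbers")
  else {
    if (object@start != floor(object@start) || object@end != floor(object@end))
      msg <- c(msg, "'start' and 'end' must be whole numbers")
    if (object@start < 0) msg <- c(msg, "'start' must be >= 0")
    if (object@start >= object@end) msg <- c(msg, "'start' must be < 'end'")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GenomicRegion-class
#' @param chrom,start,end region fields (0-based half-open).
#' @export
GenomicRegion <- function(chrom, start, end) {
  new("GenomicRegion", chrom = as.character(chrom),
      start = as.numeric(start), end = as.numeric(end))
}

#' BinGrid: a fixed-resolution tiling of a region
#'
#' Tiles `region` into `nBins = ceiling(width / resolution)` bins of width
#' `resolution`; the final bin is clipped at the region end so the bins tile
#' the region exactly.
#'
#' @slot region a [GenomicRegion-class].
#' @slot resolution bin width in bp.
#' @slot binStarts ascending 0-based bin start positions.
#' @export
setClass("BinGrid",
  representation(region = "GenomicRegion", resolution = "numeric",
                 binStarts = "numeric"))

setValidity("BinGrid", function(object) {
  msg <- character()
  if (object@resolution <= 0) msg <- c(msg, "'resolution' must be > 0")
  n <- ceiling((object@region@end - object@region@start) / object@resolution)
  if (length(object@binStarts) != n)
    msg <- c(msg, "binStarts length does not tile the region")
  else if (length(object@binStarts) &&
           (object@binStarts[1L] != object@region@start ||
            any(diff(object@binStarts) != object@resolution)))
    msg <- c(msg, "binStarts must step from region start by 'resolution'")
  if (length(msg)) msg else TRUE
})

#' SignalTrack: a per-base step function over a region
#'
#' Non-overlapping, sorted half-open intervals with real values; bases not
#' covered by any interval carry the value 0 (coverage-track semantics).
#'
#' @slot region a [GenomicRegion-class].
#' @slot starts,ends 0-based half-open interval bounds, sorted, within region.
#' @slot values one value per interval.
#' @export
setClass("SignalTrack",
  representation(region = "GenomicRegion", starts = "numeric",
                 ends = "numeric", values = "numeric"))

setValidity("SignalTrack", function(object) {
  msg <- character()
  n <- length(object@starts)
  if (length(object@ends) != n || length(object@values) != n)
    msg <- c(msg, "starts, ends and values must have equal length")
  else if (n) {
    if (any(object@ends <= object@starts))
      msg <- c(msg, "every interval must have end > start")
    if (is.unsorted(object@starts, strictly = FALSE))
      msg <- c(msg, "intervals must be sorted by start")
    if (n > 1L && any(object@starts[-1L] < object@ends[-n]))
      msg <- c(msg, "intervals must not overlap")
    if (object@starts[1L] < object@region@start ||
        object@ends[n] > object@region@end)
      msg <- c(msg, "intervals must lie within the region")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' PWMotif: a position probability model of a TF binding motif
#'
#' @slot name motif name as read from the source file.
#' @slot matrix 4 x L probability matrix, rows A, C, G, T; each column sums
#'   to 1 and every entry is strictly positive (pseudocount already applied).
#' @slot background length-4 base frequencies summing to 1.
#' @slot pseudocount pseudocount used to regularize count matrices.
#' @export
setClass("PWMotif",
  representation(name = "character", matrix = "matrix",
                 background = "numeric", pseudocount = "numeric"))

setValidity("PWMotif", function(object) {
  msg <- character()
  m <- object@matrix
  if (nrow(m) != 4L || is.null(rownames(m)) ||
      !identical(rownames(m), c("A", "C", "G", "T")))
    msg <- c(msg, "matrix must have rows A, C, G, T")
  else {
    if (any(m <= 0)) msg <- c(msg, "all probabilities must be > 0")
    if (any(abs(colSums(m) - 1) > 1e-6))
      msg <- c(msg, "each position must sum to 1 (tolerance 1e-6)")
  }
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-6 || any(object@background <= 0))
    msg <- c(msg, "background must be 4 positive frequencies summing to 1")
  if (length(msg)) msg else TRUE
})

#' ContactMatrix: binned intrachromosomal Hi-C counts
#'
#' Symmetric, non-negative matrix over a [BinGrid-class]. Bins whose row is
#' all zero are masked; after ICE balancing `biases` holds the per-bin
#' correction factors (NA for masked bins) such that
#' `balanced[i,j] * biases[i] * biases[j]` reproduces the raw input.
#'
#' @slot grid the [BinGrid-class].
#' @slot values nBins x nBins matrix.
#' @slot balanced logical flag.
#' @slot biases per-bin positive factors (NA when masked or unbalanced).
#' @slot masked logical per bin.
#' @export
setClass("ContactMatrix",
  representation(grid = "BinGrid", values = "matrix", balanced = "logical",
                 biases = "numeric", masked = "logical"))

setValidity("ContactMatrix", function(object) {
  msg <- character()
  v <- object@values
  n <- length(object@grid@binStarts)
  if (!identical(dim(v), c(n, n)))
    msg <- c(msg, "values must be nBins x nBins")
  else {
    if (!isTRUE(all.equal(v, t(v), check.attributes = FALSE, tolerance = 0)))
      msg <- c(msg, "values must be exactly symmetric")
    if (any(v < 0)) msg <- c(msg, "values must be non-negative")
    if (length(object@masked) != n)
      msg <- c(msg, "masked must have one entry per bin")
    else if (any(object@masked & rowSums(abs(v)) > 0))
      msg <- c(msg, "masked bins must have all-zero rows")
  }
  if (length(msg)) msg else TRUE
})

#' InteractionGraph: the top-interaction graph over bins
#'
#' Edges carry the log10-transformed interaction weight `w` and the derived
#' distance `d = 1/w`. Backbone edges connect genomically consecutive
#' unmasked bins and guarantee connectivity; they are marked `backbone`.
#'
#' @slot nNodes number of bins of the originating grid.
#' @slot edges data.frame with columns i, j (0-based bin indices, i < j),
#'   w, d, backbone.
#' @slot masked logical per bin.
#' @export
setClass("InteractionGraph",
  representation(nNodes = "integer", edges = "data.frame", masked = "logical"))

setValidity("InteractionGraph", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("i", "j", "w", "d", "backbone")
  if (!all(need %in% names(e)))
    msg <- c(msg, "edges must have columns i, j, w, d, backbone")
  else if (nrow(e)) {
    if (any(e$i >= e$j)) msg <- c(msg, "edges must satisfy i < j")
    if (any(e$d <= 0)) msg <- c(msg, "edge distances must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' SpatialLayout: 2D Kamada-Kawai coordinates per bin
#'
#' @slot grid the [BinGrid-class].
#' @slot xy nBins x 2 coordinates (NA rows for masked bins).
#' @slot meanInterbin mean layout distance between genomically consecutive
#'   unmasked bins; the unit of the buffer and neighborhood radii.
#' @slot stress final stress of the embedding.
#' @slot seed seed recorded for provenance.
#' @slot masked logical per bin.
#' @export
setClass("SpatialLayout",
  representation(grid = "BinGrid", xy = "matrix", meanInterbin = "numeric",
                 stress = "numeric", seed = "integer", masked = "logical"))

setValidity("SpatialLayout", function(object) {
  msg <- character()
  n <- length(object@grid@binStarts)
  if (!identical(dim(object@xy), c(n, 2L)))
    msg <- c(msg, "xy must be nBins x 2")
  if (length(object@masked) != n)
    msg <- c(msg, "masked must have one entry per bin")
  if (sum(!object@masked) >= 2L &&
      (!is.finite(object@meanInterbin) || object@meanInterbin <= 0))
    msg <- c(msg, "meanInterbin must be positive")
  if (length(msg)) msg else TRUE
})

#' GaudiPlot: per-bin spatial occupancy polygons with optional signal
#'
#' One closed counter-clockwise polygon per unmasked bin, obtained by
#' intersecting the bin's buffer disc with its Voronoi cell; polygons are
#' pairwise interior-disjoint.
#'
#' @slot layout the [SpatialLayout-class].
#' @slot polygons named list (by 0-based bin index) of k x 2 vertex matrices.
#' @slot areas per-polygon shoelace areas.
#' @slot signal optional per-unmasked-bin signal values (NA allowed).
#' @slot bufferRadius the buffer-disc radius in layout units.
#' @export
setClass("GaudiPlot",
  representation(layout = "SpatialLayout", polygons = "list",
                 areas = "numeric", signal = "numeric",
                 bufferRadius = "numeric"))

setValidity("GaudiPlot", function(object) {
  msg <- character()
  if (length(object@areas) != length(object@polygons))
    msg <- c(msg, "areas must parallel polygons")
  if (any(object@areas < -1e-12)) msg <- c(msg, "areas must be non-negative")
  if (length(msg)) msg else TRUE
})

#' NeighborhoodSelection: bins spatially proximal to a TSS bin
#'
#' @slot tssBin 0-based index of the TSS-containing bin.
#' @slot radius selection radius in layout units
#'   (neighborhood factor x mean interbin distance).
#' @slot memberBins 0-based indices of bins within `radius` of the TSS bin.
#' @slot memberRegions data.frame (chrom, start, end) of member-bin intervals.
#' @export
setClass("NeighborhoodSelection",
  representation(tssBin = "integer", radius = "numeric",
                 memberBins = "integer", memberRegions = "data.frame"))

setValidity("NeighborhoodSelection", function(object) {
  if (!(object@tssBin %in% object@memberBins))
    "tssBin must be among memberBins" else TRUE
})

#' GaudiConfig: the tunable parameters of the pipeline
#'
#' Defaults are the published procedural parameters: 5,000 bp bins, top 20%
#' of interactions, buffer radius 1.5x and neighborhood radius 3.0x the mean
#' interbin distance, top 10% of contribution scores. The remaining fields
#' are geometry/scanning plumbing with documented defaults.
#'
#' @param resolution bin width in bp.
#' @param topFraction fraction of nonzero interactions kept as graph edges.
#' @param bufferFactor buffer-disc radius in units of mean interbin distance.
#' @param neighborhoodFactor TSS neighborhood radius in the same units.
#' @param contributionQuantile per-base quantile defining "top" contribution
#'   scores (0.90 keeps the top 10%).
#' @param pwmScoreFraction motif hit threshold as a fraction of the motif's
#'   maximum attainable log-odds.
#' @param dummyCount number of dummy nodes closing the Voronoi diagram.
#' @param dummyRadiusFactor dummy-ring radius as a multiple of the layout's
#'   maximum centroid distance.
#' @param discSegments number of sides of the polygon approximating the
#'   buffer disc.
#' @param seed integer seed recorded for provenance.
#' @export
setClass("GaudiConfig",
  representation(resolution = "numeric", topFraction = "numeric",
                 bufferFactor = "numeric", neighborhoodFactor = "numeric",
                 contributionQuantile = "numeric",
                 pwmScoreFraction = "numeric", dummyCount = "integer",
                 dummyRadiusFactor = "numeric", discSegments = "integer",
                 seed = "integer"))

setValidity("GaudiConfig", function(object) {
  msg <- character()
  if (object@resolution <= 0) msg <- c(msg, "resolution must be > 0")
  if (object@topFraction <= 0 || object@topFraction > 1)
    msg <- c(msg, "topFraction must be in (0, 1]")
  if (object@bufferFactor <= 0) msg <- c(msg, "bufferFactor must be > 0")
  if (object@neighborhoodFactor < 0)
    msg <- c(msg, "neighborhoodFactor must be >= 0")
  if (object@contributionQuantile <= 0 || object@contributionQuantile >= 1)
    msg <- c(msg, "contributionQuantile must be in (0, 1)")
  if (object@pwmScoreFraction < 0 || object@pwmScoreFraction > 1)
    msg <- c(msg, "pwmScoreFraction must be in [0, 1]")
  if (object@discSegments < 8L) msg <- c(msg, "discSegments must be >= 8")
  if (length(msg)) msg else TRUE
})

#' @rdname GaudiConfig-class
#' @export
gaudiConfig <- function(resolution = 5000, topFraction = 0.20,
                        bufferFactor = 1.5, neighborhoodFactor = 3.0,
                        contributionQuantile = 0.90, pwmScoreFraction = 0.8,
                        dummyCount = 36L, dummyRadiusFactor = 4.0,
                        discSegments = 64L, seed = 1L) {
  new("GaudiConfig", resolution = resolution, topFraction = topFraction,
      bufferFactor = bufferFactor, neighborhoodFactor = neighborhoodFactor,
      contributionQuantile = contributionQuantile,
      pwmScoreFraction = pwmScoreFraction, dummyCount = as.integer(dummyCount),
      dummyRadiusFactor = dummyRadiusFactor,
      discSegments = as.integer(discSegments), seed = as.integer(seed))
}
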