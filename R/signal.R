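#' Summarize a signal track per bin
#'
#' @param track a [SignalTrack-class] whose region covers the grid region.
#' @param grid a [BinGrid-class].
#' @param stat `"mean"`, `"sum"` or `"max"`. Uncovered bases count as 0;
#'   the mean uses the full bin width as denominator.
#' @return numeric vector, one value per bin.
#' @export
binSignal <- function(track, grid, stat = c("mean", "sum", "max")) {
  stat <- match.arg(stat)
  stopifnot(is(track, "SignalTrack"), is(grid, "BinGrid"))
  treg <- track@region; greg <- grid@region
  if (treg@chrom != greg@chrom || treg@start > greg@start ||
      treg@end < greg@end)
    stop("track region must cover the grid region")
  vals <- baseValues(track, greg@start, greg@end)
  starts <- grid@binStarts - greg@start
  ends <- binEnds(grid) - greg@start
  vapply(seq_along(starts), function(i) {
    v <- vals[(starts[i] + 1):ends[i]]
    switch(stat,
           mean = sum(v) / grid@resolution,
           sum = sum(v),
           max = max(v, 0))
  }, numeric(1L))
}

#' Bin index containing a position
#'
#' @param grid a [BinGrid-class].
#' @param tss 0-based base position inside the grid region.
#' @return 0-based bin index `floor((tss - start) / resolution)`.
#' @export
tssBinOf <- function(grid, tss) {
  stopifnot(is(grid, "BinGrid"))
  reg <- grid@region
  if (tss < reg@start || tss >= reg@end)
    stop("position ", tss, " is outside ", formatRegion(reg))
  as.integer((tss - reg@start) %/% grid@resolution)
}

#' Bins spatially proximal to a TSS-containing bin
#'
#' Selects all unmasked bins whose layout distance to the TSS bin is at
#' most `neighborhoodFactor` times the mean interbin distance (inclusive),
#' the spatial neighborhood used for the motif search.
#'
#' @param layout a [SpatialLayout-class].
#' @param tssBin 0-based index of the (unmasked) TSS-containing bin.
#' @param neighborhoodFactor radius in units of mean interbin distance
#'   (default 3.0).
#' @return a [NeighborhoodSelection-class].
#' @export
tssNeighborhood <- function(layout, tssBin, neighborhoodFactor = 3.0) {
  stopifnot(is(layout, "SpatialLayout"))
  tssBin <- as.integer(tssBin)
  if (tssBin < 0L || tssBin >= nBins(layout))
    stop("tssBin out of range")
  if (layout@masked[tssBin + 1L])
    stop("TSS bin ", tssBin, " is masked")
  radius <- neighborhoodFactor * layout@meanInterbin
  u <- which(!layout@masked)
  p <- layout@xy[tssBin + 1L, ]
  d <- sqrt(rowSums(sweep(layout@xy[u, , drop = FALSE], 2L, p)^2))
  members <- sort(u[d <= radius] - 1L)
  grid <- layout@grid
  regs <- data.frame(chrom = grid@region@chrom,
                     start = grid@binStarts[members + 1L],
                     end = binEnds(grid)[members + 1L])
  new("NeighborhoodSelection", tssBin = tssBin, radius = radius,
      memberBins = as.integer(members), memberRegions = regs)
}

#' Arcs between the TSS bin and its spatial neighbors
#'
#' Table mirroring the interaction arcs drawn under contribution tracks:
#' one row per (TSS bin, member bin) pair, with genomic midpoints.
#'
#' @param selection a [NeighborhoodSelection-class].
#' @param grid the [BinGrid-class] of the layout.
#' @export
neighborhoodArcs <- function(selection, grid) {
  stopifnot(is(selection, "NeighborhoodSelection"), is(grid, "BinGrid"))
  others <- setdiff(selection@memberBins, selection@tssBin)
  mid <- function(b) grid@binStarts[b + 1L] + grid@resolution / 2
  data.frame(tss_bin = selection@tssBin, member_bin = others,
             tss_pos = mid(selection@tssBin), member_pos = mid(others))
}

#' High-contribution genomic intervals within a spatial neighborhood
#'
#' The per-base threshold is the `quantile` of contribution scores across
#' the whole analysis window (type-7 sample quantile); retained bases are
#' those with score `>=` the threshold that fall inside the neighborhood's
#' member bins, merged into maximal intervals.
#'
#' @param contrib contribution-score [SignalTrack-class] covering `window`.
#' @param window the analysis [GenomicRegion-class].
#' @param quantile reference quantile (default 0.90, i.e. top 10% of
#'   scores).
#' @param selection a [NeighborhoodSelection-class].
#' @return data.frame (chrom, start, end) of retained intervals; the
#'   threshold is attached as attribute `"threshold"` and the number of
#'   retained bases window-wide (before the neighborhood intersection) as
#'   `"nRetainedWindow"`.
#' @export
highContributionIntervals <- function(contrib, window, quantile = 0.90,
                                      selection) {
  stopifnot(is(contrib, "SignalTrack"), is(window, "GenomicRegion"),
            is(selection, "NeighborhoodSelection"))
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  treg <- contrib@region
  if (treg@chrom != window@chrom || treg@start > window@start ||
      treg@end < window@end)
    stop("contribution track must cover the window")
  x <- baseValues(contrib, window@start, window@end)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  if (all(x == 0)) {
    warning("contribution track is all zero over the window")
    attr(empty, "threshold") <- 0
    attr(empty, "nRetainedWindow") <- 0L
    return(empty)
  }
  thr <- stats::quantile(x, quantile, names = FALSE, type = 7L)
  keepWindow <- x >= thr
  member <- logical(length(x))
  mr <- selection@memberRegions
  for (k in seq_len(nrow(mr))) {
    s <- max(mr$start[k], window@start); e <- min(mr$end[k], window@end)
    if (s < e) member[(s - window@start + 1):(e - window@start)] <- TRUE
  }
  keep <- keepWindow & member
  if (!any(keep)) {
    attr(empty, "threshold") <- thr
    attr(empty, "nRetainedWindow") <- sum(keepWindow)
    return(empty)
  }
  r <- rle(keep)
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1L
  on <- which(r$values)
  out <- data.frame(chrom = window@chrom,
                    start = window@start + startIdx[on] - 1,
                    end = window@start + endIdx[on])
  attr(out, "threshold") <- thr
  attr(out, "nRetainedWindow") <- sum(keepWindow)
  out
}
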