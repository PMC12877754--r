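#' Parse a genomic coordinate string
#'
#' Accepts the `chrom:start-end` style used in publications and genome
#' browsers, with optional thousands separators (commas) and either a hyphen
#' or an en-dash between the bounds, e.g.
#' `"chr6:134,835,000-135,835,000"`. Coordinates are interpreted as 0-based
#' half-open.
#'
#' @param text a single coordinate string.
#' @return a [GenomicRegion-class].
#' @examples
#' parseRegion("chr6:134,835,000-135,835,000")
#' @export
parseRegion <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("region must be a single string")
  s <- gsub(",", "", trimws(text))
  s <- gsub("–", "-", s)  # en-dash
  m <- regmatches(s, regexec("^([^:[:space:]]+):([0-9]+)-([0-9]+)$", s))[[1L]]
  if (length(m) != 4L)
    stop("cannot parse region string: '", text,
         "' (expected chrom:start-end)")
  start <- as.numeric(m[3L]); end <- as.numeric(m[4L])
  if (start >= end)
    stop("region start ", m[3L], " is not below end ", m[4L], " in '",
         text, "'")
  GenomicRegion(m[2L], start, end)
}

#' Format a region as a canonical coordinate string
#'
#' Inverse of [parseRegion()] on canonical strings (no separators, hyphen).
#'
#' @param region a [GenomicRegion-class].
#' @export
formatRegion <- function(region) {
  stopifnot(is(region, "GenomicRegion"))
  sprintf("%s:%.0f-%.0f", region@chrom, region@start, region@end)
}

#' Tile a region into fixed-width bins
#'
#' Bin `i` (0-based) spans `[start + i * resolution,
#' min(start + (i+1) * resolution, end))`; the last bin may be clipped so
#' the bins tile the region exactly.
#'
#' @param region a [GenomicRegion-class].
#' @param resolution bin width in bp (default 5,000, the resolution of the
#'   interaction maps this package targets).
#' @return a [BinGrid-class].
#' @examples
#' makeBinGrid(parseRegion("chr6:134,835,000-135,835,000"), 5000)  # 200 bins
#' @export
makeBinGrid <- function(region, resolution = 5000) {
  stopifnot(is(region, "GenomicRegion"))
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive number")
  n <- ceiling((region@end - region@start) / resolution)
  new("BinGrid", region = region, resolution = as.numeric(resolution),
      binStarts = region@start + resolution * (seq_len(n) - 1))
}

#' Bin end positions (exclusive), clipped at the region end
#' @param grid a [BinGrid-class].
#' @export
binEnds <- function(grid) {
  stopifnot(is(grid, "BinGrid"))
  pmin(grid@binStarts + grid@resolution, grid@region@end)
}

#' Convert a GenomicRegion to a GRanges
#'
#' Shifts to the 1-based closed convention of \pkg{GenomicRanges}. The
#' reverse shift is `GenomicRegion(seqnames, start - 1, end)`.
#'
#' @param region a [GenomicRegion-class].
#' @export
asGRanges <- function(region) {
  stopifnot(is(region, "GenomicRegion"))
  if (!requireNamespace("GenomicRanges", quietly = TRUE))
    stop("GenomicRanges is not installed")
  GenomicRanges::GRanges(region@chrom,
                         IRanges::IRanges(region@start + 1, region@end))
}
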