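#' Construct a SignalTrack from intervals
#'
#' Intervals are sorted and validated; bases not covered carry 0.
#'
#' @param region a [GenomicRegion-class].
#' @param starts,ends 0-based half-open interval bounds.
#' @param values one value per interval.
#' @export
signalTrack <- function(region, starts = numeric(), ends = numeric(),
                        values = numeric()) {
  o <- order(starts, ends)
  new("SignalTrack", region = region, starts = as.numeric(starts[o]),
      ends = as.numeric(ends[o]), values = as.numeric(values[o]))
}

#' Integral of a SignalTrack
#'
#' Sum of interval length times value; uncovered bases contribute 0.
#' @param track a [SignalTrack-class].
#' @export
trackIntegral <- function(track) {
  stopifnot(is(track, "SignalTrack"))
  sum((track@ends - track@starts) * track@values)
}

#' Materialize per-base values of a SignalTrack
#'
#' @param track a [SignalTrack-class].
#' @param from,to 0-based half-open sub-interval of the track region
#'   (defaults to the whole region).
#' @return numeric vector of length `to - from`, one value per base.
#' @export
baseValues <- function(track, from = regionStart(regionOf(track)),
                       to = regionEnd(regionOf(track))) {
  stopifnot(is(track, "SignalTrack"))
  reg <- track@region
  if (from < reg@start || to > reg@end || from >= to)
    stop("[from, to) must be a non-empty sub-interval of the track region")
  out <- numeric(to - from)
  s <- pmax(track@starts, from); e <- pmin(track@ends, to)
  keep <- which(s < e)
  for (k in keep)
    out[(s[k] - from + 1):(e[k] - from)] <- track@values[k]
  out
}

#' Read a bedGraph file as a SignalTrack
#'
#' Four whitespace-delimited columns (chrom, start, end, value), 0-based
#' half-open. Intervals on other chromosomes or outside `region` are
#' dropped; partially overlapping intervals are clipped to the region.
#' Overlapping input intervals (within the region, same chromosome) are an
#' error; uncovered bases read as 0.
#'
#' @param path bedGraph file.
#' @param region a [GenomicRegion-class] to clip to.
#' @return a [SignalTrack-class].
#' @export
readBedGraph <- function(path, region) {
  stopifnot(is(region, "GenomicRegion"))
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(signalTrack(region))
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "numeric", "numeric",
                                  "character"))
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val))
    stop("non-numeric bedGraph value: '", df$value[which(is.na(val))[1L]], "'")
  if (any(df$end <= df$start))
    stop("bedGraph interval with end <= start at line ",
         which(df$end <= df$start)[1L])
  keep <- df$chrom == region@chrom & df$end > region@start &
    df$start < region@end
  df <- df[keep, , drop = FALSE]; val <- val[keep]
  if (!nrow(df)) return(signalTrack(region))
  s <- pmax(df$start, region@start); e <- pmin(df$end, region@end)
  o <- order(s, e)
  s <- s[o]; e <- e[o]; val <- val[o]
  if (length(s) > 1L && any(s[-1L] < e[-length(e)]))
    stop("overlapping bedGraph intervals within ", formatRegion(region))
  signalTrack(region, s, e, val)
}

#' Write a SignalTrack as bedGraph
#' @param track a [SignalTrack-class].
#' @param path output file.
#' @export
writeBedGraph <- function(track, path) {
  stopifnot(is(track, "SignalTrack"))
  df <- data.frame(chrom = track@region@chrom,
                   start = sprintf("%.0f", track@starts),
                   end = sprintf("%.0f", track@ends),
                   value = format(track@values, digits = 10, trim = TRUE,
                                  scientific = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED (3+ column) file as regions
#'
#' @param path BED file, 0-based half-open, >= 3 whitespace-delimited columns.
#' @param region optional [GenomicRegion-class]; rows are clipped to it and
#'   non-overlapping rows dropped.
#' @return data.frame (chrom, start, end) sorted by (chrom, start).
#' @export
readBed <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  df <- read.table(path, header = FALSE, comment.char = "#", fill = TRUE)
  if (ncol(df) < 3L) stop("BED file must have >= 3 columns")
  df <- data.frame(chrom = as.character(df[[1L]]), start = as.numeric(df[[2L]]),
                   end = as.numeric(df[[3L]]))
  if (any(df$end <= df$start))
    stop("BED interval with end <= start at line ",
         which(df$end <= df$start)[1L])
  if (!is.null(region)) {
    stopifnot(is(region, "GenomicRegion"))
    keep <- df$chrom == region@chrom & df$end > region@start &
      df$start < region@end
    df <- df[keep, , drop = FALSE]
    df$start <- pmax(df$start, region@start)
    df$end <- pmin(df$end, region@end)
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read genome sequences from FASTA
#'
#' Sequences are uppercased; `N` is permitted and handled by the motif
#' scanner (zero log-odds contribution).
#'
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
readGenomeFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) stop("FASTA file contains no records: ", path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm))
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1L])
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- nm
  x
}

#' Write sequences to FASTA
#' @param seqs named character vector or DNAStringSet.
#' @param path output file.
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
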