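#' Read motif models from MEME minimal or JASPAR PFM text
#'
#' MEME minimal files supply letter-probability matrices (rows are positions,
#' columns A, C, G, T); each row must sum to ~1. JASPAR PFM files supply
#' per-base count rows; counts `c` become probabilities
#' `(c + pseudocount) / (colsum + 4 * pseudocount)`. In both cases a
#' pseudocount regularizes zero entries so log-odds stay finite, and columns
#' are renormalized to sum exactly to 1. Motif names are preserved verbatim
#' and file order is kept.
#'
#' @param path motif file.
#' @param format `"meme"` or `"jaspar"`.
#' @param pseudocount small positive regularizer (default 0.01 per cell).
#' @param background length-4 base frequencies (A, C, G, T); for MEME files
#'   the file's background line, when present, takes precedence.
#' @return list of [PWMotif-class], named by motif name.
#' @export
readPWMs <- function(path, format = c("meme", "jaspar"), pseudocount = 0.01,
                     background = rep(0.25, 4)) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "meme") parseMemeMotifs(lines, pseudocount, background)
  else parseJasparMotifs(lines, pseudocount, background)
}

newPWMotif <- function(name, prob, background, pseudocount) {
  prob <- sweep(prob, 2L, colSums(prob), "/")
  rownames(prob) <- c("A", "C", "G", "T")
  bg <- background / sum(background)
  names(bg) <- c("A", "C", "G", "T")
  new("PWMotif", name = name, matrix = prob, background = bg,
      pseudocount = pseudocount)
}

parseMemeMotifs <- function(lines, pseudocount, background) {
  bgLine <- grep("^Background letter frequencies", lines)
  if (length(bgLine)) {
    toks <- strsplit(trimws(lines[bgLine[1L] + 1L]), "\\s+")[[1L]]
    freq <- as.numeric(toks[c(FALSE, TRUE)])
    base <- toks[c(TRUE, FALSE)]
    if (!anyNA(freq) && setequal(base, c("A", "C", "G", "T")))
      background <- freq[match(c("A", "C", "G", "T"), base)]
  }
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) stop("no MOTIF entries found (MEME minimal format)")
  out <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    name <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[starts[m]])),
                     "\\s+")[[1L]][1L]
    to <- if (m < length(starts)) starts[m + 1L] - 1L else length(lines)
    block <- lines[starts[m]:to]
    hdr <- grep("letter-probability matrix", block)
    if (!length(hdr))
      stop("motif ", name, ": missing letter-probability matrix header")
    rows <- list()
    for (ln in block[-seq_len(hdr[1L])]) {
      ln <- trimws(ln)
      if (!nzchar(ln)) { if (length(rows)) break else next }
      v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
      if (anyNA(v)) break
      if (length(v) != 4L)
        stop("motif ", name, ": matrix row with ", length(v), " fields")
      rows[[length(rows) + 1L]] <- v
    }
    if (!length(rows)) stop("motif ", name, ": empty probability matrix")
    prob <- do.call(cbind, rows)  # 4 x L, rows A C G T
    if (any(abs(colSums(prob) - 1) > 0.01))
      stop("motif ", name, ": probability rows do not sum to ~1")
    prob <- (prob + pseudocount) / (1 + 4 * pseudocount)
    out[[m]] <- newPWMotif(name, prob, background, pseudocount)
  }
  names(out) <- vapply(out, motifName, character(1L))
  out
}

parseJasparMotifs <- function(lines, pseudocount, background) {
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' motif headers found (JASPAR PFM format)")
  out <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    name <- trimws(sub("^>\\s*", "", lines[starts[m]]))
    to <- if (m < length(starts)) starts[m + 1L] - 1L else length(lines)
    block <- lines[(starts[m] + 1L):to]
    block <- block[nzchar(trimws(block))]
    if (length(block) < 4L)
      stop("motif ", name, ": expected 4 count rows, got ", length(block))
    counts <- matrix(NA_real_, 4L, 0L)
    order4 <- c("A", "C", "G", "T")
    rows <- vector("list", 4L)
    for (r in 1:4) {
      ln <- gsub("\\[|\\]", " ", block[r])
      toks <- strsplit(trimws(ln), "\\s+")[[1L]]
      base <- if (toks[1L] %in% order4) { b <- toks[1L]; toks <- toks[-1L]; b }
              else order4[r]
      v <- suppressWarnings(as.numeric(toks))
      if (anyNA(v)) stop("motif ", name, ": non-numeric count row")
      if (any(v < 0)) stop("motif ", name, ": negative counts")
      rows[[match(base, order4)]] <- v
    }
    if (length(unique(lengths(rows))) != 1L)
      stop("motif ", name, ": count rows have unequal lengths")
    counts <- do.call(rbind, rows)
    prob <- sweep(counts + pseudocount, 2L,
                  colSums(counts) + 4 * pseudocount, "/")
    out[[m]] <- newPWMotif(name, prob, background, pseudocount)
  }
  names(out) <- vapply(out, motifName, character(1L))
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pwms list of [PWMotif-class].
#' @param path output file.
#' @export
writeMemePWMs <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwms[[1L]]@background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg[1L], bg[2L], bg[3L], bg[4L]), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p@name), con)
    writeLines(sprintf(
      "letter-probability matrix: alphabet= 4 w= %d nsites= 20 E= 0",
      ncol(p@matrix)), con)
    for (k in seq_len(ncol(p@matrix)))
      writeLines(paste(sprintf("%.6f", p@matrix[, k]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Build a near-deterministic PWM from a consensus string
#'
#' Each position gives probability `1 - 3 * offRate` to the consensus base
#' and `offRate` to the rest; used for synthetic motif models.
#'
#' @param name motif name.
#' @param consensus string over A, C, G, T.
#' @param offRate per-position probability of each non-consensus base.
#' @param background length-4 base frequencies.
#' @export
consensusPWM <- function(name, consensus, offRate = 0.001,
                         background = rep(0.25, 4)) {
  bases <- strsplit(toupper(consensus), "")[[1L]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("consensus must be over A, C, G, T")
  prob <- matrix(offRate, 4L, length(bases),
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  prob[cbind(match(bases, c("A", "C", "G", "T")), seq_along(bases))] <-
    1 - 3 * offRate
  newPWMotif(name, prob, background, offRate)
}
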