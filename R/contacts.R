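#' Construct a ContactMatrix
#'
#' Bins with an all-zero row are masked. `values` must be symmetric and
#' non-negative.
#'
#' @param grid a [BinGrid-class].
#' @param values nBins x nBins symmetric matrix.
#' @param balanced whether the matrix is already balanced.
#' @param biases optional per-bin bias factors (NA for masked bins).
#' @export
contactMatrix <- function(grid, values, balanced = FALSE, biases = NULL) {
  stopifnot(is(grid, "BinGrid"))
  n <- nBins(grid)
  masked <- rowSums(abs(values)) == 0
  if (is.null(biases)) biases <- rep(NA_real_, n)
  new("ContactMatrix", grid = grid, values = unname(values),
      balanced = balanced, biases = biases, masked = masked)
}

#' Read intrachromosomal contacts in COO text form
#'
#' Five whitespace-delimited columns: `chrom1 start1 chrom2 start2 count`,
#' with starts on the grid's bin lattice. Records outside the grid (other
#' chromosomes or positions beyond the window) are ignored and their number
#' reported via a message. Duplicate `(i, j)` records are summed and the
#' matrix is symmetrized by mirroring.
#'
#' @param path COO text file.
#' @param grid a [BinGrid-class].
#' @return an unbalanced [ContactMatrix-class].
#' @export
readContacts <- function(path, grid) {
  stopifnot(is(grid, "BinGrid"))
  n <- nBins(grid)
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- matrix(0, n, n)
  if (file.size(path) > 0L) {
    df <- read.table(path, header = FALSE,
                     col.names = c("chrom1", "start1", "chrom2", "start2",
                                   "count"),
                     colClasses = c("character", "numeric", "character",
                                    "numeric", "numeric"))
    if (any(df$count < 0))
      stop("negative contact count at line ", which(df$count < 0)[1L])
    reg <- grid@region
    inGrid <- df$chrom1 == reg@chrom & df$chrom2 == reg@chrom &
      df$start1 >= reg@start & df$start1 < reg@end &
      df$start2 >= reg@start & df$start2 < reg@end
    nIgnored <- sum(!inGrid)
    if (nIgnored)
      message("readContacts: ignored ", nIgnored,
              " records outside the grid")
    df <- df[inGrid, , drop = FALSE]
    if (nrow(df)) {
      off1 <- df$start1 - reg@start; off2 <- df$start2 - reg@start
      if (any(off1 %% grid@resolution != 0) ||
          any(off2 %% grid@resolution != 0))
        stop("contact start not on the bin lattice (resolution ",
             grid@resolution, ")")
      i <- off1 %/% grid@resolution + 1L
      j <- off2 %/% grid@resolution + 1L
      lo <- pmin(i, j); hi <- pmax(i, j)
      for (k in seq_along(lo))
        vals[lo[k], hi[k]] <- vals[lo[k], hi[k]] + df$count[k]
      low <- lower.tri(vals)
      vals[low] <- t(vals)[low]
    }
  }
  contactMatrix(grid, vals, balanced = FALSE)
}

#' Write a ContactMatrix as COO text (upper triangle incl. diagonal)
#' @param cm a [ContactMatrix-class].
#' @param path output file.
#' @export
writeContactsCOO <- function(cm, path) {
  stopifnot(is(cm, "ContactMatrix"))
  grid <- cm@grid
  idx <- which(upper.tri(cm@values, diag = TRUE) & cm@values != 0,
               arr.ind = TRUE)
  df <- data.frame(chrom1 = grid@region@chrom,
                   start1 = sprintf("%.0f", grid@binStarts[idx[, 1L]]),
                   chrom2 = grid@region@chrom,
                   start2 = sprintf("%.0f", grid@binStarts[idx[, 2L]]),
                   count = format(cm@values[idx], digits = 10, trim = TRUE,
                                  scientific = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' ICE-balance a contact matrix
#'
#' Iterative correction removing sequencing-depth and genomic biases:
#' repeats `b_i <- b_i * sqrt(s_i / mean(s))` (where `s_i` is the current
#' row sum over unmasked bins) until the row sums are uniform to within
#' `tol` (relative) or `maxIter` is reached. The output is rescaled so the
#' mean unmasked row sum is exactly 1, with the rescaling folded into the
#' reported biases so that `balanced[i,j] * biases[i] * biases[j]`
#' reproduces the input exactly. All-zero rows are masked before iteration.
#'
#' @param cm an unbalanced [ContactMatrix-class].
#' @param maxIter maximum iterations (default 200).
#' @param tol relative row-sum tolerance (default 1e-8).
#' @return a balanced [ContactMatrix-class] with biases filled in; if the
#'   iteration does not converge a warning is raised and the attribute
#'   `converged` on the result is `FALSE`.
#' @export
iceBalance <- function(cm, maxIter = 200L, tol = 1e-8) {
  stopifnot(is(cm, "ContactMatrix"), tol > 0)
  if (cm@balanced) stop("matrix is already balanced")
  u <- which(!cm@masked)
  if (!length(u)) stop("all rows are zero; nothing to balance")
  W <- cm@values[u, u, drop = FALSE]
  b <- rep(1, length(u))
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    M <- W / outer(b, b)
    s <- rowSums(M)
    sbar <- mean(s)
    if (max(abs(s / sbar - 1)) < tol) { converged <- TRUE; break }
    b <- b * sqrt(s / sbar)
  }
  M <- W / outer(b, b)
  m <- mean(rowSums(M))
  n <- nBins(cm)
  vals <- matrix(0, n, n)
  vals[u, u] <- M / m
  vals <- (vals + t(vals)) / 2  # kill last-bit asymmetry from outer()
  biases <- rep(NA_real_, n)
  biases[u] <- b * sqrt(m)
  if (!converged)
    warning("ICE balancing did not reach tolerance ", tol, " in ",
            maxIter, " iterations")
  out <- new("ContactMatrix", grid = cm@grid, values = vals, balanced = TRUE,
             biases = biases, masked = cm@masked)
  attr(out, "converged") <- converged
  out
}
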