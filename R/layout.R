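#' Stress of a 2D configuration against target distances
#'
#' `stress(X) = sum_{i<j} (||x_i - x_j|| - D_ij)^2 / D_ij^2`, the
#' Kamada-Kawai objective.
#'
#' @param xy n x 2 coordinate matrix.
#' @param D n x n target distance matrix.
#' @export
layoutStressOf <- function(xy, D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  dd <- as.matrix(dist(xy))
  ut <- upper.tri(D)
  sum(((dd[ut] - D[ut])^2) / D[ut]^2)
}

#' Embed target distances in 2D (Kamada-Kawai stress minimization)
#'
#' Minimizes the Kamada-Kawai stress (weights `1 / D_ij^2`) by a
#' deterministic two-phase descent: SMACOF majorization (monotone on the
#' stress) from two fixed starts -- a circle in node order with radius
#' equal to the mean target distance, and classical MDS -- followed by
#' L-BFGS refinement with the analytic stress gradient from the better
#' warm start. Every step is deterministic, so the output is identical
#' across runs for the same input.
#'
#' @param D symmetric positive distance matrix (zero diagonal).
#' @param seed integer recorded for provenance; randomness is only used to
#'   break exactly coincident points, so results are seed-stable.
#' @param maxIter,tol majorization iteration controls for the warm start.
#' @return list with `xy` (n x 2) and `stress`.
#' @export
kamadaKawaiEmbed <- function(D, seed = 1L, maxIter = 50L, tol = 1e-12) {
  D <- as.matrix(D)
  if (any(!is.finite(D))) stop("non-finite entries in distance matrix")
  n <- nrow(D)
  if (n == 1L) return(list(xy = matrix(0, 1L, 2L), stress = 0))
  radius <- mean(D[upper.tri(D)])
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  circInit <- radius * cbind(cos(theta), sin(theta))
  mdsInit <- tryCatch({
    m <- cmdscale(D, k = 2L)
    if (ncol(m) < 2L) m <- cbind(m, 0)
    m
  }, error = function(e) NULL)
  best <- NULL
  for (init in Filter(Negate(is.null), list(circInit, mdsInit))) {
    res <- smacofDescent(init, D, maxIter, tol)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  W <- 1 / D^2
  diag(W) <- 0
  fn <- function(par) {
    X <- matrix(par, n, 2L)
    dd <- as.matrix(dist(X))
    ut <- upper.tri(D)
    sum(W[ut] * (dd[ut] - D[ut])^2)
  }
  gr <- function(par) {
    X <- matrix(par, n, 2L)
    dd <- as.matrix(dist(X))
    dd[dd == 0] <- 1e-12
    C <- 2 * W * (dd - D) / dd
    diag(C) <- 0
    as.numeric(X * rowSums(C) - C %*% X)
  }
  opt <- optim(as.numeric(best$xy), fn, gr, method = "L-BFGS-B",
               control = list(maxit = 2000L, factr = 1e3))
  if (opt$value < best$stress)
    best <- list(xy = matrix(opt$par, n, 2L), stress = opt$value)
  best$seed <- as.integer(seed)
  best
}

smacofDescent <- function(X, D, maxIter, tol) {
  n <- nrow(D)
  W <- 1 / D^2
  diag(W) <- 0
  V <- diag(rowSums(W)) - W
  Vinv <- solve(V + 1 / n)  # Moore-Penrose via the rank-completion identity
  s <- layoutStressOf(X, D)
  for (it in seq_len(maxIter)) {
    dd <- as.matrix(dist(X))
    B <- matrix(0, n, n)
    pos <- dd > 0
    B[pos] <- -W[pos] * D[pos] / dd[pos]
    diag(B) <- -rowSums(B)
    Xnew <- Vinv %*% (B %*% X)
    snew <- layoutStressOf(Xnew, D)
    if (snew > s) break  # majorization guarantees descent; numerical floor
    X <- Xnew
    if (s - snew < tol * max(s, 1e-300)) { s <- snew; break }
    s <- snew
  }
  list(xy = unname(X), stress = s)
}

#' Mean layout distance between genomically consecutive bins
#'
#' The spatial unit of the buffer and neighborhood radii: the mean Euclidean
#' distance between consecutive unmasked bin pairs in the layout.
#'
#' @param xy n x 2 coordinates of the unmasked bins in genomic order, or a
#'   [SpatialLayout-class].
#' @export
meanInterbinDistance <- function(xy) {
  if (is(xy, "SpatialLayout"))
    xy <- xy@xy[!xy@masked, , drop = FALSE]
  n <- nrow(xy)
  if (n < 2L) stop("need at least 2 unmasked bins")
  steps <- sqrt(rowSums((xy[-1L, , drop = FALSE] -
                         xy[-n, , drop = FALSE])^2))
  mean(steps)
}

#' Layout a balanced contact matrix in 2D
#'
#' Runs [buildGraph()], [completeDistances()] and [kamadaKawaiEmbed()] and
#' packages the result with the mean interbin distance.
#'
#' @param cm a balanced [ContactMatrix-class].
#' @param topFraction fraction of interactions selected as edges.
#' @param seed integer recorded for provenance.
#' @return a [SpatialLayout-class]; masked bins have NA coordinates.
#' @export
layoutContacts <- function(cm, topFraction = 0.20, seed = 1L) {
  g <- buildGraph(cm, topFraction)
  D <- completeDistances(g)
  emb <- kamadaKawaiEmbed(D, seed = seed)
  n <- nBins(cm)
  xy <- matrix(NA_real_, n, 2L)
  u <- which(!cm@masked)
  xy[u, ] <- emb$xy
  mib <- if (length(u) >= 2L)
    meanInterbinDistance(emb$xy) else NA_real_
  new("SpatialLayout", grid = cm@grid, xy = xy, meanInterbin = mib,
      stress = emb$stress, seed = as.integer(seed), masked = cm@masked)
}

#' Construct a SpatialLayout from explicit coordinates
#'
#' Mainly for tests and for loading a saved layout TSV.
#'
#' @param grid a [BinGrid-class].
#' @param xy nBins x 2 coordinates (NA rows = masked bins).
#' @param seed integer recorded for provenance.
#' @param stress optional stress value.
#' @export
spatialLayout <- function(grid, xy, seed = 1L, stress = NA_real_) {
  masked <- is.na(xy[, 1L]) | is.na(xy[, 2L])
  u <- which(!masked)
  mib <- if (length(u) >= 2L)
    meanInterbinDistance(xy[u, , drop = FALSE]) else NA_real_
  new("SpatialLayout", grid = grid, xy = unname(xy), meanInterbin = mib,
      stress = as.numeric(stress), seed = as.integer(seed), masked = masked)
}

#' Write a layout as TSV (bin_index, chrom, start, x, y)
#' @param layout a [SpatialLayout-class].
#' @param path output file.
#' @export
writeLayoutTSV <- function(layout, path) {
  stopifnot(is(layout, "SpatialLayout"))
  grid <- layout@grid
  df <- data.frame(bin_index = seq_len(nBins(layout)) - 1L,
                   chrom = grid@region@chrom,
                   start = sprintf("%.0f", grid@binStarts),
                   x = sprintf("%.10g", layout@xy[, 1L]),
                   y = sprintf("%.10g", layout@xy[, 2L]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
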