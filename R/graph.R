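#' Build the top-interaction graph from a balanced matrix
#'
#' Candidate edges are the nonzero off-diagonal upper-triangle entries among
#' unmasked bins. Each is transformed `w = log10(1 + value)` and the
#' `k = ceiling(topFraction * M)` edges with the largest `w` are selected
#' (ties broken by larger `w`, then ascending `(i, j)`), each carrying the
#' distance `d = 1 / w`. Backbone edges between genomically consecutive
#' unmasked bins are always added (when not already selected) with `d` equal
#' to the median selected distance (1.0 when no edge was selected), marked
#' `backbone`; they keep the polymer chain connected.
#'
#' @param cm a balanced [ContactMatrix-class].
#' @param topFraction fraction of candidate interactions to select
#'   (default 0.20).
#' @return an [InteractionGraph-class].
#' @export
buildGraph <- function(cm, topFraction = 0.20) {
  stopifnot(is(cm, "ContactMatrix"))
  if (!cm@balanced) stop("buildGraph expects a balanced matrix")
  if (topFraction <= 0 || topFraction > 1)
    stop("topFraction must be in (0, 1]")
  u <- which(!cm@masked)
  V <- cm@values
  ut <- which(upper.tri(V), arr.ind = TRUE)
  keep <- V[ut] > 0 & !cm@masked[ut[, 1L]] & !cm@masked[ut[, 2L]]
  cand <- data.frame(i = ut[keep, 1L] - 1L, j = ut[keep, 2L] - 1L,
                     v = V[ut][keep])
  M <- nrow(cand)
  if (M == 0L && length(u) < 2L)
    stop("no candidate interactions and fewer than 2 unmasked bins")
  if (M > 0L) {
    cand$w <- log10(1 + cand$v)
    k <- min(ceiling(topFraction * M), M)
    o <- order(-cand$w, cand$i, cand$j)
    sel <- cand[o[seq_len(k)], , drop = FALSE]
    edges <- data.frame(i = sel$i, j = sel$j, w = sel$w, d = 1 / sel$w,
                        backbone = FALSE)
  } else {
    edges <- data.frame(i = integer(), j = integer(), w = numeric(),
                        d = numeric(), backbone = logical())
  }
  dBack <- if (nrow(edges)) median(edges$d) else 1.0
  if (length(u) >= 2L) {
    bi <- u[-length(u)] - 1L; bj <- u[-1L] - 1L
    have <- paste(edges$i, edges$j)
    add <- !(paste(bi, bj) %in% have)
    if (any(add))
      edges <- rbind(edges,
                     data.frame(i = bi[add], j = bj[add], w = 1 / dBack,
                                d = dBack, backbone = TRUE))
  }
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  new("InteractionGraph", nNodes = nBins(cm), edges = edges,
      masked = cm@masked)
}

#' All-pairs shortest-path distances over an interaction graph
#'
#' Completes the edge distances into a full metric by Dijkstra shortest
#' paths (the embedding needs target distances for every pair).
#'
#' @param g an [InteractionGraph-class].
#' @return symmetric matrix over unmasked bins, dimnames = 0-based bin
#'   indices.
#' @export
completeDistances <- function(g) {
  stopifnot(is(g, "InteractionGraph"))
  u <- which(!g@masked) - 1L
  if (length(u) == 1L)
    return(matrix(0, 1L, 1L, dimnames = list(u, u)))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(g@edges$i), to = as.character(g@edges$j),
               weight = g@edges$d),
    directed = FALSE, vertices = data.frame(name = as.character(u)))
  D <- igraph::distances(ig, algorithm = "dijkstra")
  if (any(!is.finite(D)))
    stop("interaction graph is disconnected")  # cannot occur with backbone
  ord <- as.character(u)
  D[ord, ord, drop = FALSE]
}
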