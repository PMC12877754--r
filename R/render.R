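#' Render a Gaudi plot to SVG
#'
#' Polygons are filled with a sequential colormap after clipping the signal
#' to its 1st-99th percentile range; NA bins are grey. Highlighted bins get
#' a dot marker; when a TSS bin and a neighborhood radius are supplied, a
#' dashed circle marks the spatial neighborhood used for the motif search.
#'
#' @param plot a [GaudiPlot-class].
#' @param values per-unmasked-bin signal (defaults to the plot's signal
#'   slot); NA allowed.
#' @param highlight 0-based bin indices to mark with a dot.
#' @param tssBin optional 0-based TSS bin index for the dashed circle.
#' @param neighborhoodRadius radius of the dashed circle in layout units.
#' @param path output SVG file.
#' @param palette sequential palette name passed to
#'   [grDevices::hcl.colors()].
#' @param width SVG canvas size in pixels.
#' @return `path`, invisibly.
#' @export
renderGaudi <- function(plot, values = plot@signal, highlight = integer(),
                        tssBin = NULL, neighborhoodRadius = NULL,
                        path, palette = "viridis", width = 600) {
  stopifnot(is(plot, "GaudiPlot"))
  nUn <- length(plot@polygons)
  if (length(values) == nBins(plot@layout) && length(values) != nUn)
    values <- values[!plot@layout@masked]
  if (length(values) != nUn)
    stop("need one value per unmasked bin (", nUn, "), got ",
         length(values))
  values <- as.numeric(values)
  ok <- is.finite(values)
  cols <- rep("#bbbbbb", nUn)  # NA bins grey
  if (any(ok)) {
    lo <- quantile(values[ok], 0.01, names = FALSE)
    hi <- quantile(values[ok], 0.99, names = FALSE)
    v <- pmin(pmax(values[ok], lo), hi)
    ramp <- grDevices::hcl.colors(256L, palette)
    idx <- if (hi > lo) pmax(1L, ceiling(255 * (v - lo) / (hi - lo)))
           else rep(128L, length(v))
    cols[ok] <- ramp[idx]
  }
  bins <- as.integer(names(plot@polygons))
  u <- which(!plot@layout@masked)
  pts <- plot@layout@xy[u, , drop = FALSE]
  allXY <- do.call(rbind, c(plot@polygons, list(pts)))
  pad <- 0.05 * max(diff(range(allXY[, 1L])), diff(range(allXY[, 2L])), 1)
  x0 <- min(allXY[, 1L]) - pad; x1 <- max(allXY[, 1L]) + pad
  y0 <- min(allXY[, 2L]) - pad; y1 <- max(allXY[, 2L]) + pad
  scale <- width / (x1 - x0)
  height <- ceiling((y1 - y0) * scale)
  tx <- function(x) (x - x0) * scale
  ty <- function(y) height - (y - y0) * scale  # SVG y grows downward
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height))
  for (k in seq_len(nUn)) {
    poly <- plot@polygons[[k]]
    if (nrow(poly) < 3L) next
    ptsStr <- paste(sprintf("%.2f,%.2f", tx(poly[, 1L]), ty(poly[, 2L])),
                    collapse = " ")
    lines <- c(lines, sprintf(
      '<polygon class="bin" data-bin="%d" points="%s" fill="%s" stroke="#ffffff" stroke-width="0.5"/>',
      bins[k], ptsStr, cols[k]))
  }
  if (!is.null(tssBin) && !is.null(neighborhoodRadius)) {
    ci <- match(as.integer(tssBin), bins)
    if (is.na(ci)) stop("tssBin ", tssBin, " is not an unmasked bin")
    lines <- c(lines, sprintf(
      '<circle class="neighborhood" cx="%.2f" cy="%.2f" r="%.2f" fill="none" stroke="#333333" stroke-width="1.5" stroke-dasharray="6,4"/>',
      tx(pts[ci, 1L]), ty(pts[ci, 2L]), neighborhoodRadius * scale))
  }
  for (h in highlight) {
    ci <- match(as.integer(h), bins)
    if (is.na(ci)) next
    lines <- c(lines, sprintf(
      '<circle class="highlight-dot" cx="%.2f" cy="%.2f" r="4" fill="#2ca02c" stroke="#000000" stroke-width="0.8"/>',
      tx(pts[ci, 1L]), ty(pts[ci, 2L])))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
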