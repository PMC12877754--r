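#' Shoelace area of a polygon
#'
#' Positive for counter-clockwise vertex order.
#' @param poly k x 2 vertex matrix (closed implicitly).
#' @export
polygonArea <- function(poly) {
  k <- nrow(poly)
  if (is.null(k) || k < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Regular polygon approximating a disc
#' @param center length-2 center.
#' @param r radius.
#' @param n number of sides (counter-clockwise vertices).
#' @export
discPolygon <- function(center, r, n = 64L) {
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1L] + r * cos(theta), center[2L] + r * sin(theta))
}

# Clip a convex polygon by the half-plane a*x + b*y <= c
# (Sutherland-Hodgman single-edge pass).
clipHalfPlane <- function(poly, a, b, c) {
  k <- nrow(poly)
  if (is.null(k) || k == 0L) return(poly)
  f <- a * poly[, 1L] + b * poly[, 2L] - c
  inside <- f <= 1e-12
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0L, , drop = FALSE])
  out <- matrix(numeric(), 0L, 2L)
  for (s in seq_len(k)) {
    e <- if (s == k) 1L else s + 1L
    p1 <- poly[s, ]; p2 <- poly[e, ]
    if (inside[s]) out <- rbind(out, p1)
    if (xor(inside[s], inside[e])) {
      t <- f[s] / (f[s] - f[e])
      out <- rbind(out, p1 + t * (p2 - p1))
    }
  }
  out
}

#' Spatial occupancy polygons of a layout (Gaudi geometry)
#'
#' Each unmasked bin receives the intersection of (a) its Voronoi cell in
#' the diagram over all bins plus a closing ring of dummy nodes and (b) a
#' buffer disc of radius `bufferFactor` times the mean interbin distance,
#' approximated by a regular `discSegments`-gon. The Voronoi cell is
#' realized exactly as the intersection of perpendicular-bisector
#' half-planes against every other generator, so the result is an exact
#' polygon intersection. Dummy nodes sit on a circle of radius
#' `dummyRadiusFactor` times the layout's maximum centroid distance
#' (floor 1), which closes unbounded cells without ever clipping a buffer
#' disc. Coincident bin coordinates (closer than 1e-9) are separated by a
#' deterministic jitter of `1e-6 * meanInterbin` and reported via a message.
#'
#' @param layout a [SpatialLayout-class].
#' @param bufferFactor buffer radius in units of mean interbin distance
#'   (default 1.5).
#' @param dummyCount number of dummy nodes (default 36).
#' @param dummyRadiusFactor dummy-ring radius factor (default 4).
#' @param discSegments disc polygon sides (default 64).
#' @return a [GaudiPlot-class]; polygon list names are 0-based bin indices.
#' @export
voronoiOccupancy <- function(layout, bufferFactor = 1.5, dummyCount = 36L,
                             dummyRadiusFactor = 4.0, discSegments = 64L) {
  stopifnot(is(layout, "SpatialLayout"), bufferFactor > 0)
  u <- which(!layout@masked)
  if (!length(u)) stop("layout has no unmasked bins")
  pts <- layout@xy[u, , drop = FALSE]
  n <- nrow(pts)
  mib <- if (is.finite(layout@meanInterbin)) layout@meanInterbin else 1.0
  if (n > 1L) {
    dd <- as.matrix(dist(pts))
    diag(dd) <- Inf
    if (any(dd < 1e-9)) {
      message("voronoiOccupancy: coincident bin coordinates; applying ",
              "deterministic jitter")
      ang <- 2 * pi * (seq_len(n) - 1L) / n
      jit <- 1e-6 * mib
      dup <- which(apply(dd, 1L, min) < 1e-9)
      pts[dup, ] <- pts[dup, , drop = FALSE] +
        jit * cbind(cos(ang[dup]), sin(ang[dup]))
    }
  }
  centroid <- colMeans(pts)
  spread <- max(1.0, if (n > 1L)
    max(sqrt(rowSums(sweep(pts, 2L, centroid)^2))) else 1.0)
  ringR <- dummyRadiusFactor * spread
  ang <- 2 * pi * (seq_len(dummyCount) - 1L) / dummyCount
  dummies <- cbind(centroid[1L] + ringR * cos(ang),
                   centroid[2L] + ringR * sin(ang))
  gens <- rbind(pts, dummies)
  r <- bufferFactor * mib
  polys <- vector("list", n)
  areas <- numeric(n)
  for (b in seq_len(n)) {
    p <- pts[b, ]
    poly <- discPolygon(p, r, discSegments)
    # only generators within 2r can cut the disc with their bisector
    dv <- sweep(gens, 2L, p)
    d2 <- rowSums(dv^2)
    near <- which(d2 > 1e-18 & d2 < (2 * r)^2)
    near <- near[near != b]
    for (q in near) {
      mid <- (gens[q, ] + p) / 2
      a <- dv[q, 1L]; bb <- dv[q, 2L]
      poly <- clipHalfPlane(poly, a, bb, a * mid[1L] + bb * mid[2L])
      if (nrow(poly) == 0L) break
    }
    polys[[b]] <- poly
    areas[b] <- polygonArea(poly)
  }
  names(polys) <- as.character(u - 1L)
  names(areas) <- names(polys)
  new("GaudiPlot", layout = layout, polygons = polys, areas = areas,
      signal = rep(NA_real_, n), bufferRadius = r)
}

#' Attach per-bin signal values to a GaudiPlot
#'
#' @param plot a [GaudiPlot-class].
#' @param values one value per unmasked bin (NA allowed), or one per grid
#'   bin (masked entries dropped).
#' @export
gaudiSignal <- function(plot, values) {
  stopifnot(is(plot, "GaudiPlot"))
  nUn <- length(plot@polygons)
  if (length(values) == nBins(plot@layout) && length(values) != nUn)
    values <- values[!plot@layout@masked]
  if (length(values) != nUn)
    stop("need one signal value per unmasked bin (", nUn, ")")
  plot@signal <- as.numeric(values)
  plot
}

#' Write a GaudiPlot as a GeoJSON FeatureCollection
#'
#' One polygon Feature per unmasked bin with properties bin_index, chrom,
#' start, area and signal.
#'
#' @param plot a [GaudiPlot-class].
#' @param path output file.
#' @export
writeGaudiGeoJSON <- function(plot, path) {
  stopifnot(is(plot, "GaudiPlot"))
  grid <- plot@layout@grid
  feats <- lapply(seq_along(plot@polygons), function(k) {
    poly <- plot@polygons[[k]]
    bin <- as.integer(names(plot@polygons)[k])
    ring <- rbind(poly, poly[1L, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ]))))),
         properties = list(bin_index = bin,
                           chrom = grid@region@chrom,
                           start = grid@binStarts[bin + 1L],
                           area = plot@areas[[k]],
                           signal = if (is.na(plot@signal[k])) NULL
                                    else plot@signal[k]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
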