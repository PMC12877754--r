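# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: the scorer works on character vectors, the
# shortest-path oracle enumerates paths, and the Fisher oracle enumerates
# hypergeometric tables.

# --- brute-force PWM scorer -------------------------------------------------

oracleRevComp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1L]]]), collapse = "")
}

# score every window of seq on one strand; returns numeric vector
oracleScanStrand <- function(seq, probMat, background) {
  ch <- strsplit(seq, "")[[1L]]
  L <- ncol(probMat)
  nW <- length(ch) - L + 1L
  if (nW < 1L) return(numeric())
  vapply(seq_len(nW), function(t) {
    s <- 0
    for (k in seq_len(L)) {
      b <- ch[t + k - 1L]
      if (b != "N")
        s <- s + log2(probMat[b, k] / background[b])
    }
    s
  }, numeric(1L))
}

# full brute-force hit table in plus-strand coordinates
oracleScanPWM <- function(seq, chrom, offset, pwm, thrFrac,
                          bothStrands = TRUE) {
  pm <- motifMatrix(pwm); bg <- motifBackground(pwm)
  L <- ncol(pm)
  maxScore <- sum(apply(log2(pm / bg), 2L, max))
  thr <- thrFrac * maxScore
  plus <- oracleScanStrand(seq, pm, bg)
  res <- data.frame(start = numeric(), strand = character(),
                    score = numeric())
  hp <- which(plus >= thr)
  if (length(hp))
    res <- rbind(res, data.frame(start = offset + hp - 1, strand = "+",
                                 score = plus[hp]))
  if (bothStrands) {
    minus <- oracleScanStrand(oracleRevComp(seq), pm, bg)
    hm <- which(minus >= thr)
    if (length(hm)) {
      n <- nchar(seq)
      res <- rbind(res, data.frame(start = offset + n - L - (hm - 1),
                                   strand = "-", score = minus[hm]))
    }
  }
  res[order(res$start, res$strand), , drop = FALSE]
}

randomPWM <- function(name, L) {
  m <- matrix(rgamma(4 * L, shape = 0.5), 4L, L)
  m <- sweep(m, 2L, colSums(m), "/")
  m <- (m + 0.01) / (1 + 0.04)  # regularize like the readers do
  rownames(m) <- c("A", "C", "G", "T")
  new("PWMotif", name = name, matrix = sweep(m, 2L, colSums(m), "/"),
      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
      pseudocount = 0.01)
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# --- graph shortest-path oracle (enumerate all simple paths, tiny n) --------

oracleShortestPath <- function(edges, n, from, to) {
  # edges: data.frame(i, j, d) with 0-based nodes
  best <- Inf
  adj <- lapply(seq_len(n) - 1L, function(v) {
    rbind(edges[edges$i == v, c("j", "d")],
          setNames(edges[edges$j == v, c("i", "d")], c("j", "d")))
  })
  recurse <- function(v, visited, acc) {
    if (acc >= best) return()
    if (v == to) { best <<- acc; return() }
    nb <- adj[[v + 1L]]
    for (r in seq_len(nrow(nb)))
      if (!(nb$j[r] %in% visited))
        recurse(nb$j[r], c(visited, nb$j[r]), acc + nb$d[r])
  }
  recurse(from, from, 0)
  best
}

# --- Kamada-Kawai stress and lattice oracle ---------------------------------

oracleStress <- function(xy, D) {
  s <- 0
  n <- nrow(D)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      s <- s + (d - D[i, j])^2 / D[i, j]^2
    }
  s
}

# fixed random suite of small target-distance matrices
layoutOracleSuite <- function() {
  withr::with_seed(42L, {
    lapply(1:20, function(k) {
      n <- sample(2:4, 1L)
      d <- matrix(0, n, n)
      d[upper.tri(d)] <- runif(sum(upper.tri(d)), 0.5, 1.5)
      d + t(d)
    })
  })
}

# lattice minimum (step 0.05, node 0 at origin, node 1 on +x axis) for
# n = 2 or 3; n = 4 minima are precomputed with the same lattice by
# inst/scripts/layout_lattice_oracle.py and frozen in the tests.
latticeMinStress <- function(D, step = 0.05, lim = 2) {
  n <- nrow(D)
  x1s <- seq(step, lim, by = step)
  if (n == 2L)
    return(min((x1s - D[1, 2])^2 / D[1, 2]^2))
  g <- seq(-lim, lim, by = step)
  p <- as.matrix(expand.grid(x = g, y = g))
  if (n == 3L) {
    best <- Inf
    d02 <- sqrt(rowSums(p^2))
    s02 <- (d02 - D[1, 3])^2 / D[1, 3]^2
    for (x1 in x1s) {
      s01 <- (x1 - D[1, 2])^2 / D[1, 2]^2
      d12 <- sqrt((p[, 1] - x1)^2 + p[, 2]^2)
      s12 <- (d12 - D[2, 3])^2 / D[2, 3]^2
      best <- min(best, s01 + min(s02 + s12))
    }
    return(best)
  }
  stop("latticeMinStress computes n <= 3 live; use the frozen n = 4 values")
}

# --- exact 2x2 Fisher oracle (hypergeometric enumeration) -------------------

oracleFisher2x2 <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# --- misc -------------------------------------------------------------------

smallPairConfig <- function(...) {
  # 100-kb window (20 bins): same structure as the full study window but
  # small enough for fast parser-roundtrip and symmetry tests
  conditionPairConfig(
    window = parseRegion("chrS:0-100,000"), resolution = 5000,
    tadBoundaries = c(10L), tssBinE = 4L, tssBinL = 15L,
    ap1Offsets = c(-2L, -1L, 1L), ap1Conditions = c("A", "A", "both"),
    tcfOffsets = c(-1L, 0L, 1L), tcfConditions = rep("B", 3L), ...)
}
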