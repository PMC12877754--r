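grid2 <- makeBinGrid(GenomicRegion("chr1", 0, 10000), 5000)
grid3 <- makeBinGrid(GenomicRegion("chr1", 0, 15000), 5000)

test_that("COO contacts read, sum duplicates, mirror, ignore outside", {
  f <- withr::local_tempfile(lines = c("chr1 0 chr1 5000 4",
                                       "chr1 0 chr1 0 10"))
  cm <- readContacts(f, grid2)
  # mirroring fills [j, i] from [i, j]; the (5000, 5000) diagonal was not
  # observed and stays 0
  expect_equal(contactValues(cm), matrix(c(10, 4, 4, 0), 2))

  f2 <- withr::local_tempfile(lines = c("chr1 0 chr1 5000 2",
                                        "chr1 5000 chr1 0 2"))
  expect_equal(contactValues(readContacts(f2, grid2))[1, 2], 4)

  f3 <- withr::local_tempfile(lines = character())
  expect_equal(contactValues(readContacts(f3, grid3)),
               matrix(0, 3, 3))

  f4 <- withr::local_tempfile(lines = c("chr1 0 chr1 5000 1",
                                        "chr2 0 chr2 5000 9",
                                        "chr1 0 chr1 99000 9"))
  expect_message(cm4 <- readContacts(f4, grid2), "ignored 2")
  expect_equal(contactValues(cm4)[1, 2], 1)

  f5 <- withr::local_tempfile(lines = "chr1 123 chr1 5000 1")
  expect_error(readContacts(f5, grid2), "lattice")
  f6 <- withr::local_tempfile(lines = "chr1 0 chr1 5000 -3")
  expect_error(readContacts(f6, grid2), "negative")
})

test_that("ICE balancing reproduces closed forms and masks zero rows", {
  cm <- contactMatrix(grid2, matrix(c(0, 4, 4, 0), 2))
  bal <- iceBalance(cm)
  expect_equal(contactValues(bal), matrix(c(0, 1, 1, 0), 2))
  expect_equal(binBiases(bal), c(2, 2))

  cm3 <- contactMatrix(grid3, matrix(1, 3, 3))
  bal3 <- iceBalance(cm3)
  expect_equal(contactValues(bal3), matrix(1 / 3, 3, 3))
  expect_equal(rowSums(contactValues(bal3)), rep(1, 3))

  vals <- matrix(0, 3, 3); vals[1, 2] <- vals[2, 1] <- 4
  cmM <- contactMatrix(grid3, vals)
  expect_true(maskedBins(cmM)[3])
  balM <- iceBalance(cmM)
  expect_equal(contactValues(balM)[1:2, 1:2], matrix(c(0, 1, 1, 0), 2))
  expect_true(is.na(binBiases(balM)[3]))

  cm0 <- contactMatrix(grid2, matrix(0, 2, 2))
  expect_error(iceBalance(cm0), "all rows are zero")
})

test_that("balanced row sums are uniform and biases invert the balancing", {
  set.seed(23)
  grid <- makeBinGrid(GenomicRegion("chr1", 0, 5000 * 100), 5000)
  for (k in 1:3) {
    raw <- matrix(rpois(100 * 100, 30) * runif(100)^2, 100)
    raw <- raw + t(raw)
    cm <- contactMatrix(grid, raw)
    bal <- iceBalance(cm, maxIter = 200, tol = 1e-9)
    rs <- rowSums(contactValues(bal))
    expect_lt(sd(rs) / mean(rs), 1e-6)
    b <- binBiases(bal)
    rebuilt <- contactValues(bal) * outer(b, b)
    expect_equal(rebuilt, raw, tolerance = 1e-6)
  }
})

test_that("top-interaction selection keeps the k strongest, determinism", {
  # 5-bin matrix with upper-triangle entries 1..10
  grid5 <- makeBinGrid(GenomicRegion("chr1", 0, 25000), 5000)
  v <- matrix(0, 5, 5)
  v[upper.tri(v)] <- 1:10
  v <- v + t(v); diag(v) <- 1
  cm <- contactMatrix(grid5, v, balanced = TRUE)
  g <- buildGraph(cm, 0.2)
  sel <- graphEdges(g)[!graphEdges(g)$backbone, ]
  expect_equal(nrow(sel), 2L)  # ceil(0.2 * 10)
  selVals <- v[cbind(sel$i + 1, sel$j + 1)]
  expect_setequal(selVals, c(9, 10))
  expect_equal(sel$d, 1 / log10(1 + selVals))

  # invariant: every selected value >= every unselected candidate value
  g5 <- buildGraph(cm, 0.5)
  e5 <- graphEdges(g5)
  selV <- v[cbind(e5$i + 1, e5$j + 1)][!e5$backbone]
  unselV <- setdiff(1:10, selV)
  expect_gte(min(selV), max(unselV))

  # all candidates equal: deterministic ascending (i, j) tie-break
  vt <- matrix(1, 4, 4)
  gridT <- makeBinGrid(GenomicRegion("chr1", 0, 20000), 5000)
  cmT <- contactMatrix(gridT, vt, balanced = TRUE)
  gT <- buildGraph(cmT, 0.5)  # k = 3 of 6
  selT <- graphEdges(gT)[!graphEdges(gT)$backbone, ]
  expect_equal(selT[, c("i", "j")],
               data.frame(i = c(0L, 0L, 0L), j = c(1L, 2L, 3L)),
               ignore_attr = TRUE)

  # zero off-diagonal: backbone-only graph with d = 1
  vz <- diag(5)
  cmZ <- contactMatrix(grid5, vz, balanced = TRUE)
  gZ <- buildGraph(cmZ, 0.2)
  eZ <- graphEdges(gZ)
  expect_true(all(eZ$backbone))
  expect_equal(eZ$d, rep(1, 4))
})

test_that("selected edge count is exactly min(k, M) across fractions", {
  set.seed(31)
  grid20 <- makeBinGrid(GenomicRegion("chr1", 0, 1e5), 5000)
  v <- matrix(runif(400), 20); v <- v + t(v); diag(v) <- 1
  v[v < 0.4] <- 0  # structural zeros are not candidates
  v <- (v + t(v)) / 2
  cm <- contactMatrix(grid20, v, balanced = TRUE)
  M <- sum(v[upper.tri(v)] > 0)
  for (f in c(0.05, 0.2, 0.61, 1)) {
    e <- graphEdges(buildGraph(cm, f))
    expect_equal(sum(!e$backbone), min(ceiling(f * M), M))
  }
})

test_that("shortest-path completion matches path enumeration", {
  mkGraph <- function(edges, n)
    new("InteractionGraph", nNodes = as.integer(n),
        edges = cbind(edges, w = 1 / edges$d, backbone = FALSE),
        masked = rep(FALSE, n))

  path3 <- mkGraph(data.frame(i = c(0L, 1L), j = c(1L, 2L), d = c(1, 1)), 3)
  D <- completeDistances(path3)
  expect_equal(D["0", "2"], 2)

  tri <- mkGraph(data.frame(i = c(0L, 0L, 1L), j = c(1L, 2L, 2L),
                            d = c(1, 3, 1)), 3)
  Dt <- completeDistances(tri)
  expect_equal(Dt["0", "2"], 2)  # the two-hop path beats the heavy edge
  expect_equal(Dt["0", "2"],
               oracleShortestPath(tri@edges, 3, 0, 2))

  single <- mkGraph(data.frame(i = 0L, j = 1L, d = 0.5), 2)
  expect_equal(unname(completeDistances(single)),
               matrix(c(0, 0.5, 0.5, 0), 2))

  # random graphs against the enumeration oracle
  set.seed(5)
  for (k in 1:10) {
    n <- sample(4:6, 1)
    full <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
    full <- full[full$i < full$j, ]
    keep <- full[sample(nrow(full), n + 2), ]
    keep <- rbind(keep, data.frame(i = 0:(n - 2), j = 1:(n - 1)))
    keep <- keep[!duplicated(keep[, c("i", "j")]), ]
    keep$d <- round(runif(nrow(keep), 0.1, 2), 3)
    g <- mkGraph(keep, n)
    D <- completeDistances(g)
    for (t in 1:(n - 1))
      expect_equal(D["0", as.character(t)],
                   oracleShortestPath(keep, n, 0, t))
  }
})

test_that("embedding realizes realizable metrics and never worsens stress", {
  e2 <- kamadaKawaiEmbed(matrix(c(0, 1, 1, 0), 2))
  expect_equal(sqrt(sum((e2$xy[1, ] - e2$xy[2, ])^2)), 1, tolerance = 1e-3)
  expect_lt(e2$stress, 1e-6)

  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  e3 <- kamadaKawaiEmbed(D3)
  dd <- as.matrix(dist(e3$xy))
  expect_equal(dd[upper.tri(dd)], rep(1, 3), tolerance = 1e-2)

  sq <- matrix(c(0, 1, sqrt(2), 1,
                 1, 0, 1, sqrt(2),
                 sqrt(2), 1, 0, 1,
                 1, sqrt(2), 1, 0), 4)
  e4 <- kamadaKawaiEmbed(sq)
  expect_lt(e4$stress, 1e-3)

  expect_error(kamadaKawaiEmbed(matrix(c(0, Inf, Inf, 0), 2)),
               "non-finite")
})

test_that("mean interbin distance averages consecutive pairs", {
  xy <- cbind(0:4, 0)
  expect_equal(meanInterbinDistance(xy), 1)
  expect_equal(meanInterbinDistance(cbind(c(0, 0.5), 0)), 0.5)
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(meanInterbinDistance(square), 1)  # (1 + 1 + 1) / 3
  expect_error(meanInterbinDistance(cbind(1, 1)), "at least 2")
})

test_that("layouts are byte-identical across repeated runs", {
  sim <- simulateHiC(makeBinGrid(GenomicRegion("chr1", 0, 2e5), 5000),
                     tadBoundaries = 20L, noise = "poisson", seed = 99L)
  bal <- iceBalance(sim$contacts)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeLayoutTSV(layoutContacts(bal, seed = 7L), f1)
  writeLayoutTSV(layoutContacts(bal, seed = 7L), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("masked bins get NA coordinates and are skipped downstream", {
  vals <- matrix(5, 4, 4)
  vals[2, ] <- 0; vals[, 2] <- 0
  gridM <- makeBinGrid(GenomicRegion("chr1", 0, 20000), 5000)
  cm <- contactMatrix(gridM, vals)
  lay <- layoutContacts(iceBalance(cm))
  expect_true(all(is.na(layoutCoords(lay)[2, ])))
  expect_equal(sum(!maskedBins(lay)), 3L)
  expect_gt(meanInterbin(lay), 0)
})
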