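test_that("per-bin statistics respect zero-fill and conservation", {
  reg <- GenomicRegion("chr1", 0, 20000)
  grid <- makeBinGrid(reg, 5000)

  const <- signalTrack(reg, 0, 20000, 2.5)
  expect_equal(binSignal(const, grid, "mean"), rep(2.5, 4))

  set.seed(17)
  s <- seq(0, 19000, by = 1000)
  tr <- signalTrack(reg, s, s + 700, round(runif(20, 0, 5), 2))
  expect_equal(sum(binSignal(tr, grid, "sum")), trackIntegral(tr))

  half <- signalTrack(reg, 0, 2500, 1.0)  # first half of bin 0 only
  expect_equal(binSignal(half, grid, "mean")[1], 0.5)
  expect_equal(binSignal(half, grid, "max"), c(1, 0, 0, 0))

  small <- signalTrack(GenomicRegion("chr1", 0, 10000))
  expect_error(binSignal(small, grid), "cover")
})

test_that("TSS bin indexing is half-open at bin boundaries", {
  grid <- makeBinGrid(GenomicRegion("chr1", 0, 20000), 5000)
  expect_equal(tssBinOf(grid, 4999), 0L)
  expect_equal(tssBinOf(grid, 5000), 1L)
  fig <- makeBinGrid(parseRegion("chr6:134,835,000-135,835,000"), 5000)
  expect_equal(tssBinOf(fig, 135335000), 100L)  # window midpoint
  expect_error(tssBinOf(grid, 20000), "outside")
})

test_that("spatial neighborhoods select by layout distance, inclusive", {
  n <- 11
  grid <- makeBinGrid(GenomicRegion("chr1", 0, 5000 * n), 5000)
  lay <- spatialLayout(grid, cbind(0:(n - 1), 0))  # meanInterbin = 1
  sel <- tssNeighborhood(lay, 5L, 3.0)
  expect_equal(memberBins(sel), 2:8)  # tss +/- 3 inclusive: 7 members

  sel0 <- tssNeighborhood(lay, 5L, 0)
  expect_equal(memberBins(sel0), 5L)

  selAll <- tssNeighborhood(lay, 5L, 100)
  expect_equal(memberBins(selAll), 0:(n - 1))

  expect_equal(nrow(neighborhoodArcs(sel, grid)), 6L)

  xy <- cbind(0:(n - 1), 0); xy[3, ] <- NA
  layM <- spatialLayout(grid, xy)
  expect_error(tssNeighborhood(layM, 2L), "masked")
  selM <- tssNeighborhood(layM, 5L, 3.0)
  expect_false(2L %in% memberBins(selM))
})

test_that("contribution filtering thresholds window-wide then intersects", {
  reg <- GenomicRegion("chr1", 0, 10)
  grid <- makeBinGrid(reg, 5)
  lay <- spatialLayout(grid, cbind(c(0, 1), 0))
  selAll <- tssNeighborhood(lay, 0L, 100)
  tr <- signalTrack(reg, 0:9, 1:10, 1:10)

  iv <- highContributionIntervals(tr, reg, 0.9, selAll)
  # type-7 quantile of 1..10 at 0.9 is 9.1: only the score-10 base passes
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$start, iv$end), c(9, 10))
  expect_equal(attr(iv, "threshold"), 9.1)

  trEq <- signalTrack(reg, 0, 10, 3)
  ivEq <- highContributionIntervals(trEq, reg, 0.9, selAll)
  expect_equal(c(ivEq$start, ivEq$end), c(0, 10))  # >= is non-strict

  selBin0 <- tssNeighborhood(lay, 0L, 0.5)
  ivB <- highContributionIntervals(tr, reg, 0.5, selBin0)
  expect_true(all(ivB$end <= 5))  # top bin excluded by the neighborhood

  trZ <- signalTrack(reg)
  expect_warning(ivZ <- highContributionIntervals(trZ, reg, 0.9, selAll),
                 "all zero")
  expect_equal(nrow(ivZ), 0L)
})

test_that("retained-base count is exact and merging is idempotent", {
  set.seed(41)
  reg <- GenomicRegion("chr1", 0, 4000)
  grid <- makeBinGrid(reg, 1000)
  lay <- spatialLayout(grid, cbind(0:3, 0))
  for (k in 1:10) {
    x <- round(runif(4000), 3)
    tr <- signalTrack(reg, 0:3999, 1:4000, x)
    sel <- tssNeighborhood(lay, sample(0:3, 1), sample(c(0, 1, 2.5), 1))
    q <- runif(1, 0.5, 0.95)
    iv <- highContributionIntervals(tr, reg, q, sel)
    thr <- attr(iv, "threshold")
    member <- logical(4000)
    for (r in seq_len(nrow(memberRegions(sel)))) {
      mr <- memberRegions(sel)[r, ]
      member[(mr$start + 1):mr$end] <- TRUE
    }
    expect_equal(sum(iv$end - iv$start), sum(x >= thr & member))
    # merged intervals are maximal: no two adjacent
    if (nrow(iv) > 1)
      expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
  }
})

test_that("planted consensus sites are found on the correct strands", {
  pwm <- consensusPWM("M", "ACGT")
  hits <- scanPWM("TTTTACGTTTTT", "chr1", 100, pwm, 0.8, TRUE)
  # ACGT is palindromic, so the site is also reported on the minus strand
  expect_equal(hits$start, c(104, 104))
  expect_setequal(hits$strand, c("+", "-"))
  plusOnly <- scanPWM("TTTTACGTTTTT", "chr1", 100, pwm, 0.8, FALSE)
  expect_equal(nrow(plusOnly), 1L)
  expect_equal(plusOnly$start, 104)
  expect_equal(plusOnly$strand, "+")

  pwm2 <- consensusPWM("M2", "AACC")
  hits2 <- scanPWM("TTGGTT", "chr1", 50, pwm2, 0.8, TRUE)
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$start, 52)  # window GGTT = revcomp of AACC

  # threshold 1.0 with no exact consensus window
  hits3 <- scanPWM("AAAAAAA", "chr1", 0, consensusPWM("M3", "ACGT"), 1.0)
  expect_equal(nrow(hits3), 0L)

  # motif longer than sequence: empty, not an error
  expect_equal(nrow(scanPWM("ACG", "chr1", 0, pwm)), 0L)
  expect_error(scanPWM("ACXT", "chr1", 0, pwm), "invalid sequence")
})

test_that("N bases contribute zero log-odds", {
  pwm <- consensusPWM("M", "ACGT", offRate = 0.1)
  h1 <- scanPWM("ACGT", "chr1", 0, pwm, 0.5, FALSE)
  hN <- scanPWM("ACGN", "chr1", 0, pwm, 0.5, FALSE)
  expect_equal(nrow(h1), 1L)
  S <- log2(motifMatrix(pwm) / motifBackground(pwm))
  expect_equal(hN$score, h1$score - S["T", 4], ignore_attr = TRUE)
})

test_that("the scanner agrees exactly with the brute-force scorer", {
  set.seed(101)
  for (rep in 1:30) {
    L <- sample(5:12, 1)
    pwm <- randomPWM(paste0("R", rep), L)
    seq <- randomSeq(200)
    if (rep %% 7 == 0) {  # inject Ns
      pos <- sample(200, 5)
      substr(seq, pos[1], pos[1]) <- "N"
    }
    thr <- runif(1, 0.5, 0.9)
    mine <- scanPWM(seq, "c", 1000, pwm, thr, TRUE)
    oracle <- oracleScanPWM(seq, "c", 1000, pwm, thr, TRUE)
    expect_equal(nrow(mine), nrow(oracle))
    expect_equal(mine$start, oracle$start)
    expect_equal(mine$strand, oracle$strand)
    expect_equal(mine$score, oracle$score, tolerance = 1e-12)
  }
})

test_that("raising the score threshold never adds hits (monotone)", {
  set.seed(303)
  pwm <- randomPWM("mono", 8)
  seq <- randomSeq(500)
  prev <- Inf
  for (thr in c(0.5, 0.65, 0.8, 0.95)) {
    nh <- nrow(scanPWM(seq, "c", 0, pwm, thr, TRUE))
    expect_lte(nh, prev)
    prev <- nh
  }
})

test_that("family collapse counts unique sites, unmapped keep own name", {
  hits <- data.frame(
    motif = c("FOSL1", "JUNB", "TCF7L2", "TCF7L2"),
    chrom = "chr1",
    start = c(100, 100, 300, 400),
    end = c(107, 107, 307, 407),
    strand = c("+", "-", "+", "+"),
    score = 1, scoreFraction = 1)
  counts <- countHitsByFamily(hits)
  expect_equal(counts[["AP1"]], 1L)       # same coordinates collapse
  expect_equal(counts[["TCF/LEF"]], 2L)   # disjoint sites stay separate

  expect_equal(length(countHitsByFamily(hits[0, ])), 0L)

  odd <- hits[1, ]; odd$motif <- "NOVEL1"
  expect_message(co <- countHitsByFamily(odd), "unmapped")
  expect_equal(names(co), "NOVEL1")

  # HOCOMOCO-style identifiers resolve to their family
  hoco <- hits[1:2, ]
  hoco$motif <- c("JUNB_MOUSE.H11MO.0.A", "FOSL1_MOUSE.H11MO.0.A")
  expect_equal(names(countHitsByFamily(hoco)), "AP1")

  # partially overlapping hits of one family chain into one site
  chain <- data.frame(motif = c("JUN", "FOS"), chrom = "chr1",
                      start = c(100, 104), end = c(107, 111),
                      strand = "+", score = 1, scoreFraction = 1)
  expect_equal(unname(countHitsByFamily(chain)), 1L)
  sites <- familySites(chain)
  expect_equal(c(sites$start, sites$end), c(100, 111))
})

test_that("enrichment matches the hypergeometric oracle and BH ordering", {
  pwm <- consensusPWM("M", "ACGTACGT")
  withHit <- function() paste0(randomSeq(10), "ACGTACGT", randomSeq(10))
  withoutHit <- function() paste0(strrep("A", 28))
  set.seed(55)
  fg <- c(replicate(8, withHit()), replicate(2, withoutHit()))
  bg <- c(replicate(1, withHit()), replicate(9, withoutHit()))
  res <- motifEnrichment(fg, bg, list(pwm), 0.9)
  expect_equal(res$fgWith, 8L)
  expect_equal(res$bgWith, 1L)
  expect_equal(res$oddsRatio, (8 * 9) / (2 * 1))
  expect_equal(res$p, oracleFisher2x2(8, 2, 1, 9), tolerance = 1e-9)

  resEq <- motifEnrichment(fg, fg, list(pwm), 0.9)
  expect_equal(resEq$oddsRatio, 1)
  expect_equal(resEq$p, 1)

  none <- consensusPWM("none", "GGGGGGGGGG")
  resN <- motifEnrichment(fg, bg, list(none), 1.0)
  expect_equal(resN$p, 1)

  multi <- motifEnrichment(fg, bg, list(pwm, none), 0.9)
  expect_true(all(diff(multi$q) >= 0))  # ranked ascending by q
  expect_equal(multi$q, p.adjust(multi$p[order(multi$p)], "BH")[
    rank(multi$p, ties.method = "first")][order(multi$q)])

  expect_error(motifEnrichment(character(), bg, list(pwm)), "non-empty")
})

test_that("differential reports carry counts, deltas and site membership", {
  mkHits <- function(starts, motif = "JUNB")
    data.frame(motif = motif, chrom = "chr6", start = starts,
               end = starts + 7, strand = "+", score = 10,
               scoreFraction = 1)
  hitsA <- mkHits(c(100, 200, 300, 400, 500, 600))
  hitsB <- mkHits(c(100, 200, 300))
  rep <- differentialOccupancy(hitsA, hitsB)
  expect_equal(rep$countA, 6L)
  expect_equal(rep$countB, 3L)
  expect_equal(rep$delta, 3L)
  sites <- attr(rep, "sites")
  expect_equal(sum(sites$inA & !sites$inB), 3L)  # open in A, closed in B

  repEq <- differentialOccupancy(hitsA, hitsA)
  expect_equal(repEq$delta, 0L)

  repB <- differentialOccupancy(hitsA[0, ], mkHits(c(10, 50), "TCF7"))
  expect_equal(repB$countA, 0L)
  expect_equal(repB$delta, -2L)

  gridA <- makeBinGrid(GenomicRegion("chr6", 0, 10000), 5000)
  gridB <- makeBinGrid(GenomicRegion("chr6", 0, 20000), 5000)
  expect_error(differentialOccupancy(hitsA, hitsB, gridA = gridA,
                                     gridB = gridB), "different grids")

  # rows are sorted by |delta| descending
  two <- differentialOccupancy(rbind(hitsA, mkHits(900, "TCF7")),
                               rbind(hitsB, mkHits(900, "TCF7")))
  expect_equal(two$family, c("AP1", "TCF/LEF"))
})
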