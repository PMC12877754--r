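test_that("region strings parse with separators, en-dash and plain form", {
  r <- parseRegion("chr6:134,835,000-135,835,000")
  expect_equal(regionChrom(r), "chr6")
  expect_equal(regionStart(r), 134835000)
  expect_equal(regionEnd(r), 135835000)

  r2 <- parseRegion("chr10:114,920,000–115,925,000")  # en-dash
  expect_equal(c(regionStart(r2), regionEnd(r2)), c(114920000, 115925000))

  r3 <- parseRegion("chr1:0-5000")
  expect_equal(c(regionStart(r3), regionEnd(r3)), c(0, 5000))

  expect_error(parseRegion("chr1:5000-5000"), "not below")
  expect_error(parseRegion("chr1-100-200"), "cannot parse")
  expect_error(parseRegion("chr1:abc-200"), "cannot parse")
})

test_that("parseRegion inverts formatRegion on canonical strings", {
  set.seed(7)
  for (k in 1:25) {
    s <- sort(sample.int(1e8, 2))
    r <- GenomicRegion(paste0("chr", sample(1:19, 1)), s[1], s[2])
    expect_equal(formatRegion(parseRegion(formatRegion(r))),
                 formatRegion(r))
  }
})

test_that("bin grids tile the region exactly, clipping the last bin", {
  g <- makeBinGrid(parseRegion("chr6:134,835,000-135,835,000"), 5000)
  expect_equal(nBins(g), 200L)

  g2 <- makeBinGrid(GenomicRegion("chr1", 0, 10000), 5000)
  expect_equal(binStarts(g2), c(0, 5000))

  g3 <- makeBinGrid(GenomicRegion("chr1", 0, 10001), 5000)
  expect_equal(nBins(g3), 3L)
  expect_equal(binEnds(g3)[3] - binStarts(g3)[3], 1)

  # tiling invariant: bin widths sum to the region width
  for (res in c(137, 1000, 4999)) {
    gg <- makeBinGrid(GenomicRegion("chrX", 100, 25000), res)
    expect_equal(sum(binEnds(gg) - binStarts(gg)), 25000 - 100)
  }
  expect_error(makeBinGrid(GenomicRegion("chr1", 0, 10), 0), "positive")
})

test_that("bedGraph reading clips, zero-fills and rejects overlaps", {
  reg <- GenomicRegion("chr1", 0, 20)
  f <- withr::local_tempfile(lines = "chr1 0 10 2.5")
  tr <- readBedGraph(f, reg)
  expect_equal(baseValues(tr), c(rep(2.5, 10), rep(0, 10)))

  f2 <- withr::local_tempfile(lines = c("chr1 0 10 1.0", "chr1 10 20 3.0"))
  tr2 <- readBedGraph(f2, reg)
  expect_equal(mean(baseValues(tr2)), 2.0)

  f3 <- withr::local_tempfile(lines = character())
  expect_equal(trackIntegral(readBedGraph(f3, reg)), 0)

  f4 <- withr::local_tempfile(lines = c("chr1 0 10 1", "chr1 5 15 1"))
  expect_error(readBedGraph(f4, reg), "overlap")
  f5 <- withr::local_tempfile(lines = "chr1 10 5 1")
  expect_error(readBedGraph(f5, reg), "end <= start")
  f6 <- withr::local_tempfile(lines = "chr1 0 10 xyz")
  expect_error(readBedGraph(f6, reg), "non-numeric")
})

test_that("bedGraph integral is conserved under clipping (property)", {
  set.seed(11)
  reg <- GenomicRegion("chr2", 50, 450)
  for (k in 1:20) {
    n <- sample(1:12, 1)
    bounds <- sort(sample(0:500, 2 * n))
    s <- bounds[seq(1, 2 * n, 2)]; e <- bounds[seq(2, 2 * n, 2)]
    keep <- e > s
    s <- s[keep]; e <- e[keep]
    if (!length(s)) next
    v <- round(runif(length(s), -3, 3), 3)
    f <- withr::local_tempfile(
      lines = sprintf("chr2 %d %d %s", s, e, format(v, trim = TRUE)))
    tr <- readBedGraph(f, reg)
    cs <- pmax(s, 50); ce <- pmin(e, 450)
    expected <- sum(pmax(ce - cs, 0) * v)
    expect_equal(trackIntegral(tr), expected, tolerance = 1e-9)
  }
})

test_that("FASTA reading uppercases, keeps N, rejects duplicates", {
  f <- withr::local_tempfile(lines = c(">s", "acgt"))
  x <- readGenomeFasta(f)
  expect_equal(as.character(x[["s"]]), "ACGT")

  f2 <- withr::local_tempfile(lines = c(">m", "ACGT", "acgt", "NNgt"))
  x2 <- readGenomeFasta(f2)
  expect_equal(nchar(as.character(x2[["m"]])), 12L)
  expect_match(as.character(x2[["m"]]), "NN")

  f3 <- withr::local_tempfile(lines = c(">a", "ACGT", ">a", "TTTT"))
  expect_error(readGenomeFasta(f3), "duplicate")
  f4 <- withr::local_tempfile(lines = character())
  expect_error(readGenomeFasta(f4), "no records")
})

test_that("MEME minimal motifs parse with recoverable consensus", {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "Background letter frequencies",
             "A 0.3 C 0.2 G 0.2 T 0.3", "",
             "MOTIF ACGT_TEST",
             "letter-probability matrix: alphabet= 4 w= 4 nsites= 10 E= 0",
             "1 0 0 0", "0 1 0 0", "0 0 1 0", "0 0 0 1", "",
             "MOTIF SECOND",
             "letter-probability matrix: alphabet= 4 w= 2",
             "0.97 0.01 0.01 0.01", "0.01 0.01 0.97 0.01")
  f <- withr::local_tempfile(lines = lines)
  pwms <- readPWMs(f, "meme")
  expect_length(pwms, 2L)
  expect_equal(names(pwms), c("ACGT_TEST", "SECOND"))  # file order kept
  expect_equal(motifConsensus(pwms[[1]]), "ACGT")
  expect_equal(motifConsensus(pwms[[2]]), "AG")
  expect_equal(unname(motifBackground(pwms[[1]])), c(0.3, 0.2, 0.2, 0.3))

  bad <- sub("1 0 0 0", "0.5 0 0 0", lines)
  fb <- withr::local_tempfile(lines = bad)
  expect_error(readPWMs(fb, "meme"), "sum to ~1")
})

test_that("JASPAR counts convert with the per-cell pseudocount", {
  lines <- c(">MA0001 TEST", "A [ 8 0 ]", "C [ 0 8 ]", "G [ 0 0 ]",
             "T [ 0 0 ]")
  f <- withr::local_tempfile(lines = lines)
  pwms <- readPWMs(f, "jaspar", pseudocount = 0.01)
  m <- motifMatrix(pwms[[1]])
  expect_equal(unname(m["A", 1]), 8.01 / 8.04, tolerance = 1e-12)
  expect_equal(unname(m["G", 2]), 0.01 / 8.04, tolerance = 1e-12)

  fneg <- withr::local_tempfile(lines = sub("8 0", "-1 0", lines[1:5]))
  expect_error(readPWMs(fneg, "jaspar"), "negative")
})

test_that("parsed PWMs satisfy the probability invariants (property)", {
  set.seed(13)
  for (k in 1:15) {
    L <- sample(4:12, 1)
    counts <- matrix(rpois(4 * L, 20), 4L)
    lines <- c(">rnd", paste(c("A", "C", "G", "T"),
                             apply(counts, 1, paste, collapse = " ")))
    f <- withr::local_tempfile(lines = lines)
    p <- readPWMs(f, "jaspar")[[1]]
    m <- motifMatrix(p)
    expect_true(all(abs(colSums(m) - 1) < 1e-9))
    expect_true(all(m > 0))
    expect_true(validObject(p))
  }
})

test_that("BED reading sorts, clips and filters", {
  f <- withr::local_tempfile(lines = c("chr1 300 400", "chr1 100 200 x 0 +",
                                       "chr1 250 260"))
  df <- readBed(f)
  expect_equal(df$start, c(100, 250, 300))
  expect_equal(df$end[1] - df$start[1], 100)

  df2 <- readBed(f, GenomicRegion("chr1", 0, 50))
  expect_equal(nrow(df2), 0L)

  fbad <- withr::local_tempfile(lines = "chr1 100 100")
  expect_error(readBed(fbad), "end <= start")
})
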