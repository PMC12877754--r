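withSeed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

tadIdOf <- function(binIdx0, tadBoundaries) {
  # boundaries are 0-based bin indices where a new TAD starts
  findInterval(binIdx0, sort(tadBoundaries))
}

#' Simulate a TAD-structured Hi-C contact matrix
#'
#' Expected counts follow a power-law distance decay with a within-TAD
#' enrichment: `mu_ij = depth * (1 + |i - j|)^(-decayAlpha) *
#' (tadBoost if i, j share a TAD else 1)` for `i != j`, and `depth` on the
#' diagonal. With `noise = "poisson"` counts are Poisson draws around `mu`
#' (upper triangle drawn, then mirrored so the matrix is exactly
#' symmetric).
#'
#' @param grid a [BinGrid-class].
#' @param tadBoundaries 0-based bin indices at which a new TAD starts
#'   (strictly inside the grid).
#' @param decayAlpha power-law decay exponent (default 1, the canonical
#'   contact-decay slope).
#' @param tadBoost within-TAD contact multiplier (default 3).
#' @param depth expected diagonal count (default 100).
#' @param noise `"none"` (deterministic means) or `"poisson"`.
#' @param seed integer seed; NULL uses the current RNG state.
#' @return list with `contacts` (unbalanced [ContactMatrix-class]) and
#'   `truth` (tadBoundaries, seed).
#' @export
simulateHiC <- function(grid, tadBoundaries = integer(), decayAlpha = 1,
                        tadBoost = 3, depth = 100,
                        noise = c("none", "poisson"), seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(is(grid, "BinGrid"), depth > 0, decayAlpha >= 0, tadBoost >= 1)
  n <- nBins(grid)
  if (length(tadBoundaries) &&
      (any(tadBoundaries <= 0) || any(tadBoundaries >= n)))
    stop("tadBoundaries must lie strictly inside the grid")
  idx <- seq_len(n) - 1L
  tad <- tadIdOf(idx, tadBoundaries)
  s <- abs(outer(idx, idx, "-"))
  mu <- depth * (1 + s)^(-decayAlpha)
  sameTad <- outer(tad, tad, "==")
  boost <- ifelse(sameTad, tadBoost, 1)
  diag(boost) <- 1
  mu <- mu * boost
  diag(mu) <- depth
  vals <- withSeed(seed, {
    if (noise == "none") mu
    else {
      v <- matrix(0, n, n)
      ut <- upper.tri(mu, diag = TRUE)
      v[ut] <- rpois(sum(ut), mu[ut])
      low <- lower.tri(v)
      v[low] <- t(v)[low]
      v
    }
  })
  list(contacts = contactMatrix(grid, vals, balanced = FALSE),
       truth = list(tadBoundaries = as.integer(sort(tadBoundaries)),
                    seed = seed))
}

#' Simulate a genome window with planted motif instances
#'
#' Background bases are i.i.d. with the given GC content; each planted
#' consensus is written verbatim at its position (reverse-complemented for
#' minus-strand plants). Plants must be non-overlapping and inside the
#' window.
#'
#' @param window a [GenomicRegion-class].
#' @param gc GC fraction of the background (default 0.4).
#' @param planted data.frame with columns consensus, position (0-based
#'   genomic start), strand ("+"/"-"); optional extra columns are carried
#'   into the truth table.
#' @param seed integer seed; NULL uses the current RNG state.
#' @param scrubChance when TRUE (default), chance occurrences of any
#'   planted consensus (either strand) in the background are broken by a
#'   deterministic single-base substitution, so exact-consensus scan hits
#'   coincide with the planted truth.
#' @return list with `chrom`, `seq` (character), and `truth` (data.frame of
#'   planted sites with start/end).
#' @export
simulateGenome <- function(window, gc = 0.4, planted = NULL, seed = NULL,
                           scrubChance = TRUE) {
  stopifnot(is(window, "GenomicRegion"), gc >= 0, gc <= 1)
  w <- regionWidth(window)
  seq <- withSeed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), w, replace = TRUE, prob = p), collapse = "")
  })
  truth <- data.frame(consensus = character(), start = numeric(),
                      end = numeric(), strand = character())
  if (!is.null(planted) && nrow(planted)) {
    planted$start <- planted$position
    planted$end <- planted$position + nchar(planted$consensus)
    if (any(planted$start < window@start) || any(planted$end > window@end))
      stop("planted site outside the window")
    o <- order(planted$start)
    planted <- planted[o, , drop = FALSE]
    if (nrow(planted) > 1L &&
        any(planted$start[-1L] < planted$end[-nrow(planted)]))
      stop("planted sites overlap")
    for (k in seq_len(nrow(planted))) {
      ins <- toupper(planted$consensus[k])
      if (planted$strand[k] == "-") ins <- revComp(ins)
      off <- planted$start[k] - window@start
      substr(seq, off + 1, off + nchar(ins)) <- ins
    }
    truth <- planted
    rownames(truth) <- NULL
    if (scrubChance)
      seq <- scrubChanceConsensus(seq, window@start, truth)
  }
  list(chrom = window@chrom, seq = seq, truth = truth)
}

# Break chance (non-planted) occurrences of the planted consensus strings,
# on either strand, by substituting the middle base with a deterministic
# alternative that matches neither the consensus nor its reverse complement
# at that position. Bounded re-scan in case a substitution creates a new
# occurrence.
scrubChanceConsensus <- function(seq, offset, truth) {
  patterns <- unique(toupper(truth$consensus))
  patterns <- unique(c(patterns, vapply(patterns, revComp, character(1L))))
  protected <- cbind(truth$start - offset, truth$end - offset)  # 0-based
  for (pass in 1:10) {
    dirty <- FALSE
    for (pat in patterns) {
      L <- nchar(pat)
      occ <- gregexpr(pat, seq, fixed = TRUE)[[1L]]
      if (occ[1L] == -1L) next
      for (p in occ) {  # p is 1-based
        s0 <- p - 1L
        if (any(s0 < protected[, 2L] & s0 + L > protected[, 1L])) next
        mid <- p + L %/% 2L
        orig <- substr(seq, mid, mid)
        avoid <- c(orig, substr(pat, 1L + L %/% 2L, 1L + L %/% 2L),
                   substr(revComp(pat), 1L + L %/% 2L, 1L + L %/% 2L))
        repl <- setdiff(c("A", "T", "C", "G"), avoid)[1L]
        substr(seq, mid, mid) <- repl
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  seq
}

# Exact per-base integral of a unit tent over [0, W] with apex 1 at W/2;
# returns W per-base values summing exactly to W/2.
tentBump <- function(W) {
  h <- W / 2
  Fn <- function(x) ifelse(x <= h, x^2 / (2 * h),
                           h / 2 + (x - h) - (x - h)^2 / (2 * h))
  Fn(seq_len(W)) - Fn(seq_len(W) - 1)
}

#' Simulate accessibility and contribution tracks
#'
#' The accessibility (ATAC-like) track is `basal` everywhere plus
#' `peakHeight` over the peak bins, with zero-truncated Gaussian noise of
#' sd `noiseSd` applied per `noiseChunk`-bp chunk (coverage noise is
#' locally correlated). The contribution track carries a footprint-shaped
#' tent bump of apex ~1 spanning each planted site +/- 5 bp (per-base
#' values are the exact per-base integral of the tent, so each bump
#' integrates to `(siteWidth + 10) / 2`), on top of a low-amplitude
#' half-normal background of scale `contribBackground` (sequence models
#' assign every base a small nonzero contribution; set 0 for a
#' strictly-sparse track).
#'
#' @param grid a [BinGrid-class].
#' @param peakBins 0-based indices of accessible (peak) bins.
#' @param peakHeight added coverage over peak bins (default 5).
#' @param basal basal coverage (default 1); `peakHeight > basal >= 0`.
#' @param noiseSd Gaussian noise sd on the accessibility track (default 0).
#' @param plantedSites data.frame with start, end (0-based genomic) of the
#'   sites whose footprints are visible in this condition; NULL for none.
#' @param contribBackground half-normal scale of the contribution
#'   background (default 0.01).
#' @param noiseChunk chunk width in bp for accessibility noise; must divide
#'   the resolution (default 100).
#' @param seed integer seed; NULL uses the current RNG state.
#' @return list with `atac` and `contrib` [SignalTrack-class] objects.
#' @export
simulateTracks <- function(grid, peakBins = integer(), peakHeight = 5,
                           basal = 1, noiseSd = 0, plantedSites = NULL,
                           contribBackground = 0.01, noiseChunk = 100,
                           seed = NULL) {
  stopifnot(is(grid, "BinGrid"), peakHeight > basal, basal >= 0)
  n <- nBins(grid)
  if (length(peakBins) && (any(peakBins < 0) || any(peakBins >= n)))
    stop("peak bins outside the grid")
  reg <- grid@region
  w <- regionWidth(reg)
  if (grid@resolution %% noiseChunk != 0)
    stop("noiseChunk must divide the resolution")
  withSeed(seed, {
    nChunk <- ceiling(w / noiseChunk)
    cs <- reg@start + noiseChunk * (seq_len(nChunk) - 1)
    ce <- pmin(cs + noiseChunk, reg@end)
    chunkBin <- (cs - reg@start) %/% grid@resolution
    vals <- basal + peakHeight * (chunkBin %in% peakBins)
    if (noiseSd > 0) vals <- pmax(0, vals + rnorm(nChunk, 0, noiseSd))
    atac <- signalTrack(reg, cs, ce, vals)
    base <- if (contribBackground > 0)
      abs(rnorm(w, 0, contribBackground)) else numeric(w)
    if (!is.null(plantedSites) && nrow(plantedSites)) {
      for (k in seq_len(nrow(plantedSites))) {
        s <- plantedSites$start[k] - 5; e <- plantedSites$end[k] + 5
        W <- e - s
        lo <- max(s, reg@start); hi <- min(e, reg@end)
        if (lo < hi) {
          bump <- tentBump(W)[(lo - s + 1):(hi - s)]
          at <- (lo - reg@start + 1):(hi - reg@start)
          base[at] <- base[at] + bump
        }
      }
    }
    contrib <- if (any(base != 0))
      signalTrack(reg, reg@start + seq_len(w) - 1, reg@start + seq_len(w),
                  base)
    else signalTrack(reg)
    list(atac = atac, contrib = contrib)
  })
}

#' Configuration for a two-condition simulation
#'
#' Defines the study conditions the package's end-to-end analysis targets:
#' one 1-Mb window at 5-kb resolution (200 bins) containing two loci, "E"
#' in an early TAD and "L" in a late TAD. AP1-family consensus sites are
#' planted in bins flanking the TSS of E and are accessible (peaked and
#' footprinted) in condition A, three of them also in condition B;
#' TCF/LEF-family sites flank the TSS of L and are accessible only in
#' condition B. This mirrors a vehicle-versus-treatment design in which
#' AP1 occupancy drops from six to three sites while five TCF/LEF sites
#' gain occupancy.
#'
#' @param window analysis window (default the 1-Mb window
#'   `chr6:134,835,000-135,835,000`).
#' @param resolution bin width (default 5000).
#' @param tadBoundaries 0-based bin indices starting new TADs; default:
#'   four equal TADs (50, 100, 150 for the 1-Mb default window).
#' @param tssBinE,tssBinL 0-based TSS bins of the two loci; default: the
#'   centers of the first and last TAD (25 and 175 for the default
#'   window), TSS at the bin midpoint.
#' @param ap1Offsets bin offsets from `tssBinE` carrying one AP1 site each.
#' @param ap1Conditions condition tag per AP1 site: "A", "B" or "both".
#' @param tcfOffsets bin offsets from `tssBinL` carrying one TCF/LEF site.
#' @param tcfConditions condition tag per TCF/LEF site.
#' @param ap1Consensus,tcfConsensus planted consensus cores (defaults
#'   TGACTCA and CTTTGTT).
#' @param decayAlpha,tadBoost,depth,hicNoise Hi-C generator parameters.
#' @param peakHeight,basal,noiseSd,contribBackground track generator
#'   parameters.
#' @param gc background GC content.
#' @export
conditionPairConfig <- function(
    window = parseRegion("chr6:134,835,000-135,835,000"),
    resolution = 5000,
    tadBoundaries = NULL,
    tssBinE = NULL, tssBinL = NULL,
    ap1Offsets = c(-3L, -2L, -1L, 1L, 2L, 3L),
    ap1Conditions = c("A", "A", "A", "both", "both", "both"),
    tcfOffsets = c(-2L, -1L, 0L, 1L, 2L),
    tcfConditions = rep("B", 5L),
    ap1Consensus = "TGACTCA", tcfConsensus = "CTTTGTT",
    decayAlpha = 1, tadBoost = 3, depth = 100,
    hicNoise = c("none", "poisson"),
    peakHeight = 5, basal = 1, noiseSd = 0, contribBackground = 0.01,
    gc = 0.4) {
  n <- ceiling(regionWidth(window) / resolution)
  # defaults scale with the window: four equal TADs, locus E centered in
  # the first, locus L in the last (the 1-Mb default gives 50/100/150,
  # bins 25 and 175)
  if (is.null(tadBoundaries)) tadBoundaries <- round(n * (1:3) / 4)
  if (is.null(tssBinE)) tssBinE <- round(n / 8)
  if (is.null(tssBinL)) tssBinL <- round(7 * n / 8)
  list(window = window, resolution = resolution,
       tadBoundaries = as.integer(tadBoundaries),
       tssBinE = as.integer(tssBinE), tssBinL = as.integer(tssBinL),
       ap1Offsets = as.integer(ap1Offsets), ap1Conditions = ap1Conditions,
       tcfOffsets = as.integer(tcfOffsets), tcfConditions = tcfConditions,
       ap1Consensus = ap1Consensus, tcfConsensus = tcfConsensus,
       decayAlpha = decayAlpha, tadBoost = tadBoost, depth = depth,
       hicNoise = match.arg(hicNoise), peakHeight = peakHeight,
       basal = basal, noiseSd = noiseSd,
       contribBackground = contribBackground, gc = gc)
}

#' Simulate a matched two-condition bundle (Hi-C, tracks, genome)
#'
#' Generates one shared genome with all sites planted, per-condition Hi-C
#' matrices over the same TADs, and per-condition accessibility and
#' contribution tracks in which only the sites tagged for that condition
#' (or "both") are peaked and footprinted.
#'
#' @param config list from [conditionPairConfig()].
#' @param seed integer seed; every draw derives from it.
#' @return list with `grid`, `genome`, `conditions` (named list A, B; each
#'   with `contacts`, `atac`, `contrib`, `peakBins`), `pwms` (AP1 and
#'   TCF/LEF consensus models), and `truth` (site table with condition
#'   tags, TAD boundaries, TSS bins).
#' @export
simulateConditionPair <- function(config = conditionPairConfig(),
                                  seed = 1L) {
  grid <- makeBinGrid(config$window, config$resolution)
  n <- nBins(grid)
  binMid <- function(b) grid@binStarts[b + 1L] +
    floor(grid@resolution / 2)
  ap1Bins <- config$tssBinE + config$ap1Offsets
  tcfBins <- config$tssBinL + config$tcfOffsets
  if (any(c(ap1Bins, tcfBins, config$tssBinE, config$tssBinL) < 0) ||
      any(c(ap1Bins, tcfBins, config$tssBinE, config$tssBinL) >= n))
    stop("loci or site bins fall outside the window")
  sites <- rbind(
    data.frame(family = "AP1", consensus = config$ap1Consensus,
               bin = ap1Bins, condition = config$ap1Conditions,
               strand = "+", locus = "E"),
    data.frame(family = "TCF/LEF", consensus = config$tcfConsensus,
               bin = tcfBins, condition = config$tcfConditions,
               strand = "+", locus = "L"))
  sites$position <- binMid(sites$bin)
  sites$chrom <- config$window@chrom
  withSeed(seed, {
    gen <- simulateGenome(config$window, config$gc, sites, seed = NULL)
    sites <- gen$truth  # start/end filled in
    condBundle <- function(tag) {
      vis <- sites$condition %in% c(tag, "both")
      peakBins <- sort(unique(c(sites$bin[vis],
                                if (tag == "A") config$tssBinE
                                else config$tssBinL)))
      hic <- simulateHiC(grid, config$tadBoundaries, config$decayAlpha,
                         config$tadBoost, config$depth, config$hicNoise,
                         seed = NULL)
      tr <- simulateTracks(grid, peakBins, config$peakHeight, config$basal,
                           config$noiseSd,
                           sites[vis, , drop = FALSE],
                           config$contribBackground, seed = NULL)
      list(contacts = hic$contacts, atac = tr$atac, contrib = tr$contrib,
           peakBins = peakBins)
    }
    conditions <- list(A = condBundle("A"), B = condBundle("B"))
    pwms <- list(consensusPWM("JUNB", config$ap1Consensus),
                 consensusPWM("TCF7", config$tcfConsensus))
    names(pwms) <- vapply(pwms, motifName, character(1L))
    list(grid = grid, genome = gen,
         conditions = conditions, pwms = pwms,
         truth = list(sites = sites,
                      tadBoundaries = config$tadBoundaries,
                      tssBinE = config$tssBinE, tssBinL = config$tssBinL,
                      seed = as.integer(seed)))
  })
}

#' Write a simulated bundle to disk in the pipeline's input formats
#'
#' COO contacts, bedGraph tracks, FASTA genome, MEME motifs and a BED truth
#' table, so file-based runs exercise the same parsers as external data.
#'
#' @param bundle result of [simulateConditionPair()].
#' @param dir output directory (created if missing).
#' @return named list of written paths.
#' @export
writeConditionPair <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(...))
  paths <- list()
  for (tag in names(bundle$conditions)) {
    cond <- bundle$conditions[[tag]]
    paths[[paste0("contacts_", tag)]] <-
      writeContactsCOO(cond$contacts, p("contacts_", tag, ".coo.tsv"))
    paths[[paste0("atac_", tag)]] <-
      writeBedGraph(cond$atac, p("atac_", tag, ".bedgraph"))
    paths[[paste0("contrib_", tag)]] <-
      writeBedGraph(cond$contrib, p("contrib_", tag, ".bedgraph"))
  }
  seqs <- setNames(list(bundle$genome$seq), bundle$genome$chrom)
  paths$genome <- writeFasta(seqs, p("genome.fa"))
  paths$pwms <- writeMemePWMs(bundle$pwms, p("motifs.meme"))
  tr <- bundle$truth$sites
  bed <- data.frame(chrom = tr$chrom, start = sprintf("%.0f", tr$start),
                    end = sprintf("%.0f", tr$end),
                    name = paste0(tr$family, ":", tr$condition),
                    score = 0L, strand = tr$strand)
  paths$truth <- p("truth_sites.bed")
  write.table(bed, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  paths
}
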