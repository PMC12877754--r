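BASE_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = NA_integer_)

seqToCodes <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  bad <- !(ch %in% names(BASE_CODES))
  if (any(bad))
    stop("invalid sequence character '", ch[which(bad)[1L]], "'")
  unname(BASE_CODES[ch])
}

#' Reverse complement of a DNA string
#' @param seq string over A, C, G, T, N (case preserved upper).
#' @export
revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan a sequence with a PWM (log2-odds, both strands)
#'
#' At every window the score is `sum_k log2(p_k(base) / bg(base))`; `N`
#' bases contribute 0. A hit is reported when the score reaches
#' `scoreFractionThreshold` times the motif's maximum attainable log-odds
#' (computed with the same background). Minus-strand windows are scored on
#' the reverse complement and reported in plus-strand coordinates.
#'
#' @param seq DNA string over A, C, G, T, N.
#' @param chrom chromosome name recorded in the hits.
#' @param offset 0-based genomic start of `seq`.
#' @param pwm a [PWMotif-class].
#' @param scoreFractionThreshold hit threshold as a fraction of the maximum
#'   log-odds (default 0.8).
#' @param bothStrands scan the minus strand as well (default TRUE).
#' @return data.frame (motif, chrom, start, end, strand, score,
#'   scoreFraction); empty when the motif is longer than the sequence.
#' @export
scanPWM <- function(seq, chrom, offset, pwm, scoreFractionThreshold = 0.8,
                    bothStrands = TRUE) {
  stopifnot(is(pwm, "PWMotif"))
  emptyHits <- data.frame(motif = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          strand = character(), score = numeric(),
                          scoreFraction = numeric())
  L <- motifLength(pwm)
  nb <- nchar(seq)
  if (L > nb) return(emptyHits)
  S <- log2(pwm@matrix / pwm@background)  # 4 x L
  maxScore <- sum(apply(S, 2L, max))
  scanOne <- function(codes) {
    nW <- length(codes) - L + 1L
    total <- numeric(nW)
    for (k in seq_len(L)) {
      contrib <- S[cbind(codes[k:(k + nW - 1L)], k)]
      contrib[is.na(contrib)] <- 0  # N bases
      total <- total + contrib
    }
    total
  }
  thr <- scoreFractionThreshold * maxScore
  frac <- function(sc) if (maxScore > 0) pmin(pmax(sc / maxScore, 0), 1)
                       else rep(1, length(sc))
  codes <- seqToCodes(seq)
  plus <- scanOne(codes)
  hitP <- which(plus >= thr)
  out <- if (length(hitP)) {
    data.frame(motif = pwm@name, chrom = chrom,
               start = offset + hitP - 1, end = offset + hitP - 1 + L,
               strand = "+", score = plus[hitP],
               scoreFraction = frac(plus[hitP]))
  } else emptyHits
  if (bothStrands) {
    rcodes <- 5L - rev(codes)  # A<->T, C<->G on the code scale; NA stays NA
    minus <- scanOne(rcodes)
    hitM <- which(minus >= thr)
    if (length(hitM)) {
      startPlus <- offset + (nb - L - (hitM - 1L))
      out <- rbind(out, data.frame(
        motif = pwm@name, chrom = chrom, start = startPlus,
        end = startPlus + L, strand = "-", score = minus[hitM],
        scoreFraction = frac(minus[hitM])))
    }
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan genomic intervals of a sequence with a motif set
#'
#' Extracts each interval from `genomeSeq` (whose genomic start is
#' `genomeOffset`) and scans it with every PWM.
#'
#' @param genomeSeq DNA string of the analysis window.
#' @param genomeOffset 0-based genomic start of `genomeSeq`.
#' @param chrom chromosome name.
#' @param intervals data.frame (chrom, start, end), e.g. from
#'   [highContributionIntervals()].
#' @param pwms list of [PWMotif-class].
#' @param scoreFractionThreshold,bothStrands passed to [scanPWM()].
#' @return combined hit data.frame.
#' @export
scanRegions <- function(genomeSeq, genomeOffset, chrom, intervals, pwms,
                        scoreFractionThreshold = 0.8, bothStrands = TRUE) {
  hits <- list()
  lens <- vapply(pwms, motifLength, integer(1L))
  for (k in seq_len(nrow(intervals))) {
    s <- intervals$start[k]; e <- intervals$end[k]
    if (e - s < min(lens)) next  # too short for any motif: no window fits
    sub <- substr(genomeSeq, s - genomeOffset + 1, e - genomeOffset)
    for (p in pwms[lens <= e - s])
      hits[[length(hits) + 1L]] <-
        scanPWM(sub, chrom, s, p, scoreFractionThreshold, bothStrands)
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- scanPWM("A", chrom, 0, consensusPWM("x", "AA"))  # empty frame
  rownames(out) <- NULL
  out
}

#' Default motif-name to TF-family map
#'
#' FOS/JUN members map to AP1; TCF7/TCF7L1/TCF7L2/LEF1 map to TCF/LEF.
#' Motif names are matched on their leading symbol (text before the first
#' `.` or `_`), case-insensitively, so database identifiers like
#' `JUNB_MOUSE.H11MO.0.A` resolve.
#' @export
defaultFamilyMap <- function() {
  c(FOS = "AP1", FOSB = "AP1", FOSL1 = "AP1", FOSL2 = "AP1",
    JUN = "AP1", JUNB = "AP1", JUND = "AP1",
    TCF7 = "TCF/LEF", TCF7L1 = "TCF/LEF", TCF7L2 = "TCF/LEF",
    LEF1 = "TCF/LEF")
}

motifFamily <- function(names, familyMap = defaultFamilyMap()) {
  key <- toupper(sub("[._].*$", "", names))
  fam <- familyMap[key]
  unmapped <- is.na(fam)
  if (any(unmapped)) {
    fam[unmapped] <- names[unmapped]  # fall back to the motif's own name
    message("motifFamily: unmapped motif(s) kept as their own family: ",
            paste(unique(names[unmapped]), collapse = ", "))
  }
  unname(fam)
}

#' Collapse motif hits into unique sites per TF family
#'
#' Hits of one family that share any base (either strand) collapse into a
#' single site, so paralogous motifs at one footprint are counted once.
#'
#' @param hits hit data.frame from [scanPWM()]/[scanRegions()].
#' @param familyMap named vector mapping motif symbols to families.
#' @return data.frame (family, chrom, start, end, nHits), one row per
#'   collapsed site.
#' @export
familySites <- function(hits, familyMap = defaultFamilyMap()) {
  if (!nrow(hits))
    return(data.frame(family = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      nHits = integer()))
  hits$family <- motifFamily(hits$motif, familyMap)
  out <- list()
  for (fam in unique(hits$family)) {
    for (ch in unique(hits$chrom[hits$family == fam])) {
      h <- hits[hits$family == fam & hits$chrom == ch, , drop = FALSE]
      ir <- IRanges::IRanges(h$start + 1, h$end)  # 1-based closed
      red <- IRanges::reduce(ir)
      ov <- IRanges::countOverlaps(red, ir)
      out[[length(out) + 1L]] <- data.frame(
        family = fam, chrom = ch,
        start = IRanges::start(red) - 1, end = IRanges::end(red),
        nHits = ov)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$family, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count unique motif sites per TF family
#'
#' @inheritParams familySites
#' @return named integer vector of collapsed-site counts.
#' @export
countHitsByFamily <- function(hits, familyMap = defaultFamilyMap()) {
  sites <- familySites(hits, familyMap)
  if (!nrow(sites)) return(setNames(integer(), character()))
  tab <- table(sites$family)
  setNames(as.integer(tab), names(tab))
}

#' Motif enrichment between two sequence sets
#'
#' For each motif, sequences with at least one hit (both strands) are
#' counted in foreground and background and tested with a two-sided Fisher
#' exact test on the 2x2 presence table; q-values are Benjamini-Hochberg.
#' The odds ratio is the sample cross-product
#' `(fgWith * bgWithout) / (fgWithout * bgWith)`. Rows are ranked by
#' ascending q, then descending odds ratio.
#'
#' @param fg,bg character vectors of DNA sequences (non-empty).
#' @param pwms list of [PWMotif-class].
#' @param scoreFractionThreshold hit threshold passed to [scanPWM()].
#' @return data.frame (motif, fgWith, fgTotal, bgWith, bgTotal, oddsRatio,
#'   p, q).
#' @export
motifEnrichment <- function(fg, bg, pwms, scoreFractionThreshold = 0.8) {
  if (!length(fg) || !length(bg))
    stop("foreground and background sets must be non-empty")
  hasHit <- function(seqs, pwm)
    vapply(seqs, function(s)
      nrow(scanPWM(s, "seq", 0, pwm, scoreFractionThreshold, TRUE)) > 0,
      logical(1L), USE.NAMES = FALSE)
  rows <- lapply(pwms, function(p) {
    a <- sum(hasHit(fg, p)); b <- length(fg) - a
    c_ <- sum(hasHit(bg, p)); d <- length(bg) - c_
    pv <- fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE))$p.value
    or <- (a * d) / (b * c_)  # sample odds ratio; may be Inf or NaN
    data.frame(motif = p@name, fgWith = a, fgTotal = length(fg),
               bgWith = c_, bgTotal = length(bg), oddsRatio = or, p = pv)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$q, -out$oddsRatio), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential TF-family occupancy between two conditions
#'
#' Counts collapsed family sites per condition and reports
#' `delta = countA - countB` per family, sorted by `|delta|` descending.
#' The per-site table (collapsed over both conditions' hits) records in
#' which condition each site is occupied, so sites "open in A, closed in B"
#' are listable.
#'
#' @param hitsA,hitsB hit data.frames for the two conditions.
#' @param familyMap motif-to-family map.
#' @param gridA,gridB optional [BinGrid-class]es; when both are given they
#'   must be identical (same window, resolution).
#' @return data.frame (family, countA, countB, delta) with the per-site
#'   table attached as attribute `"sites"`.
#' @export
differentialOccupancy <- function(hitsA, hitsB,
                                  familyMap = defaultFamilyMap(),
                                  gridA = NULL, gridB = NULL) {
  if (!is.null(gridA) && !is.null(gridB)) {
    same <- identical(formatRegion(gridA@region),
                      formatRegion(gridB@region)) &&
      gridA@resolution == gridB@resolution
    if (!same) stop("conditions were analyzed over different grids")
  }
  cA <- countHitsByFamily(hitsA, familyMap)
  cB <- countHitsByFamily(hitsB, familyMap)
  fams <- union(names(cA), names(cB))
  countA <- ifelse(fams %in% names(cA), cA[fams], 0L)
  countB <- ifelse(fams %in% names(cB), cB[fams], 0L)
  rep <- data.frame(family = fams, countA = as.integer(countA),
                    countB = as.integer(countB),
                    delta = as.integer(countA) - as.integer(countB))
  rep <- rep[order(-abs(rep$delta), rep$family), , drop = FALSE]
  rownames(rep) <- NULL
  both <- rbind(hitsA, hitsB)
  sites <- familySites(both, familyMap)
  if (nrow(sites)) {
    famA <- if (nrow(hitsA)) motifFamily(hitsA$motif, familyMap)
            else character()
    famB <- if (nrow(hitsB)) motifFamily(hitsB$motif, familyMap)
            else character()
    sites$inA <- vapply(seq_len(nrow(sites)), function(k)
      nrow(hitsA) > 0 && any(famA == sites$family[k] &
        hitsA$chrom == sites$chrom[k] & hitsA$start < sites$end[k] &
        hitsA$end > sites$start[k]), logical(1L))
    sites$inB <- vapply(seq_len(nrow(sites)), function(k)
      nrow(hitsB) > 0 && any(famB == sites$family[k] &
        hitsB$chrom == sites$chrom[k] & hitsB$start < sites$end[k] &
        hitsB$end > sites$start[k]), logical(1L))
  } else {
    sites$inA <- logical(); sites$inB <- logical()
  }
  attr(rep, "sites") <- sites
  rep
}

#' Write motif hits as BED6
#'
#' name = motif, score = round(1000 x scoreFraction), strand as scanned.
#' @param hits hit data.frame.
#' @param path output file.
#' @export
writeHitsBED <- function(hits, path) {
  df <- data.frame(chrom = hits$chrom,
                   start = sprintf("%.0f", hits$start),
                   end = sprintf("%.0f", hits$end),
                   name = hits$motif,
                   score = round(1000 * hits$scoreFraction),
                   strand = hits$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
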