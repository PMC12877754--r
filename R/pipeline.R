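#' Run the spatial-occupancy analysis for one condition
#'
#' Balances the contacts, embeds the bins, builds the Gaudi geometry,
#' attaches per-bin accessibility, selects the TSS spatial neighborhood,
#' retains high-contribution bases inside it, and scans them for motifs.
#'
#' @param contacts raw [ContactMatrix-class].
#' @param atac accessibility [SignalTrack-class].
#' @param contrib contribution-score [SignalTrack-class].
#' @param genomeSeq DNA string of the window.
#' @param pwms list of [PWMotif-class].
#' @param tssPositions named numeric vector of TSS base positions, one per
#'   locus.
#' @param config a [GaudiConfig-class].
#' @return list with `contacts` (balanced), `layout`, `gaudi` (signal
#'   attached), `binAtac`, and per-locus `loci` (selection, intervals,
#'   hits, familyCounts, arcs).
#' @export
runConditionAnalysis <- function(contacts, atac, contrib, genomeSeq, pwms,
                                 tssPositions, config = gaudiConfig()) {
  stopifnot(is(contacts, "ContactMatrix"), is(config, "GaudiConfig"))
  grid <- contacts@grid
  window <- grid@region
  balanced <- if (contacts@balanced) contacts else iceBalance(contacts)
  layout <- layoutContacts(balanced, config@topFraction, config@seed)
  gaudi <- voronoiOccupancy(layout, config@bufferFactor, config@dummyCount,
                            config@dummyRadiusFactor, config@discSegments)
  binAtac <- binSignal(atac, grid, "mean")
  gaudi <- gaudiSignal(gaudi, binAtac)
  loci <- lapply(tssPositions, function(tss) {
    tssBin <- tssBinOf(grid, tss)
    sel <- tssNeighborhood(layout, tssBin, config@neighborhoodFactor)
    iv <- highContributionIntervals(contrib, window,
                                    config@contributionQuantile, sel)
    hits <- scanRegions(genomeSeq, window@start, window@chrom, iv, pwms,
                        config@pwmScoreFraction, TRUE)
    list(tssBin = tssBin, selection = sel, intervals = iv, hits = hits,
         familyCounts = countHitsByFamily(hits),
         arcs = neighborhoodArcs(sel, grid))
  })
  list(contacts = balanced, layout = layout, gaudi = gaudi,
       binAtac = binAtac, loci = loci)
}

#' Differential occupancy between two analyzed conditions
#'
#' @param resA,resB results of [runConditionAnalysis()] over the same grid.
#' @param familyMap motif-to-family map.
#' @return named list of per-locus occupancy reports (see
#'   [differentialOccupancy()]).
#' @export
differentialReports <- function(resA, resB,
                                familyMap = defaultFamilyMap()) {
  loci <- intersect(names(resA$loci), names(resB$loci))
  reps <- lapply(loci, function(lc)
    differentialOccupancy(resA$loci[[lc]]$hits, resB$loci[[lc]]$hits,
                          familyMap,
                          gridA = resA$contacts@grid,
                          gridB = resB$contacts@grid))
  names(reps) <- loci
  reps
}

#' Read a plain key = value pipeline config file
#'
#' Lines of the form `key = value`; `#` starts a comment. Keys mirror
#' [gaudiConfig()] fields plus input paths (`region`, `tss_e`, `tss_l`,
#' `contacts_a`, `contacts_b`, `atac_a`, ..., `genome`, `pwms`,
#' `pwm_format`).
#'
#' @param path config file.
#' @return named character list.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- lapply(kv, function(x) paste(x[-1L], collapse = "="))
  names(out) <- vapply(kv, `[[`, character(1L), 1L)
  out
}

#' Run the full pipeline and write its artifact directory
#'
#' Executes balance, layout, Gaudi geometry, signal binning, neighborhood
#' selection, contribution filtering, motif scanning and reporting for one
#' or two conditions, writing fixed-name artifacts (layout TSV, GeoJSON,
#' SVG, hits BED, arcs TSV, report TSV) plus a `manifest.json` recording
#' the config snapshot, input checksums, seed, stage timings, output paths
#' and package version. Re-running with identical inputs and seed
#' reproduces identical artifacts.
#'
#' @param inputs either a simulated bundle from [simulateConditionPair()]
#'   or a named list of file paths with elements `region` (coordinate
#'   string), `tss` (named vector of TSS positions), `contacts`, `atac`,
#'   `contrib` (each a named list with entries per condition, e.g. `A`,
#'   `B`), `genome` (FASTA), `pwms` (motif file), `pwmFormat`.
#' @param outDir artifact directory (created).
#' @param config a [GaudiConfig-class].
#' @return invisibly, a list with per-condition results, per-locus
#'   differential reports (two-condition runs), and the manifest.
#' @export
runAll <- function(inputs, outDir, config = gaudiConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "GaudiHiC",
                   version = as.character(packageVersion("GaudiHiC")),
                   seed = config@seed,
                   config = list(
                     resolution = config@resolution,
                     topFraction = config@topFraction,
                     bufferFactor = config@bufferFactor,
                     neighborhoodFactor = config@neighborhoodFactor,
                     contributionQuantile = config@contributionQuantile,
                     pwmScoreFraction = config@pwmScoreFraction,
                     dummyCount = config@dummyCount,
                     dummyRadiusFactor = config@dummyRadiusFactor,
                     discSegments = config@discSegments),
                   stages = list(), inputs = list(), outputs = list())
  manifestPath <- file.path(outDir, "manifest.json")
  stageTimed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                           digits = NA)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  message("runAll: parameters: ",
          paste(names(manifest$config), unlist(manifest$config),
                sep = "=", collapse = " "))
  fromFiles <- !is.null(inputs$region) && is.character(inputs$region)
  if (fromFiles) {
    window <- parseRegion(inputs$region)
    grid <- makeBinGrid(window, config@resolution)
    conds <- names(inputs$contacts)
    for (nm in c("contacts", "atac", "contrib"))
      for (tag in conds)
        manifest$inputs[[paste0(nm, "_", tag)]] <-
          unname(tools::md5sum(inputs[[nm]][[tag]]))
    manifest$inputs$genome <- unname(tools::md5sum(inputs$genome))
    manifest$inputs$pwms <- unname(tools::md5sum(inputs$pwms))
    genome <- readGenomeFasta(inputs$genome)
    if (!(window@chrom %in% names(genome)))
      stop("genome FASTA lacks record '", window@chrom, "'")
    genomeSeq <- as.character(genome[[window@chrom]])
    if (nchar(genomeSeq) == regionWidth(window))
      offsetOK <- TRUE  # record spans exactly the window
    else if (nchar(genomeSeq) < regionWidth(window))
      stop("genome record shorter than the analysis window")
    pwms <- readPWMs(inputs$pwms,
                     if (is.null(inputs$pwmFormat)) "meme"
                     else inputs$pwmFormat)
    bundles <- lapply(setNames(conds, conds), function(tag) {
      if (is.null(inputs$contrib[[tag]]))
        stop("missing contribution track for condition ", tag)
      list(contacts = readContacts(inputs$contacts[[tag]], grid),
           atac = readBedGraph(inputs$atac[[tag]], window),
           contrib = readBedGraph(inputs$contrib[[tag]], window))
    })
    tss <- inputs$tss
  } else {
    grid <- inputs$grid
    window <- grid@region
    genomeSeq <- inputs$genome$seq
    pwms <- inputs$pwms
    bundles <- inputs$conditions
    tss <- c(E = grid@binStarts[inputs$truth$tssBinE + 1L] +
               floor(grid@resolution / 2),
             L = grid@binStarts[inputs$truth$tssBinL + 1L] +
               floor(grid@resolution / 2))
  }
  if (nchar(genomeSeq) > regionWidth(window))
    genomeSeq <- substr(genomeSeq, 1L, regionWidth(window))
  results <- list()
  for (tag in names(bundles)) {
    b <- bundles[[tag]]
    if (is.null(b$contrib))
      stop("missing contribution track for condition ", tag)
    res <- stageTimed(paste0("analysis_", tag),
                      runConditionAnalysis(b$contacts, b$atac, b$contrib,
                                           genomeSeq, pwms, tss, config))
    results[[tag]] <- res
    pfx <- file.path(outDir, tag)
    manifest$outputs[[paste0("layout_", tag)]] <-
      writeLayoutTSV(res$layout, paste0(pfx, "_layout.tsv"))
    manifest$outputs[[paste0("gaudi_", tag)]] <-
      writeGaudiGeoJSON(res$gaudi, paste0(pfx, "_gaudi.geojson"))
    for (lc in names(res$loci)) {
      li <- res$loci[[lc]]
      manifest$outputs[[paste0("svg_", tag, "_", lc)]] <-
        renderGaudi(res$gaudi, highlight = li$tssBin, tssBin = li$tssBin,
                    neighborhoodRadius = li$selection@radius,
                    path = paste0(pfx, "_gaudi_", lc, ".svg"))
      manifest$outputs[[paste0("hits_", tag, "_", lc)]] <-
        writeHitsBED(li$hits, paste0(pfx, "_hits_", lc, ".bed"))
      arcsPath <- paste0(pfx, "_arcs_", lc, ".tsv")
      write.table(li$arcs, arcsPath, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      manifest$outputs[[paste0("arcs_", tag, "_", lc)]] <- arcsPath
    }
  }
  reports <- NULL
  if (length(results) == 2L) {
    tags <- names(results)
    reports <- stageTimed("report",
                          differentialReports(results[[tags[1L]]],
                                              results[[tags[2L]]]))
    for (lc in names(reports)) {
      path <- file.path(outDir, paste0("report_", lc, ".tsv"))
      write.table(reports[[lc]], path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      manifest$outputs[[paste0("report_", lc)]] <- path
      sites <- attr(reports[[lc]], "sites")
      spath <- file.path(outDir, paste0("sites_", lc, ".tsv"))
      write.table(sites, spath, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      manifest$outputs[[paste0("sites_", lc)]] <- spath
    }
  }
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(results = results, reports = reports,
                 manifest = manifest))
}

#' Differential family counts from a simulated bundle (lean path)
#'
#' Runs only the stages the occupancy comparison needs -- balance, layout,
#' TSS neighborhoods, contribution filtering, motif scanning -- skipping
#' the Gaudi geometry and rendering, and returns the per-locus family
#' counts per condition. Used for seed-suite recovery checks where only
#' the counts matter.
#'
#' @param bundle result of [simulateConditionPair()].
#' @param config a [GaudiConfig-class].
#' @return data.frame (locus, family, countA, countB, delta).
#' @export
differentialCounts <- function(bundle, config = gaudiConfig()) {
  window <- regionOf(bundle$grid)
  tssBins <- c(E = bundle$truth$tssBinE, L = bundle$truth$tssBinL)
  hits <- lapply(bundle$conditions, function(cond) {
    lay <- layoutContacts(iceBalance(cond$contacts), config@topFraction,
                          config@seed)
    lapply(tssBins, function(tb) {
      sel <- tssNeighborhood(lay, tb, config@neighborhoodFactor)
      iv <- highContributionIntervals(cond$contrib, window,
                                      config@contributionQuantile, sel)
      scanRegions(bundle$genome$seq, regionStart(window), window@chrom,
                  iv, bundle$pwms, config@pwmScoreFraction, TRUE)
    })
  })
  tags <- names(hits)
  rows <- lapply(names(tssBins), function(lc) {
    rep <- differentialOccupancy(hits[[tags[1L]]][[lc]],
                                 hits[[tags[2L]]][[lc]])
    if (nrow(rep)) cbind(locus = lc, rep) else NULL
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
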