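# End-to-end orchestration: simulate -> write -> re-load from files ->
# occupancy -> annotation -> convergence -> screen, with a reproducibility
# manifest (config echo + per-file checksums). Stages consume the files the
# previous stage wrote, so re-running a single stage from cached inputs
# reproduces the full-run output; no stage mutates its inputs.

#' Load a simulated cistrome directory written by [writeCistrome]
#'
#' @param dir Directory containing `manifest.tsv` and the files it lists.
#' @return list with `genes`, `truth`, `gre`, `ebox`, `peakSets`, `tracks`
#'   (normalization factors restored from the manifest).
#' @export
readCistromeDir <- function(dir) {
  manPath <- file.path(dir, "manifest.tsv")
  if (!file.exists(manPath)) stop("no manifest.tsv under ", dir)
  man <- utils::read.table(manPath, header = TRUE, sep = "\t",
                           colClasses = "character")
  peakSets <- list(); tracks <- list()
  for (i in seq_len(nrow(man))) {
    key <- man$key[i]
    path <- file.path(dir, man$file[i])
    if (!file.exists(path)) stop("manifest entry missing on disk: ", path)
    if (man$type[i] == "peaks") {
      parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
      peakSets[[key]] <- readPeakBed(path, parts[1L], parts[2L], parts[3L],
                                     summitCol = 7L)
    } else {
      nf <- as.numeric(man$norm_factor[i])
      tracks[[key]] <- readBedGraph(path, normFactor = nf)
    }
  }
  out <- list(genes = readGeneTable(file.path(dir, "genes.tsv")),
              truth = if (file.exists(file.path(dir, "truth.tsv")))
                readTruthTable(file.path(dir, "truth.tsv")) else NULL,
              peakSets = peakSets, tracks = tracks)
  for (m in c("gre", "ebox")) {
    f <- file.path(dir, paste0(m, "_sites.bed"))
    if (file.exists(f)) {
      ps <- readPeakBed(f, "input", "WT", "vehicle")
      out[[m]] <- MotifSiteSet(if (m == "gre") "GRE" else "E-box",
                               GenomicRanges::granges(peaks(ps)))
    }
  }
  out
}

conditionTrackSet <- function(tracks, fac) {
  keys <- grep(paste0("^", fac, "\\."), names(tracks), value = TRUE)
  out <- tracks[keys]
  names(out) <- sub(paste0("^", fac, "\\."), "", keys)
  out
}

#' Run the full pipeline on a synthetic configuration
#'
#' Simulates the cistrome, writes all inputs under `outdir/sim`, re-loads
#' them from disk, and runs every analysis stage, writing TSV/JSON reports
#' and a reproducibility manifest (`pipeline_manifest.json` with the config
#' and md5 checksums of every emitted file). Deterministic under
#' `config$seed`: identical config gives byte-identical outputs.
#'
#' @param config A [simConfig].
#' @param outdir Output directory.
#' @param nPerm Permutations for the co-occurrence contrast (default
#'   10000).
#' @param bootB Bootstrap resamples for CIs (default 1000).
#' @return Invisibly, a list with the stage results.
#' @export
runPipeline <- function(config = simConfig(), outdir, nPerm = 10000L,
                        bootB = 1000L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  simDir <- file.path(outdir, "sim")

  message("stage simulate: generating synthetic cistrome (seed ",
          config$seed, ")")
  sim <- simulateCistrome(config)
  writeCistrome(sim, simDir)
  writeMotifBed(sim$gre, file.path(simDir, "gre_sites.bed"))
  writeMotifBed(sim$ebox, file.path(simDir, "ebox_sites.bed"))

  data <- tryCatch(readCistromeDir(simDir),
                   error = function(e) stop("stage load: ",
                                            conditionMessage(e)))

  message("stage occupancy: motif-site signal profiles")
  occ <- withStage("occupancy", {
    grTracks <- conditionTrackSet(data$tracks, "GR")
    bmTracks <- conditionTrackSet(data$tracks, "BMAL1")
    list(grOnGre = siteSignalMatrix(grTracks, data$gre),
         bmOnEbox = siteSignalMatrix(bmTracks, data$ebox),
         grOnEbox = siteSignalMatrix(grTracks, data$ebox),
         bmOnGre = siteSignalMatrix(bmTracks, data$gre))
  })
  occContrast <- occupancyContrast(occ$grOnGre, B = bootB,
                                   seed = config$seed)
  writeOccupancyReport(occ, occContrast, file.path(outdir, "occupancy.tsv"))

  message("stage annotate: peak-to-TSS annotation")
  annot <- withStage("annotate", {
    keys <- grep("^GR\\.", names(data$peakSets), value = TRUE)
    anns <- lapply(data$peakSets[keys], annotatePeaks, genes = data$genes)
    names(anns) <- sub("^GR\\.", "", keys)
    anns
  })
  proxim <- proximalFractionContrast(annot, B = bootB, seed = config$seed)
  writeProximalReport(annot, proxim, file.path(outdir, "annotation.tsv"))

  message("stage converge: GR-BMAL1 interdistance contrast")
  conv <- withStage("converge", {
    out <- list()
    for (g in c("WT", "KO")) {
      dd <- peakInterdistance(data$peakSets[[paste0("GR.", g,
                                                    ".prednisone")]],
                              data$peakSets[[paste0("BMAL1.", g,
                                                    ".prednisone")]])
      dv <- peakInterdistance(data$peakSets[[paste0("GR.", g,
                                                    ".vehicle")]],
                              data$peakSets[[paste0("BMAL1.", g,
                                                    ".vehicle")]])
      out[[g]] <- cooccurrenceContrast(
        binnedCooccurrence(dd, condition = paste0(g, ".prednisone")),
        binnedCooccurrence(dv, condition = paste0(g, ".vehicle")),
        dd$distances, dv$distances, nPerm = nPerm, seed = config$seed)
    }
    out
  })
  writeConvergenceReport(conv, file.path(outdir, "convergence.tsv"))

  message("stage screen: RNApol-II quadrant + factor-gain selection")
  screen <- withStage("screen", runScreen(data$tracks, data$genes))
  writeScreenTable(screen, file.path(outdir, "screen.tsv"))
  recovery <- if (!is.null(data$truth))
    screenRecovery(screen, data$truth) else NULL
  summary <- list(
    peakCounts = peakCounts(data$peakSets),
    quadrantCounts = as.list(screen$summary$quadrantCounts),
    nSelected = screen$summary$nSelected,
    recovery = recovery)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  writePipelineManifest(config, outdir)
  invisible(list(occupancy = occ, occupancyContrast = occContrast,
                 annotation = annot, proximal = proxim,
                 convergence = conv, screen = screen,
                 recovery = recovery))
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
}

writeMotifBed <- function(mss, path) {
  s <- motifSites(mss)
  writeLinesLF(sprintf("%s\t%d\t%d",
                       as.character(GenomicRanges::seqnames(s)),
                       GenomicRanges::start(s) - 1L,
                       GenomicRanges::end(s)), path)
}

writeOccupancyReport <- function(occ, contrast, path) {
  rows <- c("profile\tcondition\taggregate")
  for (nm in names(occ)) {
    agg <- occupancyAggregate(occ[[nm]])
    rows <- c(rows, sprintf("%s\t%s\t%s", nm, names(agg), formatNum(agg)))
  }
  rows <- c(rows, "", "contrast_genotype\tfold\tci_lo\tci_hi",
            sprintf("%s\t%s\t%s\t%s", contrast$folds$genotype,
                    formatNum(contrast$folds$fold),
                    formatNum(contrast$folds$ci_lo),
                    formatNum(contrast$folds$ci_hi)))
  writeLinesLF(rows, path)
}

writeProximalReport <- function(annot, proxim, path) {
  fr <- proxim$fractions
  rows <- c("condition\tn\tproximal_fraction",
            sprintf("%s\t%d\t%s", fr$condition, fr$n,
                    formatNum(fr$fraction)),
            "", "genotype\tdelta\tci_lo\tci_hi",
            sprintf("%s\t%s\t%s\t%s", proxim$deltas$genotype,
                    formatNum(proxim$deltas$delta),
                    formatNum(proxim$deltas$ci_lo),
                    formatNum(proxim$deltas$ci_hi)))
  writeLinesLF(rows, path)
}

writeConvergenceReport <- function(conv, path) {
  rows <- "genotype\tbin\tcount_drug\tcount_vehicle\tratio\tp_value"
  for (g in names(conv)) {
    tb <- conv[[g]]
    rows <- c(rows, sprintf("%s\t%s\t%d\t%d\t%s\t%s", g, tb$bin,
                            tb$count_drug, tb$count_vehicle,
                            formatNum(tb$ratio), formatNum(tb$p_value)))
  }
  writeLinesLF(rows, path)
}

writePipelineManifest <- function(config, outdir) {
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "pipeline_manifest.json"))
  sums <- tools::md5sum(file.path(outdir, files))
  cfg <- config; class(cfg) <- NULL
  jsonlite::write_json(
    list(config = cfg,
         files = as.list(stats::setNames(unname(sums), files))),
    file.path(outdir, "pipeline_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
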