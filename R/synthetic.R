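# Synthetic 2x2 (genotype x treatment) cistrome generator. Emits the full
# set of peak calls and signal tracks for GR, BMAL1 and RNA polymerase II,
# plus an input track, a gene table, motif-site sets and a per-gene truth
# table with the planted effect sizes, so that every downstream statistic of
# the pipeline can be checked against known ground truth.
#
# Planted drug effects are multiplicative occupancy gains applied over
# bin-aligned quantification windows:
#   * GR signal over GRE-site windows (+/- quantHalfwidth) gains
#     greGainWt (WT) / greGainKo (KO) under drug;
#   * BMAL1 signal over E-box windows gains eboxGainWt (WT) under drug;
#   * RNApol-II signal over TSS windows (+/- tssHalfwidth) gains each gene's
#     planted fold change per genotype;
#   * convergent genes additionally gain GR and BMAL1 signal over their core
#     promoter tile.
# TSSs and motif centres are snapped to the track bin grid, and random
# background peaks are kept out of motif windows and convergent-gene
# neighbourhoods, so the planted folds are exactly identifiable in the
# noise-free limit. Drug/vehicle condition pairs share their background peak
# complement and differ only by the planted effects (a paired design).

#' Simulation configuration
#'
#' Builds and validates the parameter set of the synthetic cistrome
#' generator. Defaults describe a desk-scale genome with clearly planted
#' effects: 2 chromosomes x 5 Mb, 200 genes (>= 20 kb TSS spacing),
#' 300 GRE + 300 E-box sites, 400 peaks per condition, GRE occupancy gain
#' 3 (WT) vs 1.3 (KO), proximal (<10 kb of TSS) peak placement 0.3 under
#' vehicle shifting to 0.7 (WT) / 0.4 (KO) under drug, 40% of WT drug GR
#' peaks paired with a BMAL1 peak within 0-900 bp, and 25 convergent genes.
#'
#' @param seed Integer seed; the same seed gives byte-identical outputs.
#' @param nChroms,chromLength Genome layout (bp; multiple of `bin`).
#' @param nGenes Number of genes (placed with >= `minGeneSpacing` spacing).
#' @param nGreSites,nEboxSites Motif-site counts (12 bp GRE, 6 bp E-box).
#' @param promoterFraction Fraction of motif sites placed in promoters
#'   (within -1000..+100 bp of a TSS, strand sense).
#' @param nPeaks Peaks per condition for GR and BMAL1.
#' @param greGainWt,greGainKo Drug-induced multiplicative GR occupancy gain
#'   over GRE windows per genotype (folds >= 1).
#' @param eboxGainWt Drug-induced BMAL1 occupancy gain over E-box windows.
#' @param proximalRateVehicle,proximalShiftWt,proximalShiftKo Fraction of
#'   peaks placed < 10 kb from a TSS (vehicle; WT drug; KO drug).
#' @param cooccurRateDrugWt Fraction of WT drug GR peaks receiving a partner
#'   BMAL1 peak at a uniform 0-900 bp summit offset.
#' @param nConvergentGenes Genes planted with WT-only RNApol-II
#'   up-regulation plus GR and BMAL1 promoter gains.
#' @param nWtOnlyGenes,nSharedGenes,nKoOnlyGenes Additional gene-class
#'   counts (non-convergent WT-only up; up in both; KO-only up); the rest
#'   are null genes.
#' @param upFoldRange,nullFoldRange Uniform ranges for planted RNApol-II
#'   fold changes of up-regulated and unaffected gene/genotype combinations.
#' @param convGainRange Uniform range for planted convergent-promoter GR and
#'   BMAL1 gain folds.
#' @param noiseSigma sdlog of the per-step multiplicative lognormal noise.
#' @param bumpSd Gaussian bump standard deviation (bp); ~75 bp approximates
#'   the fragment-size smearing of sheared chromatin (~150-600 bp).
#' @param bumpHeights Named bump heights for GR, BMAL1, RNApolII.
#' @param convBumpHeight Bump height of convergent-promoter peaks.
#' @param bin Track resolution (bp); all planted windows are bin-aligned.
#' @param quantHalfwidth Motif-site quantification half-width (bp).
#' @param tssHalfwidth TSS window half-width (bp).
#' @param convTileWidth Width of the convergent-promoter gain tile (bp).
#' @param minGeneSpacing Minimum TSS spacing (bp).
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      nChroms = 2L, chromLength = 5e6,
                      nGenes = 200L,
                      nGreSites = 300L, nEboxSites = 300L,
                      promoterFraction = 0.5,
                      nPeaks = 400L,
                      greGainWt = 3, greGainKo = 1.3,
                      eboxGainWt = 2.5,
                      proximalRateVehicle = 0.3,
                      proximalShiftWt = 0.7,
                      proximalShiftKo = 0.4,
                      cooccurRateDrugWt = 0.4,
                      nConvergentGenes = 25L,
                      nWtOnlyGenes = 25L, nSharedGenes = 20L,
                      nKoOnlyGenes = 20L,
                      upFoldRange = c(2, 4), nullFoldRange = c(0.8, 1.2),
                      convGainRange = c(2.5, 4),
                      noiseSigma = 0.15,
                      bumpSd = 75,
                      bumpHeights = c(GR = 8, BMAL1 = 8, RNApolII = 6),
                      convBumpHeight = 12,
                      bin = 50L,
                      quantHalfwidth = 200L,
                      tssHalfwidth = 500L,
                      convTileWidth = 400L,
                      minGeneSpacing = 20000L) {
  cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
              chromLength = as.integer(chromLength),
              nGenes = as.integer(nGenes),
              nGreSites = as.integer(nGreSites),
              nEboxSites = as.integer(nEboxSites),
              promoterFraction = promoterFraction,
              nPeaks = as.integer(nPeaks),
              greGainWt = greGainWt, greGainKo = greGainKo,
              eboxGainWt = eboxGainWt,
              proximalRateVehicle = proximalRateVehicle,
              proximalShiftWt = proximalShiftWt,
              proximalShiftKo = proximalShiftKo,
              cooccurRateDrugWt = cooccurRateDrugWt,
              nConvergentGenes = as.integer(nConvergentGenes),
              nWtOnlyGenes = as.integer(nWtOnlyGenes),
              nSharedGenes = as.integer(nSharedGenes),
              nKoOnlyGenes = as.integer(nKoOnlyGenes),
              upFoldRange = upFoldRange, nullFoldRange = nullFoldRange,
              convGainRange = convGainRange,
              noiseSigma = noiseSigma, bumpSd = bumpSd,
              bumpHeights = bumpHeights,
              convBumpHeight = convBumpHeight,
              bin = as.integer(bin),
              quantHalfwidth = as.integer(quantHalfwidth),
              tssHalfwidth = as.integer(tssHalfwidth),
              convTileWidth = as.integer(convTileWidth),
              minGeneSpacing = as.integer(minGeneSpacing))
  counts <- c(cfg$nChroms, cfg$chromLength, cfg$nGenes, cfg$nGreSites,
              cfg$nEboxSites, cfg$nPeaks, cfg$nConvergentGenes)
  if (any(counts <= 0L)) stop("all counts must be > 0")
  if (any(c(cfg$greGainWt, cfg$greGainKo, cfg$eboxGainWt) < 1))
    stop("gain parameters are folds and must be >= 1")
  fr <- c(cfg$promoterFraction, cfg$proximalRateVehicle, cfg$proximalShiftWt,
          cfg$proximalShiftKo, cfg$cooccurRateDrugWt)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (cfg$chromLength %% cfg$bin != 0L)
    stop("chromLength must be a multiple of bin")
  for (hw in c(cfg$quantHalfwidth, cfg$tssHalfwidth, cfg$convTileWidth))
    if (hw %% cfg$bin != 0L) stop("windows must be multiples of bin")
  nclass <- cfg$nConvergentGenes + cfg$nWtOnlyGenes + cfg$nSharedGenes +
            cfg$nKoOnlyGenes
  if (nclass > cfg$nGenes)
    stop("gene class counts exceed nGenes")
  perChrom <- geneAllocation(cfg$nGenes, cfg$nChroms)
  margin <- 15000L
  if (any((perChrom - 1L) * cfg$minGeneSpacing + 2L * margin >
          cfg$chromLength))
    stop("genome too small for requested gene count at minimum spacing")
  class(cfg) <- "SimConfig"
  cfg
}

geneAllocation <- function(nGenes, nChroms) {
  base <- nGenes %/% nChroms
  extra <- nGenes %% nChroms
  base + (seq_len(nChroms) <= extra)
}

simChromNames <- function(cfg) paste0("chr", seq_len(cfg$nChroms))

#' Generate the synthetic genome layout
#'
#' Places genes uniformly with a minimum TSS spacing, and GRE / E-box motif
#' sites either inside promoters (-1000..+100 bp of a TSS, strand sense) or
#' uniformly, all snapped to the track bin grid. Deterministic under
#' `config$seed`.
#'
#' @param config A [simConfig] object.
#' @return list with `genes` (a [geneTable]), `gre` and `ebox`
#'   ([MotifSiteSet-class] objects).
#' @export
generateGenome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  bin <- config$bin
  margin <- 15000L
  perChrom <- geneAllocation(config$nGenes, config$nChroms)
  chroms <- simChromNames(config)
  geneChrom <- character(); tss0 <- integer()
  for (ci in seq_len(config$nChroms)) {
    n <- perChrom[ci]
    if (n == 0L) next
    spacingCells <- config$minGeneSpacing %/% bin
    availCells <- (config$chromLength - 2L * margin) %/% bin -
                  (n - 1L) * spacingCells
    if (availCells < 0L) stop("genome too small for gene placement")
    u <- sort(sample.int(availCells + 1L, n, replace = TRUE) - 1L)
    pos <- margin + ((seq_len(n) - 1L) * spacingCells + u) * bin
    geneChrom <- c(geneChrom, rep(chroms[ci], n))
    tss0 <- c(tss0, as.integer(pos))
  }
  strand <- sample(c("+", "-"), config$nGenes, replace = TRUE)
  ids <- sprintf("g%04d", seq_len(config$nGenes))
  genes <- geneTable(ids, geneChrom, tss0 + 1L, strand)
  gre <- placeMotifSites(config, genes, config$nGreSites, width = 12L)
  ebox <- placeMotifSites(config, genes, config$nEboxSites, width = 6L)
  list(genes = genes,
       gre = MotifSiteSet("GRE", gre),
       ebox = MotifSiteSet("E-box", ebox))
}

# Sample motif-site centres (0-based, bin-aligned) and return site GRanges.
placeMotifSites <- function(config, genes, n, width) {
  bin <- config$bin
  nProm <- round(config$promoterFraction * n)
  centers <- data.frame(chrom = character(), c0 = integer())
  guard <- 0L
  while (nrow(centers) < n) {
    need <- n - nrow(centers)
    nP <- if (nrow(centers) < nProm) min(nProm - nrow(centers), need) else 0L
    newC <- data.frame(chrom = character(), c0 = integer())
    if (nP > 0L) {
      gi <- sample.int(nrow(genes), nP, replace = TRUE)
      dir <- ifelse(genes$strand[gi] == "+", 1L, -1L)
      k <- sample(seq(-1000L, 100L, by = bin) %/% bin, nP, replace = TRUE)
      c0 <- (genes$tss[gi] - 1L) + dir * k * bin
      newC <- rbind(newC, data.frame(chrom = genes$chrom[gi], c0 = c0))
    }
    if (need - nP > 0L) {
      ci <- sample.int(config$nChroms, need - nP, replace = TRUE)
      cells <- (config$chromLength - 2000L) %/% bin
      c0 <- 1000L + (sample.int(cells, need - nP, replace = TRUE) - 1L) * bin
      newC <- rbind(newC, data.frame(chrom = simChromNames(config)[ci],
                                     c0 = as.integer(c0)))
    }
    centers <- rbind(centers, newC)
    centers <- centers[!duplicated(paste(centers$chrom, centers$c0)), ,
                       drop = FALSE]
    guard <- guard + 1L
    if (guard > 100L) stop("could not place distinct motif sites")
  }
  centers <- centers[seq_len(n), , drop = FALSE]
  half <- width %/% 2L
  GenomicRanges::GRanges(centers$chrom,
    IRanges::IRanges(start = centers$c0 - half + 1L,
                     end = centers$c0 + (width - half)))
}

#' Assign gene classes and planted effect sizes
#'
#' Gene classes are `convergent` (WT-only RNApol-II up-regulation plus
#' planted GR and BMAL1 promoter gains), `WT-only-up`, `shared-up`,
#' `KO-only-up` and `null`. Convergent genes are drawn from genes whose core
#' promoter tile is free of motif-site windows, so their planted factor
#' gains are identifiable. Planted folds are rounded to 6 decimals so the
#' truth table round-trips losslessly through TSV.
#'
#' @param config A [simConfig].
#' @param genome Output of [generateGenome].
#' @return data.frame (the truth table) with columns `gene_id`, `class`,
#'   `polii_fc_wt`, `polii_fc_ko`, `gr_gain_fold`, `bmal1_gain_fold`.
#' @export
assignTruth <- function(config, genome) {
  set.seed(config$seed + 1L)
  genes <- genome$genes
  n <- nrow(genes)
  zones <- convCoreZones(config, genes)
  motifC0 <- rbind(motifCenters(genome$gre), motifCenters(genome$ebox))
  clash <- vapply(seq_len(n), function(i) {
    any(motifC0$chrom == zones$chrom[i] &
        motifC0$c0 > zones$lo[i] & motifC0$c0 < zones$hi[i])
  }, logical(1L))
  eligible <- which(!clash)
  if (length(eligible) < config$nConvergentGenes)
    stop("too few motif-free promoters for the requested convergent genes")
  cls <- rep("null", n)
  conv <- sample(eligible, config$nConvergentGenes)
  cls[conv] <- "convergent"
  rest <- setdiff(seq_len(n), conv)
  pick <- sample(rest, config$nWtOnlyGenes + config$nSharedGenes +
                       config$nKoOnlyGenes)
  cls[pick[seq_len(config$nWtOnlyGenes)]] <- "WT-only-up"
  cls[pick[config$nWtOnlyGenes + seq_len(config$nSharedGenes)]] <- "shared-up"
  cls[pick[config$nWtOnlyGenes + config$nSharedGenes +
           seq_len(config$nKoOnlyGenes)]] <- "KO-only-up"
  rUp <- function(k) round(stats::runif(k, config$upFoldRange[1L],
                                        config$upFoldRange[2L]), 6L)
  rNull <- function(k) round(stats::runif(k, config$nullFoldRange[1L],
                                          config$nullFoldRange[2L]), 6L)
  fcWt <- rNull(n); fcKo <- rNull(n)
  up_wt <- cls %in% c("convergent", "WT-only-up", "shared-up")
  up_ko <- cls %in% c("KO-only-up", "shared-up")
  fcWt[up_wt] <- rUp(sum(up_wt))
  fcKo[up_ko] <- rUp(sum(up_ko))
  grGain <- rep(NA_real_, n); bmGain <- rep(NA_real_, n)
  isConv <- cls == "convergent"
  grGain[isConv] <- round(stats::runif(sum(isConv), config$convGainRange[1L],
                                       config$convGainRange[2L]), 6L)
  bmGain[isConv] <- round(stats::runif(sum(isConv), config$convGainRange[1L],
                                       config$convGainRange[2L]), 6L)
  data.frame(gene_id = genes$gene_id, class = cls,
             polii_fc_wt = fcWt, polii_fc_ko = fcKo,
             gr_gain_fold = grGain, bmal1_gain_fold = bmGain,
             stringsAsFactors = FALSE)
}

# 0-based motif centre positions
motifCenters <- function(mss) {
  s <- motifSites(mss)
  data.frame(chrom = as.character(GenomicRanges::seqnames(s)),
             c0 = as.integer(floor(((GenomicRanges::start(s) - 1L) +
                                    GenomicRanges::end(s)) / 2)))
}

# convergent core-promoter tile (0-based [lo, hi) genomic) per gene, padded
# by the motif quantification halfwidth so no motif window can intersect it
convCoreZones <- function(config, genes) {
  t0 <- genes$tss - 1L
  dir <- ifelse(genes$strand == "+", 1L, -1L)
  tileLo <- ifelse(dir == 1L, t0 - config$convTileWidth, t0)
  tileHi <- tileLo + config$convTileWidth
  data.frame(chrom = genes$chrom,
             lo = tileLo - config$quantHalfwidth,
             hi = tileHi + config$quantHalfwidth,
             tileLo = tileLo, tileHi = tileHi)
}

# ---- placement-zone algebra (per-chromosome IRanges set operations) -------

zoneList <- function(chroms, lo0, hi0) {
  # 0-based half-open [lo0, hi0) -> per-chrom IRanges (1-based closed)
  keep <- hi0 > lo0
  chroms <- chroms[keep]; lo0 <- lo0[keep]; hi0 <- hi0[keep]
  split(IRanges::IRanges(start = lo0 + 1L, end = hi0), chroms)
}

zoneReduce <- function(zl) lapply(zl, IRanges::reduce)

zoneOp <- function(a, b, op) {
  chroms <- union(names(a), names(b))
  out <- lapply(chroms, function(ch) {
    x <- a[[ch]] %||% IRanges::IRanges()
    y <- b[[ch]] %||% IRanges::IRanges()
    op(x, y)
  })
  stats::setNames(out, chroms)
}

zoneDiff <- function(a, b) zoneOp(a, b, IRanges::setdiff)
zoneIntersect <- function(a, b) zoneOp(a, b, IRanges::intersect)

# sample k distinct 0-based positions uniformly from a zone list
samplePositions <- function(zl, k) {
  chroms <- sort(names(zl))
  widths <- vapply(chroms, function(ch) sum(IRanges::width(zl[[ch]])), 0)
  total <- sum(widths)
  if (total < k) stop("placement region too small for requested peaks")
  r <- sort(sample.int(total, k))
  cumw <- cumsum(widths)
  chIdx <- findInterval(r - 1L, c(0, cumw), rightmost.closed = FALSE)
  pos0 <- integer(k); chOut <- character(k)
  for (i in seq_len(k)) {
    ch <- chroms[chIdx[i]]
    off <- r[i] - c(0, cumw)[chIdx[i]]  # 1..width within this chrom's zones
    ir <- zl[[ch]]
    w <- IRanges::width(ir)
    j <- findInterval(off - 1L, c(0, cumsum(w)), rightmost.closed = FALSE)
    within <- off - c(0, cumsum(w))[j]
    chOut[i] <- ch
    pos0[i] <- (IRanges::start(ir)[j] - 1L) + (within - 1L)
  }
  data.frame(chrom = chOut, s0 = pos0, stringsAsFactors = FALSE)
}

# ---- condition track synthesis -------------------------------------------

#' Simulate all condition peak sets and signal tracks
#'
#' Produces peak sets and step-function tracks for GR and BMAL1
#' (genotype x treatment), RNA polymerase II (genotype x treatment, one peak
#' per gene TSS), and a flat input track. Baseline signal is a flat
#' background of 1 plus Gaussian bumps (sd `bumpSd`) at peak summits;
#' planted drug effects are multiplicative gains over bin-aligned windows
#' (see the module header); multiplicative lognormal noise (sdlog
#' `noiseSigma`) is applied per step. All tracks are emitted depth-matched
#' with normalization factor 1.
#'
#' @param config A [simConfig].
#' @param genome Output of [generateGenome].
#' @param truth Output of [assignTruth].
#' @return list of class `SyntheticCistrome` with elements `config`,
#'   `genes`, `gre`, `ebox`, `truth`, `peakSets` (named
#'   [PeakSet-class] list), `tracks` (named [SignalTrack-class] list, keys
#'   `"<factor>.<genotype>.<treatment>"` plus `"input"`), and `pairing`
#'   (logical flags for WT drug GR peaks given a BMAL1 partner).
#' @export
simulateConditionTracks <- function(config, genome, truth) {
  set.seed(config$seed + 2L)
  genes <- genome$genes
  bin <- config$bin
  chroms <- simChromNames(config)

  isConv <- truth$class == "convergent"
  convGenes <- genes[match(truth$gene_id[isConv], genes$gene_id), ,
                     drop = FALSE]
  convTruth <- truth[isConv, , drop = FALSE]

  # --- placement zones (0-based half-open coordinates) ---
  motifC <- rbind(motifCenters(genome$gre), motifCenters(genome$ebox))
  exclMargin <- config$quantHalfwidth + 4L * ceiling(config$bumpSd) + 1L
  exclMotif <- zoneReduce(zoneList(motifC$chrom,
                                   motifC$c0 - exclMargin,
                                   motifC$c0 + exclMargin))
  convPad <- 10000L + 4L * ceiling(config$bumpSd) + 1L
  convT0 <- convGenes$tss - 1L
  exclConv <- zoneReduce(zoneList(convGenes$chrom, convT0 - convPad,
                                  convT0 + convPad))
  universe <- zoneReduce(zoneList(chroms,
                                  rep(1000L, length(chroms)),
                                  rep(config$chromLength - 1000L,
                                      length(chroms))))
  nonConvGenes <- genes[!genes$gene_id %in% convGenes$gene_id, , drop = FALSE]
  t0nc <- nonConvGenes$tss - 1L
  proxZone <- zoneReduce(zoneList(nonConvGenes$chrom, t0nc - 9999L,
                                  t0nc + 10000L))
  proxZone <- zoneIntersect(proxZone, universe)
  proxZone <- zoneDiff(proxZone, exclMotif)
  proxZone <- zoneDiff(proxZone, exclConv)
  t0all <- genes$tss - 1L
  allProx <- zoneReduce(zoneList(genes$chrom, t0all - 10000L,
                                 t0all + 10001L))
  distZone <- zoneDiff(universe, allProx)
  distZone <- zoneDiff(distZone, exclMotif)
  distZone <- zoneDiff(distZone, exclConv)

  heights <- config$bumpHeights
  jitter <- function(k) stats::runif(k, 0.8, 1.2)
  dir <- ifelse(convGenes$strand == "+", 1L, -1L)
  convGrSummit <- data.frame(chrom = convGenes$chrom,
                             s0 = convT0 - dir * 200L,
                             h = config$convBumpHeight * jitter(nrow(convGenes)))
  convBmSummit <- data.frame(chrom = convGenes$chrom,
                             s0 = convT0 - dir * 150L,
                             h = config$convBumpHeight * jitter(nrow(convGenes)))

  # paired peak architecture for one factor/genotype: shared background
  # peaks plus drug-specific proximal recruitment replacing distal peaks
  grArch <- function(proxVeh, proxDrug, convPeaks) {
    n <- config$nPeaks
    nConv <- nrow(convPeaks)
    npV <- round(proxVeh * n); npD <- round(proxDrug * n)
    if (npV < nConv) stop("vehicle proximal count below convergent count")
    if (npD < npV) stop("drug proximal rate must be >= vehicle rate")
    sharedProxN <- npV - nConv
    extraProxN <- npD - npV
    distVehN <- n - npV
    distDrugN <- n - npD
    prox <- samplePositions(proxZone, sharedProxN + max(extraProxN, 0L))
    prox$h <- heights[["GR"]] * jitter(nrow(prox))
    dist <- samplePositions(distZone, distVehN)
    dist$h <- heights[["GR"]] * jitter(nrow(dist))
    sharedProx <- rbind(convPeaks, prox[seq_len(sharedProxN), , drop = FALSE])
    extraProx <- if (extraProxN > 0L)
      prox[sharedProxN + seq_len(extraProxN), , drop = FALSE]
      else prox[0L, , drop = FALSE]
    sharedDist <- dist[seq_len(distDrugN), , drop = FALSE]
    vehOnlyDist <- dist[setdiff(seq_len(distVehN), seq_len(distDrugN)), ,
                        drop = FALSE]
    list(vehicle = rbind(sharedProx, sharedDist, vehOnlyDist),
         drug = rbind(sharedProx, extraProx, sharedDist))
  }

  grWt <- grArch(config$proximalRateVehicle, config$proximalShiftWt,
                 convGrSummit)
  grKo <- grArch(config$proximalRateVehicle, config$proximalShiftKo,
                 convGrSummit)

  # BMAL1 WT: shared background (incl. convergent promoter peaks), extra
  # vehicle-only peaks, and drug-only partner peaks near sampled GR drug
  # summits
  nB <- config$nPeaks
  nPart <- round(config$cooccurRateDrugWt * nB)
  nSharedB <- nB - nPart
  nSharedRand <- nSharedB - nrow(convBmSummit)
  if (nSharedRand < 0L) stop("nPeaks too small for convergent BMAL1 peaks")
  nProxShared <- round(config$proximalRateVehicle * nSharedRand)
  sharedB <- rbind(convBmSummit,
                   {p <- samplePositions(proxZone, nProxShared)
                    p$h <- heights[["BMAL1"]] * jitter(nrow(p)); p},
                   {d <- samplePositions(distZone, nSharedRand - nProxShared)
                    d$h <- heights[["BMAL1"]] * jitter(nrow(d)); d})
  nProxV <- round(config$proximalRateVehicle * nPart)
  vehOnlyB <- rbind({p <- samplePositions(proxZone, nProxV)
                     p$h <- heights[["BMAL1"]] * jitter(nrow(p)); p},
                    {d <- samplePositions(distZone, nPart - nProxV)
                     d$h <- heights[["BMAL1"]] * jitter(nrow(d)); d})
  # partner host peaks are kept far enough from convergent TSSs that a
  # partner (offset <= 900 bp, bump support 300 bp) cannot reach into the
  # +/-10 kb screen span of a convergent gene
  hostPad <- 10000L + 900L + 4L * ceiling(config$bumpSd) + 1L
  minDistConv <- vapply(seq_len(nrow(grWt$drug)), function(i) {
    j <- convGenes$chrom == grWt$drug$chrom[i]
    if (!any(j)) Inf else min(abs(grWt$drug$s0[i] - convT0[j]))
  }, 0)
  elig <- which(minDistConv > hostPad)
  if (length(elig) < nPart)
    stop("too few GR drug peaks clear of convergent spans for pairing")
  grDrugIdx <- sort(sample(elig, nPart))
  partners <- data.frame(chrom = grWt$drug$chrom[grDrugIdx],
                         s0 = grWt$drug$s0[grDrugIdx] +
                              sample(0:900, nPart, replace = TRUE),
                         h = heights[["BMAL1"]] * jitter(nPart))
  bmWt <- list(vehicle = rbind(sharedB, vehOnlyB),
               drug = rbind(sharedB, partners))
  pairing <- data.frame(gr_drug_index = grDrugIdx,
                        offset = partners$s0 - grWt$drug$s0[grDrugIdx])

  # BMAL1 KO: nonspecific background only, no planted pairing
  nSharedKo <- round(0.75 * nB)
  koShared <- samplePositions(distZone, nSharedKo)
  koShared$h <- 0.5 * heights[["BMAL1"]] * jitter(nrow(koShared))
  koVehX <- samplePositions(distZone, nB - nSharedKo)
  koVehX$h <- 0.5 * heights[["BMAL1"]] * jitter(nrow(koVehX))
  koDrugX <- samplePositions(distZone, nB - nSharedKo)
  koDrugX$h <- 0.5 * heights[["BMAL1"]] * jitter(nrow(koDrugX))
  bmKo <- list(vehicle = rbind(koShared, koVehX),
               drug = rbind(koShared, koDrugX))

  # RNApol-II: one peak per gene at its TSS, identical in all conditions
  polPeaks <- data.frame(chrom = genes$chrom, s0 = genes$tss - 1L,
                         h = heights[["RNApolII"]] * jitter(nrow(genes)))

  # --- window multipliers for planted drug effects ---
  greC <- motifCenters(genome$gre)
  eboxC <- motifCenters(genome$ebox)
  czone <- convCoreZones(config, convGenes)
  polT0 <- genes$tss - 1L
  fcByGt <- list(WT = truth$polii_fc_wt[match(genes$gene_id, truth$gene_id)],
                 KO = truth$polii_fc_ko[match(genes$gene_id, truth$gene_id)])

  mkTrack <- function(peakDf, gainWindows = NULL) {
    # gainWindows: data.frame(chrom, lo0, hi0, gain); later rows overwrite
    stepsList <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      nbins <- config$chromLength %/% bin
      vals <- rep(1, nbins)
      pk <- peakDf[peakDf$chrom == ch, , drop = FALSE]
      if (nrow(pk)) {
        supp <- 4L * ceiling(config$bumpSd)
        for (i in seq_len(nrow(pk))) {
          s0 <- pk$s0[i]
          j1 <- max(1L, (s0 - supp) %/% bin + 1L)
          j2 <- min(nbins, (s0 + supp) %/% bin + 1L)
          j <- j1:j2
          mid <- (j - 1L) * bin + bin / 2
          d <- mid - s0
          keep <- abs(d) <= supp
          vals[j[keep]] <- vals[j[keep]] +
            pk$h[i] * exp(-d[keep]^2 / (2 * config$bumpSd^2))
        }
      }
      if (!is.null(gainWindows)) {
        gw <- gainWindows[gainWindows$chrom == ch, , drop = FALSE]
        if (nrow(gw)) {
          mult <- rep(1, nbins)
          for (i in seq_len(nrow(gw))) {
            j1 <- gw$lo0[i] %/% bin + 1L
            j2 <- gw$hi0[i] %/% bin
            if (j2 >= j1) mult[max(1L, j1):min(nbins, j2)] <- gw$gain[i]
          }
          vals <- vals * mult
        }
      }
      if (config$noiseSigma > 0)
        vals <- vals * exp(stats::rnorm(nbins, 0, config$noiseSigma))
      r <- rle(vals)
      ends <- cumsum(r$lengths) * bin
      starts <- ends - r$lengths * bin + 1L
      stepsList[[ci]] <- data.frame(chrom = ch, start = starts, end = ends,
                                    value = r$values)
    }
    df <- do.call(rbind, stepsList)
    SignalTrack(GenomicRanges::GRanges(df$chrom,
                  IRanges::IRanges(start = df$start, end = df$end),
                  score = df$value),
                normFactor = 1)
  }

  motifGainWin <- function(centers, gain)
    data.frame(chrom = centers$chrom,
               lo0 = centers$c0 - config$quantHalfwidth,
               hi0 = centers$c0 + config$quantHalfwidth, gain = gain)
  convGainWin <- function(folds)
    data.frame(chrom = czone$chrom, lo0 = czone$tileLo, hi0 = czone$tileHi,
               gain = folds)
  tssGainWin <- function(folds)
    data.frame(chrom = genes$chrom, lo0 = polT0 - config$tssHalfwidth,
               hi0 = polT0 + config$tssHalfwidth, gain = folds)

  mkPeakSet <- function(df, fac, gt, tr) {
    df <- df[order(df$chrom, df$s0), , drop = FALSE]
    key <- paste(df$chrom, df$s0)
    while (anyDuplicated(key)) {            # resolve rare summit collisions
      i <- which(duplicated(key))[1L]
      df$s0[i] <- df$s0[i] + 1L
      key <- paste(df$chrom, df$s0)
    }
    gr <- GenomicRanges::GRanges(df$chrom,
            IRanges::IRanges(start = df$s0 - 99L, end = df$s0 + 100L),
            summit = df$s0 + 1L, score = df$h)
    PeakSet(gr, fac, gt, tr)
  }

  tracks <- list(); peakSets <- list()
  addCond <- function(fac, gt, tr, df, gains) {
    key <- paste(fac, gt, tr, sep = ".")
    peakSets[[key]] <<- mkPeakSet(df, fac, gt, tr)
    tracks[[key]] <<- mkTrack(df, gains)
  }

  addCond("GR", "WT", "vehicle", grWt$vehicle, NULL)
  addCond("GR", "WT", "prednisone", grWt$drug,
          rbind(motifGainWin(greC, config$greGainWt),
                convGainWin(convTruth$gr_gain_fold)))
  addCond("GR", "KO", "vehicle", grKo$vehicle, NULL)
  addCond("GR", "KO", "prednisone", grKo$drug,
          motifGainWin(greC, config$greGainKo))
  addCond("BMAL1", "WT", "vehicle", bmWt$vehicle, NULL)
  addCond("BMAL1", "WT", "prednisone", bmWt$drug,
          rbind(motifGainWin(eboxC, config$eboxGainWt),
                convGainWin(convTruth$bmal1_gain_fold)))
  addCond("BMAL1", "KO", "vehicle", bmKo$vehicle, NULL)
  addCond("BMAL1", "KO", "prednisone", bmKo$drug, NULL)
  addCond("RNApolII", "WT", "vehicle", polPeaks, NULL)
  addCond("RNApolII", "WT", "prednisone", polPeaks, tssGainWin(fcByGt$WT))
  addCond("RNApolII", "KO", "vehicle", polPeaks, NULL)
  addCond("RNApolII", "KO", "prednisone", polPeaks, tssGainWin(fcByGt$KO))
  tracks[["input"]] <- mkTrack(polPeaks[0L, , drop = FALSE], NULL)

  structure(list(config = config, genes = genes, gre = genome$gre,
                 ebox = genome$ebox, truth = truth, peakSets = peakSets,
                 tracks = tracks, pairing = pairing),
            class = "SyntheticCistrome")
}

#' Run the full synthetic generator
#'
#' Convenience wrapper: [generateGenome], [assignTruth],
#' [simulateConditionTracks] under one seed.
#'
#' @param config A [simConfig] (default `simConfig()`).
#' @return A `SyntheticCistrome` list; see [simulateConditionTracks].
#' @export
simulateCistrome <- function(config = simConfig()) {
  genome <- generateGenome(config)
  truth <- assignTruth(config, genome)
  simulateConditionTracks(config, genome, truth)
}

#' @export
print.SyntheticCistrome <- function(x, ...) {
  cat(sprintf(
    "SyntheticCistrome: %d chrom x %.3g bp, %d genes, seed %d\n",
    x$config$nChroms, as.numeric(x$config$chromLength), nrow(x$genes),
    x$config$seed))
  cat(sprintf("  %d peak sets, %d tracks; %d convergent genes\n",
              length(x$peakSets), length(x$tracks),
              sum(x$truth$class == "convergent")))
  invisible(x)
}

#' Write a truth table as TSV
#' @param truth Truth table from [assignTruth].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
  fmt <- function(x) ifelse(is.na(x), "NA", formatNum(x))
  lines <- c(paste(names(truth), collapse = "\t"),
             sprintf("%s\t%s\t%s\t%s\t%s\t%s", truth$gene_id, truth$class,
                     fmt(truth$polii_fc_wt), fmt(truth$polii_fc_ko),
                     fmt(truth$gr_gain_fold), fmt(truth$bmal1_gain_fold)))
  writeLinesLF(lines, path)
  invisible(path)
}

#' Read a truth table written by [writeTruthTable]
#' @param path Path to the TSV file.
#' @return data.frame with the same columns and values.
#' @export
readTruthTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "numeric",
                                   "numeric", "numeric", "numeric"),
                    na.strings = "NA", stringsAsFactors = FALSE)
}

#' Write all simulator outputs to a directory
#'
#' Emits one BED per peak set, one bedGraph per track, the gene table, the
#' truth table, the resolved configuration (YAML) and a `manifest.tsv`
#' mapping condition keys to files and normalization factors.
#'
#' @param sim A `SyntheticCistrome`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
writeCistrome <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (key in names(sim$peakSets)) {
    f <- file.path(outdir, paste0(gsub("\\.", "_", key), "_peaks.bed"))
    writePeakBed(sim$peakSets[[key]], f)
    rows[[length(rows) + 1L]] <- c(key, "peaks", basename(f), "")
  }
  for (key in names(sim$tracks)) {
    f <- file.path(outdir, paste0(gsub("\\.", "_", key), ".bedGraph"))
    writeBedGraph(sim$tracks[[key]], f)
    rows[[length(rows) + 1L]] <- c(key, "track", basename(f),
                                   formatNum(normFactor(sim$tracks[[key]])))
  }
  writeGeneTable(sim$genes, file.path(outdir, "genes.tsv"))
  writeTruthTable(sim$truth, file.path(outdir, "truth.tsv"))
  cfg <- sim$config; class(cfg) <- NULL
  writeLinesLF(strsplit(yaml::as.yaml(cfg), "\n")[[1L]],
               file.path(outdir, "config.yaml"))
  man <- vapply(rows, paste, "", collapse = "\t")
  writeLinesLF(c("key\ttype\tfile\tnorm_factor", man),
               file.path(outdir, "manifest.tsv"))
  invisible(outdir)
}
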