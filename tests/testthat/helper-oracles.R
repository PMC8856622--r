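# Independent brute-force oracles and small random-instance generators.
# The oracles deliberately use per-base vectors / all-pairs scans so they
# share no code path with the package implementations they check.

# per-base oracle: materialize the step function as a base-resolution
# vector, then average the queried slice (gaps are zeros)
oracleMeanSignal <- function(track, chrom, start, end, normalized = FALSE) {
  st <- trackSteps(track)
  sel <- as.character(GenomicRanges::seqnames(st)) == chrom
  vals <- numeric(end)      # 1..end, positions beyond steps stay 0
  s <- GenomicRanges::start(st)[sel]
  e <- GenomicRanges::end(st)[sel]
  v <- S4Vectors::mcols(st)$score[sel]
  for (i in seq_along(s)) {
    lo <- max(1L, s[i]); hi <- min(end, e[i])
    if (hi >= lo) vals[lo:hi] <- v[i]
  }
  stopifnot(start >= 1L)
  m <- mean(vals[start:end])
  if (normalized) m <- m * normFactor(track)
  m
}

# all-pairs nearest-TSS with explicit tie-break
oracleNearestTss <- function(summit, chrom, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(list(gene_id = NA_character_, distance = Inf))
  d <- abs(summit - g$tss)
  cand <- which(d == min(d))
  if (length(cand) > 1L) cand <- cand[order(g$gene_id[cand])][1L]
  signed <- if (g$strand[cand] == "+") summit - g$tss[cand]
            else g$tss[cand] - summit
  list(gene_id = g$gene_id[cand], distance = signed)
}

# direct region classifier from the signed distance
oracleRegion <- function(d) {
  if (d >= -1000 && d < 100) "promoter"
  else if (d >= 100 && d < 1000) "5'UTR-proxy"
  else if (d >= 1000 && d < 10000) "gene-body"
  else if (d >= -10000 && d < -1000) "TTS-flank"
  else "intergenic"
}

# all-pairs nearest-summit distances A -> B
oracleInterdistance <- function(summitsA, chromA, summitsB, chromB) {
  out <- numeric(0)
  nmiss <- 0L
  for (i in seq_along(summitsA)) {
    j <- which(chromB == chromA[i])
    if (!length(j)) { nmiss <- nmiss + 1L; next }
    out <- c(out, min(abs(summitsA[i] - summitsB[j])))
  }
  list(distances = out, nNoPartner = nmiss)
}

# direct histogram by explicit comparisons: [b1,b2], (b2,b3], ..., (bk,Inf)
oracleBinCounts <- function(d, bins = c(0, 300, 900, 5000)) {
  k <- length(bins)
  counts <- integer(k)
  for (x in d) {
    if (x >= bins[1] && x <= bins[2]) counts[1] <- counts[1] + 1L
    else {
      placed <- FALSE
      for (j in seq(2, k - 1)) {
        if (x > bins[j] && x <= bins[j + 1]) {
          counts[j] <- counts[j] + 1L; placed <- TRUE; break
        }
      }
      if (!placed && x > bins[k]) counts[k] <- counts[k] + 1L
    }
  }
  counts
}

# random step track on one or two chromosomes (non-overlapping sorted steps)
randomTrack <- function(chromLen = 1e5, nSteps = 100, chroms = "chr1",
                        normFactor = NULL) {
  dfs <- lapply(chroms, function(ch) {
    cuts <- sort(sample.int(chromLen - 1L, 2L * nSteps))
    s <- cuts[seq(1, length(cuts), by = 2)]
    e <- cuts[seq(2, length(cuts), by = 2)]
    data.frame(chrom = ch, start = s, end = e,
               value = round(stats::runif(nSteps, 0, 10), 3))
  })
  df <- do.call(rbind, dfs)
  SignalTrack(GenomicRanges::GRanges(df$chrom,
                IRanges::IRanges(df$start, df$end), score = df$value),
              normFactor = normFactor)
}

randomGenes <- function(n = 50, chroms = c("chr1", "chr2"),
                        chromLen = 1e5) {
  geneTable(sprintf("g%03d", sample(seq_len(10L * n), n)),
            sample(chroms, n, replace = TRUE),
            sample.int(chromLen, n, replace = TRUE),
            sample(c("+", "-"), n, replace = TRUE))
}

randomPeakSet <- function(n = 100, chroms = c("chr1", "chr2"),
                          chromLen = 1e5, fac = "GR", gt = "WT",
                          tr = "vehicle") {
  repeat {
    ch <- sample(chroms, n, replace = TRUE)
    s0 <- sample.int(chromLen - 400L, n, replace = TRUE) + 150L
    if (!anyDuplicated(paste(ch, s0))) break
  }
  gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(s0 - 100L, s0 + 100L),
                               summit = s0, score = stats::runif(n, 1, 10))
  PeakSet(gr, fac, gt, tr)
}

# small, fast simulator configuration used across tests
tinyConfig <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, nChroms = 2L, chromLength = 1e6,
                   nGenes = 30L, nGreSites = 40L, nEboxSites = 40L,
                   nPeaks = 60L, nConvergentGenes = 6L, nWtOnlyGenes = 6L,
                   nSharedGenes = 4L, nKoOnlyGenes = 4L)
  do.call(simConfig, utils::modifyList(defaults, list(...)))
}

grTrackSet <- function(sim) {
  list("WT.vehicle" = sim$tracks[["GR.WT.vehicle"]],
       "WT.prednisone" = sim$tracks[["GR.WT.prednisone"]],
       "KO.vehicle" = sim$tracks[["GR.KO.vehicle"]],
       "KO.prednisone" = sim$tracks[["GR.KO.prednisone"]])
}
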