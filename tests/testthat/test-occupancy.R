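mkSites <- function(centers0, chrom = "chr1", width = 12L) {
  half <- width %/% 2L
  MotifSiteSet("GRE", GenomicRanges::GRanges(chrom,
    IRanges::IRanges(centers0 - half + 1L, centers0 + (width - half))))
}

constTrack <- function(value, nf = 1, len = 1e5, chrom = "chr1") {
  SignalTrack(GenomicRanges::GRanges(chrom, IRanges::IRanges(1, len),
                                     score = value), normFactor = nf)
}

test_that("site signal matrix reproduces constant tracks and proportional contrasts", {
  sites <- mkSites(c(1000L, 5000L, 20000L))
  ts <- list("WT.vehicle" = constTrack(3, nf = 2),
             "WT.prednisone" = constTrack(6, nf = 2))
  prof <- siteSignalMatrix(ts, sites, halfwidth = 200L, pseudocount = 0)
  expect_true(all(siteMatrix(prof)[, "WT.vehicle"] == 3 * 2))
  expect_true(all(siteMatrix(prof)[, "WT.prednisone"] == 6 * 2))
  fc <- foldChanges(prof)
  expect_equal(fc$fold[fc$genotype == "WT"], 2)
  expect_error(siteSignalMatrix(ts, MotifSiteSet("GRE",
    GenomicRanges::GRanges())), "empty")
})

test_that("site signal entries match the per-base oracle on random tracks", {
  set.seed(21)
  for (i in 1:15) {
    tr <- randomTrack(chromLen = 5e4, nSteps = sample(20:120, 1))
    ctr <- sort(sample(seq(500L, 49000L), 8L))
    sites <- mkSites(ctr)
    prof <- siteSignalMatrix(list("WT.vehicle" = tr, "WT.prednisone" = tr),
                             sites, halfwidth = 200L)
    for (j in seq_along(ctr)) {
      expect_equal(unname(siteMatrix(prof)[j, "WT.vehicle"]),
                   oracleMeanSignal(tr, "chr1", ctr[j] - 199L,
                                    ctr[j] + 200L, normalized = TRUE),
                   tolerance = 1e-9)
    }
  }
})

test_that("occupancy aggregate is invariant to site order and chromosome names", {
  set.seed(22)
  tr <- randomTrack(chromLen = 5e4, nSteps = 60)
  ctr <- sample(seq(500L, 49000L), 20L)
  ts <- list("WT.vehicle" = tr, "WT.prednisone" = tr)
  p1 <- siteSignalMatrix(ts, mkSites(sort(ctr)))
  p2 <- siteSignalMatrix(ts, mkSites(ctr))
  expect_equal(occupancyAggregate(p1), occupancyAggregate(p2))

  ren <- function(x) {
    st <- trackSteps(x)
    SignalTrack(GenomicRanges::GRanges("chrZ",
      IRanges::IRanges(GenomicRanges::start(st), GenomicRanges::end(st)),
      score = S4Vectors::mcols(st)$score), normFactor = normFactor(x))
  }
  p3 <- siteSignalMatrix(list("WT.vehicle" = ren(tr),
                              "WT.prednisone" = ren(tr)),
                         mkSites(sort(ctr), chrom = "chrZ"))
  expect_equal(unname(occupancyAggregate(p3)),
               unname(occupancyAggregate(p1)))
})

test_that("cross-motif quantification is the same operation with swapped inputs", {
  sim <- simulateCistrome(tinyConfig())
  bmT <- list("WT.vehicle" = sim$tracks[["BMAL1.WT.vehicle"]],
              "WT.prednisone" = sim$tracks[["BMAL1.WT.prednisone"]])
  onGre <- siteSignalMatrix(bmT, sim$gre)
  onEbox <- siteSignalMatrix(bmT, sim$ebox)
  expect_identical(motifName(onGre), "GRE")
  expect_identical(motifName(onEbox), "E-box")
  # same code path: entries for the GRE profile equal direct window means
  ctr <- floor((GenomicRanges::start(motifSites(sim$gre)) - 1 +
                GenomicRanges::end(motifSites(sim$gre))) / 2)
  chs <- as.character(GenomicRanges::seqnames(motifSites(sim$gre)))
  i <- 5L
  expect_equal(unname(siteMatrix(onGre)[i, "WT.vehicle"]),
               meanSignal(bmT[["WT.vehicle"]], chs[i],
                          start = ctr[i] - 199L, end = ctr[i] + 200L,
                          normalized = TRUE))
})

test_that("occupancy contrast handles the null case and names missing conditions", {
  sites <- mkSites(c(1000L, 5000L, 9000L, 15000L))
  set.seed(23)
  tr <- randomTrack(chromLen = 5e4, nSteps = 60)
  prof <- siteSignalMatrix(list("WT.vehicle" = tr, "WT.prednisone" = tr),
                           sites)
  ctr <- occupancyContrast(prof, B = 200L, seed = 5L)
  expect_equal(ctr$folds$fold, 1)
  expect_true(ctr$folds$ci_lo <= 1 && ctr$folds$ci_hi >= 1)
  expect_true(all(ctr$log2PerSite$WT == 0))

  profBad <- siteSignalMatrix(list("WT.vehicle" = tr), sites)
  expect_error(occupancyContrast(profBad), "prednisone")
})

test_that("peak counts are exact per condition", {
  expect_equal(nrow(peakCounts(list())), 0L)
  sim <- simulateCistrome(tinyConfig())
  pc <- peakCounts(sim$peakSets)
  grRows <- pc[pc$factor %in% c("GR", "BMAL1"), ]
  expect_true(all(grRows$n == 60L))
  polRows <- pc[pc$factor == "RNApolII", ]
  expect_true(all(polRows$n == 30L))  # one peak per gene TSS
})
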