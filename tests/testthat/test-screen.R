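constTrack2 <- function(value, len = 1e5) {
  SignalTrack(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, len),
                                     score = value), normFactor = 1)
}

test_that("quadrant classification follows the threshold rule", {
  expect_equal(quadrantClassify(2, 1), "WT-only-up")
  expect_equal(quadrantClassify(2, 2), "shared-up")
  expect_equal(quadrantClassify(1, 2), "KO-only-up")
  expect_equal(quadrantClassify(1, 1), "none")
  expect_equal(quadrantClassify(1.5, 1.49), "WT-only-up")  # >= vs <
  expect_error(quadrantClassify(-1, 1), "positive")
})

test_that("promoter factor gain reads proportional and identical tracks", {
  g <- geneTable("g1", "chr1", 50000L, "+")
  expect_equal(promoterFactorGain(constTrack2(4), constTrack2(2), g,
                                  pseudocount = 0), 1)
  expect_equal(promoterFactorGain(constTrack2(2), constTrack2(2), g), 0)
  expect_equal(promoterFactorGain(constTrack2(4), constTrack2(2), g,
                                  pseudocount = 0, mode = "mean"), 1)
  expect_error(promoterFactorGain(constTrack2(1), constTrack2(1), g,
                                  span = 100L, window = 400L), "span")
})

test_that("gain localizes the drug-specific window and recovers planted folds", {
  g <- geneTable("g1", "chr1", 50000L, "+")
  # vehicle flat 1; drug has a 3x gain over exactly one 400 bp tile
  veh <- constTrack2(1)
  # gain tile aligned to the [tss - 400, tss) tiling: 1-based [49600, 49999]
  drugSteps <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 49600, 50000), c(49599, 49999, 1e5)),
    score = c(1, 3, 1))
  drug <- SignalTrack(drugSteps, normFactor = 1)
  expect_equal(promoterFactorGain(drug, veh, g, pseudocount = 0), log2(3))

  # planted convergent genes in the noise-free simulator, exact to 1e-6
  sim <- simulateCistrome(tinyConfig(noiseSigma = 0))
  conv <- sim$truth[sim$truth$class == "convergent", ]
  genes <- sim$genes[match(conv$gene_id, sim$genes$gene_id), ]
  gain <- promoterFactorGain(sim$tracks[["GR.WT.prednisone"]],
                             sim$tracks[["GR.WT.vehicle"]], genes,
                             pseudocount = 0)
  expect_equal(gain, log2(conv$gr_gain_fold), tolerance = 1e-6)
})

test_that("the screen is null on identical tracks and monotone in thresholds", {
  genes <- geneTable(c("g1", "g2"), c("chr1", "chr1"), c(30000L, 70000L),
                     c("+", "-"))
  tr <- constTrack2(2)
  tracks <- stats::setNames(rep(list(tr), 8L),
    c("RNApolII.WT.vehicle", "RNApolII.WT.prednisone",
      "RNApolII.KO.vehicle", "RNApolII.KO.prednisone",
      "GR.WT.vehicle", "GR.WT.prednisone",
      "BMAL1.WT.vehicle", "BMAL1.WT.prednisone"))
  scr <- runScreen(tracks, genes)
  expect_equal(scr$summary$nSelected, 0L)
  expect_true(all(scr$genes$quadrant == "none"))
  expect_error(runScreen(tracks[-1L], genes), "RNApolII.WT.vehicle")

  sim <- simulateCistrome(tinyConfig())
  nSel <- vapply(c(1.2, 1.5, 2.5, 5), function(th)
    runScreen(sim$tracks, sim$genes, upThreshold = th)$summary$nSelected,
    0L)
  expect_true(all(diff(nSel) <= 0))
  nSelG <- vapply(c(0.2, log2(1.5), 1.5, 4), function(th)
    runScreen(sim$tracks, sim$genes,
              gainThreshold = th)$summary$nSelected, 0L)
  expect_true(all(diff(nSelG) <= 0))
})

test_that("screen output is invariant to gene-table order", {
  sim <- simulateCistrome(tinyConfig())
  s1 <- runScreen(sim$tracks, sim$genes)
  shuffled <- sim$genes[rev(seq_len(nrow(sim$genes))), ]
  s2 <- runScreen(sim$tracks, shuffled)
  expect_identical(s1$genes, s2$genes)
})

test_that("noise-free screen recovers exactly the planted convergent set", {
  sim <- simulateCistrome(tinyConfig(noiseSigma = 0))
  scr <- runScreen(sim$tracks, sim$genes)
  rec <- screenRecovery(scr, sim$truth)
  expect_equal(rec$sensitivity, 1)
  sel <- scr$genes$gene_id[scr$genes$selected]
  planted <- sim$truth$gene_id[sim$truth$class == "convergent"]
  expect_true(all(planted %in% sel))
  # quadrant classes match the planted classes for every gene
  m <- merge(scr$genes[, c("gene_id", "quadrant")], sim$truth)
  plantedQuadrant <- ifelse(m$class %in% c("convergent", "WT-only-up"),
                            "WT-only-up",
                            ifelse(m$class == "shared-up", "shared-up",
                                   ifelse(m$class == "KO-only-up",
                                          "KO-only-up", "none")))
  expect_equal(m$quadrant, plantedQuadrant)
})
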