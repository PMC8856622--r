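mkSet <- function(summits, chrom = "chr1", fac = "GR") {
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(summits - 50L, summits + 50L), summit = summits,
    score = 1)
  PeakSet(gr, fac, "WT", "vehicle")
}

test_that("interdistance handles identity, arithmetic and missing partners", {
  a <- mkSet(c(1000L, 5000L))
  expect_equal(sort(peakInterdistance(a, a)$distances), c(0, 0))
  b <- mkSet(450L, fac = "BMAL1")
  expect_equal(peakInterdistance(mkSet(150L), b)$distances, 300)
  # A peaks without a same-chromosome B peak are excluded but counted
  a2 <- mkSet(c(1000L, 2000L))
  bX <- mkSet(500L, chrom = "chr9", fac = "BMAL1")
  r <- peakInterdistance(a2, bX)
  expect_equal(length(r$distances), 0L)
  expect_equal(r$nNoPartner, 2L)
  expect_error(peakInterdistance(a, PeakSet(GenomicRanges::GRanges(),
                                            "BMAL1", "WT", "vehicle")),
               "nonempty")
})

test_that("interdistance matches the all-pairs oracle and is directional", {
  set.seed(41)
  for (i in 1:15) {
    a <- randomPeakSet(n = sample(50:200, 1))
    b <- randomPeakSet(n = sample(50:200, 1), fac = "BMAL1")
    got <- peakInterdistance(a, b)
    want <- oracleInterdistance(
      peakSummits(a), as.character(GenomicRanges::seqnames(peaks(a))),
      peakSummits(b), as.character(GenomicRanges::seqnames(peaks(b))))
    expect_equal(sort(got$distances), sort(want$distances))
    expect_equal(got$nNoPartner, want$nNoPartner)
  }
  # asymmetry: A->B need not equal B->A
  a <- mkSet(c(1000L, 1100L))
  b <- mkSet(c(1000L, 9000L), fac = "BMAL1")
  expect_false(identical(sort(peakInterdistance(a, b)$distances),
                         sort(peakInterdistance(b, a)$distances)))
})

test_that("binned histogram uses [0,300], (300,900] edge conventions", {
  r <- binnedCooccurrence(c(0, 150, 500, 2000))
  expect_equal(unname(r$counts), c(2L, 1L, 1L, 0L))
  expect_equal(sum(r$fractions), 1)
  # the shared boundary 300 falls in the first bin
  expect_equal(unname(binnedCooccurrence(300)$counts), c(1L, 0L, 0L, 0L))
  expect_equal(unname(binnedCooccurrence(numeric(0))$counts),
               rep(0L, 4L))
  expect_error(binnedCooccurrence(1, bins = c(0, 300, 200)),
               "increasing")

  set.seed(42)
  d <- stats::rexp(500, 1 / 1500)
  expect_equal(unname(binnedCooccurrence(d)$counts), oracleBinCounts(d))
})

test_that("histogram counts are conserved under bin refinement", {
  set.seed(43)
  d <- stats::rexp(400, 1 / 800)
  parent <- binnedCooccurrence(d, bins = c(0, 300, 900, 5000))
  refined <- binnedCooccurrence(d, bins = c(0, 100, 300, 600, 900, 5000))
  expect_equal(unname(parent$counts[1]),
               sum(refined$counts[1:2]))          # [0,300]
  expect_equal(unname(parent$counts[2]),
               sum(refined$counts[3:4]))          # (300,900]
  expect_equal(sum(parent$counts), sum(refined$counts))
})

test_that("co-occurrence contrast is null for identical inputs and scale-stable", {
  set.seed(44)
  d <- stats::rexp(300, 1 / 3000)  # populates every bin
  r <- binnedCooccurrence(d)
  tb <- cooccurrenceContrast(r, r, d, d, nPerm = 500L, seed = 2L)
  expect_equal(tb$ratio, rep(1, 4))
  expect_true(all(tb$p_value > 0.01))
  # doubling all counts leaves the ratios essentially unchanged
  d2 <- rep(d, 2L)
  tb2 <- cooccurrenceContrast(binnedCooccurrence(d2), binnedCooccurrence(d),
                              d2, d, nPerm = 200L, seed = 2L)
  expect_equal(tb2$ratio, rep(1, 4), tolerance = 0.02)
  expect_error(cooccurrenceContrast(r, binnedCooccurrence(d,
    bins = c(0, 100, 200, 300)), d, d), "differ")
})

test_that("permutation p-values match exact enumeration on tiny instances", {
  dd <- c(100, 200, 250, 2000)
  dv <- c(1200, 4000, 7000, 150)
  rd <- binnedCooccurrence(dd); rv <- binnedCooccurrence(dv)
  tb <- cooccurrenceContrast(rd, rv, dd, dv, nPerm = 20000L, seed = 7L)
  pooled <- c(dd, dv)
  obs <- tb$ratio
  combos <- utils::combn(8L, 4L)
  exact <- numeric(4L)
  for (c_i in seq_len(ncol(combos))) {
    i <- combos[, c_i]
    cd <- oracleBinCounts(pooled[i])
    cv <- oracleBinCounts(pooled[-i])
    fr <- ((cd + 0.5) / 4) / ((cv + 0.5) / 4)
    exact <- exact + (fr >= obs)
  }
  exactP <- exact / ncol(combos)
  # Monte-Carlo agreement: binomial error at N = 20000 is < 0.01 here
  expect_equal(tb$p_value, exactP, tolerance = 0.05)
})
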