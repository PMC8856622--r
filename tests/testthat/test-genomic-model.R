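test_that("meanSignal matches direct cases and brute force on random tracks", {
  tr <- SignalTrack(GenomicRanges::GRanges("chr1",
          IRanges::IRanges(1, 1000), score = 3.5), normFactor = 1)
  expect_equal(meanSignal(tr, "chr1", start = 101, end = 400), 3.5)
  # half-covered window at value 2 averages to 1
  tr2 <- SignalTrack(GenomicRanges::GRanges("chr1",
           IRanges::IRanges(1, 50), score = 2), normFactor = 1)
  expect_equal(meanSignal(tr2, "chr1", start = 1, end = 100), 1)

  set.seed(11)
  for (i in 1:25) {
    tr <- randomTrack(chromLen = 1e4, nSteps = sample(5:80, 1))
    s <- sample.int(9000L, 1L); e <- s + sample.int(900L, 1L)
    expect_equal(meanSignal(tr, "chr1", start = s, end = e),
                 oracleMeanSignal(tr, "chr1", s, e), tolerance = 1e-9)
  }
})

test_that("meanSignal is linear in track values and invariant to step splitting", {
  set.seed(12)
  tr <- randomTrack(chromLen = 1e4, nSteps = 40)
  st <- trackSteps(tr)
  sc <- S4Vectors::mcols(st)$score
  tr3 <- SignalTrack(GenomicRanges::GRanges(
    GenomicRanges::seqnames(st), IRanges::IRanges(
      GenomicRanges::start(st), GenomicRanges::end(st)), score = 3 * sc),
    normFactor = normFactor(tr))
  m1 <- meanSignal(tr, "chr1", start = 500, end = 6000)
  expect_equal(meanSignal(tr3, "chr1", start = 500, end = 6000), 3 * m1)

  # split every step in two adjacent equal-valued halves
  wide <- which(GenomicRanges::width(st) >= 2L)
  narrow <- setdiff(seq_along(st), wide)
  s <- GenomicRanges::start(st); e <- GenomicRanges::end(st)
  mid <- s + (e - s) %/% 2L
  parts <- rbind(
    data.frame(start = s[wide], end = mid[wide], score = sc[wide]),
    data.frame(start = mid[wide] + 1L, end = e[wide], score = sc[wide]),
    data.frame(start = s[narrow], end = e[narrow], score = sc[narrow]))
  trSplit <- SignalTrack(GenomicRanges::GRanges("chr1",
    IRanges::IRanges(parts$start, parts$end), score = parts$score),
    normFactor = normFactor(tr))
  expect_equal(meanSignal(trSplit, "chr1", start = 500, end = 6000), m1,
               tolerance = 1e-12)
})

test_that("nearestTss signs distances by strand and breaks ties lexicographically", {
  genes <- geneTable(c("gA", "gB"), c("chr1", "chr1"), c(4000L, 9000L),
                     c("+", "-"))
  # summit 5000, TSS 4000 on + strand -> +1000 (downstream)
  r <- nearestTss(5000L, genes, chrom = "chr1")
  expect_equal(r$gene_id, "gA")
  expect_equal(r$distance, 1000)
  # summit 8000, TSS 9000 on - strand -> +1000 (downstream in strand sense)
  r2 <- nearestTss(8000L, genes, chrom = "chr1")
  expect_equal(r2$gene_id, "gB")
  expect_equal(r2$distance, 1000)
  # equidistant -> smaller gene_id
  tie <- geneTable(c("gZ", "gA"), c("chr1", "chr1"), c(1000L, 3000L),
                   c("+", "+"))
  expect_equal(nearestTss(2000L, tie, chrom = "chr1")$gene_id, "gA")
  # no gene on the peak's chromosome -> Inf sentinel
  r3 <- nearestTss(100L, genes, chrom = "chrX")
  expect_true(is.infinite(r3$distance))
  expect_true(is.na(r3$gene_id))
  expect_error(nearestTss(1L, genes[0, ], chrom = "chr1"), "empty")
})

test_that("nearestTss agrees with the all-pairs oracle on random instances", {
  set.seed(13)
  for (i in 1:20) {
    genes <- randomGenes(n = sample(20:100, 1))
    n <- sample(50:300, 1)
    chrom <- sample(c("chr1", "chr2", "chr3"), n, replace = TRUE)
    summit <- sample.int(1e5, n, replace = TRUE)
    got <- nearestTss(summit, genes, chrom = chrom)
    for (j in seq_len(n)) {
      want <- oracleNearestTss(summit[j], chrom[j], genes)
      expect_identical(got$gene_id[j], want$gene_id)
      expect_equal(got$distance[j], want$distance)
    }
  }
})

test_that("tssSignal reads constant tracks and silent chromosomes correctly", {
  genes <- geneTable(c("g1", "g2"), c("chr1", "chr2"), c(5000L, 5000L),
                     c("+", "-"))
  tr <- SignalTrack(GenomicRanges::GRanges("chr1",
          IRanges::IRanges(1, 10000), score = 4), normFactor = 2)
  v <- tssSignal(tr, genes, halfwidth = 500L)
  expect_equal(unname(v["g1"]), 4 * 2)
  expect_equal(unname(v["g2"]), 0)  # no signal on chr2

  set.seed(14)
  tr2 <- randomTrack(chromLen = 2e4, nSteps = 60)
  g <- geneTable("gX", "chr1", 9000L, "+")
  expect_equal(unname(tssSignal(tr2, g, halfwidth = 500L,
                                normalized = FALSE)),
               oracleMeanSignal(tr2, "chr1", 8500L, 9499L),
               tolerance = 1e-9)
})
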