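test_that("weight-normalized work matches the defining formula", {
  expect_equal(normalizedWork(25, 300, 1800), 25 * 300^2 / 1800^2)
  expect_equal(normalizedWork(25, 0, 1800), 0)
  expect_equal(normalizedWork(25, 600, 1800),
               4 * normalizedWork(25, 300, 1800))
  expect_error(normalizedWork(-1, 10, 10), "> 0")
  set.seed(51)
  m <- runif(1, 10, 40); d <- runif(1, 50, 500); t <- runif(1, 60, 3600)
  k <- runif(1, 0.5, 3)
  expect_equal(normalizedWork(k * m, d, t), k * normalizedWork(m, d, t))
  expect_equal(normalizedWork(m, k * d, t), k^2 * normalizedWork(m, d, t))
  expect_equal(normalizedWork(m, d, k * t), normalizedWork(m, d, t) / k^2)
})

test_that("basal OCR subtracts the rotenone/antimycin floor and normalizes by protein", {
  s <- ocrSeries(list(baseline = c(100, 102, 98), rotAA = c(20, 22, 18)),
                 proteinMass = 10)
  expect_equal(basalOcr(s), 8)
  sNull <- ocrSeries(list(baseline = c(50, 50, 50), rotAA = c(50, 50, 50)),
                     proteinMass = 5)
  expect_equal(basalOcr(sNull), 0)
  s2 <- ocrSeries(s$phases, proteinMass = 20)
  expect_equal(basalOcr(s2), basalOcr(s) / 2)
  expect_error(basalOcr(ocrSeries(list(baseline = c(1, 1, 1)),
                                  proteinMass = 1)), "rotAA")
  sNeg <- ocrSeries(list(baseline = c(10, 10, 10), rotAA = c(20, 20, 20)),
                    proteinMass = 1)
  expect_warning(v <- basalOcr(sNeg), "negative")
  expect_equal(v, -10)  # flagged, not clamped
  expect_error(ocrSeries(list(baseline = c(1, 2)), 1), "3")
})

test_that("RCR is state III over oligomycin state IV", {
  expect_equal(rcr(ocrSeries(list(ADP = c(150, 150, 150),
                                  oligomycin = c(50, 50, 50)))), 3)
  expect_equal(rcr(ocrSeries(list(ADP = c(80, 80, 80),
                                  oligomycin = c(80, 80, 80)))), 1)
  expect_equal(rcr(ocrSeries(list(ADP = c(150, 140, 160),
                                  oligomycin = c(50, 50, 50)))),
               rcr(ocrSeries(list(ADP = c(160, 150, 140),
                                  oligomycin = c(50, 50, 50)))))
  expect_error(rcr(ocrSeries(list(ADP = c(1, 1, 1),
                                  oligomycin = c(0, 0, 0)))), "zero")
})

test_that("13C labeling ratio subtracts background and floors at zero", {
  expect_equal(as.numeric(labelingRatio(12, 100, 0.02)), 10)
  expect_equal(as.numeric(labelingRatio(2, 100, 0.02)), 0)
  expect_equal(as.numeric(labelingRatio(12, 100, 0)), 12)
  expect_warning(v <- labelingRatio(1, 100, 0.05), "background")
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "clamped"))
  expect_error(labelingRatio(1, 0, 0), "> 0")
})

test_that("qPCR ratios follow exponential amplification arithmetic", {
  expect_equal(mtdnaRatio(20, 20)$ratio, 1)
  expect_equal(mtdnaRatio(20, 21)$ratio, 2)
  # reference and DNA concentration cancel in the ratio
  expect_equal(mtdnaRatio(22, 24, ctReference = 15, dnaConc = 3)$ratio,
               mtdnaRatio(22, 24)$ratio)
  expect_equal(mtdnaRatio(20, 22, efficiency = 1.9)$ratio, 1.9^2)
  expect_error(mtdnaRatio(50, 20), "45")

  expect_equal(percentInput(25, 25, 0), 100)
  expect_equal(percentInput(26, 25, 0), 50)
  expect_equal(percentInput(25, 25 + log2(100), log2(100)), 100)
  expect_error(percentInput(0, 25, 0), "45")
})

test_that("lumicycle amplitude recovers known cosine amplitudes", {
  t <- seq(0, 120, by = 1 / 3)
  A <- 85
  pure <- A * cos(2 * pi * t / 24)
  expect_equal(lumicycleAmplitude(t, pure), A, tolerance = 0.02)
  # linear drift is removed by the running-mean detrend
  drift <- pure + 4 * t + 200
  expect_equal(lumicycleAmplitude(t, drift), A, tolerance = 0.02)
  expect_error(lumicycleAmplitude(t, rep(5, length(t))), "oscillation")
  tCoarse <- seq(0, 120, by = 2)
  expect_error(lumicycleAmplitude(tCoarse, cos(2 * pi * tCoarse / 24)),
               "interval")
})

test_that("amplitude estimator tracks damped cosines against a dense oracle", {
  t <- seq(0, 120, by = 1 / 3)
  for (damp in c(0.95, 0.9)) {   # <= 10% loss per 24 h cycle
    A <- 100
    y <- A * damp^(t / 24) * cos(2 * pi * t / 24)
    got <- lumicycleAmplitude(t, y)
    # oracle: dense-grid detrended third-cycle half peak-to-trough
    td <- seq(0, 120, by = 0.01)
    yd <- A * damp^(td / 24) * cos(2 * pi * td / 24)
    trend <- vapply(td, function(x)
      mean(yd[td >= x - 12 & td <= x + 12]), 0)
    dd <- yd - trend
    asc <- which(dd[-length(dd)] <= 0 & dd[-1] > 0)
    seg <- dd[asc[3]:asc[4]]
    want <- (max(seg) - min(seg)) / 2
    expect_equal(got, want, tolerance = 0.05)
  }
})

test_that("assay CSV readers validate their headers and round values through", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("phase,ocr", "baseline,100", "baseline,102", "baseline,98",
               "rotAA,20", "rotAA,22", "rotAA,18"), f)
  s <- readOcrCsv(f, proteinMass = 10)
  expect_equal(basalOcr(s), 8)

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("sample,target,ct", "s1,ND1,20", "s1,HK2,21"), f2)
  ct <- readCtTable(f2)
  expect_equal(mtdnaRatio(ct$ct[ct$target == "ND1"],
                          ct$ct[ct$target == "HK2"])$ratio, 2)
  writeLines(c("sample,ct", "s1,20"), f2)
  expect_error(readCtTable(f2), "columns")

  f3 <- tempfile(fileext = ".csv")
  tt <- seq(0, 120, by = 0.5)
  writeLines(c("time_h,counts",
               paste(tt, 50 * cos(2 * pi * tt / 24), sep = ",")), f3)
  lum <- readLumicycleCsv(f3)
  expect_equal(lumicycleAmplitude(lum$time_h, lum$counts), 50,
               tolerance = 0.02)
})
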