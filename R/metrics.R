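# Derived physiological and assay measures used alongside the cistrome
# analysis: treadmill work, Seahorse-style respirometry summaries, 13C
# labeling, qPCR-derived ratios and circadian reporter amplitude. Each
# implements the stated defining formula; negative background-subtracted
# values are flagged rather than silently altered (labelingRatio floors at
# zero with a QC flag, since a fraction cannot be negative).

#' Weight-normalized running work
#'
#' `bodyMass (g) * distance^2 (m^2) / time^2 (s^2)`, the weight-normalized
#' endurance score (reported on a microjoule-labelled scale).
#'
#' @param bodyMass Body mass in grams (> 0).
#' @param distance Distance run in meters (>= 0).
#' @param time Elapsed time in seconds (> 0).
#' @return Nonnegative score.
#' @examples
#' normalizedWork(25, 300, 1800)  # ~0.6944
#' @export
normalizedWork <- function(bodyMass, distance, time) {
  if (any(bodyMass <= 0) || any(time <= 0) || any(distance < 0))
    stop("bodyMass and time must be > 0 and distance >= 0")
  bodyMass * distance^2 / time^2
}

#' Oxygen-consumption phase series
#'
#' Holds the per-phase OCR reads of a respirometry run. Each phase carries
#' exactly three consecutive reads.
#'
#' @param phases Named list of numeric length-3 read vectors; allowed names
#'   are `baseline`, `ADP`, `oligomycin`, `FCCP`, `rotAA`.
#' @param proteinMass Total protein content of the well, in micrograms.
#' @return list of class `OcrSeries`.
#' @export
ocrSeries <- function(phases, proteinMass = NA_real_) {
  allowed <- c("baseline", "ADP", "oligomycin", "FCCP", "rotAA")
  if (!is.list(phases) || is.null(names(phases)))
    stop("'phases' must be a named list")
  bad <- setdiff(names(phases), allowed)
  if (length(bad)) stop("unknown phase label: ", bad[1L])
  for (nm in names(phases)) {
    v <- phases[[nm]]
    if (length(v) != 3L || any(!is.finite(v)) || any(v < 0))
      stop("phase '", nm, "' must hold exactly 3 nonnegative reads")
  }
  structure(list(phases = phases, proteinMass = proteinMass),
            class = "OcrSeries")
}

#' Basal oxygen consumption rate, protein-normalized
#'
#' Mean of the three baseline reads minus the mean of the three reads after
#' rotenone/antimycin addition, divided by the protein mass. A negative
#' value is reported as-is with a QC warning (not clamped).
#'
#' @param series An [ocrSeries] with `baseline` and `rotAA` phases and a
#'   positive `proteinMass`.
#' @return Protein-normalized basal OCR.
#' @examples
#' s <- ocrSeries(list(baseline = c(100, 102, 98), rotAA = c(20, 22, 18)),
#'                proteinMass = 10)
#' basalOcr(s)  # 8
#' @export
basalOcr <- function(series) {
  stopifnot(inherits(series, "OcrSeries"))
  for (nm in c("baseline", "rotAA"))
    if (is.null(series$phases[[nm]])) stop("missing phase: ", nm)
  if (!is.finite(series$proteinMass) || series$proteinMass <= 0)
    stop("proteinMass must be a positive number")
  out <- (mean(series$phases$baseline) - mean(series$phases$rotAA)) /
         series$proteinMass
  if (out < 0)
    warning("negative basal OCR (baseline below rotenone/antimycin floor); ",
            "value reported unclamped")
  out
}

#' Respiratory control ratio (state III / oligomycin state IV)
#'
#' Ratio of the mean OCR after ADP addition (state III) to the mean OCR
#' after oligomycin addition (state IV_o).
#'
#' @param series An [ocrSeries] with `ADP` and `oligomycin` phases.
#' @return Positive ratio.
#' @examples
#' rcr(ocrSeries(list(ADP = c(150, 150, 150),
#'                    oligomycin = c(50, 50, 50))))  # 3
#' @export
rcr <- function(series) {
  stopifnot(inherits(series, "OcrSeries"))
  for (nm in c("ADP", "oligomycin"))
    if (is.null(series$phases[[nm]])) stop("missing phase: ", nm)
  s4 <- mean(series$phases$oligomycin)
  if (s4 <= 0) stop("state IV (oligomycin) OCR is zero; ratio undefined")
  mean(series$phases$ADP) / s4
}

#' 13C labeling ratio as percent of total metabolite
#'
#' `100 * (labeled/total - backgroundFraction)`, computed on peak-area-per-
#' milligram values; background is the labeling ratio measured in tissue
#' exposed to unlabeled nutrients. Negative results are floored at 0 and
#' flagged (attribute `clamped`), since a labeled fraction cannot be
#' negative.
#'
#' @param labeledAreaPerMg,totalAreaPerMg Peak area per mg tissue
#'   (total > 0).
#' @param backgroundFraction Background labeled fraction in `[0, 1]`.
#' @return Percentage with logical attribute `clamped`.
#' @examples
#' labelingRatio(12, 100, 0.02)  # 10
#' @export
labelingRatio <- function(labeledAreaPerMg, totalAreaPerMg,
                          backgroundFraction) {
  if (any(totalAreaPerMg <= 0)) stop("total area must be > 0")
  if (any(backgroundFraction < 0 | backgroundFraction > 1))
    stop("backgroundFraction must lie in [0, 1]")
  pct <- 100 * (labeledAreaPerMg / totalAreaPerMg - backgroundFraction)
  clamped <- pct < 0
  if (any(clamped))
    warning("labeling below background; floored at 0 (QC flag set)")
  structure(pmax(pct, 0), clamped = clamped)
}

#' mtDNA/nDNA ratio from qPCR Ct values
#'
#' Quantities are `eff^(-(ct - ctReference)) / dnaConc` for the
#' mitochondrial locus ND1 and the nuclear locus HK2; the reported ratio
#' ND1/HK2 cancels the reference and DNA concentration (both retained for
#' per-sample reporting).
#'
#' @param ctNd1,ctHk2 Ct values of the mitochondrial and nuclear loci,
#'   in (0, 45).
#' @param ctReference Ct of the internal standard (e.g. Rn45s); cancels in
#'   the ratio. Default 0.
#' @param dnaConc DNA concentration; cancels in the ratio. Default 1.
#' @param efficiency Amplification efficiency per cycle (default 2, perfect
#'   doubling).
#' @return list with `ratio`, `nd1Quantity`, `hk2Quantity`.
#' @examples
#' mtdnaRatio(20, 21)$ratio  # 2: one cycle earlier = twice the copies
#' @export
mtdnaRatio <- function(ctNd1, ctHk2, ctReference = 0, dnaConc = 1,
                       efficiency = 2) {
  for (ct in c(ctNd1, ctHk2))
    if (ct <= 0 || ct >= 45) stop("Ct values must lie in (0, 45)")
  if (dnaConc <= 0) stop("dnaConc must be > 0")
  q <- function(ct) efficiency^(-(ct - ctReference)) / dnaConc
  list(ratio = q(ctNd1) / q(ctHk2),
       nd1Quantity = q(ctNd1), hk2Quantity = q(ctHk2))
}

#' ChIP-qPCR signal as percent of input
#'
#' `100 * eff^((ctInput - inputAdjustmentCycles) - ctIp)`. The adjustment
#' encodes the input dilution/fraction correction in cycles (e.g.
#' `log2(100)` cycles for a 1% input at perfect doubling); the experiment's
#' input fraction determines it, so it is a required parameter.
#'
#' @param ctIp,ctInput Ct of the IP and input reactions, in (0, 45).
#' @param inputAdjustmentCycles Input-fraction correction in cycles.
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Percent of input.
#' @examples
#' percentInput(25, 25, 0)  # 100
#' percentInput(26, 25, 0)  # 50
#' @export
percentInput <- function(ctIp, ctInput, inputAdjustmentCycles,
                         efficiency = 2) {
  for (ct in c(ctIp, ctInput))
    if (ct <= 0 || ct >= 45) stop("Ct values must lie in (0, 45)")
  100 * efficiency^((ctInput - inputAdjustmentCycles) - ctIp)
}

#' Circadian reporter amplitude from a bioluminescence trace
#'
#' Background-subtracts the trace with a centred 24 h running mean, splits
#' it into cycles at ascending zero crossings of the detrended signal, and
#' reports half the max-minus-min height on the requested cycle (third by
#' default, ~3 days after the start of recording).
#'
#' @param time Strictly increasing time in hours; sampling interval must be
#'   <= 1 h.
#' @param counts Luminescence counts, parallel to `time`.
#' @param cycle Which full oscillation to measure (default 3).
#' @param detrendWindow Running-mean window in hours (default 24).
#' @return Amplitude `(max - min) / 2` on the chosen cycle.
#' @export
lumicycleAmplitude <- function(time, counts, cycle = 3L,
                               detrendWindow = 24) {
  stopifnot(length(time) == length(counts))
  if (length(time) < 8L) stop("trace too short")
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing")
  if (max(diff(time)) > 1 + 1e-9)
    stop("sampling interval must be <= 1 h")
  half <- detrendWindow / 2
  # half-open window: on a regular grid it spans exactly one period, so a
  # periodic component averages to zero instead of double-counting endpoints
  trend <- vapply(time, function(t)
    mean(counts[time >= t - half & time < t + half]), 0)
  d <- counts - trend
  n <- length(d)
  asc <- which(d[-n] <= 0 & d[-1L] > 0)
  if (length(asc) < cycle + 1L)
    stop("fewer than ", cycle, " full oscillations detected")
  i1 <- asc[cycle]; i2 <- asc[cycle + 1L]
  seg <- d[i1:i2]
  (max(seg) - min(seg)) / 2
}

# ---- tabular readers for assay inputs ------------------------------------

#' Read a respirometry phase CSV
#'
#' Long format with header `phase,ocr` (three rows per phase), one file per
#' well/sample.
#'
#' @param path CSV path.
#' @param proteinMass Protein mass of the well (micrograms).
#' @return An [ocrSeries].
#' @export
readOcrCsv <- function(path, proteinMass = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("phase", "ocr")))
    stop("OCR CSV must have columns: phase, ocr")
  ocrSeries(split(df$ocr, factor(df$phase, levels = unique(df$phase))),
            proteinMass = proteinMass)
}

#' Read a qPCR Ct table CSV
#'
#' Header `sample,target,ct`; returns the data.frame validated for Ct
#' range.
#'
#' @param path CSV path.
#' @return data.frame with columns `sample`, `target`, `ct`.
#' @export
readCtTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("sample", "target", "ct")))
    stop("Ct CSV must have columns: sample, target, ct")
  if (any(df$ct <= 0 | df$ct >= 45))
    stop("Ct values must lie in (0, 45)")
  df
}

#' Read a lumicycle export CSV
#'
#' Header `time_h,counts`, time in hours.
#'
#' @param path CSV path.
#' @return data.frame with columns `time_h`, `counts`.
#' @export
readLumicycleCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("time_h", "counts")))
    stop("lumicycle CSV must have columns: time_h, counts")
  df
}
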