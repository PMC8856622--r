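# Motif-site occupancy quantification: mean normalized signal over windows
# centred on motif sites, per condition, with drug-vs-vehicle contrasts.
# "Relative signal" is operationalized as library-normalized coverage over
# motif-site windows, optionally divided by input coverage over the same
# windows; the quantification is symmetric in factor and motif, so
# cross-motif profiles (GR on E-box, BMAL1 on GRE) use the same code path
# with swapped inputs.

#' Site x condition occupancy profile over motif-site windows
#'
#' For each motif site, the mean normalized signal over
#' `[center - halfwidth, center + halfwidth)` (site center = floor of the
#' interval midpoint) is computed for every condition track. The
#' per-condition aggregate is a trimmed mean over sites, and drug/vehicle
#' fold changes are formed per genotype with a pseudocount.
#'
#' @param trackSet Named list of [SignalTrack-class] objects; names are
#'   condition labels `"<genotype>.<treatment>"` (e.g. `"WT.vehicle"`).
#' @param sites A [MotifSiteSet-class]; must be nonempty.
#' @param halfwidth Window half-width in bp (default 200).
#' @param inputTrack Optional input [SignalTrack-class]; when supplied,
#'   each site entry is divided by the input coverage over the same window
#'   (input pseudocount `pseudocount` guards empty windows).
#' @param pseudocount Pseudocount in normalized units used for fold changes
#'   (default 0.01).
#' @param trim Trim fraction for the site aggregate (default 0.1).
#' @return An [OccupancyProfile-class].
#' @export
siteSignalMatrix <- function(trackSet, sites, halfwidth = 200L,
                             inputTrack = NULL, pseudocount = 0.01,
                             trim = 0.1) {
  stopifnot(is.list(trackSet), length(trackSet) >= 1L)
  if (is.null(names(trackSet)) || any(!nzchar(names(trackSet))))
    stop("trackSet must be a named list of condition tracks")
  s <- motifSites(sites)
  if (!length(s)) stop("empty motif-site set")
  chrom <- as.character(GenomicRanges::seqnames(s))
  c0 <- as.integer(floor(((GenomicRanges::start(s) - 1L) +
                          GenomicRanges::end(s)) / 2))
  ws <- c0 - halfwidth + 1L   # 1-based window [c0-hw, c0+hw)
  we <- c0 + halfwidth
  mat <- vapply(trackSet, function(tr)
    windowMeans(tr, chrom, ws, we, normalized = TRUE),
    numeric(length(s)))
  mat <- matrix(mat, nrow = length(s),
                dimnames = list(NULL, names(trackSet)))
  if (!is.null(inputTrack)) {
    inp <- windowMeans(inputTrack, chrom, ws, we, normalized = TRUE)
    mat <- mat / (inp + pseudocount)
  }
  agg <- apply(mat, 2L, mean, trim = trim)
  fc <- contrastTable(agg, pseudocount)
  methods::new("OccupancyProfile", motif = motifName(sites),
               halfwidth = as.integer(halfwidth), signal = mat,
               aggregate = agg, foldChanges = fc,
               pseudocount = pseudocount, trim = trim)
}

# drug/vehicle fold per genotype from a named per-condition vector
contrastTable <- function(agg, pseudocount) {
  lab <- strsplit(names(agg), ".", fixed = TRUE)
  gt <- vapply(lab, `[`, "", 1L)
  tr <- vapply(lab, `[`, "", 2L)
  out <- data.frame(genotype = character(), fold = numeric(),
                    stringsAsFactors = FALSE)
  for (g in unique(gt)) {
    v <- which(gt == g & tr == "vehicle")
    d <- which(gt == g & tr == "prednisone")
    if (length(v) == 1L && length(d) == 1L)
      out <- rbind(out, data.frame(
        genotype = g,
        fold = (agg[d] + pseudocount) / (agg[v] + pseudocount)))
  }
  rownames(out) <- NULL
  out
}

#' Treatment contrast of an occupancy profile with bootstrap CIs
#'
#' Per genotype, the drug/vehicle fold change of the trimmed-mean site
#' aggregate, `(aggregate_drug + eps) / (aggregate_vehicle + eps)`, with a
#' 95% percentile bootstrap over sites, plus the per-site log2 fold-change
#' vectors.
#'
#' @param profile An [OccupancyProfile-class] containing both treatments for
#'   at least one genotype.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap (default 1).
#' @return list with `folds` (data.frame: genotype, fold, ci_lo, ci_hi) and
#'   `log2PerSite` (named list of per-site log2 fold-change vectors).
#' @export
occupancyContrast <- function(profile, B = 1000L, seed = 1L) {
  mat <- siteMatrix(profile)
  eps <- profile@pseudocount
  trim <- profile@trim
  lab <- strsplit(colnames(mat), ".", fixed = TRUE)
  gt <- vapply(lab, `[`, "", 1L)
  tr <- vapply(lab, `[`, "", 2L)
  gts <- unique(gt)
  folds <- data.frame(); perSite <- list()
  set.seed(seed)
  for (g in gts) {
    v <- which(gt == g & tr == "vehicle")
    d <- which(gt == g & tr == "prednisone")
    if (length(v) != 1L || length(d) != 1L)
      stop("missing condition for genotype ", g,
           ": need both vehicle and prednisone")
    fold <- (mean(mat[, d], trim = trim) + eps) /
            (mean(mat[, v], trim = trim) + eps)
    n <- nrow(mat)
    bs <- vapply(seq_len(B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      (mean(mat[i, d], trim = trim) + eps) /
        (mean(mat[i, v], trim = trim) + eps)
    }, 0)
    ci <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
    folds <- rbind(folds, data.frame(genotype = g, fold = fold,
                                     ci_lo = ci[1L], ci_hi = ci[2L]))
    perSite[[g]] <- log2((mat[, d] + eps) / (mat[, v] + eps))
  }
  rownames(folds) <- NULL
  list(folds = folds, log2PerSite = perSite)
}

#' Peak counts per condition
#'
#' @param peaksets A list of [PeakSet-class] objects.
#' @return data.frame with columns `factor`, `genotype`, `treatment`, `n`.
#' @export
peakCounts <- function(peaksets) {
  if (!length(peaksets))
    return(data.frame(factor = character(), genotype = character(),
                      treatment = character(), n = integer(),
                      stringsAsFactors = FALSE))
  df <- data.frame(
    factor = vapply(peaksets, peakFactor, ""),
    genotype = vapply(peaksets, genotype, ""),
    treatment = vapply(peaksets, treatment, ""),
    n = vapply(peaksets, length, 0L),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df[order(df$factor, df$genotype, df$treatment), , drop = FALSE]
}
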