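# Interval/signal primitives shared by all downstream stages: windowed means
# over step-function tracks, and nearest-TSS assignment with strand-signed
# distances.

#' Length-weighted mean signal over an interval
#'
#' Positions not covered by a step count as 0. With `normalized = TRUE` the
#' mean is multiplied by the track's signal-per-million factor.
#'
#' @param track A [SignalTrack-class].
#' @param region A `GRanges` of length 1, or a chromosome name when `start`
#'   and `end` are given.
#' @param start,end Optional 1-based closed bounds (used when `region` is a
#'   chromosome name).
#' @param normalized Multiply by `normFactor(track)`? Default `FALSE`.
#' @return Nonnegative scalar.
#' @examples
#' tr <- SignalTrack(GenomicRanges::GRanges("chr1",
#'         IRanges::IRanges(1, 10), score = 2), normFactor = 1)
#' meanSignal(tr, "chr1", start = 1, end = 20)  # half-covered at 2 -> 1
#' @export
meanSignal <- function(track, region, start = NULL, end = NULL,
                       normalized = FALSE) {
  if (is(region, "GRanges")) {
    stopifnot(length(region) == 1L)
    chrom <- as.character(GenomicRanges::seqnames(region))
    start <- GenomicRanges::start(region)
    end <- GenomicRanges::end(region)
  } else chrom <- as.character(region)
  if (end < start) stop("empty interval: end < start")
  windowMeans(track, chrom, start, end, normalized = normalized)
}

# Vectorized windowed means over a step track. chrom/start/end are parallel
# vectors of 1-based closed windows; the denominator is the nominal window
# width, so windows hanging off the covered region correctly average in 0s.
windowMeans <- function(track, chrom, start, end, normalized = TRUE) {
  width0 <- end - start + 1
  if (any(width0 <= 0)) stop("windows must have positive width")
  st <- trackSteps(track)
  out <- numeric(length(chrom))
  if (length(st)) {
    q <- GenomicRanges::GRanges(chrom,
           IRanges::IRanges(start = pmax(start, 1), end = pmax(end, 1)))
    hits <- GenomicRanges::findOverlaps(q, st)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ovw <- pmin(end[qh], GenomicRanges::end(st)[sh]) -
             pmax(start[qh], GenomicRanges::start(st)[sh]) + 1
      contrib <- ovw * S4Vectors::mcols(st)$score[sh]
      sums <- rowsum(contrib, group = qh)
      out[as.integer(rownames(sums))] <- sums[, 1L]
    }
  }
  out <- out / width0
  if (normalized) out <- out * normFactor(track)
  out
}

#' Nearest TSS and strand-signed distance for each peak
#'
#' Distances are measured summit-to-TSS. The assigned gene minimizes the
#' absolute distance among genes on the peak's chromosome; ties are broken by
#' the lexicographically smaller `gene_id`. The signed distance is positive
#' when the summit lies downstream of the TSS in the gene's strand sense.
#' Peaks on chromosomes with no gene get `gene_id = NA` and distance `Inf`.
#'
#' @param x A [PeakSet-class], or an integer vector of 1-based summit
#'   positions (with `chrom` given).
#' @param genes A gene table ([geneTable]); must be nonempty.
#' @param chrom Chromosome names parallel to `x` when `x` is a vector.
#' @return data.frame with columns `gene_id`, `distance` (signed bp),
#'   one row per peak, in peak order.
#' @export
nearestTss <- function(x, genes, chrom = NULL) {
  if (is.null(genes) || nrow(genes) == 0L) stop("gene table is empty")
  if (is(x, "PeakSet")) {
    chrom <- as.character(GenomicRanges::seqnames(peaks(x)))
    summit <- peakSummits(x)
  } else summit <- as.integer(x)
  stopifnot(length(chrom) == length(summit))
  n <- length(summit)
  geneId <- rep(NA_character_, n)
  dist <- rep(Inf, n)
  gs <- genes[order(genes$chrom, genes$tss, genes$gene_id), , drop = FALSE]
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    g <- gs[gs$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    # collapse genes sharing a TSS position to the lexicographically
    # smallest id (the tie-break winner at that position)
    first <- !duplicated(g$tss)
    u <- g$tss[first]
    uid <- g$gene_id[first]
    ustr <- g$strand[first]
    i <- findInterval(summit[sel], u)
    li <- pmax(i, 1L)
    ri <- pmin(i + 1L, length(u))
    dl <- ifelse(i >= 1L, summit[sel] - u[li], Inf)
    dr <- ifelse(i < length(u), u[ri] - summit[sel], Inf)
    useLeft <- dl < dr | (dl == dr & uid[li] <= uid[ri])
    pick <- ifelse(useLeft, li, ri)
    tss <- u[pick]
    geneId[sel] <- uid[pick]
    signed <- ifelse(ustr[pick] == "+", summit[sel] - tss, tss - summit[sel])
    dist[sel] <- signed
  }
  data.frame(gene_id = geneId, distance = dist, stringsAsFactors = FALSE)
}

#' Mean normalized signal over TSS-centred windows
#'
#' For each gene, the length-weighted mean of the (normalized) track signal
#' over the window of `2 * halfwidth` bp centred on the TSS, the operational
#' readout for RNA polymerase II promoter occupancy.
#'
#' @param track A [SignalTrack-class].
#' @param genes A gene table ([geneTable]).
#' @param halfwidth Window half-width in bp (default 500).
#' @param normalized Use the track's normalization factor (default `TRUE`).
#' @return Named numeric vector, one value per gene.
#' @export
tssSignal <- function(track, genes, halfwidth = 500L, normalized = TRUE) {
  if (is.null(genes) || nrow(genes) == 0L) stop("gene table is empty")
  v <- windowMeans(track, genes$chrom,
                   genes$tss - halfwidth, genes$tss + halfwidth - 1L,
                   normalized = normalized)
  stats::setNames(v, genes$gene_id)
}
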