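# The convergent-gene screen: RNA polymerase II TSS signal per condition ->
# drug/vehicle fold change per genotype -> quadrant classification
# (up in WT but not in KO) -> intersection with drug-driven GR and BMAL1
# signal gains within 10 kb of the TSS (evaluated in the WT genotype, where
# BMAL1 is present).

#' Classify genes into treatment-response quadrants
#'
#' `WT-only-up` if `fcWt >= threshold` and `fcKo < threshold`; `shared-up`
#' if both pass; `KO-only-up` if only `fcKo` passes; otherwise `none`.
#'
#' @param fcWt,fcKo Positive fold changes (vectors allowed).
#' @param upThreshold Up-regulation fold threshold (default 1.5).
#' @return character vector of classes.
#' @examples
#' quadrantClassify(2, 1)    # "WT-only-up"
#' quadrantClassify(2, 2)    # "shared-up"
#' quadrantClassify(1, 1)    # "none"
#' @export
quadrantClassify <- function(fcWt, fcKo, upThreshold = 1.5) {
  if (any(fcWt <= 0) || any(fcKo <= 0))
    stop("fold changes must be positive")
  upW <- fcWt >= upThreshold
  upK <- fcKo >= upThreshold
  out <- rep("none", length(fcWt))
  out[upW & !upK] <- "WT-only-up"
  out[upW & upK] <- "shared-up"
  out[!upW & upK] <- "KO-only-up"
  out
}

#' Drug-driven factor signal gain near a TSS
#'
#' Tiles `[tss - span, tss + span)` into non-overlapping windows of `window`
#' bp; the gain is `log2((maxDrugWindow + eps) / (sameWindowVehicle + eps))`
#' evaluated at the window maximizing the drug signal (ties broken by the
#' window nearest the TSS). `mode = "mean"` instead contrasts the mean
#' signal over the whole span.
#'
#' @param trackDrug,trackVehicle [SignalTrack-class] objects.
#' @param gene One row of a gene table, or a gene table (vectorized over
#'   rows).
#' @param span Half-span around the TSS in bp (default 10000).
#' @param window Tile width in bp (default 400; must divide `2 * span`).
#' @param pseudocount Pseudocount in normalized units (default 0.01).
#' @param mode `"max"` (default) or `"mean"`.
#' @return Numeric log2 gain, one per gene row.
#' @export
promoterFactorGain <- function(trackDrug, trackVehicle, gene,
                               span = 10000L, window = 400L,
                               pseudocount = 0.01,
                               mode = c("max", "mean")) {
  mode <- match.arg(mode)
  if (span < window) stop("span must be >= window")
  if ((2L * span) %% window != 0L)
    stop("window must divide the full span 2*span")
  n <- nrow(gene)
  out <- numeric(n)
  if (mode == "mean") {
    md <- windowMeans(trackDrug, gene$chrom, gene$tss - span,
                      gene$tss + span - 1L, normalized = TRUE)
    mv <- windowMeans(trackVehicle, gene$chrom, gene$tss - span,
                      gene$tss + span - 1L, normalized = TRUE)
    return(log2((md + pseudocount) / (mv + pseudocount)))
  }
  k <- (2L * span) %/% window
  off <- (seq_len(k) - 1L) * window - span       # tile starts rel. to tss0
  ws <- rep(gene$tss, each = k) + off            # all tiles, gene-major
  we <- ws + window - 1L
  chrom <- rep(gene$chrom, each = k)
  d <- windowMeans(trackDrug, chrom, ws, we, normalized = TRUE)
  v <- windowMeans(trackVehicle, chrom, ws, we, normalized = TRUE)
  center <- ws + (window - 1L) / 2
  for (i in seq_len(n)) {
    j <- (i - 1L) * k + seq_len(k)
    best <- j[d[j] == max(d[j])]
    if (length(best) > 1L)                       # tie -> nearest the TSS
      best <- best[which.min(abs(center[best] - gene$tss[i]))]
    out[i] <- log2((d[best] + pseudocount) / (v[best] + pseudocount))
  }
  out
}

#' Run the convergent-gene screen
#'
#' Requires the six condition tracks of the screen: RNA polymerase II for
#' both genotypes and treatments (`RNApolII.WT.vehicle`, ...), and GR and
#' BMAL1 in WT for both treatments. Genes are classified by RNApol-II
#' quadrant and intersected with promoter-proximal GR and BMAL1 gains.
#'
#' @param tracks Named list of [SignalTrack-class] objects keyed
#'   `"<factor>.<genotype>.<treatment>"`.
#' @param genes A gene table ([geneTable]).
#' @param upThreshold RNApol-II fold threshold (default 1.5).
#' @param gainThreshold log2 gain threshold for GR/BMAL1 (default
#'   `log2(1.5)`).
#' @param tssHalfwidth RNApol-II TSS window half-width (default 500).
#' @param span,window,gainMode Passed to [promoterFactorGain].
#' @param pseudocount Pseudocount in normalized units (default 0.01).
#' @return list of class `GeneScreenResult` with `genes` (data.frame, one
#'   row per gene sorted by `gene_id`: per-condition polII signal, fold
#'   changes, `quadrant`, `gr_gain`, `bmal1_gain`, `selected`) and
#'   `summary` (class counts and number selected).
#' @export
runScreen <- function(tracks, genes, upThreshold = 1.5,
                      gainThreshold = log2(1.5), tssHalfwidth = 500L,
                      span = 10000L, window = 400L, pseudocount = 0.01,
                      gainMode = "max") {
  need <- c("RNApolII.WT.vehicle", "RNApolII.WT.prednisone",
            "RNApolII.KO.vehicle", "RNApolII.KO.prednisone",
            "GR.WT.vehicle", "GR.WT.prednisone",
            "BMAL1.WT.vehicle", "BMAL1.WT.prednisone")
  missing <- setdiff(need, names(tracks))
  if (length(missing))
    stop("missing condition track(s): ", paste(missing, collapse = ", "))
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  sig <- lapply(need[1:4], function(k)
    tssSignal(tracks[[k]], genes, halfwidth = tssHalfwidth))
  names(sig) <- need[1:4]
  fcWt <- (sig[["RNApolII.WT.prednisone"]] + pseudocount) /
          (sig[["RNApolII.WT.vehicle"]] + pseudocount)
  fcKo <- (sig[["RNApolII.KO.prednisone"]] + pseudocount) /
          (sig[["RNApolII.KO.vehicle"]] + pseudocount)
  quadrant <- quadrantClassify(fcWt, fcKo, upThreshold)
  grGain <- promoterFactorGain(tracks[["GR.WT.prednisone"]],
                               tracks[["GR.WT.vehicle"]], genes,
                               span = span, window = window,
                               pseudocount = pseudocount, mode = gainMode)
  bmGain <- promoterFactorGain(tracks[["BMAL1.WT.prednisone"]],
                               tracks[["BMAL1.WT.vehicle"]], genes,
                               span = span, window = window,
                               pseudocount = pseudocount, mode = gainMode)
  selected <- quadrant == "WT-only-up" & grGain > gainThreshold &
              bmGain > gainThreshold
  df <- data.frame(gene_id = genes$gene_id,
                   polii_wt_vehicle = unname(sig[[1L]]),
                   polii_wt_prednisone = unname(sig[[2L]]),
                   polii_ko_vehicle = unname(sig[[3L]]),
                   polii_ko_prednisone = unname(sig[[4L]]),
                   log2_fc_wt = log2(fcWt), log2_fc_ko = log2(fcKo),
                   quadrant = quadrant, gr_gain = grGain,
                   bmal1_gain = bmGain, selected = selected,
                   stringsAsFactors = FALSE, row.names = NULL)
  summary <- list(
    quadrantCounts = table(factor(quadrant,
      levels = c("WT-only-up", "shared-up", "KO-only-up", "none"))),
    nSelected = sum(selected))
  structure(list(genes = df, summary = summary,
                 thresholds = list(upThreshold = upThreshold,
                                   gainThreshold = gainThreshold)),
            class = "GeneScreenResult")
}

#' @export
print.GeneScreenResult <- function(x, ...) {
  cat(sprintf("GeneScreenResult: %d genes, %d selected\n",
              nrow(x$genes), x$summary$nSelected))
  print(x$summary$quadrantCounts)
  invisible(x)
}

#' Compare a screen result to a planted truth table
#'
#' Sensitivity and specificity of the selected set against the planted
#' `convergent` class.
#'
#' @param screen A `GeneScreenResult`.
#' @param truth A truth table ([assignTruth]).
#' @return list with `sensitivity`, `specificity`, `nTruePos`,
#'   `nFalsePos`.
#' @export
screenRecovery <- function(screen, truth) {
  m <- merge(screen$genes[, c("gene_id", "selected")],
             truth[, c("gene_id", "class")], by = "gene_id")
  pos <- m$class == "convergent"
  list(sensitivity = mean(m$selected[pos]),
       specificity = mean(!m$selected[!pos]),
       nTruePos = sum(m$selected & pos),
       nFalsePos = sum(m$selected & !pos))
}

#' Write the per-gene screen table as TSV
#' @param screen A `GeneScreenResult`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeScreenTable <- function(screen, path) {
  g <- screen$genes
  num <- vapply(g, is.numeric, TRUE)
  out <- g
  out[num] <- lapply(g[num], formatNum)
  lines <- c(paste(names(out), collapse = "\t"),
             do.call(sprintf,
                     c(list(paste(rep("%s", ncol(out)), collapse = "\t")),
                       lapply(out, as.character))))
  writeLinesLF(lines, path)
  invisible(path)
}
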