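# S4 containers for the cistrome pipeline. Coordinates follow the Bioconductor
# convention (1-based, closed intervals, GRanges); BED/bedGraph 0-based
# half-open coordinates are converted at the I/O boundary (see readPeakBed).

FACTOR_LEVELS    <- c("GR", "BMAL1", "RNApolII", "input")
GENOTYPE_LEVELS  <- c("WT", "KO")
TREATMENT_LEVELS <- c("vehicle", "prednisone")

#' PeakSet: condition-labelled ChIP-seq peak calls
#'
#' A set of peak calls for one factor in one genotype x treatment condition.
#' Peaks are stored as a [GenomicRanges::GRanges] with metadata columns
#' `summit` (absolute 1-based summit position, guaranteed to lie inside the
#' peak) and `score` (nonnegative). Peaks are kept sorted by (chrom, start)
#' and duplicate (chrom, start, end) triples are rejected.
#'
#' @slot peaks A `GRanges` with `summit` and `score` metadata columns.
#' @slot factorName One of `"GR"`, `"BMAL1"`, `"RNApolII"`, `"input"`.
#' @slot genotype One of `"WT"`, `"KO"`.
#' @slot treatment One of `"vehicle"`, `"prednisone"`.
#'
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
#'                              summit = 151L, score = 5)
#' PeakSet(gr, factorName = "GR", genotype = "WT", treatment = "vehicle")
#' @export
setClass("PeakSet",
  representation(peaks = "GRanges", factorName = "character",
                 genotype = "character", treatment = "character"))

setValidity("PeakSet", function(object) {
  p <- object@peaks
  msg <- character()
  if (length(object@factorName) != 1L || !object@factorName %in% FACTOR_LEVELS)
    msg <- c(msg, sprintf("factorName must be one of %s",
                          paste(FACTOR_LEVELS, collapse = ", ")))
  if (length(object@genotype) != 1L || !object@genotype %in% GENOTYPE_LEVELS)
    msg <- c(msg, "genotype must be 'WT' or 'KO'")
  if (length(object@treatment) != 1L || !object@treatment %in% TREATMENT_LEVELS)
    msg <- c(msg, "treatment must be 'vehicle' or 'prednisone'")
  if (!all(c("summit", "score") %in% names(S4Vectors::mcols(p))))
    msg <- c(msg, "peaks must carry 'summit' and 'score' metadata columns")
  else {
    s <- S4Vectors::mcols(p)$summit
    if (any(s < GenomicRanges::start(p) | s > GenomicRanges::end(p)))
      msg <- c(msg, "every summit must lie within its peak interval")
    if (any(S4Vectors::mcols(p)$score < 0))
      msg <- c(msg, "peak scores must be nonnegative")
  }
  if (length(p) > 1L) {
    o <- order(as.character(GenomicRanges::seqnames(p)),
               GenomicRanges::start(p), GenomicRanges::end(p))
    if (!identical(o, seq_along(p)))
      msg <- c(msg, "peaks must be sorted by (chrom, start, end)")
    key <- paste(GenomicRanges::seqnames(p), GenomicRanges::start(p),
                 GenomicRanges::end(p))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chrom, start, end) peaks are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param peaks A `GRanges`; if the `summit` column is missing it defaults to
#'   the floor midpoint of the interval, and `score` defaults to 0.
#' @param factorName,genotype,treatment Condition labels.
#' @return A validated [PeakSet-class] object, sorted by coordinate.
#' @export
PeakSet <- function(peaks, factorName, genotype, treatment) {
  if (!is(peaks, "GRanges")) stop("'peaks' must be a GRanges")
  mc <- S4Vectors::mcols(peaks)
  if (is.null(mc$summit))
    mc$summit <- bedMidpoint(GenomicRanges::start(peaks),
                             GenomicRanges::end(peaks))
  if (is.null(mc$score)) mc$score <- rep(0, length(peaks))
  mc$summit <- as.integer(mc$summit)
  S4Vectors::mcols(peaks) <- mc[, c("summit", "score"), drop = FALSE]
  o <- order(as.character(GenomicRanges::seqnames(peaks)),
             GenomicRanges::start(peaks), GenomicRanges::end(peaks))
  peaks <- peaks[o]
  methods::new("PeakSet", peaks = peaks, factorName = factorName,
               genotype = genotype, treatment = treatment)
}

# floor midpoint of a BED interval, returned as a 1-based position:
# BED [start0, end0) has 0-based midpoint floor((start0+end0)/2);
# with 1-based closed [start1, end1], start0 = start1-1, end0 = end1.
bedMidpoint <- function(start1, end1) {
  as.integer(floor(((start1 - 1L) + end1) / 2) + 1L)
}

#' SignalTrack: step-function coverage with a library-normalization factor
#'
#' Per-chromosome, non-overlapping, sorted constant-value steps (a `GRanges`
#' with a numeric `score` column). Positions not covered by any step have
#' value 0. The `normFactor` slot is the signal-per-million scaling applied
#' when queries ask for normalized signal.
#'
#' @slot steps A `GRanges` with a nonnegative `score` metadata column;
#'   steps on a chromosome are disjoint and sorted.
#' @slot normFactor Positive scalar.
#' @export
setClass("SignalTrack",
  representation(steps = "GRanges", normFactor = "numeric"))

setValidity("SignalTrack", function(object) {
  st <- object@steps
  msg <- character()
  if (length(object@normFactor) != 1L || !is.finite(object@normFactor) ||
      object@normFactor <= 0)
    msg <- c(msg, "normFactor must be a positive scalar")
  if (!"score" %in% names(S4Vectors::mcols(st)))
    msg <- c(msg, "steps must carry a 'score' metadata column")
  else if (any(S4Vectors::mcols(st)$score < 0))
    msg <- c(msg, "step values must be nonnegative")
  if (length(st) > 1L) {
    o <- order(as.character(GenomicRanges::seqnames(st)),
               GenomicRanges::start(st))
    if (!identical(o, seq_along(st)))
      msg <- c(msg, "steps must be sorted by (chrom, start)")
    same <- as.character(GenomicRanges::seqnames(st))[-length(st)] ==
            as.character(GenomicRanges::seqnames(st))[-1L]
    ov <- same & GenomicRanges::end(st)[-length(st)] >=
                 GenomicRanges::start(st)[-1L]
    if (any(ov)) msg <- c(msg, "steps within a chromosome must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SignalTrack
#'
#' @param steps `GRanges` with a `score` column (constant value per step).
#' @param normFactor Signal-per-million factor. Default `NULL` computes
#'   `1e6 / totalMass` where `totalMass = sum(score * width)`; an empty or
#'   zero-mass track gets factor 1.
#' @return A validated [SignalTrack-class].
#' @export
SignalTrack <- function(steps, normFactor = NULL) {
  if (!is(steps, "GRanges")) stop("'steps' must be a GRanges")
  o <- order(as.character(GenomicRanges::seqnames(steps)),
             GenomicRanges::start(steps))
  steps <- steps[o]
  if (is.null(normFactor)) {
    mass <- sum(as.numeric(S4Vectors::mcols(steps)$score) *
                GenomicRanges::width(steps))
    normFactor <- if (mass > 0) 1e6 / mass else 1
  }
  methods::new("SignalTrack", steps = steps, normFactor = normFactor)
}

#' MotifSiteSet: genome-wide motif-site intervals
#'
#' Sorted intervals for one motif class (e.g. the glucocorticoid-responsive
#' element GRE, or the E-box bound by CLOCK/BMAL1).
#'
#' @slot motif Nonempty motif name.
#' @slot sites Sorted `GRanges` of site intervals.
#' @export
setClass("MotifSiteSet",
  representation(motif = "character", sites = "GRanges"))

setValidity("MotifSiteSet", function(object) {
  msg <- character()
  if (length(object@motif) != 1L || !nzchar(object@motif))
    msg <- c(msg, "motif name must be a nonempty string")
  s <- object@sites
  if (length(s) > 1L) {
    o <- order(as.character(GenomicRanges::seqnames(s)),
               GenomicRanges::start(s))
    if (!identical(o, seq_along(s)))
      msg <- c(msg, "sites must be sorted by (chrom, start)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MotifSiteSet
#' @param motif Motif name (e.g. `"GRE"`, `"E-box"`).
#' @param sites `GRanges` of site intervals (sorted on construction).
#' @export
MotifSiteSet <- function(motif, sites) {
  if (!is(sites, "GRanges")) stop("'sites' must be a GRanges")
  o <- order(as.character(GenomicRanges::seqnames(sites)),
             GenomicRanges::start(sites))
  methods::new("MotifSiteSet", motif = motif, sites = sites[o])
}

#' OccupancyProfile: motif-site occupancy across conditions
#'
#' The site x condition matrix of mean normalized signal over windows
#' centred on motif sites, the per-condition trimmed-mean aggregate, and the
#' drug-vs-vehicle fold-change table per genotype.
#'
#' @slot motif Motif name.
#' @slot halfwidth Window half-width in bp.
#' @slot signal Numeric matrix, sites x conditions.
#' @slot aggregate Named numeric vector of per-condition trimmed means.
#' @slot foldChanges data.frame with columns `genotype`, `fold`.
#' @slot pseudocount Pseudocount used for fold changes.
#' @slot trim Trim fraction used for the aggregate.
#' @export
setClass("OccupancyProfile",
  representation(motif = "character", halfwidth = "integer",
                 signal = "matrix", aggregate = "numeric",
                 foldChanges = "data.frame", pseudocount = "numeric",
                 trim = "numeric"))

setValidity("OccupancyProfile", function(object) {
  msg <- character()
  if (any(object@signal < 0)) msg <- c(msg, "signal entries must be >= 0")
  agg <- apply(object@signal, 2L, mean, trim = object@trim)
  if (!isTRUE(all.equal(unname(agg), unname(object@aggregate),
                        tolerance = 1e-8)))
    msg <- c(msg, "aggregate must be reproducible from the signal matrix")
  if (length(msg)) msg else TRUE
})
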