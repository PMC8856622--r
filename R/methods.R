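# Accessors and show methods.

#' @describeIn PeakSet-class the underlying `GRanges` of peaks
#' @param x,object A `PeakSet`, `SignalTrack`, `MotifSiteSet` or
#'   `OccupancyProfile`.
#' @param ... Unused.
#' @export
setMethod("peaks", "PeakSet", function(x, ...) x@peaks)

#' @describeIn PeakSet-class the ChIP'd factor label
#' @export
setMethod("peakFactor", "PeakSet", function(x) x@factorName)

#' @describeIn PeakSet-class the genotype label
#' @export
setMethod("genotype", "PeakSet", function(x) x@genotype)

#' @describeIn PeakSet-class the treatment label
#' @export
setMethod("treatment", "PeakSet", function(x) x@treatment)

#' @describeIn PeakSet-class integer vector of 1-based summit positions
#' @export
setMethod("peakSummits", "PeakSet", function(x)
  S4Vectors::mcols(x@peaks)$summit)

#' @describeIn PeakSet-class "factor.genotype.treatment" label
#' @export
setMethod("conditionLabel", "PeakSet", function(x)
  paste(x@factorName, x@genotype, x@treatment, sep = "."))

#' @describeIn PeakSet-class number of peaks
#' @export
setMethod("length", "PeakSet", function(x) length(x@peaks))

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %s | %s | %s\n  %d peaks on %d chromosome(s)\n",
              object@factorName, object@genotype, object@treatment,
              length(object@peaks),
              length(unique(as.character(
                GenomicRanges::seqnames(object@peaks))))))
})

#' @describeIn SignalTrack-class the step `GRanges`
#' @export
setMethod("trackSteps", "SignalTrack", function(x) x@steps)

#' @describeIn SignalTrack-class the signal-per-million factor
#' @export
setMethod("normFactor", "SignalTrack", function(x) x@normFactor)

#' @describeIn SignalTrack-class replace the normalization factor
#' @param value Positive scalar.
#' @export
setMethod("normFactor<-", "SignalTrack", function(x, value) {
  x@normFactor <- value
  methods::validObject(x)
  x
})

setMethod("show", "SignalTrack", function(object) {
  mass <- sum(as.numeric(S4Vectors::mcols(object@steps)$score) *
              GenomicRanges::width(object@steps))
  cat(sprintf(
    "SignalTrack: %d steps, total mass %.4g, normFactor %.4g\n",
    length(object@steps), mass, object@normFactor))
})

#' @describeIn MotifSiteSet-class the motif name
#' @export
setMethod("motifName", "MotifSiteSet", function(x) x@motif)

#' @describeIn MotifSiteSet-class the site `GRanges`
#' @export
setMethod("motifSites", "MotifSiteSet", function(x) x@sites)

#' @describeIn MotifSiteSet-class number of sites
#' @export
setMethod("length", "MotifSiteSet", function(x) length(x@sites))

setMethod("show", "MotifSiteSet", function(object) {
  cat(sprintf("MotifSiteSet: %s, %d sites\n", object@motif,
              length(object@sites)))
})

#' @describeIn OccupancyProfile-class site x condition signal matrix
#' @export
setMethod("siteMatrix", "OccupancyProfile", function(x) x@signal)

#' @describeIn OccupancyProfile-class per-condition trimmed-mean aggregate
#' @export
setMethod("occupancyAggregate", "OccupancyProfile", function(x) x@aggregate)

#' @describeIn OccupancyProfile-class drug/vehicle fold-change table
#' @export
setMethod("foldChanges", "OccupancyProfile", function(x) x@foldChanges)

#' @describeIn OccupancyProfile-class motif name
#' @export
setMethod("motifName", "OccupancyProfile", function(x) x@motif)

setMethod("show", "OccupancyProfile", function(object) {
  cat(sprintf("OccupancyProfile: %s, %d sites x %d conditions (halfwidth %d bp)\n",
              object@motif, nrow(object@signal), ncol(object@signal),
              object@halfwidth))
  agg <- object@aggregate
  cat("  aggregate:", paste(sprintf("%s=%.4g", names(agg), agg),
                            collapse = ", "), "\n")
  if (nrow(object@foldChanges))
    cat("  drug/vehicle fold:",
        paste(sprintf("%s=%.4g", object@foldChanges$genotype,
                      object@foldChanges$fold), collapse = ", "), "\n")
})
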