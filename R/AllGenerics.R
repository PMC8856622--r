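#' @include AllClasses.R
NULL

#' @export
setGeneric("peaks", function(x, ...) standardGeneric("peaks"))

#' @export
setGeneric("peakFactor", function(x) standardGeneric("peakFactor"))

#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))

#' @export
setGeneric("treatment", function(x) standardGeneric("treatment"))

#' @export
setGeneric("peakSummits", function(x) standardGeneric("peakSummits"))

#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @export
setGeneric("trackSteps", function(x) standardGeneric("trackSteps"))

#' @export
setGeneric("normFactor", function(x) standardGeneric("normFactor"))

#' @export
setGeneric("normFactor<-", function(x, value) standardGeneric("normFactor<-"))

#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))

#' @export
setGeneric("motifSites", function(x) standardGeneric("motifSites"))

#' @export
setGeneric("siteMatrix", function(x) standardGeneric("siteMatrix"))

#' @export
setGeneric("occupancyAggregate", function(x) standardGeneric("occupancyAggregate"))

#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))
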