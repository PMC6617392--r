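## Accessor generics. Slot access from user code is discouraged; these are the
## supported surface.

#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))
#' @export
setGeneric("genomeDoubled", function(x) standardGeneric("genomeDoubled"))
#' @export
setGeneric("ccf", function(x) standardGeneric("ccf"))
#' @export
setGeneric("ccfCapped", function(x) standardGeneric("ccfCapped"))
#' @export
setGeneric("clonalStatus", function(x) standardGeneric("clonalStatus"))
#' @export
setGeneric("purity", function(x) standardGeneric("purity"))
#' @export
setGeneric("gap", function(x) standardGeneric("gap"))
#' @export
setGeneric("driverFractions", function(x) standardGeneric("driverFractions"))
#' @export
setGeneric("totalDriverFraction",
  function(x) standardGeneric("totalDriverFraction"))
#' @export
setGeneric("subtypeLabel", function(x) standardGeneric("subtypeLabel"))
#' @export
setGeneric("subtypeScores", function(x) standardGeneric("subtypeScores"))
#' @export
setGeneric("callConfidence", function(x) standardGeneric("callConfidence"))
#' @export
setGeneric("callMethod", function(x) standardGeneric("callMethod"))
#' @export
setGeneric("qvalue", function(x) standardGeneric("qvalue"))
#' @export
setGeneric("clones", function(x) standardGeneric("clones"))
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' Accessors for clonalgap result objects
#'
#' Small accessor family over the S4 result classes:
#' \itemize{
#'   \item \code{ploidy}, \code{genomeDoubled} on [PloidyEstimate-class]
#'   \item \code{ccf}, \code{ccfCapped}, \code{clonalStatus} on
#'     [CcfEstimate-class]
#'   \item \code{purity} on [CtdnaPurity-class] (the fraction of ctDNA of
#'     cancer-cell origin) and on [ClonalArchitecture-class] (the simulated
#'     sample purity)
#'   \item \code{gap}, \code{driverFractions}, \code{totalDriverFraction} on
#'     [ResistanceGapResult-class]
#'   \item \code{subtypeLabel}, \code{subtypeScores}, \code{callConfidence},
#'     \code{callMethod}, \code{qvalue} on [SubtypeCall-class]
#'   \item \code{clones}, \code{mutations}, \code{segments} on
#'     [ClonalArchitecture-class]
#' }
#'
#' @param x the object to extract from.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases ploidy genomeDoubled ccf ccfCapped clonalStatus purity gap
#'   driverFractions totalDriverFraction subtypeLabel subtypeScores
#'   callConfidence callMethod qvalue clones mutations segments
NULL

setMethod("ploidy", "PloidyEstimate", function(x) x@ploidy)
setMethod("genomeDoubled", "PloidyEstimate", function(x) x@genomeDoubled)

setMethod("ccf", "CcfEstimate", function(x) x@ccf)
setMethod("ccfCapped", "CcfEstimate", function(x) x@capped)
setMethod("clonalStatus", "CcfEstimate", function(x) x@status)

setMethod("purity", "CtdnaPurity", function(x) x@ccfSample)
setMethod("purity", "ClonalArchitecture", function(x) x@purity)

setMethod("gap", "ResistanceGapResult", function(x) x@gap)
setMethod("driverFractions", "ResistanceGapResult",
  function(x) x@driverFractions)
setMethod("totalDriverFraction", "ResistanceGapResult",
  function(x) x@totalDriverFraction)

setMethod("subtypeLabel", "SubtypeCall", function(x) x@label)
setMethod("subtypeScores", "SubtypeCall", function(x) x@scores)
setMethod("callConfidence", "SubtypeCall", function(x) x@confidence)
setMethod("callMethod", "SubtypeCall", function(x) x@method)
setMethod("qvalue", "SubtypeCall", function(x) x@qvalue)

setMethod("clones", "ClonalArchitecture", function(x) x@clones)
setMethod("mutations", "ClonalArchitecture", function(x) x@mutations)
setMethod("segments", "ClonalArchitecture", function(x) x@segments)
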