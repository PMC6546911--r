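## Accessor generics. Slots are never reached into from user code.

#' @describeIn KineticScheme-class state labels in scheme order
#' @param object a clampFRET S4 object
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))
#' @export
setMethod("stateLabels", "KineticScheme", function(object) object@stateLabels)

#' @describeIn KineticScheme-class named per-state FRET means (NA = dark)
#' @export
setGeneric("fretMeans", function(object) standardGeneric("fretMeans"))
#' @export
setMethod("fretMeans", "KineticScheme", function(object) object@fretMean)

#' @describeIn KineticScheme-class transition-rate matrix (1/s)
#' @export
setGeneric("rateMatrix", function(object) standardGeneric("rateMatrix"))
#' @export
setMethod("rateMatrix", "KineticScheme", function(object) object@rates)

#' @describeIn KineticScheme-class per-state sub-step counts
#' @export
setGeneric("subSteps", function(object) standardGeneric("subSteps"))
#' @export
setMethod("subSteps", "KineticScheme", function(object) object@substeps)

#' @describeIn StatePath-class events table (entry_time_s, state)
#' @export
setGeneric("pathEvents", function(object) standardGeneric("pathEvents"))
#' @export
setMethod("pathEvents", "StatePath", function(object) object@events)

#' @describeIn StatePath-class total simulated duration (s)
#' @export
setGeneric("pathDuration", function(object) standardGeneric("pathDuration"))
#' @export
setMethod("pathDuration", "StatePath", function(object) object@totalDuration)

#' @describeIn Trace-class trace identifier
#' @export
setGeneric("traceId", function(object) standardGeneric("traceId"))
#' @export
setMethod("traceId", "Trace", function(object) object@traceId)
#' @export
setMethod("traceId", "FretTrace", function(object) object@traceId)
#' @export
setMethod("traceId", "DecodedPath", function(object) object@traceId)

#' @describeIn Trace-class frame times (s)
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))
#' @export
setMethod("traceTime", "Trace", function(object) object@time)
#' @export
setMethod("traceTime", "FretTrace", function(object) object@time)

#' @describeIn Trace-class donor channel intensities
#' @export
setGeneric("donorSignal", function(object) standardGeneric("donorSignal"))
#' @export
setMethod("donorSignal", "Trace", function(object) object@donor)

#' @describeIn Trace-class acceptor channel intensities
#' @export
setGeneric("acceptorSignal",
           function(object) standardGeneric("acceptorSignal"))
#' @export
setMethod("acceptorSignal", "Trace", function(object) object@acceptor)

#' @describeIn Trace-class metadata list (simulation ground truth)
#' @export
setGeneric("traceMetadata", function(object) standardGeneric("traceMetadata"))
#' @export
setMethod("traceMetadata", "Trace", function(object) object@metadata)

#' @describeIn FretTrace-class per-frame apparent FRET efficiency
#' @export
setGeneric("fretEfficiency",
           function(object) standardGeneric("fretEfficiency"))
#' @export
setMethod("fretEfficiency", "FretTrace", function(object) object@efficiency)

#' @describeIn FretTrace-class background-corrected total intensity
#' @export
setGeneric("totalIntensity",
           function(object) standardGeneric("totalIntensity"))
#' @export
setMethod("totalIntensity", "FretTrace", function(object)
  object@totalIntensity)

#' @describeIn FretTrace-class first/last analyzable frame (1-based)
#' @export
setGeneric("validWindow", function(object) standardGeneric("validWindow"))
#' @export
setMethod("validWindow", "FretTrace", function(object) object@validWindow)

#' @describeIn FretTrace-class annotation list
#' @export
setGeneric("traceAnnotations",
           function(object) standardGeneric("traceAnnotations"))
#' @export
setMethod("traceAnnotations", "FretTrace", function(object)
  object@annotations)

#' @describeIn HMMModel-class emission means, sorted ascending
#' @export
setGeneric("emissionMeans", function(object) standardGeneric("emissionMeans"))
#' @export
setMethod("emissionMeans", "HMMModel", function(object) object@means)

#' @describeIn HMMModel-class emission standard deviations
#' @export
setGeneric("emissionSds", function(object) standardGeneric("emissionSds"))
#' @export
setMethod("emissionSds", "HMMModel", function(object) object@sds)

#' @describeIn HMMModel-class per-frame transition probability matrix
#' @export
setGeneric("transitionMatrix",
           function(object) standardGeneric("transitionMatrix"))
#' @export
setMethod("transitionMatrix", "HMMModel", function(object) object@transMat)

#' @describeIn HMMModel-class number of states
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @export
setMethod("nStates", "HMMModel", function(object) object@K)

#' @describeIn HMMModel-class did EM converge before max_iter
#' @export
setGeneric("hasConverged", function(object) standardGeneric("hasConverged"))
#' @export
setMethod("hasConverged", "HMMModel", function(object) object@converged)

#' @describeIn HMMModel-class per-iteration log-likelihood trail
#' @export
setGeneric("logLikTrail", function(object) standardGeneric("logLikTrail"))
#' @export
setMethod("logLikTrail", "HMMModel", function(object) object@logLikTrail)

#' @describeIn DecodedPath-class Viterbi state per frame
#' @export
setGeneric("decodedStates", function(object) standardGeneric("decodedStates"))
#' @export
setMethod("decodedStates", "DecodedPath", function(object) object@states)

#' @describeIn DecodedPath-class posterior state probabilities (frames x K)
#' @export
setGeneric("posteriorProbs",
           function(object) standardGeneric("posteriorProbs"))
#' @export
setMethod("posteriorProbs", "DecodedPath", function(object) object@posterior)

#' @describeIn SyncHeatMap-class column-normalized density matrix
#' @export
setGeneric("heatmapDensity",
           function(object) standardGeneric("heatmapDensity"))
#' @export
setMethod("heatmapDensity", "SyncHeatMap", function(object) object@density)

#' @describeIn TDPHistogram-class transition count matrix
#' @export
setGeneric("tdpCounts", function(object) standardGeneric("tdpCounts"))
#' @export
setMethod("tdpCounts", "TDPHistogram", function(object) object@counts)

#' @describeIn TDPHistogram-class ranked off-diagonal peaks
#' @export
setGeneric("tdpPeaks", function(object) standardGeneric("tdpPeaks"))
#' @export
setMethod("tdpPeaks", "TDPHistogram", function(object) object@peaks)
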