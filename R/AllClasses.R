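#' @import methods
#' @importFrom stats rexp rbinom rpois rnorm runif median mad sd var
#'   dgamma pgamma dexp qnorm pchisq ks.test chisq.test binom.test
#'   complete.cases nls coef logLik optim setNames quantile
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib clampFRET, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.NO_SIGNAL <- NA_real_

#' KineticScheme: a labeled continuous-time Markov scheme for clamp cycling
#'
#' Holds the generative model of the clamp on DNA: ordered state labels,
#' per-state mean FRET efficiency (NA for dark states that emit no FRET,
#' i.e. unbound/released), a square matrix of first-order transition rates
#' (per second, off-diagonal), a per-state count of hidden irreversible
#' sub-steps (Erlang dwell structure), the initial state, and the set of
#' absorbing states.
#'
#' @slot stateLabels character vector of state names, in scheme order.
#' @slot fretMean named numeric; mean FRET efficiency in [0,1] per
#'   FRET-emitting state, NA for dark states.
#' @slot rates square numeric matrix of transition rates (1/s); the diagonal
#'   is unused and kept at 0.
#' @slot substeps named integer >= 1; number of sequential sub-steps making
#'   up the dwell in each state (1 = exponential dwell).
#' @slot initialState character(1), one of stateLabels.
#' @slot absorbing character; states with zero total exit rate.
#' @slot name character(1); scenario name or "" for hand-built schemes.
#' @export
setClass("KineticScheme", representation(
  stateLabels = "character",
  fretMean = "numeric",
  rates = "matrix",
  substeps = "integer",
  initialState = "character",
  absorbing = "character",
  name = "character"
))

setValidity("KineticScheme", function(object) {
  msgs <- character()
  n <- length(object@stateLabels)
  if (n < 1L) msgs <- c(msgs, "at least one state is required")
  if (anyDuplicated(object@stateLabels))
    msgs <- c(msgs, "state labels must be unique")
  if (!identical(dim(object@rates), c(n, n)))
    msgs <- c(msgs, "rates must be a square matrix matching stateLabels")
  off <- object@rates; diag(off) <- 0
  if (any(!is.finite(off)) || any(off < 0))
    msgs <- c(msgs, "off-diagonal rates must be finite and >= 0")
  if (!identical(names(object@fretMean), object@stateLabels))
    msgs <- c(msgs, "fretMean must be named by stateLabels")
  fm <- object@fretMean[!is.na(object@fretMean)]
  if (any(fm < 0 | fm > 1))
    msgs <- c(msgs, "fretMean values must lie in [0,1]")
  if (!identical(names(object@substeps), object@stateLabels))
    msgs <- c(msgs, "substeps must be named by stateLabels")
  if (any(object@substeps < 1L))
    msgs <- c(msgs, "substeps must be >= 1 for every state")
  if (!(object@initialState %in% object@stateLabels))
    msgs <- c(msgs, "initialState must be one of stateLabels")
  if (length(object@absorbing) &&
      !all(object@absorbing %in% object@stateLabels))
    msgs <- c(msgs, "absorbing states must be among stateLabels")
  exit <- rowSums(off)
  names(exit) <- object@stateLabels
  if (length(object@absorbing) && any(exit[object@absorbing] > 0))
    msgs <- c(msgs, "absorbing states must have zero total exit rate")
  if (length(msgs)) msgs else TRUE
})

#' StatePath: one realization of a kinetic scheme
#'
#' @slot events data.frame with columns entry_time_s (numeric, strictly
#'   increasing from 0) and state (character).
#' @slot totalDuration numeric(1), seconds.
#' @slot seed integer(1) used for the draw.
#' @export
setClass("StatePath", representation(
  events = "data.frame",
  totalDuration = "numeric",
  seed = "integer"
))

setValidity("StatePath", function(object) {
  ev <- object@events
  msgs <- character()
  if (!all(c("entry_time_s", "state") %in% names(ev)))
    msgs <- c(msgs, "events needs columns entry_time_s, state")
  else {
    if (nrow(ev) < 1L || ev$entry_time_s[1] != 0)
      msgs <- c(msgs, "first event must enter at time 0")
    if (nrow(ev) > 1L && any(diff(ev$entry_time_s) <= 0))
      msgs <- c(msgs, "entry times must be strictly increasing")
    if (nrow(ev) && any(ev$entry_time_s > object@totalDuration))
      msgs <- c(msgs, "entry times must not exceed totalDuration")
  }
  if (object@totalDuration <= 0)
    msgs <- c(msgs, "totalDuration must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' PhotophysicsModel: rendering parameters for donor/acceptor traces
#'
#' Parameters of the forward model turning a state path into fluorescence:
#' multi-donor labeling of the homotrimeric clamp (two dye sites per
#' monomer), per-donor brightness and independent photobleaching, channel
#' backgrounds, shot (Poisson) plus read (Gaussian) noise, and the frame
#' clock.
#'
#' @slot sitesPerMonomer integer, dye sites per clamp monomer.
#' @slot monomers integer, monomers per clamp (3 for PCNA).
#' @slot labelProb probability a site carries a donor dye.
#' @slot donorBrightness photons/frame per active donor at FRET 0.
#' @slot donorBleachRate 1/s per donor.
#' @slot backgroundDonor,backgroundAcceptor photons/frame.
#' @slot readNoiseSd photons (Gaussian read noise sd).
#' @slot frameInterval seconds per frame.
#' @slot gamma detection-correction factor (acceptor/donor sensitivity).
#' @slot poissonNoise logical; disable for exact noiseless algebra.
#' @slot fixedDonors integer; NA to draw Binomial(sites, labelProb),
#'   otherwise the exact donor count rendered for every trace.
#' @export
setClass("PhotophysicsModel", representation(
  sitesPerMonomer = "integer",
  monomers = "integer",
  labelProb = "numeric",
  donorBrightness = "numeric",
  donorBleachRate = "numeric",
  backgroundDonor = "numeric",
  backgroundAcceptor = "numeric",
  readNoiseSd = "numeric",
  frameInterval = "numeric",
  gamma = "numeric",
  poissonNoise = "logical",
  fixedDonors = "integer"
))

setValidity("PhotophysicsModel", function(object) {
  msgs <- character()
  if (object@labelProb < 0 || object@labelProb > 1)
    msgs <- c(msgs, "labelProb must lie in [0,1]")
  nonneg <- c(
    donorBrightness = object@donorBrightness,
    donorBleachRate = object@donorBleachRate,
    backgroundDonor = object@backgroundDonor,
    backgroundAcceptor = object@backgroundAcceptor,
    readNoiseSd = object@readNoiseSd,
    gamma = object@gamma
  )
  bad <- names(nonneg)[!is.finite(nonneg) | nonneg < 0]
  if (length(bad))
    msgs <- c(msgs, paste0(paste(bad, collapse = ", "),
                           " must be finite and >= 0"))
  if (object@frameInterval <= 0)
    msgs <- c(msgs, "frameInterval must be > 0")
  if (object@sitesPerMonomer < 1L || object@monomers < 1L)
    msgs <- c(msgs, "sitesPerMonomer and monomers must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Trace: per-frame donor and acceptor intensities for one molecule
#'
#' @slot traceId character(1).
#' @slot time numeric, uniform frame times in seconds.
#' @slot donor,acceptor numeric, per-frame intensities (photons).
#' @slot metadata list; for simulated traces carries ground truth
#'   (scheme name, seed, true donor count, true association/dissociation
#'   frames, true bleach times, the state path).
#' @export
setClass("Trace", representation(
  traceId = "character",
  time = "numeric",
  donor = "numeric",
  acceptor = "numeric",
  metadata = "list"
))

setValidity("Trace", function(object) {
  msgs <- character()
  n <- length(object@time)
  if (length(object@donor) != n || length(object@acceptor) != n)
    msgs <- c(msgs, "donor, acceptor and time must have equal length")
  if (n > 1L && any(diff(object@time) <= 0))
    msgs <- c(msgs, "time must be strictly increasing")
  if (any(!is.finite(object@donor)) || any(!is.finite(object@acceptor)))
    msgs <- c(msgs, "intensities must be finite")
  if (length(msgs)) msgs else TRUE
})

#' FretTrace: derived per-frame FRET efficiency with a valid window
#'
#' Apparent FRET efficiency and total (donor+acceptor, background-corrected)
#' intensity per frame. E is only meaningful inside the valid window
#' (association to first donor bleach or dissociation); outside it frames
#' are no-signal.
#'
#' @slot traceId character(1).
#' @slot time numeric, seconds.
#' @slot efficiency numeric, apparent FRET per frame (NA where no signal).
#' @slot totalIntensity numeric, background-corrected donor+acceptor.
#' @slot validWindow integer(2), first/last analyzable frame (1-based
#'   indices into the trace; c(NA,NA) when no analyzable window exists).
#' @slot annotations list: associationFrame, dissociationFrame, stepCount,
#'   stepTimes, singleStepDissociation, as available.
#' @export
setClass("FretTrace", representation(
  traceId = "character",
  time = "numeric",
  efficiency = "numeric",
  totalIntensity = "numeric",
  validWindow = "integer",
  annotations = "list"
))

setValidity("FretTrace", function(object) {
  msgs <- character()
  n <- length(object@time)
  if (length(object@efficiency) != n || length(object@totalIntensity) != n)
    msgs <- c(msgs, "efficiency and totalIntensity must match time length")
  vw <- object@validWindow
  if (length(vw) != 2L)
    msgs <- c(msgs, "validWindow must have length 2")
  else if (!all(is.na(vw))) {
    if (any(is.na(vw)) || vw[1] < 1L || vw[2] > n || vw[1] > vw[2])
      msgs <- c(msgs, "validWindow must lie within trace bounds")
    out <- object@efficiency[-seq.int(vw[1], vw[2])]
    if (length(out) && any(!is.na(out)))
      msgs <- c(msgs, "efficiency must be NA outside the valid window")
  }
  if (length(msgs)) msgs else TRUE
})

#' HMMModel: Gaussian-emission hidden Markov model shared across traces
#'
#' @slot K integer, number of states.
#' @slot means,sds numeric(K), emission means (FRET units) and sds,
#'   reported sorted by mean.
#' @slot transMat K x K row-stochastic transition probability matrix
#'   (per frame).
#' @slot initProb numeric(K), initial distribution.
#' @slot logLikTrail numeric, per-iteration log-likelihood of the winning
#'   restart (non-decreasing up to tolerance).
#' @slot converged logical(1).
#' @slot nObs integer, total frames fit.
#' @export
setClass("HMMModel", representation(
  K = "integer",
  means = "numeric",
  sds = "numeric",
  transMat = "matrix",
  initProb = "numeric",
  logLikTrail = "numeric",
  converged = "logical",
  nObs = "integer"
))

setValidity("HMMModel", function(object) {
  msgs <- character()
  K <- object@K
  if (length(object@means) != K || length(object@sds) != K)
    msgs <- c(msgs, "means and sds must have length K")
  if (any(object@sds <= 0)) msgs <- c(msgs, "sds must be > 0")
  if (!identical(dim(object@transMat), c(K, K)))
    msgs <- c(msgs, "transMat must be K x K")
  else if (any(abs(rowSums(object@transMat) - 1) > 1e-9))
    msgs <- c(msgs, "transition rows must sum to 1")
  if (length(object@initProb) != K ||
      abs(sum(object@initProb) - 1) > 1e-9)
    msgs <- c(msgs, "initProb must be a length-K distribution")
  ll <- object@logLikTrail
  if (length(ll) > 1L && any(diff(ll) < -1e-6 * pmax(1, abs(ll[-1]))))
    msgs <- c(msgs, "log-likelihood trail must be non-decreasing")
  if (length(msgs)) msgs else TRUE
})

#' DecodedPath: per-frame state assignment for one trace
#'
#' @slot traceId character(1).
#' @slot states integer, Viterbi state per frame (1..K, sorted-by-mean
#'   labels of the model).
#' @slot posterior matrix, frames x K posterior state probabilities.
#' @export
setClass("DecodedPath", representation(
  traceId = "character",
  states = "integer",
  posterior = "matrix"
))

setValidity("DecodedPath", function(object) {
  msgs <- character()
  if (nrow(object@posterior) != length(object@states))
    msgs <- c(msgs, "posterior rows must match states length")
  rs <- rowSums(object@posterior)
  if (length(object@states) && any(abs(rs - 1) > 1e-9, na.rm = TRUE))
    msgs <- c(msgs, "posterior rows must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' SyncHeatMap: synchronized FRET population density
#'
#' 2-D histogram of (time relative to anchor, FRET) over aligned frames,
#' normalized per time column.
#'
#' @slot density matrix, FRET bins x time bins; every column with at least
#'   one observation sums to 1.
#' @slot timeBreaks,fretBreaks numeric bin edges.
#' @slot nTraces integer, traces contributing.
#' @slot anchor "association" or "dissociation".
#' @export
setClass("SyncHeatMap", representation(
  density = "matrix",
  timeBreaks = "numeric",
  fretBreaks = "numeric",
  nTraces = "integer",
  anchor = "character"
))

setValidity("SyncHeatMap", function(object) {
  msgs <- character()
  cs <- colSums(object@density)
  if (any(cs > 0 & abs(cs - 1) > 1e-9))
    msgs <- c(msgs, "non-empty columns must sum to 1")
  if (nrow(object@density) != length(object@fretBreaks) - 1L ||
      ncol(object@density) != length(object@timeBreaks) - 1L)
    msgs <- c(msgs, "density dimensions must match bin edges")
  if (!object@anchor %in% c("association", "dissociation"))
    msgs <- c(msgs, "anchor must be association or dissociation")
  if (length(msgs)) msgs else TRUE
})

#' TDPHistogram: transition density plot counts
#'
#' 2-D counts over (FRET before, FRET after) for decoded state changes
#' inside an analysis window; the diagonal is structurally empty.
#'
#' @slot counts matrix over (E_before, E_after) bins.
#' @slot breaks numeric, shared bin edges for both axes.
#' @slot windowSeconds numeric(1); window length.
#' @slot side "first" or "last" (relative to association/dissociation).
#' @slot nTransitions integer, total transitions binned.
#' @slot peaks data.frame of off-diagonal peaks ranked by count, with
#'   columns e_before, e_after, count.
#' @export
setClass("TDPHistogram", representation(
  counts = "matrix",
  breaks = "numeric",
  windowSeconds = "numeric",
  side = "character",
  nTransitions = "integer",
  peaks = "data.frame"
))

setValidity("TDPHistogram", function(object) {
  msgs <- character()
  if (sum(object@counts) != object@nTransitions)
    msgs <- c(msgs, "counts must sum to nTransitions")
  if (!object@side %in% c("first", "last"))
    msgs <- c(msgs, "side must be first or last")
  if (length(msgs)) msgs else TRUE
})

#' DwellFit: maximum-likelihood fit of a dwell-time distribution
#'
#' @slot model "exponential" or "gamma".
#' @slot tau mean dwell (s) for the exponential model (NA for gamma).
#' @slot amplitude histogram-fit amplitude A of A*exp(-t/tau) (figure
#'   parity only; NA when not computed).
#' @slot shape,scale gamma parameters (NA for exponential).
#' @slot shapeCI numeric(2), normal-approximation 95 percent CI on shape.
#' @slot logLik numeric(1).
#' @slot n integer, uncensored dwells used.
#' @export
setClass("DwellFit", representation(
  model = "character",
  tau = "numeric",
  amplitude = "numeric",
  shape = "numeric",
  scale = "numeric",
  shapeCI = "numeric",
  logLik = "numeric",
  n = "integer"
))

setValidity("DwellFit", function(object) {
  msgs <- character()
  if (!object@model %in% c("exponential", "gamma"))
    msgs <- c(msgs, "model must be exponential or gamma")
  if (object@model == "exponential" && (is.na(object@tau) || object@tau <= 0))
    msgs <- c(msgs, "tau must be > 0")
  if (object@model == "gamma" &&
      (is.na(object@shape) || object@shape <= 0 ||
       is.na(object@scale) || object@scale <= 0))
    msgs <- c(msgs, "shape and scale must be > 0")
  if (length(msgs)) msgs else TRUE
})

## ---- show methods ----------------------------------------------------

setMethod("show", "KineticScheme", function(object) {
  cat("KineticScheme", if (nzchar(object@name))
    sprintf("'%s'", object@name) else "", "\n")
  cat("  states:", paste(object@stateLabels, collapse = " -> "), "\n")
  fm <- object@fretMean
  shown <- ifelse(is.na(fm), "dark", format(fm, digits = 2))
  cat("  FRET means:", paste(sprintf("%s=%s", names(fm), shown),
                             collapse = ", "), "\n")
  cat("  initial:", object@initialState,
      " absorbing:", if (length(object@absorbing))
        paste(object@absorbing, collapse = ",") else "(none)", "\n")
})

setMethod("show", "StatePath", function(object) {
  cat(sprintf("StatePath: %d events over %.3g s (seed %d)\n",
              nrow(object@events), object@totalDuration, object@seed))
  print(head(object@events, 8))
  if (nrow(object@events) > 8) cat("  ...\n")
})

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace '%s': %d frames, dt = %.4g s\n", object@traceId,
              length(object@time),
              if (length(object@time) > 1) diff(object@time[1:2]) else NA))
})

setMethod("show", "FretTrace", function(object) {
  vw <- object@validWindow
  cat(sprintf("FretTrace '%s': %d frames, valid window [%s, %s]\n",
              object@traceId, length(object@time),
              ifelse(is.na(vw[1]), "-", vw[1]),
              ifelse(is.na(vw[2]), "-", vw[2])))
})

setMethod("show", "HMMModel", function(object) {
  cat(sprintf("HMMModel: K = %d, %s (logLik %.2f on %d frames)\n",
              object@K,
              if (object@converged) "converged" else "NOT converged",
              tail(object@logLikTrail, 1), object@nObs))
  cat("  means:", paste(format(object@means, digits = 3), collapse = ", "),
      "\n  sds:  ", paste(format(object@sds, digits = 3), collapse = ", "),
      "\n")
})

setMethod("show", "SyncHeatMap", function(object) {
  cat(sprintf("SyncHeatMap (%s anchor): %d x %d bins, %d traces\n",
              object@anchor, nrow(object@density), ncol(object@density),
              object@nTraces))
})

setMethod("show", "TDPHistogram", function(object) {
  cat(sprintf("TDPHistogram (%s %.3g s): %d transitions\n",
              object@side, object@windowSeconds, object@nTransitions))
  if (nrow(object@peaks)) {
    cat("  top peaks:\n")
    print(head(object@peaks, 4))
  }
})

setMethod("show", "DwellFit", function(object) {
  if (object@model == "exponential")
    cat(sprintf("DwellFit exponential: tau = %.4g s (n = %d, logLik %.2f)\n",
                object@tau, object@n, object@logLik))
  else
    cat(sprintf(
      "DwellFit gamma: shape = %.3g [%.3g, %.3g], scale = %.4g s (n = %d)\n",
      object@shape, object@shapeCI[1], object@shapeCI[2], object@scale,
      object@n))
})
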