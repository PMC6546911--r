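## Trace quality control: apparent-FRET computation, photobleaching step
## counting by change-point detection, six-donor trace selection,
## association/dissociation moment detection, and spot-occupancy curves.

## background-corrected total intensity (FRET-invariant when gamma = 1)
.correctedTotal <- function(trace, backgroundDonor = 0,
                            backgroundAcceptor = 0) {
  (trace@donor - backgroundDonor) + (trace@acceptor - backgroundAcceptor)
}

## robust background level + noise sd: split frames into a dim and a
## bright cluster; if they are well separated the dim cluster is the
## background (pre-association / post-dissociation frames), otherwise
## the whole trace sits at one level and that level is returned.
.traceBackground <- function(x) {
  lo <- quantile(x, 0.1); hi <- quantile(x, 0.9)
  if (hi - lo < 1e-8)
    return(c(level = median(x), sd = max(mad(x), 1e-8)))
  km <- suppressWarnings(kmeans(x, centers = c(lo, hi)))
  dimC <- which.min(km$centers)
  dimX <- x[km$cluster == dimC]
  sdDim <- max(mad(dimX), sd(dimX), 1e-8)
  if (diff(range(km$centers)) > 5 * sdDim)
    c(level = median(dimX), sd = sdDim)
  else
    c(level = median(x), sd = max(mad(x), 1e-8))
}

#' Compute the apparent FRET efficiency trace
#'
#' E = (acceptor - bgA) / ((acceptor - bgA) + (donor - bgD)) per frame.
#' Frames whose background-corrected total intensity falls below
#' \code{signalFloor} are no-signal (E = NA). E is not clamped: values
#' outside [0,1] can occur under noise and are kept. The valid window is
#' initialized to the first..last signal frame; [qcTrace()] refines it
#' using association/bleach/dissociation detection.
#'
#' @param trace a [Trace-class].
#' @param backgroundDonor,backgroundAcceptor photons/frame.
#' @param signalFloor minimum corrected total intensity for a frame to
#'   carry a FRET value (photons, default 50).
#' @return a [FretTrace-class].
#' @export
#' @examples
#' sc <- makeScenario("loading_atp")
#' tr <- simulateTraces(sc, 1, 20, photophysicsModel(), seed = 1)[[1]]
#' computeFret(tr, 20, 20)
computeFret <- function(trace, backgroundDonor = 0,
                        backgroundAcceptor = 0, signalFloor = 50) {
  stopifnot(is(trace, "Trace"))
  if (!length(trace@time)) stop("zero-length trace")
  d <- trace@donor - backgroundDonor
  a <- trace@acceptor - backgroundAcceptor
  tot <- d + a
  e <- a / tot
  signal <- tot >= signalFloor
  e[!signal] <- NA_real_
  vw <- if (any(signal)) range(which(signal)) else c(NA_integer_,
                                                     NA_integer_)
  if (!any(is.na(vw))) {
    out <- setdiff(seq_along(e), seq.int(vw[1], vw[2]))
    e[out] <- NA_real_
  }
  new("FretTrace", traceId = trace@traceId, time = trace@time,
      efficiency = e, totalIntensity = tot,
      validWindow = as.integer(vw),
      annotations = list(outOfRange = which(!is.na(e) & (e < 0 | e > 1))))
}

## ---- change-point step counting --------------------------------------

## best single split of x minimizing two-segment SSE; O(n) via cumsums
.bestSplit <- function(x) {
  n <- length(x)
  if (n < 4L) return(NULL)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  i <- seq_len(n - 1L)
  sseL <- cs2[i] - cs[i]^2 / i
  sseR <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  ## guard tiny negative round-off
  cost <- pmax(sseL, 0) + pmax(sseR, 0)
  ## require at least 2 frames per side
  ok <- i >= 2L & (n - i) >= 2L
  if (!any(ok)) return(NULL)
  j <- i[ok][which.min(cost[ok])]
  sse0 <- max(cs2[n] - cs[n]^2 / n, 0)
  list(at = j, gain = sse0 - cost[i == j])
}

## recursive binary segmentation; returns sorted change-point indices
## (last frame of each left segment)
.binarySegment <- function(x, penalty) {
  n <- length(x)
  cps <- integer()
  queue <- list(c(1L, n))
  while (length(queue)) {
    seg <- queue[[1]]; queue <- queue[-1]
    xs <- x[seg[1]:seg[2]]
    sp <- .bestSplit(xs)
    if (is.null(sp) || sp$gain <= penalty) next
    at <- seg[1] + sp$at - 1L
    cps <- c(cps, at)
    queue <- c(queue, list(c(seg[1], at)), list(c(at + 1L, seg[2])))
  }
  sort(cps)
}

#' Count donor photobleaching steps in a trace
#'
#' Change-point detection on the total intensity (donor + acceptor, which
#' is invariant to FRET state under the forward model, so the only steps
#' are association, photobleaching and dissociation events): recursive
#' binary segmentation minimizing within-segment variance, a split being
#' accepted when it reduces the cost by more than
#' \code{penaltyScale * sigma^2 * log(n)} (sigma estimated robustly from
#' first differences). Only downward steps whose magnitude exceeds
#' \code{minStepFrac} of the single-donor brightness estimate are counted
#' as bleaching steps.
#'
#' @param trace a [Trace-class].
#' @param backgroundDonor,backgroundAcceptor photons/frame.
#' @param penaltyScale multiplier of the sigma^2 log(n) split penalty
#'   (default 10; calibrated so a 3-step staircase at 10 percent
#'   step-height noise is recovered exactly).
#' @param minStepFrac minimum counted drop, as a fraction of the
#'   single-donor brightness (default 0.5).
#' @param singleDonorBrightness photons/frame per donor; when NULL,
#'   estimated as the median downward drop magnitude across detected
#'   change points.
#' @return list with \code{stepCount} (integer), \code{stepTimes}
#'   (seconds, at counted downward steps), \code{changePoints} (all
#'   detected change-point frames, 1-based last-frame-of-segment),
#'   \code{segmentMeans}.
#' @export
countPhotobleachSteps <- function(trace, backgroundDonor = 0,
                                  backgroundAcceptor = 0,
                                  penaltyScale = 10, minStepFrac = 0.5,
                                  singleDonorBrightness = NULL) {
  x <- .correctedTotal(trace, backgroundDonor, backgroundAcceptor)
  n <- length(x)
  if (n < 4L)
    return(list(stepCount = 0L, stepTimes = numeric(),
                changePoints = integer(), segmentMeans = mean(x)))
  sigma <- mad(diff(x)) / sqrt(2)
  penalty <- penaltyScale * max(sigma, 1e-12)^2 * log(n)
  cps <- .binarySegment(x, penalty)
  bounds <- c(0L, cps, n)
  means <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(x[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  drops <- -diff(means)               # positive = downward step
  downs <- which(drops > 0)
  if (is.null(singleDonorBrightness)) {
    singleDonorBrightness <- if (length(downs))
      median(drops[downs]) else Inf
  }
  counted <- downs[drops[downs] >= minStepFrac * singleDonorBrightness]
  list(stepCount = length(counted),
       stepTimes = trace@time[cps[counted]],
       changePoints = cps, segmentMeans = means)
}

## ---- association / dissociation --------------------------------------

#' Detect the association moment of a trace
#'
#' First frame at which total intensity exceeds background +
#' \code{k} * noise-sd for \code{w} consecutive frames. Background level
#' and noise sd are estimated from the dimmest 20 percent of frames
#' unless supplied.
#'
#' @param trace a [Trace-class].
#' @param k threshold multiplier (default 5).
#' @param w consecutive frames required (default 3).
#' @param background,noiseSd optional explicit values (raw-intensity
#'   scale).
#' @return integer frame index (1-based), or NA if the trace never shows
#'   signal.
#' @export
detectAssociation <- function(trace, k = 5, w = 3, background = NULL,
                              noiseSd = NULL) {
  x <- trace@donor + trace@acceptor
  if (is.null(background) || is.null(noiseSd)) {
    bg <- .traceBackground(x)
    if (is.null(noiseSd))
      noiseSd <- if (is.null(background)) bg[["sd"]] else
        max(sqrt(background), 1e-8)
    if (is.null(background)) background <- bg[["level"]]
  }
  above <- x > background + k * noiseSd
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  hit <- which(runs$values & runs$lengths >= w)
  if (!length(hit)) return(NA_integer_)
  as.integer(ends[hit[1]] - runs$lengths[hit[1]] + 1L)
}

#' Detect the dissociation moment and whether it is single-step
#'
#' Finds the last sustained drop to background (last above-threshold frame
#' followed by background to the trace end or for \code{w} frames). The
#' drop is single-step iff the signal falls from its pre-drop plateau
#' (median over the 12..3 frames before the drop completes) by at least
#' (1 - tol) of that plateau within at most 2 frames. Photobleaching vs.
#' unloading is not disambiguated per event (the study design separates
#' the time scales by >= 10x).
#'
#' @param trace a [Trace-class].
#' @param k,w as in [detectAssociation()].
#' @param tol plateau fraction allowed to remain during the drop
#'   (default 0.25).
#' @param background,noiseSd optional explicit values.
#' @return list(frame = first background frame after the signal epoch or
#'   NA, singleStep = logical).
#' @export
detectDissociation <- function(trace, k = 5, w = 3, tol = 0.25,
                               background = NULL, noiseSd = NULL) {
  x <- trace@donor + trace@acceptor
  if (is.null(background) || is.null(noiseSd)) {
    bg <- .traceBackground(x)
    if (is.null(noiseSd))
      noiseSd <- if (is.null(background)) bg[["sd"]] else
        max(sqrt(background), 1e-8)
    if (is.null(background)) background <- bg[["level"]]
  }
  above <- x > background + k * noiseSd
  if (!any(above)) return(list(frame = NA_integer_, singleStep = NA))
  lastHi <- max(which(above))
  if (lastHi >= length(x))            # signal to the very end: no event
    return(list(frame = NA_integer_, singleStep = NA))
  dFrame <- lastHi + 1L
  corr <- x - background
  pre <- corr[max(1L, dFrame - 12L):max(1L, dFrame - 3L)]
  preLevel <- median(pre)
  if (preLevel <= 0) return(list(frame = as.integer(dFrame),
                                 singleStep = NA))
  hi <- which(corr >= (1 - tol) * preLevel)
  hi <- hi[hi < dFrame]
  singleStep <- length(hi) > 0 && (dFrame - max(hi)) <= 2L
  list(frame = as.integer(dFrame), singleStep = singleStep)
}

## ---- selection -------------------------------------------------------

#' Select analyzable traces (six-donor criterion)
#'
#' Loading mode keeps traces whose donor photobleaching step count equals
#' \code{expectedSteps} (default 6, the fully labeled trimer). Unloading
#' mode (bleach steps unobservable: the clamp leaves first) keeps traces
#' whose initial signal level is within \code{tolerance} of the
#' calibrated six-donor intensity; the calibration is the median initial
#' intensity of six-step loading traces, or an explicit value.
#'
#' @param traces list of [Trace-class].
#' @param mode "loading" or "unloading".
#' @param backgroundDonor,backgroundAcceptor photons/frame.
#' @param expectedSteps donor count selected for (default 6).
#' @param calibration six-donor intensity level (required in unloading
#'   mode).
#' @param tolerance relative intensity tolerance, unloading mode
#'   (default 0.2).
#' @param ... further arguments to [countPhotobleachSteps()].
#' @return list(selected = sublist of traces, report = data.frame with
#'   one row per input trace: trace_id, step_count, initial_intensity,
#'   pass, reason).
#' @export
selectTraces <- function(traces, mode = c("loading", "unloading"),
                         backgroundDonor = 0, backgroundAcceptor = 0,
                         expectedSteps = 6L, calibration = NULL,
                         tolerance = 0.2, ...) {
  mode <- match.arg(mode)
  if (mode == "unloading" && is.null(calibration))
    stop("unloading selection requires a six-donor intensity calibration")
  rows <- list(); keep <- logical(length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    assoc <- detectAssociation(tr, background = backgroundDonor +
                                 backgroundAcceptor)
    x <- .correctedTotal(tr, backgroundDonor, backgroundAcceptor)
    init <- if (!is.na(assoc))
      median(x[assoc:min(length(x), assoc + 10L)]) else NA_real_
    stepCount <- NA_integer_
    if (mode == "loading") {
      st <- countPhotobleachSteps(tr, backgroundDonor,
                                  backgroundAcceptor, ...)
      stepCount <- st$stepCount
      pass <- stepCount == expectedSteps
      reason <- if (pass) "ok" else
        sprintf("step_count_%d_ne_%d", stepCount, expectedSteps)
    } else {
      pass <- !is.na(init) &&
        abs(init - calibration) / calibration <= tolerance
      reason <- if (pass) "ok" else if (is.na(init)) "no_association"
        else "intensity_outside_tolerance"
    }
    keep[i] <- pass
    rows[[i]] <- data.frame(trace_id = tr@traceId,
                            step_count = stepCount,
                            initial_intensity = init, pass = pass,
                            reason = reason, stringsAsFactors = FALSE)
  }
  list(selected = traces[keep], report = do.call(rbind, rows))
}

#' Full per-trace QC: FRET trace with refined valid window
#'
#' Runs association detection, dissociation detection, and (loading mode)
#' photobleach step counting, then restricts the analyzable window to
#' [association, first bleach step) in loading mode or
#' [first signal frame, dissociation) in unloading mode.
#'
#' @param trace a [Trace-class].
#' @param mode "loading" or "unloading".
#' @param backgroundDonor,backgroundAcceptor photons/frame.
#' @param signalFloor see [computeFret()].
#' @param ... further arguments to [countPhotobleachSteps()].
#' @return a [FretTrace-class] with annotations (associationFrame,
#'   dissociationFrame, stepCount, stepTimes, singleStepDissociation) and
#'   the refined valid window (c(NA, NA) when no analyzable frames
#'   remain).
#' @export
qcTrace <- function(trace, mode = c("loading", "unloading"),
                    backgroundDonor = 0, backgroundAcceptor = 0,
                    signalFloor = 50, ...) {
  mode <- match.arg(mode)
  ft <- computeFret(trace, backgroundDonor, backgroundAcceptor,
                    signalFloor)
  bgRaw <- backgroundDonor + backgroundAcceptor
  assoc <- detectAssociation(trace, background = bgRaw)
  diss <- detectDissociation(trace, background = bgRaw)
  ann <- list(associationFrame = assoc, dissociationFrame = diss$frame,
              singleStepDissociation = diss$singleStep,
              stepCount = NA_integer_, stepTimes = numeric())
  lo <- assoc
  hi <- if (!is.na(diss$frame)) diss$frame - 1L else length(trace@time)
  if (mode == "loading") {
    st <- countPhotobleachSteps(trace, backgroundDonor,
                                backgroundAcceptor, ...)
    ann$stepCount <- st$stepCount
    ann$stepTimes <- st$stepTimes
    if (length(st$stepTimes) && !is.na(assoc)) {
      firstBleach <- which(trace@time >= st$stepTimes[1])[1]
      hi <- min(hi, firstBleach - 1L)
    }
  }
  e <- ft@efficiency
  if (is.na(lo) || is.na(hi) || hi <= lo) {
    e[] <- NA_real_
    vw <- c(NA_integer_, NA_integer_)
  } else {
    vw <- c(lo, hi)
    out <- setdiff(seq_along(e), seq.int(lo, hi))
    e[out] <- NA_real_
  }
  initialize(ft, efficiency = e, validWindow = as.integer(vw),
             annotations = c(ann, ft@annotations["outOfRange"]))
}

#' Spot occupancy over time
#'
#' Number of traces with above-floor mean signal per time bin: the
#' changing number of clamp spots during loading/unloading.
#'
#' @param traces list of [Trace-class].
#' @param bin bin width, seconds.
#' @param backgroundDonor,backgroundAcceptor photons/frame.
#' @param signalFloor minimum corrected total intensity (default 50).
#' @return data.frame(time, count): bin left edges and occupancy.
#' @export
countSpotsOverTime <- function(traces, bin, backgroundDonor = 0,
                               backgroundAcceptor = 0, signalFloor = 50) {
  stopifnot(length(traces) > 0)
  tMax <- max(vapply(traces, function(x) max(x@time), numeric(1)))
  edges <- seq(0, tMax + bin, by = bin)
  counts <- integer(length(edges) - 1L)
  for (tr in traces) {
    x <- .correctedTotal(tr, backgroundDonor, backgroundAcceptor)
    idx <- findInterval(tr@time, edges, rightmost.closed = TRUE)
    m <- tapply(x, factor(idx, levels = seq_along(counts)), mean)
    counts <- counts + as.integer(!is.na(m) & m >= signalFloor)
  }
  data.frame(time = edges[-length(edges)], count = counts)
}
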