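## Photophysics rendering: state paths -> donor/acceptor intensity traces
## (multi-donor labeling, independent photobleaching, Poisson + read noise)
## and optionally -> two-channel movies of Gaussian spots.

#' Construct a PhotophysicsModel
#'
#' Defaults describe the experimental labeling scheme: a homotrimeric clamp with
#' two dye sites per monomer, each labeled with probability 0.6 (1.2 donors
#' per monomer on average), rendered at 10 frames/s.
#'
#' @param sitesPerMonomer dye sites per monomer (default 2).
#' @param monomers monomers per clamp (default 3).
#' @param labelProb per-site labeling probability (default 0.6).
#' @param donorBrightness photons/frame per active donor at FRET 0
#'   (default 100).
#' @param donorBleachRate photobleach rate per donor, 1/s (default 0.02).
#' @param backgroundDonor,backgroundAcceptor photons/frame (default 20).
#' @param readNoiseSd Gaussian read noise sd, photons (default 2).
#' @param frameInterval s/frame (default 0.1).
#' @param gamma acceptor/donor detection-correction factor (default 1).
#' @param poissonNoise logical; FALSE renders expected values only
#'   (plus read noise if nonzero), for exact algebraic checks.
#' @param fixedDonors NA to draw the donor count
#'   Binomial(sitesPerMonomer * monomers, labelProb) per trace, or an
#'   integer to fix it (e.g. 6 for the fully labeled trimer).
#' @return a validated [PhotophysicsModel-class].
#' @export
#' @examples
#' photophysicsModel(fixedDonors = 6, donorBleachRate = 0)
photophysicsModel <- function(sitesPerMonomer = 2L, monomers = 3L,
                              labelProb = 0.6, donorBrightness = 100,
                              donorBleachRate = 0.02,
                              backgroundDonor = 20,
                              backgroundAcceptor = 20,
                              readNoiseSd = 2, frameInterval = 0.1,
                              gamma = 1, poissonNoise = TRUE,
                              fixedDonors = NA_integer_) {
  new("PhotophysicsModel",
      sitesPerMonomer = as.integer(sitesPerMonomer),
      monomers = as.integer(monomers), labelProb = labelProb,
      donorBrightness = donorBrightness,
      donorBleachRate = donorBleachRate,
      backgroundDonor = backgroundDonor,
      backgroundAcceptor = backgroundAcceptor,
      readNoiseSd = readNoiseSd, frameInterval = frameInterval,
      gamma = gamma, poissonNoise = poissonNoise,
      fixedDonors = as.integer(fixedDonors))
}

#' Render a state path into a donor/acceptor intensity trace
#'
#' Forward model: the donor count is drawn
#' Binomial(sites, labelProb) unless fixed; each donor carries an
#' independent Exponential photobleach clock that starts at the association
#' moment (dyes are only excited once the clamp enters the evanescent
#' field). Per frame, with n active donors and state FRET E, the expected
#' donor signal is \eqn{n b (1-E) + bg_D} and the expected acceptor signal
#' \eqn{n b E \gamma + bg_A}; dark states (unbound/released) emit
#' background only. Observed counts are Poisson(expected) plus Gaussian
#' read noise.
#'
#' The frame state is evaluated at the frame midpoint.
#'
#' @param path a [StatePath-class].
#' @param model a [PhotophysicsModel-class].
#' @param seed integer seed.
#' @param traceId identifier for the trace.
#' @return a [Trace-class]; metadata records the ground truth
#'   (donor count, association/dissociation frames (1-based), absolute
#'   bleach times, per-frame true state and FRET).
#' @export
#' @examples
#' sc <- makeScenario("loading_atp")
#' p <- simulateStatePath(sc, 20, seed = 1)
#' renderTrace(p, photophysicsModel(), seed = 2)
renderTrace <- function(path, model, seed, traceId = "trace1") {
  stopifnot(is(path, "StatePath"), is(model, "PhotophysicsModel"))
  validObject(model)
  nFrames <- floor(path@totalDuration / model@frameInterval)
  if (nFrames < 1L) stop("path shorter than one frame interval")
  if (nFrames > 5e6) stop("path longer than representable frames (5e6)")
  dt <- model@frameInterval
  tMid <- (seq_len(nFrames) - 0.5) * dt
  tStart <- (seq_len(nFrames) - 1) * dt

  ## map scheme fret means onto frames; NA = dark
  sc <- path@events
  stateSeq <- stateAtTime(path, tMid)
  fm <- attr(path, "fretMean")  # not used; fret comes via metadata below
  withSeed(seed, {
    nSites <- model@sitesPerMonomer * model@monomers
    nDonors <- if (is.na(model@fixedDonors))
      rbinom(1L, nSites, model@labelProb) else model@fixedDonors
    fret <- .frameFret(path, stateSeq)
    bound <- !is.na(fret)
    assocFrame <- if (any(bound)) which(bound)[1] else NA_integer_
    dissocFrame <- if (any(bound)) {
      lastBound <- max(which(bound))
      if (lastBound < nFrames) lastBound + 1L else NA_integer_
    } else NA_integer_
    tAssoc <- if (is.na(assocFrame)) Inf else tStart[assocFrame]
    bleachAbs <- if (nDonors > 0 && model@donorBleachRate > 0)
      tAssoc + rexp(nDonors, model@donorBleachRate) else
        rep(Inf, nDonors)
    nActive <- if (nDonors > 0)
      vapply(tMid, function(t) sum(bleachAbs > t), numeric(1)) else
        rep(0, nFrames)
    e <- ifelse(bound, fret, 0)
    sig <- ifelse(bound, nActive * model@donorBrightness, 0)
    expD <- sig * (1 - e) + model@backgroundDonor
    expA <- sig * e * model@gamma + model@backgroundAcceptor
    obsD <- if (model@poissonNoise) rpois(nFrames, expD) else expD
    obsA <- if (model@poissonNoise) rpois(nFrames, expA) else expA
    if (model@readNoiseSd > 0) {
      obsD <- obsD + rnorm(nFrames, 0, model@readNoiseSd)
      obsA <- obsA + rnorm(nFrames, 0, model@readNoiseSd)
    }
    new("Trace", traceId = traceId, time = tStart,
        donor = as.numeric(obsD), acceptor = as.numeric(obsA),
        metadata = list(
          schemeName = attr(path, "schemeName"),
          seed = as.integer(seed),
          donorCount = as.integer(nDonors),
          bleachTimes = sort(bleachAbs[is.finite(bleachAbs)]),
          associationFrame = assocFrame,
          dissociationFrame = dissocFrame,
          trueState = stateSeq,
          trueFret = fret))
  })
}

## per-frame true FRET from the scheme stored alongside the path events;
## paths carry state labels only, so the fret map is passed via the
## scheme-aware wrapper simulateTraces(). For bare paths, labels matching
## LI1/LI2/LS/UI get the study defaults.
.DEFAULT_FRET <- c(LI1 = 0.48, LI2 = 0.62, LS = 0.34, UI = 0.58)

.frameFret <- function(path, stateSeq) {
  fm <- attr(path, "fretMap")
  if (is.null(fm)) fm <- .DEFAULT_FRET
  unname(fm[stateSeq])
}

#' Simulate a batch of traces for a scenario
#'
#' Convenience wrapper binding [simulateStatePath()] and [renderTrace()]
#' under one master seed: per-trace child seeds are spawned
#' deterministically, the scheme's FRET map travels with each path, and
#' trace ids are \code{<scenario>_<i>}.
#'
#' @param scheme a [KineticScheme-class] (e.g. from [makeScenario()]).
#' @param nTraces number of traces.
#' @param duration per-trace duration (s).
#' @param model a [PhotophysicsModel-class].
#' @param seed master seed.
#' @return list of [Trace-class].
#' @export
#' @examples
#' tr <- simulateTraces(makeScenario("loading_atp"), 3, 20,
#'                      photophysicsModel(), seed = 1)
simulateTraces <- function(scheme, nTraces, duration, model, seed) {
  lapply(seq_len(nTraces), function(i) {
    p <- simulateStatePath(scheme, duration,
                           childSeed(seed, "simulate", i))
    attr(p, "fretMap") <- scheme@fretMean
    attr(p, "schemeName") <- scheme@name
    renderTrace(p, model, childSeed(seed, "render", i),
                traceId = sprintf("%s_%04d", scheme@name, i))
  })
}

#' Render traces into a two-channel movie of immobile Gaussian spots
#'
#' Each trace becomes one spot at a fixed position, identical in both
#' channels (registered optics). The per-frame expected photon count of a
#' spot is the trace's channel intensity minus the model's channel
#' background (traces should be rendered noiselessly for movie input);
#' that amplitude is spread over a unit-integral 2-D Gaussian PSF. The
#' model's channel background is then added per pixel and Poisson + read
#' noise applied per pixel.
#'
#' @param traces list of [Trace-class], equal frame counts.
#' @param field list(width, height) in pixels; optional \code{margin}
#'   (default 8 px) and \code{positions} (n x 2 matrix of x,y to use
#'   instead of random placement).
#' @param psfSigma PSF standard deviation in pixels.
#' @param model a [PhotophysicsModel-class] (noise + backgrounds).
#' @param seed integer seed (spot placement and camera noise).
#' @return list with \code{donor} and \code{acceptor} arrays
#'   (height x width x frames) and \code{truth}, a data.frame
#'   (trace_id, x, y) of ground-truth positions (1-based pixel centers).
#' @export
renderMovie <- function(traces, field, psfSigma, model, seed) {
  stopifnot(length(traces) == 0 || is(traces[[1]], "Trace"))
  w <- field$width; h <- field$height
  margin <- if (is.null(field$margin)) 8 else field$margin
  nFrames <- if (length(traces)) length(traces[[1]]@time) else
    if (!is.null(field$frames)) field$frames else 10L
  if (length(traces) > 1 &&
      !all(vapply(traces, function(x) length(x@time), 1L) == nFrames))
    stop("all traces must have equal frame counts")
  withSeed(seed, {
    pos <- if (!is.null(field$positions)) field$positions else
      .placeSpots(length(traces), w, h, margin, minSep = 4 * psfSigma)
    donor <- array(0, dim = c(h, w, nFrames))
    acceptor <- array(0, dim = c(h, w, nFrames))
    for (i in seq_along(traces)) {
      tr <- traces[[i]]
      psf <- .gaussPatch(pos[i, 1], pos[i, 2], psfSigma, w, h)
      ampD <- pmax(tr@donor - model@backgroundDonor, 0)
      ampA <- pmax(tr@acceptor - model@backgroundAcceptor, 0)
      for (f in seq_len(nFrames)) {
        donor[psf$rows, psf$cols, f] <-
          donor[psf$rows, psf$cols, f] + ampD[f] * psf$patch
        acceptor[psf$rows, psf$cols, f] <-
          acceptor[psf$rows, psf$cols, f] + ampA[f] * psf$patch
      }
    }
    donor <- donor + model@backgroundDonor
    acceptor <- acceptor + model@backgroundAcceptor
    if (model@poissonNoise) {
      donor[] <- rpois(length(donor), donor)
      acceptor[] <- rpois(length(acceptor), acceptor)
    }
    if (model@readNoiseSd > 0) {
      donor <- donor + rnorm(length(donor), 0, model@readNoiseSd)
      acceptor <- acceptor + rnorm(length(acceptor), 0, model@readNoiseSd)
    }
    truth <- data.frame(
      trace_id = vapply(traces, function(x) x@traceId, ""),
      x = if (length(traces)) pos[, 1] else numeric(),
      y = if (length(traces)) pos[, 2] else numeric(),
      stringsAsFactors = FALSE)
    list(donor = donor, acceptor = acceptor, truth = truth)
  })
}

## dart-throwing placement with minimum separation
.placeSpots <- function(n, w, h, margin, minSep) {
  if (n == 0) return(matrix(numeric(), 0, 2))
  capacity <- ((w - 2 * margin) / minSep) * ((h - 2 * margin) / minSep)
  if (n > capacity)
    stop("too many spots for the field: ", n, " requested, ~",
         floor(capacity), " fit at separation ", minSep)
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    cand <- c(runif(1, margin, w - margin), runif(1, margin, h - margin))
    ok <- placed == 0L ||
      all(sqrt(rowSums((pos[seq_len(placed), , drop = FALSE] -
                        matrix(cand, placed, 2, byrow = TRUE))^2)) >=
            minSep)
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
    tries <- tries + 1L
    if (tries > 20000L * n)
      stop("too many spots for the field (placement failed at separation ",
           minSep, ")")
  }
  pos
}

## unit-integral Gaussian patch clipped to the image
.gaussPatch <- function(x, y, sigma, w, h, halfWidth = ceiling(5 * sigma)) {
  cols <- max(1L, floor(x - halfWidth)):min(w, ceiling(x + halfWidth))
  rows <- max(1L, floor(y - halfWidth)):min(h, ceiling(y + halfWidth))
  gx <- exp(-((cols - x)^2) / (2 * sigma^2))
  gy <- exp(-((rows - y)^2) / (2 * sigma^2))
  patch <- outer(gy, gx)
  patch <- patch / (2 * pi * sigma^2)
  list(rows = rows, cols = cols, patch = patch)
}

#' Write a movie channel as a 16-bit multi-page TIFF
#'
#' Values are clipped at \code{maxCount} and stored as
#' \code{counts / maxCount} in 16-bit (the scale factor is the
#' \code{maxCount} argument; keep it with the file to recover counts).
#'
#' @param stack height x width x frames array of photon counts.
#' @param file destination .tif path.
#' @param maxCount full-scale photon count (default 65535).
#' @export
writeMovieTiff <- function(stack, file, maxCount = 65535) {
  frames <- lapply(seq_len(dim(stack)[3]), function(f)
    pmin(pmax(stack[, , f], 0), maxCount) / maxCount)
  tiff::writeTIFF(frames, file, bits.per.sample = 16L)
  invisible(file)
}

#' @rdname writeMovieTiff
#' @export
readMovieTiff <- function(file, maxCount = 65535) {
  frames <- tiff::readTIFF(file, all = TRUE)
  arr <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                          length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]] * maxCount
  arr
}
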