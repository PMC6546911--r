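# Programmatic fixtures shared across test files.

# constant-intensity trace
constTrace <- function(id = "t1", donor = 400, acceptor = 200, n = 100,
                       dt = 0.1) {
  new("Trace", traceId = id, time = (seq_len(n) - 1) * dt,
      donor = rep(donor, n), acceptor = rep(acceptor, n),
      metadata = list())
}

# trace from explicit per-frame donor/acceptor vectors
vecTrace <- function(donor, acceptor, id = "t1", dt = 0.1) {
  new("Trace", traceId = id, time = (seq_along(donor) - 1) * dt,
      donor = donor, acceptor = acceptor, metadata = list())
}

# donor-only staircase: nSteps distinct bleach plateaus then background
staircaseTrace <- function(nSteps, stepHeight = 100, segLen = 50,
                           background = 0, noiseSd = 0, seed = 1,
                           dt = 0.1) {
  levels <- c(rev(seq_len(nSteps)) * stepHeight, 0) + background
  x <- rep(levels, each = segLen)
  if (noiseSd > 0) {
    set.seed(seed)
    x <- x + rnorm(length(x), 0, noiseSd)
  }
  vecTrace(donor = x, acceptor = rep(0, length(x)), dt = dt)
}

# single-state scheme emitting a fixed FRET level
flatScheme <- function(e = 0.34, label = "LS") {
  r <- matrix(0, 1, 1, dimnames = list(label, label))
  kineticScheme(label, setNames(e, label), r, initialState = label,
                name = "flat")
}

# FretTrace wrapper around a raw efficiency vector (full valid window)
fretFromVector <- function(e, id = "f1", dt = 0.1,
                           annotations = list()) {
  new("FretTrace", traceId = id, time = (seq_along(e) - 1) * dt,
      efficiency = e, totalIntensity = rep(600, length(e)),
      validWindow = c(1L, length(e)), annotations = annotations)
}

# 2-state Gaussian Markov FretTraces with known parameters
twoStateTraces <- function(nTraces = 20, nFrames = 300,
                           means = c(0.3, 0.7), sd = 0.05,
                           pStay = 0.95, seed = 1) {
  set.seed(seed)
  lapply(seq_len(nTraces), function(i) {
    s <- integer(nFrames)
    s[1] <- sample(1:2, 1)
    for (t in 2:nFrames)
      s[t] <- if (runif(1) < pStay) s[t - 1] else 3L - s[t - 1]
    e <- rnorm(nFrames, means[s], sd)
    ft <- fretFromVector(e, id = sprintf("sim%02d", i))
    attr(ft, "trueStates") <- s
    ft
  })
}

# simulated study ensemble through render + QC; returns analyzable
# FretTraces plus the raw traces
studyEnsemble <- function(scenario, nTraces, duration, seed,
                          bleachRate = if (startsWith(scenario,
                                                      "loading"))
                            0.02 else 0.005,
                          fixedDonors = 6L) {
  sc <- makeScenario(scenario)
  mode <- if (startsWith(scenario, "loading")) "loading" else
    "unloading"
  m <- photophysicsModel(fixedDonors = fixedDonors,
                         donorBleachRate = bleachRate)
  tr <- simulateTraces(sc, nTraces, duration, m, seed = seed)
  sel <- selectTraces(tr, mode, 20, 20, calibration = 600,
                      singleDonorBrightness = 100)
  fret <- lapply(sel$selected, qcTrace, mode = mode,
                 backgroundDonor = 20, backgroundAcceptor = 20,
                 singleDonorBrightness = 100)
  fret <- Filter(function(f) !any(is.na(f@validWindow)), fret)
  list(scheme = sc, model = m, traces = tr, selected = sel$selected,
       report = sel$report, fret = fret)
}
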