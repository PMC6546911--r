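## Kinetic simulation of clamp loading/unloading: exact continuous-time
## Markov (Gillespie) sampling over labeled schemes, with optional Erlang
## sub-step structure inside a state (multiple sequential rate-limiting
## catalytic steps sharing one FRET level).

#' Construct a KineticScheme
#'
#' @param stateLabels character vector of state names, in scheme order.
#' @param fretMean named numeric of per-state mean FRET efficiencies; states
#'   omitted (or NA) are dark (no FRET signal: unbound/released).
#' @param rates square matrix of first-order transition rates (1/s), rows =
#'   from-state, columns = to-state, dimnames matching \code{stateLabels}.
#'   The diagonal is ignored.
#' @param substeps named integer of per-state sub-step counts; states
#'   omitted default to 1 (plain exponential dwell).
#' @param initialState starting state label.
#' @param name optional scenario name.
#' @return a validated [KineticScheme-class] object. States whose total exit
#'   rate is zero are recorded as absorbing.
#' @export
#' @examples
#' r <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' r["A", "B"] <- 2
#' kineticScheme(c("A", "B"), c(A = 0.5, B = 0.3), r, initialState = "A")
kineticScheme <- function(stateLabels, fretMean, rates, substeps = NULL,
                          initialState = stateLabels[1], name = "") {
  n <- length(stateLabels)
  if (is.null(dimnames(rates)))
    dimnames(rates) <- list(stateLabels, stateLabels)
  rates <- rates[stateLabels, stateLabels, drop = FALSE]
  fm <- setNames(rep(NA_real_, n), stateLabels)
  if (length(fretMean)) fm[names(fretMean)] <- fretMean
  ss <- setNames(rep(1L, n), stateLabels)
  if (!is.null(substeps)) ss[names(substeps)] <- as.integer(substeps)
  off <- rates; diag(off) <- 0
  absorbing <- stateLabels[rowSums(off) == 0]
  new("KineticScheme", stateLabels = stateLabels, fretMean = fm,
      rates = rates, substeps = ss, initialState = initialState,
      absorbing = absorbing, name = name)
}

.SCENARIOS <- c("loading_atp", "loading_atpgs", "unloading_atp",
                "unloading_atpgs", "unloading_inactive")

#' Build a named clamp-cycling scenario
#'
#' Returns a fully parameterized [KineticScheme-class] for one of the study
#' conditions:
#' \describe{
#'   \item{loading_atp}{UNBOUND -> LI1 -> LI2 -> LS with reverse transitions
#'     at a much lower frequency (default 10\% of forward). LI1 is the
#'     short-lived open-clamp/loader intermediate, LI2 the longer-lived
#'     closed-clamp intermediate, LS the loaded state.}
#'   \item{loading_atpgs}{association proceeds but LI1 -> LI2 is blocked
#'     (no ATP hydrolysis): the complex stalls at the LI1 FRET level.}
#'   \item{unloading_atp / unloading_atpgs}{LS <-> UI and UI -> RELEASED;
#'     the unloading intermediate UI traverses 2 hidden sub-steps by default
#'     (Erlang dwell, peaked at non-zero time). The two scenarios share
#'     kinetics: unloading does not require ATP hydrolysis.}
#'   \item{unloading_inactive}{LS has no exit (unloader-dead mutant).}
#' }
#'
#' Default FRET means are LI1 0.48, LI2 0.62, LS 0.34, UI 0.58. Default
#' time scales: association 1 s, tau_LI1 0.5 s, tau_LI2 1.5 s, LS -> UI
#' 2 s, total UI dwell 2 s; reverse rates 10\% of forward.
#'
#' @param name one of \code{loading_atp}, \code{loading_atpgs},
#'   \code{unloading_atp}, \code{unloading_atpgs},
#'   \code{unloading_inactive}.
#' @param rates named numeric of rate overrides with \code{"FROM->TO"} keys,
#'   e.g. \code{c("LI1->LI2" = 3)}.
#' @param fretMean named numeric of FRET-mean overrides, e.g.
#'   \code{c(LI1 = 0.5)}.
#' @param substeps named integer of sub-step overrides, e.g.
#'   \code{c(UI = 3)}.
#' @param reverseFraction reverse/forward rate ratio used when building the
#'   default scheme (default 0.1).
#' @return a [KineticScheme-class].
#' @export
#' @examples
#' makeScenario("loading_atp")
#' makeScenario("unloading_atp", substeps = c(UI = 3))
makeScenario <- function(name, rates = NULL, fretMean = NULL,
                         substeps = NULL, reverseFraction = 0.1) {
  if (!is.character(name) || length(name) != 1L || !(name %in% .SCENARIOS))
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; valid names: ", paste(.SCENARIOS, collapse = ", "))
  kAssoc <- 1.0
  k12 <- 1 / 0.5    # LI1 -> LI2, tau_LI1 = 0.5 s
  k2L <- 1 / 1.5    # LI2 -> LS,  tau_LI2 = 1.5 s
  kLU <- 1 / 2.0    # LS  -> UI
  uiTotalExit <- 1 / 2.0   # total UI exit rate (mean UI dwell 2 s)

  if (name %in% c("loading_atp", "loading_atpgs")) {
    labs <- c("UNBOUND", "LI1", "LI2", "LS")
    r <- matrix(0, 4, 4, dimnames = list(labs, labs))
    r["UNBOUND", "LI1"] <- kAssoc
    if (name == "loading_atp") {
      r["LI1", "LI2"] <- k12
      r["LI2", "LI1"] <- reverseFraction * k12
      r["LI2", "LS"] <- k2L
      r["LS", "LI2"] <- reverseFraction * k2L
    }
    fm <- c(LI1 = 0.48, LI2 = 0.62, LS = 0.34)
    ss <- NULL
    init <- "UNBOUND"
  } else {
    labs <- c("LS", "UI", "RELEASED")
    r <- matrix(0, 3, 3, dimnames = list(labs, labs))
    if (name != "unloading_inactive") {
      r["LS", "UI"] <- kLU
      kBack <- uiTotalExit * reverseFraction / (1 + reverseFraction)
      r["UI", "LS"] <- kBack
      r["UI", "RELEASED"] <- uiTotalExit - kBack
    }
    fm <- c(LS = 0.34, UI = 0.58)
    ss <- c(UI = 2L)
    init <- "LS"
  }
  if (!is.null(fretMean)) fm[names(fretMean)] <- fretMean
  if (!is.null(substeps)) {
    if (is.null(ss)) ss <- integer()
    ss[names(substeps)] <- as.integer(substeps)
  }
  if (!is.null(rates)) {
    for (key in names(rates)) {
      ft <- strsplit(key, "->", fixed = TRUE)[[1]]
      if (length(ft) != 2L || !all(ft %in% labs))
        stop("rate override key must be 'FROM->TO' over scheme states: ",
             key)
      r[ft[1], ft[2]] <- rates[[key]]
    }
  }
  kineticScheme(labs, fm, r, substeps = ss, initialState = init,
                name = name)
}

#' Simulate one state path by the Gillespie algorithm
#'
#' Exact continuous-time Markov sampling: in a state with total exit rate R
#' and m sub-steps, each sub-step dwell is Exponential(R*m), so the full
#' dwell is Erlang(m, R*m) and the mean dwell 1/R is preserved for any m.
#' The successor state is drawn with probability proportional to its rate.
#' The path is truncated at \code{duration}.
#'
#' @param scheme a [KineticScheme-class].
#' @param duration total simulated time (s), > 0.
#' @param seed integer seed; identical seed + scheme gives an identical
#'   path.
#' @return a [StatePath-class].
#' @export
#' @examples
#' sc <- makeScenario("loading_atp")
#' simulateStatePath(sc, duration = 20, seed = 1)
simulateStatePath <- function(scheme, duration, seed) {
  stopifnot(is(scheme, "KineticScheme"))
  validObject(scheme)
  if (!is.numeric(duration) || length(duration) != 1L ||
      !is.finite(duration) || duration <= 0)
    stop("duration must be a finite positive number of seconds")
  labs <- scheme@stateLabels
  r <- scheme@rates; diag(r) <- 0
  exitRate <- rowSums(r)
  ss <- scheme@substeps
  withSeed(seed, {
    state <- match(scheme@initialState, labs)
    t0 <- 0
    times <- 0
    states <- labs[state]
    repeat {
      R <- exitRate[state]
      if (R <= 0) break            # absorbing
      m <- ss[state]
      dwell <- sum(rexp(m, rate = R * m))
      t0 <- t0 + dwell
      if (t0 >= duration) break
      p <- r[state, ] / R
      state <- sample.int(length(labs), 1L, prob = p)
      times <- c(times, t0)
      states <- c(states, labs[state])
    }
    new("StatePath",
        events = data.frame(entry_time_s = times, state = states,
                            stringsAsFactors = FALSE),
        totalDuration = duration, seed = as.integer(seed))
  })
}

#' State occupied at given times along a path
#'
#' @param path a [StatePath-class].
#' @param times numeric vector of query times in [0, duration].
#' @return character vector of state labels.
#' @export
stateAtTime <- function(path, times) {
  ev <- path@events
  idx <- findInterval(times, ev$entry_time_s)
  idx[idx < 1L] <- 1L
  ev$state[idx]
}

#' Write / read a StatePath as CSV
#'
#' Columns \code{entry_time_s,state}; the duration and seed travel in a
#' \code{# duration=...; seed=...} comment line.
#'
#' @param path a [StatePath-class].
#' @param file destination path.
#' @export
writeStatePath <- function(path, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration=%.17g; seed=%d", path@totalDuration,
                     path@seed), con)
  write.csv(path@events, con, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeStatePath
#' @param file source path.
#' @export
readStatePath <- function(file) {
  hdr <- readLines(file, n = 1L)
  meta <- regmatches(hdr, regexec(
    "duration=([0-9.eE+-]+); seed=([0-9-]+)", hdr))[[1]]
  if (length(meta) != 3L) stop("missing duration/seed header in ", file)
  ev <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  new("StatePath", events = ev, totalDuration = as.numeric(meta[2]),
      seed = as.integer(meta[3]))
}

#' Serialize scheme parameters as a flat key-value config
#'
#' Keys: \code{states}, \code{initial}, \code{name},
#' \code{fret.<STATE>}, \code{substeps.<STATE>}, \code{rate.<FROM>-><TO>}.
#'
#' @param scheme a [KineticScheme-class].
#' @param file destination path.
#' @export
writeSchemeConfig <- function(scheme, file) {
  cfg <- list(states = paste(scheme@stateLabels, collapse = ","),
              initial = scheme@initialState, name = scheme@name)
  for (s in scheme@stateLabels) {
    if (!is.na(scheme@fretMean[s])) cfg[[paste0("fret.", s)]] <-
        scheme@fretMean[[s]]
    if (scheme@substeps[s] != 1L) cfg[[paste0("substeps.", s)]] <-
        scheme@substeps[[s]]
  }
  for (a in scheme@stateLabels) for (b in scheme@stateLabels)
    if (a != b && scheme@rates[a, b] > 0)
      cfg[[sprintf("rate.%s->%s", a, b)]] <- scheme@rates[a, b]
  yaml::write_yaml(cfg, file, precision = 15)
  invisible(file)
}

#' @rdname writeSchemeConfig
#' @export
readSchemeConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  labs <- strsplit(cfg$states, ",", fixed = TRUE)[[1]]
  r <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  fm <- numeric(); ss <- integer()
  for (key in names(cfg)) {
    if (startsWith(key, "rate.")) {
      ft <- strsplit(sub("^rate\\.", "", key), "->", fixed = TRUE)[[1]]
      r[ft[1], ft[2]] <- cfg[[key]]
    } else if (startsWith(key, "fret.")) {
      fm[sub("^fret\\.", "", key)] <- cfg[[key]]
    } else if (startsWith(key, "substeps.")) {
      ss[sub("^substeps\\.", "", key)] <- as.integer(cfg[[key]])
    }
  }
  kineticScheme(labs, fm, r, substeps = if (length(ss)) ss else NULL,
                initialState = cfg$initial,
                name = if (is.null(cfg$name)) "" else cfg$name)
}

#' Continuous dwell times from simulated state paths
#'
#' Extracts exact (continuous-time) state dwells from ground-truth paths:
#' the dwell-law counterpart of [dwellTimes()], free of frame
#' discretization. The final dwell of a path is censored unless it ends
#' by entering another state before the duration cap.
#'
#' @param paths list of [StatePath-class].
#' @param state state label.
#' @param policy "drop_censored" (default) or "keep_flagged".
#' @return data.frame(path, state, duration_s, censored).
#' @export
pathDwellTimes <- function(paths, state,
                           policy = c("drop_censored",
                                      "keep_flagged")) {
  policy <- match.arg(policy)
  rows <- list()
  for (i in seq_along(paths)) {
    ev <- paths[[i]]@events
    tEnd <- paths[[i]]@totalDuration
    exits <- c(ev$entry_time_s[-1], tEnd)
    hit <- which(ev$state == state)
    for (k in hit) {
      censored <- k == nrow(ev)   # truncated by the duration cap
      rows[[length(rows) + 1L]] <- data.frame(
        path = i, state = state,
        duration_s = exits[k] - ev$entry_time_s[k],
        censored = censored, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = integer(), state = character(),
               duration_s = numeric(), censored = logical())
  if (policy == "drop_censored") out <- out[!out$censored, ,
                                            drop = FALSE]
  rownames(out) <- NULL
  out
}
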