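## Kinetic summaries over decoded traces: event-synchronized FRET
## population heat maps, transition density plots, dwell-time tables and
## maximum-likelihood dwell fits (exponential vs gamma).

#' Synchronize FRET traces at association or dissociation
#'
#' Shifts each trace's time axis so its detected anchor frame is t = 0.
#' Traces lacking the anchor annotation are dropped with a reason code.
#'
#' @param fretTraces list of [FretTrace-class] with annotations from
#'   [qcTrace()].
#' @param anchor "association" or "dissociation".
#' @return list with \code{frames}: data.frame(trace_id, time,
#'   efficiency) over valid-window frames with defined E, times relative
#'   to the anchor; \code{nTraces} aligned; \code{anchor}; and
#'   \code{dropped}: data.frame(trace_id, reason).
#' @export
synchronize <- function(fretTraces,
                        anchor = c("association", "dissociation")) {
  anchor <- match.arg(anchor)
  key <- if (anchor == "association") "associationFrame" else
    "dissociationFrame"
  rows <- list(); dropped <- list()
  for (ft in fretTraces) {
    af <- ft@annotations[[key]]
    vw <- ft@validWindow
    if (is.null(af) || is.na(af)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(trace_id = ft@traceId,
                   reason = paste0("no_", anchor),
                   stringsAsFactors = FALSE)
      next
    }
    if (any(is.na(vw))) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(trace_id = ft@traceId, reason = "no_valid_window",
                   stringsAsFactors = FALSE)
      next
    }
    dt <- ft@time[2] - ft@time[1]
    t0 <- ft@time[1] + (af - 1) * dt  # anchor frame time (af may exceed
                                      # the axis for dissociation at end)
    idx <- seq.int(vw[1], vw[2])
    ok <- !is.na(ft@efficiency[idx])
    rows[[length(rows) + 1L]] <-
      data.frame(trace_id = ft@traceId, time = ft@time[idx[ok]] - t0,
                 efficiency = ft@efficiency[idx[ok]],
                 stringsAsFactors = FALSE)
  }
  list(frames = if (length(rows)) do.call(rbind, rows) else
         data.frame(trace_id = character(), time = numeric(),
                    efficiency = numeric()),
       nTraces = length(rows), anchor = anchor,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(trace_id = character(), reason = character()))
}

#' Build a synchronized FRET population heat map
#'
#' 2-D histogram of (relative time, E) over all aligned frames, each time
#' column normalized to unit mass.
#'
#' @param aligned output of [synchronize()].
#' @param tRange time range (s) relative to the anchor; default
#'   c(-2, 10) for association, c(-10, 2) for dissociation.
#' @param tBin time bin width, s (default 0.2).
#' @param eRange FRET range (default c(-0.1, 1.1)).
#' @param eBin FRET bin width (default 0.02).
#' @return a [SyncHeatMap-class].
#' @export
buildHeatMap <- function(aligned, tRange = NULL, tBin = 0.2,
                         eRange = c(-0.1, 1.1), eBin = 0.02) {
  if (is.null(tRange))
    tRange <- if (aligned$anchor == "association") c(-2, 10) else
      c(-10, 2)
  tBreaks <- seq(tRange[1], tRange[2], by = tBin)
  eBreaks <- seq(eRange[1], eRange[2], by = eBin)
  fr <- aligned$frames
  keep <- fr$time >= tRange[1] & fr$time < tBreaks[length(tBreaks)] &
    fr$efficiency >= eRange[1] & fr$efficiency < eBreaks[length(eBreaks)]
  fr <- fr[keep, , drop = FALSE]
  ti <- findInterval(fr$time, tBreaks, rightmost.closed = TRUE)
  ei <- findInterval(fr$efficiency, eBreaks, rightmost.closed = TRUE)
  m <- matrix(0, length(eBreaks) - 1L, length(tBreaks) - 1L)
  for (r in seq_len(nrow(fr))) m[ei[r], ti[r]] <- m[ei[r], ti[r]] + 1
  cs <- colSums(m)
  nz <- cs > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2, cs[nz], "/")
  new("SyncHeatMap", density = m, timeBreaks = tBreaks,
      fretBreaks = eBreaks, nTraces = as.integer(aligned$nTraces),
      anchor = aligned$anchor)
}

#' Column-modal FRET of a heat map
#'
#' Bin-center FRET of the modal bin per time column (NA for empty
#' columns); used to read the stage progression off a heat map.
#'
#' @param hm a [SyncHeatMap-class].
#' @return data.frame(time, modal_e).
#' @export
heatmapModalFret <- function(hm) {
  centers <- hm@fretBreaks[-length(hm@fretBreaks)] +
    diff(hm@fretBreaks) / 2
  tc <- hm@timeBreaks[-length(hm@timeBreaks)] + diff(hm@timeBreaks) / 2
  modal <- apply(hm@density, 2, function(col)
    if (sum(col) == 0) NA_real_ else centers[which.max(col)])
  data.frame(time = tc, modal_e = modal)
}

#' Transition density plot from decoded paths
#'
#' For each Viterbi state change inside the analysis window (the first
#' \code{windowSeconds} after the valid window opens, or the last before
#' it closes), increments the 2-D bin at (emission mean of the departing
#' state, emission mean of the arriving state). Transitions are only
#' taken within contiguous decoded runs (never across signal gaps).
#'
#' @param decodedPaths list of [DecodedPath-class].
#' @param fretTraces matching list of [FretTrace-class] (time axes and
#'   valid windows).
#' @param model the [HMMModel-class] used for decoding.
#' @param windowSeconds analysis window length (default 6).
#' @param side "first" (post-association) or "last" (pre-dissociation).
#' @param eBin FRET bin width (default 0.02).
#' @param eRange shared axis range (default c(-0.1, 1.1)).
#' @return a [TDPHistogram-class].
#' @export
transitionDensity <- function(decodedPaths, fretTraces, model,
                              windowSeconds = 6,
                              side = c("first", "last"), eBin = 0.02,
                              eRange = c(-0.1, 1.1)) {
  side <- match.arg(side)
  stopifnot(length(decodedPaths) == length(fretTraces))
  breaks <- seq(eRange[1], eRange[2], by = eBin)
  nb <- length(breaks) - 1L
  counts <- matrix(0L, nb, nb)
  nTrans <- 0L
  for (i in seq_along(decodedPaths)) {
    dp <- decodedPaths[[i]]; ft <- fretTraces[[i]]
    vw <- ft@validWindow
    if (any(is.na(vw)) || length(dp@states) < 2L) next
    dt <- ft@time[2] - ft@time[1]
    tRel <- (seq_along(dp@states) - 1L) * dt  # time since window open
    tEnd <- tRel[length(tRel)]
    inWin <- if (side == "first") tRel <= windowSeconds else
      tRel >= tEnd - windowSeconds
    s <- dp@states
    for (t in seq_len(length(s) - 1L)) {
      if (!inWin[t + 1L]) next
      if (is.na(s[t]) || is.na(s[t + 1L]) || s[t] == s[t + 1L]) next
      bFrom <- findInterval(model@means[s[t]], breaks,
                            rightmost.closed = TRUE)
      bTo <- findInterval(model@means[s[t + 1L]], breaks,
                          rightmost.closed = TRUE)
      if (bFrom == bTo) next   # states in the same bin: not plottable
      counts[bFrom, bTo] <- counts[bFrom, bTo] + 1L
      nTrans <- nTrans + 1L
    }
  }
  nzIdx <- which(counts > 0, arr.ind = TRUE)
  centers <- breaks[-length(breaks)] + eBin / 2
  peaks <- data.frame(e_before = centers[nzIdx[, 1]],
                      e_after = centers[nzIdx[, 2]],
                      count = counts[nzIdx])
  peaks <- peaks[order(-peaks$count), , drop = FALSE]
  rownames(peaks) <- NULL
  new("TDPHistogram", counts = counts, breaks = breaks,
      windowSeconds = windowSeconds, side = side,
      nTransitions = nTrans, peaks = peaks)
}

#' Extract dwell times of a state from decoded paths
#'
#' Contiguous Viterbi runs of the state become durations (run length x
#' frame interval). Runs touching the edge of their contiguous decoded
#' segment (window edge, signal gap, trace end) are censored.
#'
#' A dwell whose boundary coincides with the molecule's own observed
#' entry or exit event is complete, not censored: a run opening at the
#' detected association moment began there, and a run closing at the
#' detected dissociation moment ended there (the release is the
#' transition out). Both exemptions are on by default.
#'
#' @param decodedPaths list of [DecodedPath-class].
#' @param fretTraces matching list of [FretTrace-class].
#' @param state state index (1..K, sorted-by-mean order of the model).
#' @param policy "drop_censored" (default) removes censored records;
#'   "keep_flagged" keeps them with the flag set.
#' @param associationStartsDwell,dissociationEndsDwell treat runs
#'   bounded by the detected association/dissociation as uncensored at
#'   that edge (default TRUE).
#' @return DwellTable data.frame(trace_id, state, duration_s, censored).
#' @export
dwellTimes <- function(decodedPaths, fretTraces, state,
                       policy = c("drop_censored", "keep_flagged"),
                       associationStartsDwell = TRUE,
                       dissociationEndsDwell = TRUE) {
  policy <- match.arg(policy)
  rows <- list()
  for (i in seq_along(decodedPaths)) {
    dp <- decodedPaths[[i]]; ft <- fretTraces[[i]]
    if (!length(dp@states)) next
    dt <- ft@time[2] - ft@time[1]
    vw <- ft@validWindow
    assoc <- ft@annotations$associationFrame
    dissoc <- ft@annotations$dissociationFrame
    nW <- length(dp@states)
    ## window edges coinciding with the molecule's own entry/exit
    entryAtOpen <- associationStartsDwell && !is.null(assoc) &&
      !is.na(assoc) && assoc == vw[1]
    exitAtClose <- dissociationEndsDwell && !is.null(dissoc) &&
      !is.na(dissoc) && dissoc == vw[2] + 1L
    ## split into contiguous non-NA segments
    ok <- !is.na(dp@states)
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      seg <- dp@states[starts[j]:ends[j]]
      rr <- rle(seg)
      re <- cumsum(rr$lengths); rs <- re - rr$lengths + 1L
      for (k in which(rr$values == state)) {
        leftOpen <- (k == 1L) &&
          !(starts[j] == 1L && entryAtOpen)
        rightOpen <- (k == length(rr$values)) &&
          !(ends[j] == nW && exitAtClose)
        censored <- leftOpen || rightOpen
        rows[[length(rows) + 1L]] <- data.frame(
          trace_id = dp@traceId, state = state,
          duration_s = rr$lengths[k] * dt, censored = censored,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trace_id = character(), state = integer(),
               duration_s = numeric(), censored = logical())
  if (policy == "drop_censored") out <- out[!out$censored, ,
                                            drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a dwell-time distribution
#'
#' Maximum-likelihood fit on uncensored durations. For the exponential
#' model the MLE is the sample mean (tau); a histogram least-squares fit
#' of A exp(-t / tau) additionally supplies the amplitude A for figure
#' parity (the MLE tau remains the primary estimate). The gamma model is
#' fit by standard MLE; its shape CI (normal approximation, 95 percent)
#' supports the exponentiality check (shape = 1) and the
#' likelihood-ratio test against the nested exponential.
#'
#' @param table DwellTable from [dwellTimes()].
#' @param model "exponential" or "gamma".
#' @param nBins histogram bins for the amplitude fit (default 30).
#' @return a [DwellFit-class].
#' @export
fitDwells <- function(table, model = c("exponential", "gamma"),
                      nBins = 30L) {
  model <- match.arg(model)
  x <- table$duration_s[!table$censored]
  if (length(x) < 10L)
    stop("at least 10 uncensored dwells are required (got ",
         length(x), ")")
  if (model == "exponential") {
    tau <- mean(x)
    ll <- sum(dexp(x, rate = 1 / tau, log = TRUE))
    ## histogram fit for figure parity
    h <- hist(x, breaks = nBins, plot = FALSE)
    amp <- tryCatch({
      fit <- nls(counts ~ A * exp(-mids / th),
                 data = data.frame(counts = h$counts, mids = h$mids),
                 start = list(A = max(h$counts), th = tau))
      coef(fit)[["A"]]
    }, error = function(e) NA_real_)
    new("DwellFit", model = "exponential", tau = tau, amplitude = amp,
        shape = NA_real_, scale = NA_real_,
        shapeCI = c(NA_real_, NA_real_), logLik = ll,
        n = length(x))
  } else {
    fit <- MASS::fitdistr(x, "gamma",
                          start = list(shape = max(mean(x)^2 / var(x),
                                                   0.1),
                                       rate = max(mean(x) / var(x),
                                                  0.01)),
                          lower = c(1e-6, 1e-6))
    shape <- fit$estimate[["shape"]]
    rate <- fit$estimate[["rate"]]
    se <- fit$sd[["shape"]]
    new("DwellFit", model = "gamma", tau = NA_real_,
        amplitude = NA_real_, shape = shape, scale = 1 / rate,
        shapeCI = shape + c(-1, 1) * qnorm(0.975) * se,
        logLik = as.numeric(fit$loglik), n = length(x))
  }
}

#' Compare exponential and gamma dwell models
#'
#' Fits both models, runs the likelihood-ratio test of the nested
#' exponential (gamma with shape 1) against the gamma, and reports the
#' histogram mode (bin-midpoint of the modal bin) used to flag peaked,
#' non-exponential dwell distributions.
#'
#' @param table DwellTable from [dwellTimes()].
#' @param nBins histogram bins (default 30).
#' @return list(exponential, gamma = [DwellFit-class] objects,
#'   lrtStat, lrtP, histMode, modalBin).
#' @export
compareDwellModels <- function(table, nBins = 30L) {
  fe <- fitDwells(table, "exponential", nBins = nBins)
  fg <- fitDwells(table, "gamma", nBins = nBins)
  stat <- 2 * (fg@logLik - fe@logLik)
  p <- pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  x <- table$duration_s[!table$censored]
  h <- hist(x, breaks = nBins, plot = FALSE)
  modal <- which.max(h$counts)
  list(exponential = fe, gamma = fg, lrtStat = stat, lrtP = p,
       histMode = h$mids[modal], modalBin = modal)
}

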