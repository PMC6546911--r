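## CSV interfaces. Convention at every reader/writer: frames 0-based,
## times in seconds, FRET dimensionless.

.TRACE_HEADER <- c("trace_id", "frame", "time_s", "donor", "acceptor")

#' Write traces as CSV
#'
#' Dialect: header \code{trace_id,frame,time_s,donor,acceptor}, UTF-8,
#' frames 0-based. Round-trips losslessly through [readTraces()].
#'
#' @param traces list of [Trace-class].
#' @param path destination CSV.
#' @export
writeTraces <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(trace_id = tr@traceId,
               frame = seq_along(tr@time) - 1L,
               time_s = tr@time, donor = tr@donor,
               acceptor = tr@acceptor, stringsAsFactors = FALSE)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTraces
#' @return \code{readTraces}: list of [Trace-class], frames sorted.
#' @export
readTraces <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.TRACE_HEADER, names(df))
  if (length(missing))
    stop("malformed trace CSV: missing column(s) ",
         paste(missing, collapse = ", "))
  ids <- unique(df$trace_id)
  lapply(ids, function(id) {
    sub <- df[df$trace_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    new("Trace", traceId = as.character(id), time = sub$time_s,
        donor = sub$donor, acceptor = sub$acceptor, metadata = list())
  })
}

#' Write a simulation ground-truth sidecar table
#'
#' One row per trace: donor count, true association/dissociation frames
#' (0-based, NA when absent), scheme name.
#'
#' @param traces list of simulated [Trace-class].
#' @param path destination CSV.
#' @export
writeTruthSidecar <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    md <- tr@metadata
    data.frame(
      trace_id = tr@traceId,
      scheme = if (is.null(md$schemeName)) NA_character_ else
        md$schemeName,
      donor_count = if (is.null(md$donorCount)) NA_integer_ else
        md$donorCount,
      association_frame = if (is.null(md$associationFrame) ||
                              is.na(md$associationFrame)) NA_integer_
        else md$associationFrame - 1L,
      dissociation_frame = if (is.null(md$dissociationFrame) ||
                               is.na(md$dissociationFrame)) NA_integer_
        else md$dissociationFrame - 1L,
      stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write FRET traces as CSV
#'
#' Columns: trace_id, frame (0-based), time_s, efficiency (empty outside
#' the valid window), total_intensity.
#'
#' @param fretTraces list of [FretTrace-class].
#' @param path destination CSV.
#' @export
writeFretTraces <- function(fretTraces, path) {
  df <- do.call(rbind, lapply(fretTraces, function(ft)
    data.frame(trace_id = ft@traceId, frame = seq_along(ft@time) - 1L,
               time_s = ft@time, efficiency = ft@efficiency,
               total_intensity = ft@totalIntensity,
               stringsAsFactors = FALSE)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a heat map (or TDP) matrix as CSV
#'
#' Rows = FRET bins (bin centers as row names), columns = time bins (heat
#' map) or arrival-FRET bins (TDP).
#'
#' @param object a [SyncHeatMap-class] or [TDPHistogram-class].
#' @param path destination CSV.
#' @export
writeMatrixCsv <- function(object, path) {
  if (is(object, "SyncHeatMap")) {
    m <- object@density
    rn <- object@fretBreaks[-length(object@fretBreaks)] +
      diff(object@fretBreaks) / 2
    cn <- object@timeBreaks[-length(object@timeBreaks)] +
      diff(object@timeBreaks) / 2
  } else if (is(object, "TDPHistogram")) {
    m <- object@counts
    rn <- cn <- object@breaks[-length(object@breaks)] +
      diff(object@breaks) / 2
  } else stop("unsupported object")
  dimnames(m) <- list(format(rn, trim = TRUE),
                      format(cn, trim = TRUE))
  write.csv(m, path, quote = FALSE)
  invisible(path)
}

#' Write decoded paths as CSV
#'
#' Columns: trace_id, frame (0-based, absolute within the source trace),
#' state (sorted-by-mean index), max_posterior.
#'
#' @param decodedPaths list of [DecodedPath-class].
#' @param fretTraces matching list of [FretTrace-class] (for window
#'   offsets).
#' @param path destination CSV.
#' @export
writeDecodedPaths <- function(decodedPaths, fretTraces, path) {
  df <- do.call(rbind, lapply(seq_along(decodedPaths), function(i) {
    dp <- decodedPaths[[i]]; ft <- fretTraces[[i]]
    if (!length(dp@states)) return(NULL)
    vw <- ft@validWindow
    data.frame(trace_id = dp@traceId,
               frame = seq.int(vw[1], vw[2]) - 1L,
               state = dp@states,
               max_posterior = apply(dp@posterior, 1, function(r)
                 if (anyNA(r)) NA_real_ else max(r)),
               stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
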