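#' @importFrom stats kmeans dnorm
NULL

## Maximum-likelihood Gaussian-emission HMM, shared across traces:
## Baum-Welch EM (scaled forward-backward in compiled code), multi-restart,
## Viterbi decoding with posterior marginals, and BIC model selection.

## contiguous non-NA observation runs (length >= 2) inside the valid
## window of each FretTrace; returns concatenated obs + lengths + a map
## back to (trace, frames)
.obsRuns <- function(fretTraces) {
  xs <- list(); lens <- integer(); map <- list()
  for (i in seq_along(fretTraces)) {
    ft <- fretTraces[[i]]
    vw <- ft@validWindow
    if (any(is.na(vw))) next
    idx <- seq.int(vw[1], vw[2])
    ok <- !is.na(ft@efficiency[idx])
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= 2L)) {
      frames <- idx[starts[j]:ends[j]]
      xs[[length(xs) + 1L]] <- ft@efficiency[frames]
      lens <- c(lens, length(frames))
      map[[length(map) + 1L]] <- list(trace = i, frames = frames)
    }
  }
  list(x = unlist(xs), len = lens, map = map)
}

## sort HMM parameters by emission mean
.sortByMean <- function(mu, sigma, A, pi0) {
  o <- order(mu)
  list(mu = mu[o], sigma = sigma[o], A = A[o, o, drop = FALSE],
       pi0 = pi0[o])
}

#' Fit a shared Gaussian-emission HMM to FRET traces
#'
#' Baum-Welch expectation-maximization over all analyzable frames of all
#' traces (parameters shared across traces; each contiguous observation
#' run is one independent sequence). Scaled forward-backward recursions
#' run in compiled code. Multiple random restarts guard against local
#' optima; the restart with the best log-likelihood is kept. States are
#' reported sorted by emission mean.
#'
#' @param fretTraces list of [FretTrace-class] (valid windows set, e.g.
#'   by [qcTrace()]).
#' @param K number of states (>= 1).
#' @param init "kmeans" (default: k-means centers on the pooled
#'   observations, jittered on later restarts), "quantile" (spread over
#'   observation quantiles), or a numeric vector of K initial means.
#' @param tol relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param maxIter EM iteration cap (default 200).
#' @param nRestarts random restarts (default 5).
#' @param seed integer seed for restart jitter.
#' @return an [HMMModel-class]; \code{converged} is FALSE if no restart
#'   converged within \code{maxIter}.
#' @export
fitHmm <- function(fretTraces, K, init = "kmeans", tol = 1e-6,
                   maxIter = 200L, nRestarts = 5L, seed = 1L) {
  if (!length(fretTraces)) stop("empty trace set")
  stopifnot(K >= 1L)
  obs <- .obsRuns(fretTraces)
  if (!length(obs$x)) stop("no analyzable frames in any trace")
  x <- obs$x; lens <- obs$len
  n <- length(x)
  if (K == 1L) {
    mu <- mean(x); sd0 <- max(sd(x), 1e-4)
    ll <- sum(dnorm(x, mu, sd0, log = TRUE))
    return(new("HMMModel", K = 1L, means = mu, sds = sd0,
               transMat = matrix(1, 1, 1), initProb = 1,
               logLikTrail = ll, converged = TRUE, nObs = n))
  }
  best <- NULL
  for (r in seq_len(nRestarts)) {
    withSeed(childSeed(seed, "hmm", r), {
      if (is.numeric(init) && length(init) == K) {
        mu <- init + if (r > 1) rnorm(K, 0, 0.02) else 0
      } else if (identical(init, "kmeans")) {
        mu <- sort(kmeans(x, K, nstart = 5)$centers[, 1])
        if (r > 1) mu <- mu + rnorm(K, 0, 0.03)
      } else {
        mu <- as.numeric(quantile(x, probs = (seq_len(K) - 0.5) / K))
        if (r > 1) mu <- mu + rnorm(K, 0, 0.05)
      }
      sigma <- rep(max(sd(x) / K, 1e-3), K)
      A <- matrix(0.05 / (K - 1), K, K); diag(A) <- 0.95
      pi0 <- rep(1 / K, K)
      trail <- numeric(); conv <- FALSE; llPrev <- -Inf
      for (it in seq_len(maxIter)) {
        es <- .hmmEStep(x, lens, mu, sigma, A, pi0)
        trail <- c(trail, es$loglik)
        g <- es$gamma
        wk <- colSums(g)
        mu <- as.numeric(crossprod(g, x)) / wk
        sigma <- sqrt(pmax(
          as.numeric(crossprod(g, x^2)) / wk - mu^2, 1e-8))
        sigma <- pmax(sigma, 1e-4)
        A <- es$xiSum / pmax(rowSums(es$xiSum), 1e-300)
        A <- A / rowSums(A)
        pi0 <- es$initSum / sum(es$initSum)
        if (is.finite(llPrev) &&
            abs(es$loglik - llPrev) <= tol * (1 + abs(es$loglik))) {
          conv <- TRUE
          break
        }
        llPrev <- es$loglik
      }
      if (is.null(best) || tail(trail, 1) > tail(best$trail, 1))
        best <- list(mu = mu, sigma = sigma, A = A, pi0 = pi0,
                     trail = trail, conv = conv)
    })
  }
  p <- .sortByMean(best$mu, best$sigma, best$A, best$pi0)
  new("HMMModel", K = as.integer(K), means = p$mu, sds = p$sigma,
      transMat = p$A, initProb = p$pi0 / sum(p$pi0),
      logLikTrail = best$trail, converged = best$conv, nObs = n)
}

#' Decode a trace with a fitted HMM
#'
#' Viterbi most-probable path plus forward-backward posterior marginals
#' over the trace's valid window. Frames inside the window that carry no
#' FRET value (signal dips) get NA state and NA posteriors; each
#' contiguous run is decoded as its own sequence.
#'
#' @param model an [HMMModel-class].
#' @param fretTrace a [FretTrace-class].
#' @return a [DecodedPath-class]; \code{states} has one entry per frame
#'   of the valid window.
#' @export
decodePath <- function(model, fretTrace) {
  stopifnot(is(model, "HMMModel"), is(fretTrace, "FretTrace"))
  vw <- fretTrace@validWindow
  if (any(is.na(vw)))
    return(new("DecodedPath", traceId = fretTrace@traceId,
               states = integer(), posterior = matrix(numeric(), 0,
                                                      model@K)))
  idx <- seq.int(vw[1], vw[2])
  nW <- length(idx)
  states <- rep(NA_integer_, nW)
  post <- matrix(NA_real_, nW, model@K)
  obs <- .obsRuns(list(fretTrace))
  for (j in seq_along(obs$map)) {
    frames <- obs$map[[j]]$frames
    e <- fretTrace@efficiency[frames]
    if (length(e) != length(frames) || anyNA(e))
      stop("model/trace mismatch while decoding")
    v <- .hmmViterbi(e, model@means, model@sds, model@transMat,
                     model@initProb)
    es <- .hmmEStep(e, length(e), model@means, model@sds,
                    model@transMat, model@initProb)
    pos <- match(frames, idx)
    states[pos] <- v
    post[pos, ] <- es$gamma
  }
  new("DecodedPath", traceId = fretTrace@traceId, states = states,
      posterior = post)
}

#' Select the number of HMM states by information criterion
#'
#' Fits each K in \code{kRange} and returns the K minimizing BIC
#' (default) or AIC over converged fits (all fits if none converged).
#' Parameter count: (K - 1) initial + K (K - 1) transition + 2 K
#' emission parameters.
#'
#' @param fretTraces list of [FretTrace-class].
#' @param kRange integer vector of candidate state counts.
#' @param criterion "BIC" or "AIC".
#' @param ... passed to [fitHmm()].
#' @return list(K = chosen K, models = all fitted models, score = named
#'   criterion values).
#' @export
selectModel <- function(fretTraces, kRange = 1:4,
                        criterion = c("BIC", "AIC"), ...) {
  criterion <- match.arg(criterion)
  models <- lapply(kRange, function(K) fitHmm(fretTraces, K, ...))
  names(models) <- paste0("K", kRange)
  n <- models[[1]]@nObs
  score <- vapply(models, function(m) {
    p <- (m@K - 1) + m@K * (m@K - 1) + 2 * m@K
    ll <- tail(m@logLikTrail, 1)
    if (criterion == "BIC") -2 * ll + p * log(n) else -2 * ll + 2 * p
  }, numeric(1))
  conv <- vapply(models, function(m) m@converged, logical(1))
  pool <- if (any(conv)) which(conv) else seq_along(models)
  kBest <- kRange[pool[which.min(score[pool])]]
  list(K = kBest, models = models, score = setNames(score,
                                                    names(models)))
}

#' Serialize / restore an HMMModel as JSON
#'
#' @param model an [HMMModel-class].
#' @param file destination path.
#' @export
writeHmmModel <- function(model, file) {
  jsonlite::write_json(list(
    K = model@K, means = model@means, sds = model@sds,
    transMat = model@transMat, initProb = model@initProb,
    logLik = tail(model@logLikTrail, 1), converged = model@converged,
    nObs = model@nObs), file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeHmmModel
#' @export
readHmmModel <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("HMMModel", K = as.integer(j$K), means = j$means, sds = j$sds,
      transMat = matrix(j$transMat, j$K, j$K), initProb = j$initProb,
      logLikTrail = j$logLik, converged = j$converged,
      nObs = as.integer(j$nObs))
}
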