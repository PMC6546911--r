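## Spot detection and two-channel colocalization for TIRF movies:
## difference-of-Gaussians band-pass on a temporal projection, robust
## (median + k*MAD) thresholding, sub-pixel centroid refinement, mutual
## nearest-neighbor pairing, and aperture photometry with annulus
## background subtraction.

## separable Gaussian convolution with edge replication
.gaussKernel1d <- function(sigma) {
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-hw:hw)^2) / (2 * sigma^2))
  k / sum(k)
}

.convSep <- function(img, sigma) {
  k <- .gaussKernel1d(sigma)
  hw <- (length(k) - 1L) / 2L
  padIdx <- function(n) c(rep(1L, hw), seq_len(n), rep(n, hw))
  ## rows
  p <- img[padIdx(nrow(img)), , drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (j in seq_along(k))
    out <- out + k[j] * p[j:(j + nrow(img) - 1L), , drop = FALSE]
  ## cols
  p <- out[, padIdx(ncol(img)), drop = FALSE]
  out2 <- matrix(0, nrow(img), ncol(img))
  for (j in seq_along(k))
    out2 <- out2 + k[j] * p[, j:(j + ncol(img) - 1L), drop = FALSE]
  out2
}

#' Detect diffraction-limited spots in an image stack
#'
#' Projects the stack over time (mean or max), band-passes with a
#' difference of Gaussians (sigma and 1.6 * sigma), keeps local maxima
#' exceeding median + kMad * MAD of the filtered image, and refines each
#' to a sub-pixel intensity centroid in a (2 * ceil(2 sigma) + 1)-pixel
#' window.
#'
#' @param stack height x width x frames array (or a single matrix).
#' @param sigma expected PSF sd in pixels (default 1.2).
#' @param kMad threshold multiplier over the MAD (default 6).
#' @param projection "mean" or "max" temporal projection.
#' @return a SpotTable data.frame: x, y (sub-pixel, 1-based pixel-center
#'   coordinates), peak_frame (frame of maximum aperture-free pixel
#'   intensity at the spot), quality (filtered-image peak height over
#'   MAD). Zero rows (e.g. on a constant image) is a valid result.
#' @export
detectSpots <- function(stack, sigma = 1.2, kMad = 6,
                        projection = c("mean", "max")) {
  projection <- match.arg(projection)
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  if (length(dim(stack)) != 3L || any(dim(stack) == 0))
    stop("stack must be a non-empty height x width x frames array")
  proj <- apply(stack, c(1, 2), if (projection == "mean") mean else max)
  dog <- .convSep(proj, sigma) - .convSep(proj, 1.6 * sigma)
  madv <- mad(dog)
  thr <- median(dog) + kMad * madv
  h <- nrow(dog); w <- ncol(dog)
  ## 8-neighborhood local maxima (strict against ties off-center)
  cand <- which(dog > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < h &
               cand[, 2] > 1 & cand[, 2] < w, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; cc <- cand[i, 2]
    nb <- dog[(r - 1):(r + 1), (cc - 1):(cc + 1)]
    keep[i] <- dog[r, cc] >= max(nb)
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand))
    return(data.frame(x = numeric(), y = numeric(),
                      peak_frame = integer(), quality = numeric()))
  ## centroid refinement on the background-subtracted projection
  hw <- ceiling(2 * sigma)
  base <- median(proj)
  out <- lapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; cc <- cand[i, 2]
    rows <- max(1, r - hw):min(h, r + hw)
    cols <- max(1, cc - hw):min(w, cc + hw)
    patch <- pmax(proj[rows, cols, drop = FALSE] - base, 0)
    tot <- sum(patch)
    if (tot <= 0) return(c(cc, r, 0))
    c(sum(outer(rep(1, length(rows)), cols) * patch) / tot,
      sum(outer(rows, rep(1, length(cols))) * patch) / tot,
      dog[r, cc] / max(madv, .Machine$double.eps))
  })
  out <- do.call(rbind, out)
  ## merge detections collapsing to the same centroid
  ord <- order(-out[, 3])
  out <- out[ord, , drop = FALSE]
  cand <- cand[ord, , drop = FALSE]
  sel <- rep(TRUE, nrow(out))
  if (nrow(out) > 1) for (i in 2:nrow(out)) {
    d <- sqrt((out[seq_len(i - 1), 1] - out[i, 1])^2 +
              (out[seq_len(i - 1), 2] - out[i, 2])^2)
    if (any(sel[seq_len(i - 1)] & d < 2 * sigma)) sel[i] <- FALSE
  }
  out <- out[sel, , drop = FALSE]
  cand <- cand[sel, , drop = FALSE]
  peakFrame <- vapply(seq_len(nrow(cand)), function(i)
    which.max(stack[cand[i, 1], cand[i, 2], ]), 1L)
  data.frame(x = out[, 1], y = out[, 2], peak_frame = peakFrame,
             quality = out[, 3])
}

#' Pair spots across two registered channels
#'
#' Mutual-nearest-neighbor matching: a pair (a, b) is kept iff b is a's
#' nearest neighbor in the other table, a is b's, and their distance is at
#' most \code{radius}. Each spot joins at most one pair. An optional
#' constant channel offset (dx, dy), applied to table b before matching,
#' is the registration hook.
#'
#' @param spotsA,spotsB SpotTable data.frames (see [detectSpots()]).
#' @param radius maximum pairing distance, pixels.
#' @param offset numeric(2) shift added to spotsB coordinates
#'   (default c(0, 0)).
#' @return data.frame with columns idx_a, idx_b (row indices into the
#'   input tables), x_a, y_a, x_b, y_b, distance.
#' @export
colocalize <- function(spotsA, spotsB, radius, offset = c(0, 0)) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("radius must be a single non-negative number")
  empty <- data.frame(idx_a = integer(), idx_b = integer(),
                      x_a = numeric(), y_a = numeric(),
                      x_b = numeric(), y_b = numeric(),
                      distance = numeric())
  if (!nrow(spotsA) || !nrow(spotsB)) return(empty)
  bx <- spotsB$x + offset[1]; by <- spotsB$y + offset[2]
  d <- outer(spotsA$x, bx, "-")^2 + outer(spotsA$y, by, "-")^2
  nnA <- apply(d, 1, which.min)       # nearest b for each a
  nnB <- apply(d, 2, which.min)       # nearest a for each b
  aIdx <- which(nnB[nnA] == seq_len(nrow(spotsA)))
  bIdx <- nnA[aIdx]
  dist <- sqrt(d[cbind(aIdx, bIdx)])
  keep <- dist <= radius
  data.frame(idx_a = aIdx[keep], idx_b = bIdx[keep],
             x_a = spotsA$x[aIdx[keep]], y_a = spotsA$y[aIdx[keep]],
             x_b = spotsB$x[bIdx[keep]], y_b = spotsB$y[bIdx[keep]],
             distance = dist[keep])
}

#' Extract aperture-photometry traces for colocalized spots
#'
#' Per frame and channel: sum of pixels within \code{apertureRadius} of
#' the spot center, minus the median of an annulus
#' (apertureRadius + 2 .. apertureRadius + 4 px) times the aperture area.
#' Spots whose aperture leaves the image are skipped with a warning.
#'
#' @param donorStack,acceptorStack height x width x frames arrays.
#' @param pairs pairing table from [colocalize()]; positions taken from
#'   the a-side (reference channel).
#' @param apertureRadius pixels (default 3).
#' @return list of [Trace-class] (time axis in frames unless
#'   \code{frameInterval} given).
#' @param frameInterval seconds per frame for the time axis (default 1).
#' @export
extractTraces <- function(donorStack, acceptorStack, pairs,
                          apertureRadius = 3, frameInterval = 1) {
  stopifnot(identical(dim(donorStack), dim(acceptorStack)))
  h <- dim(donorStack)[1]; w <- dim(donorStack)[2]
  nFrames <- dim(donorStack)[3]
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    x <- pairs$x_a[i]; y <- pairs$y_a[i]
    rOut <- apertureRadius + 4
    if (x - rOut < 1 || x + rOut > w || y - rOut < 1 || y + rOut > h) {
      warning("aperture outside bounds for pair ", i, "; skipped")
      next
    }
    rows <- floor(y - rOut):ceiling(y + rOut)
    cols <- floor(x - rOut):ceiling(x + rOut)
    dr <- sqrt(outer((rows - y)^2, (cols - x)^2, "+"))
    inAp <- dr <= apertureRadius
    inAnn <- dr > apertureRadius + 2 & dr <= rOut
    nAp <- sum(inAp)
    ch <- function(stack) {
      vapply(seq_len(nFrames), function(f) {
        patch <- stack[rows, cols, f]
        sum(patch[inAp]) - median(patch[inAnn]) * nAp
      }, numeric(1))
    }
    out[[length(out) + 1L]] <- new(
      "Trace", traceId = sprintf("spot_%03d", i),
      time = (seq_len(nFrames) - 1) * frameInterval,
      donor = ch(donorStack), acceptor = ch(acceptorStack),
      metadata = list(x = x, y = y, pair = i))
  }
  out
}
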