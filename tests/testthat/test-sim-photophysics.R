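noiselessModel <- function(...) {
  photophysicsModel(poissonNoise = FALSE, readNoiseSd = 0,
                    backgroundDonor = 0, backgroundAcceptor = 0,
                    donorBleachRate = 0, fixedDonors = 6L, ...)
}

test_that("noiseless forward model obeys the multi-donor algebra", {
  # E = 0, 6 donors, brightness b: donor = 6b, acceptor = 0
  sc <- flatScheme(e = 0)
  p <- simulateStatePath(sc, 5, seed = 1)
  attr(p, "fretMap") <- fretMeans(sc)
  tr <- renderTrace(p, noiselessModel(donorBrightness = 77), seed = 2)
  expect_true(all(donorSignal(tr) == 6 * 77))
  expect_true(all(acceptorSignal(tr) == 0))

  # at any state FRET E: acceptor/(acceptor+donor) = E exactly
  for (e in c(0.34, 0.48, 0.62)) {
    sce <- flatScheme(e = e)
    pe <- simulateStatePath(sce, 5, seed = 1)
    attr(pe, "fretMap") <- fretMeans(sce)
    tre <- renderTrace(pe, noiselessModel(), seed = 2)
    app <- acceptorSignal(tre) / (acceptorSignal(tre) +
                                    donorSignal(tre))
    expect_equal(app, rep(e, length(app)), tolerance = 1e-12)
  }
})

test_that("dark states emit background only", {
  sc <- makeScenario("loading_atpgs")   # UNBOUND then LI1 forever
  m <- photophysicsModel(poissonNoise = FALSE, readNoiseSd = 0,
                         backgroundDonor = 11, backgroundAcceptor = 7,
                         donorBleachRate = 0, fixedDonors = 6L)
  tr <- simulateTraces(sc, 1, 20, m, seed = 3)[[1]]
  assoc <- traceMetadata(tr)$associationFrame
  expect_gt(assoc, 1L)
  pre <- seq_len(assoc - 1L)
  expect_true(all(donorSignal(tr)[pre] == 11))
  expect_true(all(acceptorSignal(tr)[pre] == 7))
  expect_true(all(donorSignal(tr)[-pre] > 11))
})

test_that("mean active donors decays as the exponential survival law", {
  kb <- 0.5
  sc <- flatScheme(e = 0)
  m <- photophysicsModel(poissonNoise = FALSE, readNoiseSd = 0,
                         backgroundDonor = 0, backgroundAcceptor = 0,
                         donorBleachRate = kb, fixedDonors = 6L,
                         donorBrightness = 100)
  nAct <- vapply(1:5000, function(i) {
    p <- simulateStatePath(sc, 2, seed = i)
    attr(p, "fretMap") <- fretMeans(sc)
    tr <- renderTrace(p, m, seed = i + 1e5)
    donorSignal(tr) / 100          # donors active per frame
  }, numeric(20))
  tMid <- (seq_len(20) - 0.5) * 0.1
  for (f in c(5, 10, 20)) {
    expct <- 6 * exp(-kb * tMid[f])
    se <- sd(nAct[f, ]) / sqrt(ncol(nAct))
    expect_lt(abs(mean(nAct[f, ]) - expct), 3 * se)
  }
})

test_that("Poisson plus read noise is centered on the expected signal", {
  sc <- flatScheme(e = 0.34)
  p <- simulateStatePath(sc, 1000, seed = 1)
  attr(p, "fretMap") <- fretMeans(sc)
  m <- photophysicsModel(donorBleachRate = 0, fixedDonors = 6L,
                         backgroundDonor = 20, backgroundAcceptor = 20)
  tr <- renderTrace(p, m, seed = 4)             # 10,000 frames
  expD <- 6 * 100 * (1 - 0.34) + 20
  expA <- 6 * 100 * 0.34 + 20
  n <- length(donorSignal(tr))
  expect_lt(abs(mean(donorSignal(tr)) - expD),
            3 * sd(donorSignal(tr)) / sqrt(n))
  expect_lt(abs(mean(acceptorSignal(tr)) - expA),
            3 * sd(acceptorSignal(tr)) / sqrt(n))
})

test_that("fixed donor count without bleaching gives constant-mean channels", {
  sc <- flatScheme(e = 0.48)
  p <- simulateStatePath(sc, 60, seed = 1)
  attr(p, "fretMap") <- fretMeans(sc)
  m <- photophysicsModel(donorBleachRate = 0, fixedDonors = 6L,
                         backgroundDonor = 0, backgroundAcceptor = 0)
  tr <- renderTrace(p, m, seed = 5)
  half <- length(donorSignal(tr)) %/% 2
  m1 <- mean(donorSignal(tr)[seq_len(half)])
  m2 <- mean(donorSignal(tr)[-seq_len(half)])
  expect_lt(abs(m1 - m2) / m1, 0.05)
})

test_that("binomial labeling matches sites and probability", {
  sc <- flatScheme()
  m <- photophysicsModel(labelProb = 0.6)
  counts <- vapply(1:400, function(i) {
    p <- simulateStatePath(sc, 1, seed = i)
    attr(p, "fretMap") <- fretMeans(sc)
    traceMetadata(renderTrace(p, m, seed = i))$donorCount
  }, integer(1))
  expect_true(all(counts >= 0 & counts <= 6))
  se <- sqrt(6 * 0.6 * 0.4 / 400)
  expect_lt(abs(mean(counts) - 3.6), 3 * se)
})

test_that("rendering is deterministic end to end for a fixed seed", {
  sc <- makeScenario("loading_atp")
  m <- photophysicsModel()
  t1 <- simulateTraces(sc, 3, 20, m, seed = 9)
  t2 <- simulateTraces(sc, 3, 20, m, seed = 9)
  for (i in 1:3) {
    expect_identical(donorSignal(t1[[i]]), donorSignal(t2[[i]]))
    expect_identical(acceptorSignal(t1[[i]]),
                     acceptorSignal(t2[[i]]))
  }
  mv1 <- renderMovie(t1[1:2], list(width = 48, height = 48),
                     psfSigma = 1.2, m, seed = 3)
  mv2 <- renderMovie(t2[1:2], list(width = 48, height = 48),
                     psfSigma = 1.2, m, seed = 3)
  expect_identical(mv1$donor, mv2$donor)
  expect_identical(mv1$truth, mv2$truth)
})

test_that("movies integrate spot amplitude over the PSF and record truth", {
  # zero traces: pure background
  m0 <- photophysicsModel(poissonNoise = FALSE, readNoiseSd = 0,
                          backgroundDonor = 13, backgroundAcceptor = 5)
  mv0 <- renderMovie(list(), list(width = 32, height = 32,
                                  frames = 4L), 1.2, m0, seed = 1)
  expect_true(all(mv0$donor == 13))
  expect_true(all(mv0$acceptor == 5))
  expect_equal(nrow(mv0$truth), 0L)

  # one noiseless spot: 5-sigma aperture recovers the amplitude to 1%
  tr <- constTrace(donor = 500, acceptor = 300, n = 3)
  mv <- renderMovie(list(tr), list(width = 64, height = 64,
                                   positions = matrix(c(32.3, 30.7),
                                                      1, 2)),
                    psfSigma = 1.5,
                    photophysicsModel(poissonNoise = FALSE,
                                      readNoiseSd = 0,
                                      backgroundDonor = 0,
                                      backgroundAcceptor = 0),
                    seed = 2)
  tot <- sum(mv$donor[, , 1])
  expect_lt(abs(tot - 500) / 500, 0.01)
  expect_equal(nrow(mv$truth), 1L)

  # overcrowded field is rejected
  expect_error(
    renderMovie(lapply(1:200, function(i) constTrace(n = 2)),
                list(width = 24, height = 24), 2, m0, seed = 1),
    "too many spots")
})

test_that("movie TIFF round trip preserves counts to 16-bit precision", {
  m <- photophysicsModel()
  tr <- simulateTraces(makeScenario("unloading_atp"), 2, 3, m,
                       seed = 4)
  mv <- renderMovie(tr, list(width = 48, height = 48), 1.2, m,
                    seed = 5)
  f <- tempfile(fileext = ".tif")
  writeMovieTiff(mv$donor, f)
  back <- readMovieTiff(f)
  expect_equal(dim(back), dim(mv$donor))
  expect_lt(max(abs(back - pmax(mv$donor, 0))), 1.01)
})
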