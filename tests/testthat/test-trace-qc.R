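test_that("apparent FRET follows the ratio definition", {
  tr <- vecTrace(donor = c(300, 200, 100), acceptor = c(0, 200, 300))
  ft <- computeFret(tr)
  expect_equal(fretEfficiency(ft), c(0, 0.5, 0.75))
  # backgrounds are subtracted before the ratio
  tr2 <- vecTrace(donor = c(320, 220), acceptor = c(10, 210))
  ft2 <- computeFret(tr2, backgroundDonor = 20,
                     backgroundAcceptor = 10)
  expect_equal(fretEfficiency(ft2), c(0, 0.5))
  # dim frames are no-signal, not fake FRET values
  tr3 <- vecTrace(donor = c(10, 300, 10), acceptor = c(10, 300, 10))
  ft3 <- computeFret(tr3, signalFloor = 50)
  expect_true(is.na(fretEfficiency(ft3)[1]))
  expect_equal(fretEfficiency(ft3)[2], 0.5)
  expect_error(computeFret(vecTrace(numeric(), numeric())),
               "zero-length")
})

test_that("noisy single-state trace averages to the generating FRET mean", {
  sc <- flatScheme(e = 0.34)
  p <- simulateStatePath(sc, 100, seed = 1)
  attr(p, "fretMap") <- fretMeans(sc)
  m <- photophysicsModel(donorBleachRate = 0, fixedDonors = 6L,
                         backgroundDonor = 20, backgroundAcceptor = 20)
  tr <- renderTrace(p, m, seed = 2)
  ft <- computeFret(tr, 20, 20)
  e <- fretEfficiency(ft)
  e <- e[!is.na(e)]
  expect_lt(abs(mean(e) - 0.34), 3 * sd(e) / sqrt(length(e)))
})

test_that("total intensity is invariant to FRET state in noiseless traces", {
  sc <- makeScenario("loading_atp")
  m <- photophysicsModel(poissonNoise = FALSE, readNoiseSd = 0,
                         donorBleachRate = 0, fixedDonors = 6L,
                         backgroundDonor = 20, backgroundAcceptor = 20)
  tr <- simulateTraces(sc, 1, 30, m, seed = 6)[[1]]
  bound <- !is.na(traceMetadata(tr)$trueFret)
  tot <- donorSignal(tr) + acceptorSignal(tr) - 40
  expect_true(all(abs(tot[bound] - 600) < 1e-9))
  expect_true(all(abs(tot[!bound]) < 1e-9))
})

test_that("step counting is exact on noiseless staircases of 1..6 steps", {
  for (n in 1:6) {
    st <- countPhotobleachSteps(staircaseTrace(n))
    expect_equal(st$stepCount, n)
  }
  # constant trace: zero steps
  expect_equal(countPhotobleachSteps(constTrace())$stepCount, 0L)
  # step times align with the constructed bleach boundaries
  st6 <- countPhotobleachSteps(staircaseTrace(6, segLen = 40))
  expect_equal(st6$stepTimes, (seq_len(6) * 40 - 1) * 0.1,
               tolerance = 0.11)
})

test_that("step counting survives noise at 10 percent of step height", {
  st <- countPhotobleachSteps(
    staircaseTrace(3, stepHeight = 100, segLen = 200, noiseSd = 10,
                   seed = 4))
  expect_equal(st$stepCount, 3L)
  # and with the brightness supplied by calibration
  st2 <- countPhotobleachSteps(
    staircaseTrace(3, stepHeight = 100, segLen = 200, noiseSd = 10,
                   seed = 5), singleDonorBrightness = 100)
  expect_equal(st2$stepCount, 3L)
})

test_that("loading selection keeps exactly the six-donor traces", {
  sc <- makeScenario("loading_atp")
  pool <- unlist(lapply(c(4L, 5L, 6L), function(nd) {
    m <- photophysicsModel(fixedDonors = nd, donorBleachRate = 0.02)
    simulateTraces(sc, 12, 240, m, seed = 100 + nd)
  }), recursive = FALSE)
  truth <- vapply(pool, function(t) traceMetadata(t)$donorCount,
                  integer(1))
  sel <- selectTraces(pool, "loading", 20, 20,
                      singleDonorBrightness = 100)
  expect_equal(nrow(sel$report), length(pool))
  kept <- vapply(sel$selected, function(t)
    traceMetadata(t)$donorCount, integer(1))
  expect_true(all(kept == 6L))
  # no systematic loss: most true six-donor traces are retained
  expect_gte(length(kept), 0.75 * sum(truth == 6))

  # unloading mode on the same pool, 10% tolerance
  selU <- selectTraces(pool, "unloading", 20, 20, calibration = 600,
                       tolerance = 0.1)
  keptU <- vapply(selU$selected, function(t)
    traceMetadata(t)$donorCount, integer(1))
  expect_true(all(keptU == 6L))
  expect_error(selectTraces(pool, "unloading", 20, 20), "calibration")
  # empty input: empty output and report
  e <- selectTraces(list(), "loading")
  expect_length(e$selected, 0L)
  expect_null(e$report)
})

test_that("association detection finds the signal onset", {
  # all-background trace: none
  set.seed(7)
  bg <- vecTrace(donor = rpois(200, 20), acceptor = rpois(200, 20))
  expect_true(is.na(detectAssociation(bg)))
  # noiseless step to the six-donor level at frame 100
  x <- c(rep(40, 99), rep(640, 101))
  tr <- vecTrace(donor = x * 0.66, acceptor = x * 0.34)
  expect_equal(detectAssociation(tr), 100L)
  # simulated flow-in: detected within 2 frames of truth in >= 95%
  sc <- makeScenario("loading_atp")
  m <- photophysicsModel(donorBleachRate = 0, fixedDonors = 6L)
  trs <- simulateTraces(sc, 500, 20, m, seed = 21)
  err <- vapply(trs, function(t) {
    d <- detectAssociation(t, background = 40)
    tru <- traceMetadata(t)$associationFrame
    if (is.na(d) || is.na(tru)) NA_real_ else abs(d - tru)
  }, numeric(1))
  expect_gte(mean(err <= 2, na.rm = TRUE), 0.95)
})

test_that("dissociation detection flags single-step trimer release", {
  # noiseless full drop after frame 400
  x <- c(rep(640, 400), rep(40, 100))
  tr <- vecTrace(donor = x * 0.5, acceptor = x * 0.5)
  d <- detectDissociation(tr)
  expect_equal(d$frame, 401L)
  expect_true(d$singleStep)
  # staged loss of 3 monomer-equivalents: not single-step
  xs <- c(rep(640, 300), rep(440, 6), rep(240, 6), rep(40, 100))
  d2 <- detectDissociation(vecTrace(donor = xs * 0.5,
                                    acceptor = xs * 0.5))
  expect_false(d2$singleStep)
  # simulated trimer release with noise
  sc <- makeScenario("unloading_atp")
  m <- photophysicsModel(fixedDonors = 6L, donorBleachRate = 0.005)
  trs <- simulateTraces(sc, 40, 40, m, seed = 22)
  res <- lapply(trs, detectDissociation, background = 40)
  truth <- vapply(trs, function(t)
    traceMetadata(t)$dissociationFrame, integer(1))
  det <- vapply(res, function(r) r$frame, integer(1))
  ok <- !is.na(truth) & !is.na(det)
  expect_gte(mean(abs(det[ok] - truth[ok]) <= 2), 0.9)
  expect_gte(mean(vapply(res[ok], function(r)
    isTRUE(r$singleStep), logical(1))), 0.9)
})

test_that("qcTrace windows run association to first bleach or dissociation", {
  sc <- makeScenario("loading_atp")
  m <- photophysicsModel(fixedDonors = 6L, donorBleachRate = 0.02)
  tr <- simulateTraces(sc, 1, 240, m, seed = 30)[[1]]
  ft <- qcTrace(tr, "loading", 20, 20, singleDonorBrightness = 100)
  vw <- validWindow(ft)
  ann <- traceAnnotations(ft)
  expect_equal(vw[1], ann$associationFrame)
  md <- traceMetadata(tr)
  # window must end before the first true bleach event
  firstBleach <- md$bleachTimes[1]
  expect_lte(traceTime(ft)[vw[2]], firstBleach + 0.2)
  # all E values inside the window are defined
  expect_false(anyNA(fretEfficiency(ft)[vw[1]:vw[2]]))
})

test_that("spot occupancy curves reflect the reaction", {
  mU <- photophysicsModel(fixedDonors = 6L, donorBleachRate = 0)
  # unloader-dead mutant: flat occupancy
  inact <- simulateTraces(makeScenario("unloading_inactive"), 30, 20,
                          mU, seed = 41)
  cInact <- countSpotsOverTime(inact, bin = 1, 20, 20)
  expect_true(all(cInact$count == 30))
  # active unloading: monotone non-increasing within counting noise
  act <- simulateTraces(makeScenario("unloading_atp"), 60, 30, mU,
                        seed = 42)
  cAct <- countSpotsOverTime(act, bin = 2, 20, 20)
  expect_equal(cAct$count[1], 60)
  expect_true(all(diff(cAct$count) <= 1))
  expect_lt(cAct$count[nrow(cAct)], 15)
  # flow-in loading: non-decreasing to a plateau (no bleaching)
  lo <- simulateTraces(makeScenario("loading_atp"), 60, 30, mU,
                       seed = 43)
  cLo <- countSpotsOverTime(lo, bin = 2, 20, 20)
  expect_true(all(diff(cLo$count) >= -1))
  expect_equal(cLo$count[nrow(cLo)], 60)
})

test_that("six-step pass fraction matches the binomial labeling mass", {
  sc <- makeScenario("loading_atp")
  m <- photophysicsModel(labelProb = 0.6, donorBleachRate = 0.05)
  pool <- simulateTraces(sc, 400, 120, m, seed = 51)
  sel <- selectTraces(pool, "loading", 20, 20,
                      singleDonorBrightness = 100)
  phat <- length(sel$selected) / length(pool)
  p6 <- dbinom(6, 6, 0.6)
  se <- sqrt(p6 * (1 - p6) / length(pool))
  expect_lt(abs(phat - p6), 3 * se)
})
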