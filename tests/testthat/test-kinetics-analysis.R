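# small loading ensemble shared by the synchronization / heat-map / TDP
# tests (seeded once; ~100 analyzable traces)
loadEns <- studyEnsemble("loading_atp", 120, 240, seed = 61)
loadFit <- fitHmm(loadEns$fret, 3, seed = 62)
loadDec <- lapply(loadEns$fret, function(f) decodePath(loadFit, f))

test_that("synchronization shifts anchors to zero and conserves traces", {
  al <- synchronize(loadEns$fret, "association")
  expect_equal(al$nTraces + nrow(al$dropped), length(loadEns$fret))
  # the first aligned frame of every trace sits at t = 0
  t0 <- tapply(al$frames$time, al$frames$trace_id, min)
  expect_true(all(abs(t0) < 1e-9))
  # traces without the anchor are dropped with a reason
  blind <- fretFromVector(rep(0.3, 50),
                          annotations = list(associationFrame = NA))
  al2 <- synchronize(list(blind), "association")
  expect_equal(al2$nTraces, 0L)
  expect_equal(al2$dropped$reason, "no_association")
})

test_that("aligned FRET at the anchor frame matches the simulator truth", {
  # per trace: E at the aligned t = 0 frame vs the generating state FRET
  # at the detected association frame (simulator oracle; noise only)
  ids <- vapply(loadEns$selected, traceId, "")
  al <- synchronize(loadEns$fret, "association")
  t0 <- al$frames[abs(al$frames$time) < 1e-9, ]
  diffs <- vapply(seq_len(nrow(t0)), function(r) {
    tr <- loadEns$selected[[which(ids == t0$trace_id[r])]]
    af <- traceAnnotations(loadEns$fret[[
      which(vapply(loadEns$fret, traceId, "") ==
              t0$trace_id[r])]])$associationFrame
    t0$efficiency[r] - traceMetadata(tr)$trueFret[af]
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_gt(length(diffs), 100)
  expect_lt(abs(mean(diffs)), 3 * se + 0.005)
  # and the dominant state at t = 0+ is LI1
  hm <- buildHeatMap(al)
  mo <- heatmapModalFret(hm)
  first <- mo$modal_e[mo$time > 0][1]
  expect_lt(abs(first - 0.48), 0.03)
})

test_that("heat map columns are normalized and locate a constant state", {
  fts <- lapply(1:5, function(i)
    fretFromVector(rep(0.34, 100), id = paste0("c", i),
                   annotations = list(associationFrame = 1L)))
  hm <- buildHeatMap(synchronize(fts, "association"))
  cs <- colSums(heatmapDensity(hm))
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-9))
  mo <- heatmapModalFret(hm)
  occupied <- !is.na(mo$modal_e)
  expect_true(any(occupied))
  expect_true(all(abs(mo$modal_e[occupied] - 0.34) <= 0.02))
})

test_that("loading heat map traverses LI1, LI2, LS in forward order", {
  hm <- buildHeatMap(synchronize(loadEns$fret, "association"))
  mo <- heatmapModalFret(hm)
  post <- mo[mo$time > 0 & !is.na(mo$modal_e), ]
  near <- function(x, v) abs(x - v) <= 0.03
  tLI1 <- post$time[near(post$modal_e, 0.48)][1]
  tLI2 <- post$time[near(post$modal_e, 0.62)][1]
  tLS <- post$time[near(post$modal_e, 0.34)][1]
  expect_false(any(is.na(c(tLI1, tLI2, tLS))))
  expect_lt(tLI1, tLI2)
  expect_lt(tLI2, tLS)
})

test_that("ATP-gamma-S loading stalls at the LI1 level", {
  stall <- studyEnsemble("loading_atpgs", 60, 60, seed = 63,
                         bleachRate = 0)
  fts <- lapply(stall$traces, qcTrace, mode = "unloading",
                backgroundDonor = 20, backgroundAcceptor = 20)
  fts <- Filter(function(f) !any(is.na(validWindow(f))), fts)
  hm <- buildHeatMap(synchronize(fts, "association"))
  mo <- heatmapModalFret(hm)
  post <- mo[mo$time > 0.2 & !is.na(mo$modal_e), ]
  expect_gt(nrow(post), 10)
  expect_true(all(abs(post$modal_e - 0.48) <= 0.03))
})

test_that("a hand-built decoded path yields exactly its two transitions", {
  model <- new("HMMModel", K = 3L, means = c(0.34, 0.48, 0.62),
               sds = rep(0.02, 3),
               transMat = matrix(1 / 3, 3, 3), initProb = rep(1 / 3, 3),
               logLikTrail = 0, converged = TRUE, nObs = 30L)
  s <- rep(c(2L, 3L, 1L), each = 10)      # LI1 -> LI2 -> LS
  ft <- fretFromVector(model@means[s])
  dp <- new("DecodedPath", traceId = "hand", states = s,
            posterior = matrix(1 / 3, 30, 3))
  td <- transitionDensity(list(dp), list(ft), model, 6, "first")
  expect_equal(td@nTransitions, 2L)
  pk <- tdpPeaks(td)
  expect_equal(nrow(pk), 2L)
  expect_true(any(abs(pk$e_before - 0.48) < 0.02 &
                  abs(pk$e_after - 0.62) < 0.02 & pk$count == 1))
  expect_true(any(abs(pk$e_before - 0.62) < 0.02 &
                  abs(pk$e_after - 0.34) < 0.02 & pk$count == 1))
  # zero-transition path: empty histogram
  dp0 <- new("DecodedPath", traceId = "flat", states = rep(1L, 30),
             posterior = matrix(1 / 3, 30, 3))
  td0 <- transitionDensity(list(dp0), list(ft), model)
  expect_equal(td0@nTransitions, 0L)
  expect_equal(sum(tdpCounts(td0)), 0L)
})

test_that("loading TDP peaks are the forward transitions, reverse is rarer", {
  td <- transitionDensity(loadDec, loadEns$fret, loadFit, 6, "first")
  pk <- tdpPeaks(td)
  near <- function(a, b, v1, v2) abs(a - v1) < 0.03 & abs(b - v2) < 0.03
  top2 <- pk[1:2, ]
  expect_true(any(near(top2$e_before, top2$e_after, 0.48, 0.62)))
  expect_true(any(near(top2$e_before, top2$e_after, 0.62, 0.34)))
  fwd <- sum(pk$count[near(pk$e_before, pk$e_after, 0.48, 0.62) |
                      near(pk$e_before, pk$e_after, 0.62, 0.34)])
  rev <- sum(pk$count[near(pk$e_before, pk$e_after, 0.62, 0.48) |
                      near(pk$e_before, pk$e_after, 0.34, 0.62)])
  expect_lt(binom.test(rev, fwd + rev, p = 0.5,
                       alternative = "less")$p.value, 0.01)
})

test_that("TDP transition count equals decoded state changes in the window", {
  td <- transitionDensity(loadDec, loadEns$fret, loadFit, 6, "first")
  manual <- 0L
  for (i in seq_along(loadDec)) {
    s <- decodedStates(loadDec[[i]])
    dt <- traceTime(loadEns$fret[[i]])[2] -
      traceTime(loadEns$fret[[i]])[1]
    nWin <- min(length(s), floor(6 / dt) + 1L)
    if (nWin < 2) next
    ss <- s[seq_len(nWin)]
    manual <- manual + sum(diff(ss) != 0, na.rm = TRUE)
  }
  expect_equal(td@nTransitions, manual)
})

test_that("dwell records carry durations and censoring flags", {
  model <- new("HMMModel", K = 2L, means = c(0.34, 0.58),
               sds = rep(0.02, 2), transMat = diag(2),
               initProb = c(0.5, 0.5), logLikTrail = 0,
               converged = TRUE, nObs = 50L)
  # one 2.0 s run of state 2 strictly inside the window
  s <- c(rep(1L, 10), rep(2L, 20), rep(1L, 20))
  ft <- fretFromVector(model@means[s])
  dp <- new("DecodedPath", traceId = "d", states = s,
            posterior = matrix(0.5, 50, 2))
  dw <- dwellTimes(list(dp), list(ft), 2L, policy = "keep_flagged")
  expect_equal(nrow(dw), 1L)
  expect_equal(dw$duration_s, 2.0)
  expect_false(dw$censored)
  # run truncated by the trace end (no dissociation annotation): censored
  s2 <- c(rep(1L, 30), rep(2L, 20))
  ft2 <- fretFromVector(model@means[s2])
  dp2 <- new("DecodedPath", traceId = "d2", states = s2,
             posterior = matrix(0.5, 50, 2))
  dw2 <- dwellTimes(list(dp2), list(ft2), 2L, policy = "keep_flagged")
  expect_true(dw2$censored)
  expect_equal(nrow(dwellTimes(list(dp2), list(ft2), 2L)), 0L)
  # ...but not when the window closes at the detected dissociation
  ft3 <- fretFromVector(model@means[s2],
                        annotations = list(dissociationFrame = 51L))
  dw3 <- dwellTimes(list(dp2), list(ft3), 2L, policy = "keep_flagged")
  expect_false(dw3$censored)
})

test_that("decoded LI1 dwells agree with the generating time scale", {
  d1 <- dwellTimes(loadDec, loadEns$fret, 2L)
  expect_gt(nrow(d1), 50)
  # generating mean dwell = 1 / exit rate; frame quantization adds
  # about half a frame of upward bias
  se <- sd(d1$duration_s) / sqrt(nrow(d1))
  expect_lt(abs(mean(d1$duration_s) - 0.5), 3 * se + 0.06)
})

test_that("exponential MLE equals the sample mean and recovers tau", {
  tbl <- function(x) data.frame(trace_id = "t", state = 1L,
                                duration_s = x,
                                censored = rep(FALSE, length(x)))
  # constant dwells: tau equals that constant exactly
  fe <- fitDwells(tbl(rep(2.5, 20)), "exponential")
  expect_equal(fe@tau, 2.5)
  expect_equal(fe@n, 20L)
  # large exponential sample: tau within 3 SE, gamma shape CI covers 1
  set.seed(19)
  x <- rexp(10000, rate = 1 / 1.5)
  fx <- fitDwells(tbl(x), "exponential")
  expect_equal(fx@tau, mean(x), tolerance = 1e-12)
  expect_lt(abs(fx@tau - 1.5), 3 * 1.5 / sqrt(10000))
  gx <- fitDwells(tbl(x), "gamma")
  expect_gt(gx@shapeCI[2], 1)
  expect_lt(gx@shapeCI[1], 1)
  expect_error(fitDwells(tbl(rexp(5)), "exponential"), "10")
})

test_that("Erlang dwells are detected as non-exponential with mode > 0", {
  set.seed(20)
  x <- rexp(10000, 1) + rexp(10000, 1)    # Erlang(2), mean 2
  tbl <- data.frame(trace_id = "t", state = 1L, duration_s = x,
                    censored = FALSE)
  cmp <- compareDwellModels(tbl)
  expect_gt(cmp$gamma@shape, 1)
  expect_gt(cmp$gamma@shapeCI[1], 1)
  expect_lt(cmp$lrtP, 0.001)
  expect_gt(cmp$modalBin, 1L)
  expect_gt(cmp$histMode, 0)
})

test_that("UI dwell law is invariant to ATP analog under shared kinetics", {
  pAtp <- lapply(1:1500, function(i)
    simulateStatePath(makeScenario("unloading_atp"), 60, i))
  pGs <- lapply(1:1500, function(i)
    simulateStatePath(makeScenario("unloading_atpgs"), 60, 3000 + i))
  dAtp <- pathDwellTimes(pAtp, "UI")
  dGs <- pathDwellTimes(pGs, "UI")
  ks <- suppressWarnings(ks.test(dAtp$duration_s, dGs$duration_s))
  expect_gt(ks$p.value, 0.01)
  # both peak at a similar non-zero time (shared histogram bins)
  breaks <- seq(0, 60, by = 0.4)
  modeOf <- function(x) {
    h <- hist(x, breaks = breaks, plot = FALSE)
    h$mids[which.max(h$counts)]
  }
  mAtp <- modeOf(dAtp$duration_s)
  mGs <- modeOf(dGs$duration_s)
  expect_gt(mAtp, 0)
  expect_gt(mGs, 0)
  expect_lte(abs(mAtp - mGs), 0.4)
})
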