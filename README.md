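# clampFRET

Single-molecule FRET analysis of DNA sliding-clamp (PCNA) loading and
unloading, packaged with the generative simulator that makes every stage
verifiable by parameter recovery.

PCNA is a homotrimeric ring deposited on primer-template DNA by the RFC
clamp loader and removed by the ATAD5-RLC unloader. With all six
cysteines of the trimer carrying donor dyes and an acceptor on the DNA,
the apparent FRET efficiency `E = I_A / (I_A + I_D)` resolves the
reaction into discrete states: loading passes through a short-lived
intermediate **LI1** (E ≈ 0.48) and a longer-lived intermediate **LI2**
(E ≈ 0.62) before settling in the loaded state **LS** (E ≈ 0.34);
unloading passes through a single intermediate **UI** (E ≈ 0.58) whose
dwell-time distribution peaks at non-zero time (multiple hidden
catalytic sub-steps) before the clamp leaves DNA in one step. With
ATP-γ-S, loading stalls at the LI1 level while unloading still
completes.

The package provides, end to end:

- **`sim_kinetics`** — exact Gillespie simulation of labeled kinetic
  schemes (`makeScenario`, `simulateStatePath`) with Erlang sub-step
  dwells for multi-step intermediates;
- **`sim_photophysics`** — rendering of state paths into donor/acceptor
  traces and two-channel TIRF movies (`renderTrace`, `renderMovie`):
  binomial multi-donor labeling, independent photobleaching, Poisson +
  read noise, ground-truth sidecars;
- **`spot_detection`** — DoG spot detection, mutual-nearest-neighbor
  colocalization against the DNA channel, annulus-corrected aperture
  photometry (`detectSpots`, `colocalize`, `extractTraces`);
- **`trace_qc`** — apparent FRET, photobleaching step counting by
  binary-segmentation change-point detection, six-donor trace
  selection, association/dissociation detection, occupancy curves
  (`computeFret`, `countPhotobleachSteps`, `selectTraces`, `qcTrace`);
- **`hmm_inference`** — shared Gaussian-emission HMM via Baum-Welch
  (compiled forward-backward), Viterbi decoding, BIC model selection
  (`fitHmm`, `decodePath`, `selectModel`);
- **`kinetics_analysis`** — synchronized FRET population heat maps,
  transition density plots, dwell tables with principled censoring, and
  exponential/gamma dwell fits with a likelihood-ratio test
  (`synchronize`, `buildHeatMap`, `transitionDensity`, `dwellTimes`,
  `fitDwells`);
- **`runPipeline`** — a config-driven binding of all stages with a
  master seed, CSV artifacts and a JSON manifest.

## Worked example

Simulate a loading experiment at the reference state efficiencies,
select six-donor traces, and recover the states:

```r
library(clampFRET)

scheme <- makeScenario("loading_atp")      # UNBOUND -> LI1 -> LI2 -> LS
traces <- simulateTraces(scheme, 300, 240,
                         photophysicsModel(fixedDonors = 6), seed = 11)

sel  <- selectTraces(traces, "loading", 20, 20,
                     singleDonorBrightness = 100)
fret <- lapply(sel$selected, qcTrace, mode = "loading",
               backgroundDonor = 20, backgroundAcceptor = 20,
               singleDonorBrightness = 100)
fret <- Filter(function(f) !any(is.na(validWindow(f))), fret)

fit <- fitHmm(fret, K = 3, seed = 5)
fit
#> HMMModel: K = 3, converged (logLik 51378.00 on 21874 frames)
#>   means: 0.34, 0.48, 0.62
#>   sds:   0.0202, 0.0203, 0.0208
```

The three recovered emission means are the loaded state (0.34) and the
two loading intermediates (0.48, 0.62); the ensemble was generated at
exactly those values, so agreement to ±0.02 is the parameter-recovery
check the whole pipeline is built around. Downstream:

```r
decoded <- lapply(fret, function(f) decodePath(fit, f))
plotHeatMap(buildHeatMap(synchronize(fret, "association")))
tdp <- transitionDensity(decoded, fret, fit, 6, "first")
head(tdpPeaks(tdp), 2)
#>   e_before e_after count
#> 1     0.47    0.61   271    # LI1 -> LI2
#> 2     0.61    0.33   212    # LI2 -> LS
fitDwells(dwellTimes(decoded, fret, 2L), "exponential")
#> DwellFit exponential: tau = 0.5651 s (n = 304, logLik -130.51)
```

The methods vignette (`vignettes/clampFRET-methods.Rmd`) documents the
model, the parameter defaults and why, the censoring rules, and known
limitations.

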