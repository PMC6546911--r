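---
title: "Resolving clamp loading and unloading intermediates from smFRET traces"
author: "clampFRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving clamp loading and unloading intermediates from smFRET traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(clampFRET)
```

## The experiment this package models

PCNA is a homotrimeric ring that encircles DNA and slides along it. A
clamp loader (RFC) opens the ring and places it at a primer-template
junction; the unloader ATAD5-RLC removes it. In the single-molecule FRET
geometry modeled here, all six surface cysteines of the trimer carry
donor dyes (Cy3; roughly 1.2 dyes per monomer at 60% per-site labeling),
the DNA carries one acceptor (Cy5) near the primer 3' end, and the DNA is
tethered in a TIRF field. The apparent FRET efficiency
$E = I_A / (I_A + I_D)$ tracks the average distance between the clamp
ring and the acceptor, so conformational stages of loading and unloading
appear as discrete FRET levels:

| state | meaning | mean E |
|---|---|---|
| LI1 | short-lived open-clamp/loader intermediate on DNA | 0.48 |
| LI2 | longer-lived closed-clamp intermediate (after ATP hydrolysis) | 0.62 |
| LS  | fully loaded clamp, loader released | 0.34 |
| UI  | unloading intermediate with the unloader engaged | 0.58 |

Loading proceeds UNBOUND → LI1 → LI2 → LS with rare reverse transitions;
unloading proceeds LS ⇄ UI → released, where the UI dwell is peaked at
non-zero time — the signature of more than one sequential rate-limiting
step inside UI. With the slowly hydrolysable analog ATP-γ-S, loading
stalls at the LI1 level while unloading still completes, placing ATP
hydrolysis between LI1 and LI2 and making it dispensable for unloading.

Because no raw movies are deposited for this system, the package is
built to be *self-verifying*: a generative simulator produces traces and
movies with known ground truth, and every analysis stage is tested by
parameter recovery against that truth.

## The generative model

### Kinetics (`makeScenario`, `simulateStatePath`)

A `KineticScheme` is a labeled continuous-time Markov chain with a
first-order rate matrix, per-state FRET means (dark states carry none),
and a per-state count of hidden irreversible sub-steps. Sampling is
exact Gillespie: in a state with total exit rate $R$ and $m$ sub-steps,
each sub-step dwell is Exponential($Rm$), so the full dwell is
Erlang($m$, $Rm$) with the mean $1/R$ preserved for any $m$; the
successor is drawn proportionally to the outgoing rates. Sub-steps share
one FRET level, which is exactly how a multi-step catalytic intermediate
appears in a FRET trace: one level, a peaked dwell.

No rate constants are established for this system, so the scenario
defaults are pure configuration, chosen to reproduce the qualitative kinetics
(LI1 short-lived, LI2 longer-lived, UI peaked):

* association (flow-in) 1 s⁻¹;
* τ(LI1) = 0.5 s, τ(LI2) = 1.5 s (forward rates 2 and 0.667 s⁻¹);
* LS → UI 0.5 s⁻¹; total UI dwell 2 s over 2 sub-steps;
* reverse transitions at 10% of the forward rate — reverse events are
  observed rarely but their rate is not established, so the ratio is a
  config knob;
* `loading_atpgs` zeroes LI1 → LI2; `unloading_inactive` zeroes the LS
  exit (unloader-dead mutant).

Every acceptance-style test is a parameter-recovery test against these
values, never a test *of* them: changing a default moves the truth and
the recovered value together.

### Photophysics (`photophysicsModel`, `renderTrace`, `renderMovie`)

The donor count per clamp is Binomial(6, 0.6) unless fixed. Donors
contribute additively and bleach independently (one Exponential clock
per dye, started at the association moment, since dyes are only excited
inside the evanescent field); this additivity is what produces the
stepwise donor photobleaching used for trace selection. Per frame, with
$n$ active donors in a state with FRET $E$ and per-donor brightness $b$:

$$\mathbb{E}[I_D] = n\,b\,(1-E) + bg_D, \qquad
  \mathbb{E}[I_A] = n\,b\,E\,\gamma + bg_A,$$

observed as Poisson counts plus Gaussian read noise. Dark states emit
background only. Note the background-corrected total $I_D + I_A$ is
independent of $E$ when $\gamma = 1$: change-points in the total are
association, bleaching, or dissociation events, never FRET dynamics —
the invariant the step counter relies on.

Defaults: 100 photons/frame/donor, backgrounds 20, read noise 2,
$\gamma = 1$ (no detection correction by default), and 0.1 s frames
(a typical TIRF frame time; configurable). Donor bleach rates are
0.02 s⁻¹ (loading; the full six-step bleach ladder must fit inside a
240 s movie) and 0.005 s⁻¹ (unloading; bleaching at least 10× slower
than unloading so that signal loss means release, not bleaching). Acceptor bleaching is off by default and available as a flag.

Movies place each trace as an immobile unit-integral Gaussian spot in
two registered channels with per-pixel backgrounds and the same noise
model; ground-truth positions ship in a sidecar table.

### What the simulator does *not* emulate

No triplet blinking, no spectral cross-talk, no diffusion of the loaded
clamp along DNA (transient FRET excursions on LS are available only as
an optional overlay and default off), no stage drift or defocus, no
EMCCD gain register. Tests passing on these synthetics therefore
demonstrate correctness of the *algorithms* under the stated noise
model, not robustness to every artifact of real TIRF data.

## The analysis pipeline

### Spot detection and trace extraction

Difference-of-Gaussians band-pass on a temporal projection, robust
threshold at median + 6·MAD, 8-neighbor maxima, centroid refinement.
Colocalization is mutual-nearest-neighbor within a radius, with the
acceptor (DNA) channel as the reference set — the surface chemistry
tethers DNA, so DNA spots define where clamps can appear. Intensities
are aperture sums minus a local annulus background. Channel registration
is assumed identity (the simulator renders registered channels); a
constant-offset hook exists, affine registration is out of scope.

### Trace QC

* **FRET**: $E = (I_A - bg_A) / (I_A + I_D - bg_A - bg_D)$; frames below
  a 50-photon total floor are no-signal; $E$ is flagged but not clamped
  outside [0, 1].
* **Step counting**: recursive binary segmentation of the total
  intensity, minimizing within-segment variance; a split must improve
  the cost by more than $10\,\hat\sigma^2 \log n$
  ($\hat\sigma$ = MAD of first differences / √2; the penalty constant
  was set on constructed 3-step staircases at 10% step-height noise and
  lives in config). Only downward steps of at least half the single-donor
  brightness count as bleaching. Two dyes bleaching within the same
  penalty resolution merge into one counted step; this loses a few
  percent of genuine six-dye traces and is why selection retention is
  below one even at a fixed donor count.
* **Selection**: loading keeps step count = 6 exactly; unloading (where
  the clamp leaves before the dyes bleach) keeps traces whose initial
  intensity is within ±20% of the six-donor calibration level. There is
  no canonical tolerance for what counts as a six-donor intensity; ±20%
  sits halfway between the 5- and 6-donor levels.
* **Association / dissociation**: first sustained threshold crossing
  (background + 5·noise SD for 3 frames) and last sustained drop;
  a dissociation is single-step if the signal falls from its pre-drop
  plateau by ≥ 75% within ≤ 2 frames. Per-event disambiguation of
  bleaching vs. unloading is *not* attempted — the experimental design
  separates the time scales instead, and the simulator defaults honor
  that separation.
* **Valid window**: association → first bleach step (loading) or
  → dissociation (unloading). Restricting the HMM to this window is how
  the zero-FRET unbound epoch is excluded without adding a dark state.

### HMM inference

A Gaussian-emission hidden Markov model with parameters shared across
all traces: Baum-Welch EM with scaled forward-backward recursions in
compiled code, k-means initialization plus jittered restarts (5 by
default; k-means initialization matters — quantile spacing can start
two means inside the dominant LS population and EM then converges to a
split-LS local optimum), Viterbi decoding with posterior marginals, and
BIC over a K range when the state count is not fixed. States are always
reported sorted by emission mean, which resolves label switching and
gives the stable mapping loading = (LS, LI1, LI2), unloading = (LS, UI).

Empirical-Bayes variational tools (ebFRET and its relatives) are a
common choice for this segmentation; maximum-likelihood EM with BIC is
used here instead: for
well-separated shared states at this data volume the two agree on the
emission means, which is the quantity everything downstream consumes;
per-trace shrinkage priors are deliberately out of scope.

### Kinetic summaries

* **Synchronized heat maps**: traces aligned at the detected
  association or dissociation moment (t = 0), 2-D histogram over
  (relative time, E), columns normalized to unit mass. Default bins:
  0.02 E over [−0.1, 1.1], 0.2 s over [−2, 10] s (association) or
  [−10, 2] s (dissociation).
* **Transition density plots**: each Viterbi state change inside the
  first/last 6 s window increments the bin at (mean of departing state,
  mean of arriving state); 0.02 E bins. Viterbi (not posterior-weighted)
  transitions are counted; at this state separation the two conventions
  are indistinguishable.
* **Dwell times**: contiguous Viterbi runs × frame interval. A run
  touching a window edge is censored *except* when that edge is the
  molecule's own observed event — a run opening at the association
  moment began there, and a run closing at the dissociation moment ended
  there (the release *is* the exit from UI). Without these exemptions
  nearly every UI dwell would be discarded as censored. Censored dwells
  are dropped by default (`keep_flagged` retains them); the residual
  bias from dropping is small against the 15% recovery tolerance and is
  noted wherever τ values are reported.
* **Dwell fits**: exponential by MLE (τ = sample mean — the histogram
  $A e^{-t/\tau}$ least-squares fit is computed only for figure parity,
  because it depends on binning), gamma by MLE (`MASS::fitdistr`), the
  two compared by a likelihood-ratio test (exponential = gamma with
  shape 1). The exponentiality check is "gamma shape CI covers 1"; the
  multi-step signature is shape > 1, LRT rejection, and a histogram mode
  off the first bin.

## Numerical and design notes

* **Frame quantization of dwells.** Frames are rendered from the state
  at the frame midpoint, so a dwell of length $L$ covers $\approx L/dt$
  midpoints and the decoded dwell mean is close to unbiased; dwells
  shorter than one frame can vanish entirely, leaving a small upward
  bias on short-dwell states. The same quantization *inflates the gamma
  shape* of genuinely exponential dwells a few frames long (the
  geometric run-length distribution is under-dispersed relative to the
  exponential), so the dwell-law tests evaluate exponential vs. Erlang
  on the simulator's continuous dwells, and frame-level dwells are used
  for the τ-recovery checks where the tolerance absorbs the residual
  discretization effects.
* **Problem sizes.** The shipped checks use 300-trace ensembles for
  state-mean recovery (the few-hundred-trace scale such experiments
  typically pool),
  20 × 100-trace replicates for bias, and $10^4$ paths for
  simulator-vs-closed-form oracles; these sizes hold the Monte-Carlo
  error well below the tolerances they are tested against.
* **Determinism.** One master seed spawns per-stage, per-trace child
  seeds through an integer mixing function, so any stage can be
  reproduced in isolation and a re-run with the same config is
  byte-identical at the trace CSV level.
* **Degenerate inputs.** Constant traces yield zero steps (not an
  error); all-background traces yield no association; schemes violating
  an invariant are rejected naming it; dwell fits require ≥ 10
  uncensored dwells; empty spot tables and zero-trace movies are valid.

## A compact worked example

```{r example, eval = FALSE}
scheme <- makeScenario("loading_atp")
model <- photophysicsModel(fixedDonors = 6)
traces <- simulateTraces(scheme, 300, 240, model, seed = 11)

sel <- selectTraces(traces, "loading", 20, 20,
                    singleDonorBrightness = 100)
fret <- lapply(sel$selected, qcTrace, mode = "loading",
               backgroundDonor = 20, backgroundAcceptor = 20,
               singleDonorBrightness = 100)
fret <- Filter(function(f) !any(is.na(validWindow(f))), fret)

fit <- fitHmm(fret, K = 3, seed = 5)
emissionMeans(fit)         # ~ (0.34, 0.48, 0.62)

decoded <- lapply(fret, function(f) decodePath(fit, f))
plotHeatMap(buildHeatMap(synchronize(fret, "association")))
plotTDP(transitionDensity(decoded, fret, fit, 6, "first"))
fitDwells(dwellTimes(decoded, fret, 2L), "exponential")
```

The same flow is packaged as `runPipeline(runConfig(...))`, which writes
trace/QC/model/summary CSVs plus a JSON manifest.

## Known limitations

* Emissions are Gaussian per state; heavy-tailed noise (blinking,
  baseline excursions) is not modeled.
* One transition matrix is shared across traces; molecule-to-molecule
  kinetic heterogeneity would be averaged over.
* The dissociation detector reports events; it cannot tell a
  simultaneous six-dye bleach from release (the time-scale separation
  argument covers this, per-event evidence does not exist).
* Heat-map modal-FRET traces depend on bin width near state boundaries;
  the stage-order checks use the default 0.02 E bins.
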