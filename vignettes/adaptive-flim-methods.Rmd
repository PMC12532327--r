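---
title: "Adaptive intensity-inverted FLIM: models and methods"
author: "flimAdapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive intensity-inverted FLIM: models and methods}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimAdapt)
```

## The problem

Photon-counting FLIM trades three resources against each other: imaging
speed, photon dose, and signal-to-noise ratio. The SNR of a pixel's decay
histogram scales as $\sqrt{N}$ in the detected photons $N$, so in
heterogeneous specimens — where emission rates span orders of magnitude over
micrometres — a uniform-dwell raster scan is always wrong somewhere: bright
pixels are overexposed (photodamage, wasted time) while dim pixels starve
the lifetime estimator. The situation is worst when intensity and lifetime
are anti-correlated, as in tissue autofluorescence where collagen-like
long-lifetime species (2–4 ns) are also the weak emitters: a uniform scan
then systematically loses exactly the species that carry the diagnostic
contrast.

`flimAdapt` implements, as a fully seeded virtual microscope, the adaptive
strategy of planning per-pixel dwell times from a fast uniform pre-scan:
dark-dominated pixels are skipped outright, dim pixels get longer dwells,
bright pixels shorter ones, so that every region-of-interest (ROI) pixel
converges toward one photon target. Because the pre-scan is itself
time-resolved (TCSPC), its photon timings are merged into the adaptive
acquisition rather than discarded.

## The virtual sample and acquisition model

A `SampleModel` holds per-pixel maps of emission rate (detected photons per
µs of dwell at reference excitation; detection efficiency is folded in, so
planner and simulator share one calibration), lifetime (ns, optionally a
two-component mixture), a scalar dark-count rate (DCR, counts/s) and an
excitation scale. The two-species phantom places a contiguous bright,
short-lifetime region (default mean 8.71 photons/µs, $\tau = 0.8$ ns) inside
a dim, long-lifetime region (1.17 photons/µs, $\tau = 2.5$ ns) on an empty
background. Those two rates are calibrated so that a 100 µs dwell yields
region-mean expected counts of 871 and 117 — the bright-scene and low-light
operating points the planner is designed around. A seeded smooth gradient
modulates each region (±60% dim, ±5% bright by default, renormalised so the
region means are exact), giving rates spanning roughly 0.5–9 photons/µs.
The default DCR of 100 counts/s makes expected dark counts at a 100 µs
dwell ≈ 0.01 — a classification floor, not a signal. Deliberately absent:
photobleaching, PSF blur, saturation (the model is the pre-saturation linear
regime), detector afterpulsing and pile-up (mitigated in hardware by SPAD
arrays). Passing tests therefore demonstrate the planner's statistical
mechanics, not robustness to those real-world effects.

Simulated acquisition draws, per pixel at dwell $E$ µs, a signal count
$\mathrm{Pois}(\text{rate}\times\text{scale}\times E)$ and a dark count
$\mathrm{Pois}(\mathrm{DCR}\times E)$. Signal arrival times are exponential
(or a rate-weighted mixture), offset by a fixed detection delay
(`t0Ns`, default 0.55 ns), jittered by a Gaussian IRF ($\sigma$ = 40 ps,
consistent with a sub-100 ps pulse), and wrapped modulo the binned window —
the steady-state incomplete-decay histogram of a 20 MHz excitation. Dark
photons are uniform in time. Defaults are 100 ps bins × 500 (the 50 ns
period); 10 ps binning is available by configuration and is the hardware
floor. Wrapping uses the binned window rather than the raw period so that
`sum(hist) == counts` holds exactly even when the bin width does not divide
the period.

## Exposure planning

Given pre-scan counts $P(m,n)$ at dwell $T_\mathrm{prescan}$, the adaptive
exposure map is

$$E(m,n) = \begin{cases}
  T_\mathrm{baseline}\, I_\mathrm{target} / P(m,n) & P(m,n) > \alpha(m,n)\\
  0 & \text{otherwise,}
\end{cases}
\qquad \alpha(m,n) = \max(\mathrm{DCR}\cdot T_\mathrm{prescan},\,
O_\mathrm{thresh}(m,n)),$$

clamped to $[t_\min, t_\max]$ and then rounded to the nearest dwell step
(clamp-then-round; the order is a package choice — with 1 µs steps it never
matters). The DCR enters as expected counts over the pre-scan dwell, the
only dimensionally consistent comparison with a count map. The ROI
inequality is strict, $T_\mathrm{baseline} = T_\mathrm{prescan}$ by default,
and one photon target is supported (tiered targets are a configuration
extension). Standard settings mirror the low-light protocol: target 250
photons, caps 50/600 µs, 1 µs steps; with caps 50–800 µs against a 100 µs
baseline the per-pixel amplification is bounded by — and reached at —
eight-fold.

$O_\mathrm{thresh}$ comes from an adaptive Otsu scheme: per-block
(default 32 px) thresholds maximising between-class variance, bilinearly
interpolated between block centres; single-level blocks inherit the global
threshold. Two choices here were genuinely open:

* **Block scheme.** Blocks plus bilinear interpolation is one reasonable
  locality scheme; nothing finer is implied by the method itself.
* **Background awareness.** Plain Otsu maximises separation between the two
  heaviest modes. On a three-mode count map (background, dim, bright) with
  substantial bright mass it splits at the *bright* boundary, which would
  discard genuine dim signal — the opposite of "skip what is dark-count
  dominated". The pipeline therefore accepts a split only when its lower
  class is dark-dominated (class mean ≤ $\max(5\,\mathrm{DCR}\,T, 1)$
  counts) and otherwise descends recursively into the lower class (standard
  multi-level Otsu); a block with no background at all is pure signal and
  gets threshold 0. The bare `otsuThreshold()`/`adaptiveOtsu()` operations
  default to the classic single-level form.

A known consequence of inverting a noisy count: since
$\mathrm{E}[1/P] > 1/\mathrm{E}[P]$ for Poisson $P$, re-acquired counts
overshoot the target by a relative $\approx 1/\lambda$ for a pixel with
pre-scan expectation $\lambda$ — about +1% at $\lambda \sim 100$. This is a
property of the ratio formula itself, visible in any sufficiently large
simulation, and is not corrected for (the planner implements the method as
defined).

## Scan waveform synthesis

The exposure map becomes sample-hold X/Y voltage sequences at a fixed output
rate $f$ (default 10 MS/s): pixel $(m,n)$ (0-based, row-major) is held at
$(n V_s, m V_s)$ volts for $f\,E$ samples when its scan-order predecessor is
its immediate left neighbour, and $(f + \beta d)\,E$ samples otherwise,
where $d$ is the Chebyshev distance to the previous visited pixel and
$\beta = 0.02 f$ balances settling of the galvanometers against speed.
Sample counts round to the nearest integer (minimum 1); the first visited
pixel of a frame gets no settling; dwell clocks pulse at each pixel's first
sample and line clocks at each row's first visited pixel (rows with no ROI
pixels emit none). Scan order is unidirectional row-major — path
optimisation (nearest-neighbour, MST) and bidirectional scanning are out of
scope, as is any scanner step-response simulation. A 5-point moving average
(edge-replicated) smooths each voltage trace; at 1000 samples per pixel it
touches at most 6 samples per pixel, so commanded positions are essentially
exact. Predicted frame time is simply waveform length over $f$; a 256×256
raster at 100 µs dwell costs 6.55 s of dwell plus 0.13 s of row-flyback
settling, within the ~7 s envelope of the physical instrument. Voltages are
absolute $nV_s, mV_s$ (optional centring puts mid-frame at 0 V) and are
validated against the ±3 V scanner input range.

## Lifetime estimation

**CMM.** The centre-of-mass estimate is the mean arrival time past the decay
start, corrected for window truncation by solving the truncated-exponential
mean equation $m = \tau - T e^{-T/\tau}/(1 - e^{-T/\tau})$ (monotone 1-D
root find; wrapping at the laser period produces exactly this truncated
form). Implementation choices that matter numerically:

* the anchor is the histogram peak after a light 5-bin smoothing, so it is
  stable at ~250 photons;
* the measurement window opens `startOffset = 2` bins *after* the peak. By
  memorylessness, times past any edge beyond the true origin are again
  exponential, so the estimate is insensitive to where inside the peak bin
  the decay starts (a literal peak-bin anchor carries a ±half-bin ambiguity
  worth ~6% at $\tau = 0.8$ ns) and to IRF jitter, at the price of a few
  early photons;
* times are taken at bin centres relative to the window-start edge, making
  the discrete mean a midpoint-rule estimate of the continuous one (residual
  bias $O(b^2/12\tau)$, about 0.1%);
* a constant expected background per bin may be subtracted (floored at 0).
  This is distinct from the validity noise level: subtracting the validity
  level from sparse decays would clip their tails.

Monte Carlo at the 250-photon operating point shows < 1% mean bias across
$\tau \in \{0.8, 1.5, 2.5, 4.0\}$ ns. The truncation correction is on by
default; at a 50 ns window and $\tau \le 4$ ns its effect is < 1%, but it is
cheap and removes a known bias. CMM assumes one exponential; on mixtures it
returns the intensity-weighted average lifetime, which is what the tests
assert.

**Least squares.** $A e^{-t/\tau} + b$ is fitted on the bins from the peak
by Levenberg–Marquardt with two-pass Poisson weighting: an initial fit
weighted by observed counts (floored at 1), then a refit weighted by the
fitted values. The refit matters: pure observed-count (Neyman) weights bias
$\tau$ low by ~3% even at $10^4$ photons. The fit error is the reduced
chi-square of the refit; the per-pixel `fitError` stored in a
`LifetimeImage` is that value *divided by the pixel's photon count*, a
reliability metric that improves as photons accumulate (plain reduced
chi-square does not — for a correct model its expectation is roughly
photon-independent). Non-convergence marks the pixel invalid.

**Validity.** A pixel supports an estimate when its decay peak is at least
five times the expected per-bin background noise (inclusive), roughly 100
photons at typical settings, plus an optional total-count floor. Lifetime
availability is the valid fraction of all pixels.

## The dual-mode evaluation harness

`runExperimentSuite()` reproduces the two comparison protocols:

* **enhance** (equal time): uniform pre-scan → plan → adaptive scan with
  pre-scan photons merged, against a uniform raster whose dwell is chosen so
  its frame time matches pre-scan + adaptive within 1% (raster time is
  linear in dwell, so matching is exact up to rounding). Reported:
  enhancement (merged ROI mean vs uniform), availability gain, dim/bright
  region fit errors (regions defined by the adapted exposure, > 400 µs and
  < 100 µs), and the count-histogram moments. The report carries three arms;
  the narrower, less skewed "Gaussian around the target" property is
  asserted on the adaptive scan's own histogram, while enhancement uses the
  merged counts (photon reuse).
* **fast** (equal SNR): a uniform raster at the reference dwell against an
  ROI-only scan at the *same* fixed dwell — identical per-pixel statistics,
  frame time bought by skipping background. The speedup compares the two
  scan frame times; the pre-scan is reported separately since it amortises
  over multi-frame acquisitions.

The headline biological numbers of tissue experiments (56% dim-region error
improvement, 27–53% speedups, 117% count increase, 66% availability gain)
are sample properties and are not reproduced quantitatively at desk scale;
the harness asserts their directions of effect on the standard phantom.
Whether the photon target applies to the adaptive scan alone or to merged
counts is unstated in the method; the planner targets the adaptive scan
alone, so merged counts exceed the target by the pre-scan contribution.

## Problem sizes, seeds and limitations

The test suite and the acceptance script use 128×128 phantoms (≈ 7400 ROI
pixels) for convergence checks, 64×64 for the dual-mode experiments, and
replicate fields of 200–2500 pixels for estimator calibration; these sizes
put Monte-Carlo standard errors well below the asserted tolerances while
keeping a full run in tens of seconds. All randomness flows from explicit
seeds; one global seed fans out to per-stage sub-streams so stages can be
re-run independently and reports are bit-reproducible.

Known limitations: no IRF deconvolution (the IRF σ is well under a bin
width at defaults), no phasor or multi-exponential global analysis, no
learning-based segmentation, no scanner dynamics beyond the settling-sample
budget, and TIFF maps are stored as scaled 32-bit integer samples with a
JSON sidecar (exact for count/dwell maps, ~2×10⁻¹⁰ relative otherwise)
because no float-TIFF writer is available in the supported stack.
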