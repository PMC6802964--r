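---
title: "Methods: endocytic trace analysis, single-molecule statistics and calmodulin-IQ binding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: endocytic trace analysis, single-molecule statistics and calmodulin-IQ binding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endotrace)
```

endotrace quantifies the dynamics of the fission-yeast class-I myosin
(Myo1) and its calmodulin light chains (Cam1, Cam2) at sites of
endocytosis, together with the in vitro equilibrium and transient kinetics
of calmodulin binding to the tandem IQ motifs of the Myo1 neck. This
vignette explains the models the package implements, the parameters that
matter, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the design was genuinely open.

## The trace model and ramp-intercept timing

An endocytic event seen by TIRF microscopy is a transient accumulation of
fluorophore-tagged protein at an immobile membrane site: an approximately
linear rise to a plateau of constant copy number, followed by an
approximately linear disassembly. The analysis extracts, per event:

* `T_start` and `T_end` — the zero-intensity intercepts of straight lines
  fitted through the steepest rising and falling stretches of the
  background-corrected trace. The line is fitted in every contiguous
  60-point window (3 s at 20 fps, stride 1) and the window with the
  extreme slope wins; ties break to the earliest window.
* `T_dur = T_end - T_start`.
* `A_av` — the mean intensity from the 5th to the 8th second after
  `T_start` (half-open window, 60 points at 20 fps), the mid-event
  amplitude.
* `a_peak` — the maximum of the 1-s boxcar-smoothed trace, the plateau
  estimate used for molecule counting (below).
* `T_scis` — for proteins that ride the vesicle out of the evanescent
  field, the time of the first frame-to-frame collapse from above 50% to
  below 20% of the plateau within at most 1 s. Gradual disassembly (for
  example a ~3-s fall) never satisfies this and correctly yields no
  scission time.

Baseline intensity is taken as exactly zero after background correction
(core 5x5 sum minus 25x the per-pixel mean of the surrounding 1.5-um
region); a nonzero robust baseline can be passed for real data.

Two deliberate deviations from a purely fixed-window reading of this
procedure, both verified by the oracle tests:

* **Matched windows for brief ramps.** A 60-point line fitted across a ramp
  much shorter than the window leans mostly on baseline and plateau and its
  zero intercept is biased by up to half the ramp duration. `measure_event`
  therefore estimates each ramp's duration from the 10-90% crossing times
  and shrinks the fit window to match when (and only when) the ramp is
  briefer than the window. Events in the regime this package targets
  (>= 3-s ramps) always use the full 60-point window.
* **Counting from the smoothed plateau maximum.** `A_av` is defined on a
  fixed 5-8-s window after `T_start`. For kinetics in which the plateau
  does not span that window (the Cam1 preset's plateau ends ~6.4 s after
  the start), `A_av` mixes plateau and fall and underestimates the copy
  number, so molecule counts are converted from `a_peak` instead. For
  long-plateau events the two agree.

## Molecule counting and the two-illumination calibration

Counts are `amplitude / (single_fluorophore_intensity x excitation_scale)`.
The single-fluorophore intensity is the median over tracked single-molecule
spots of the per-track mean background-subtracted 5x5 intensity —
calibration movies are acquired at full laser power, endocytosis movies at
20%, and `excitation_scale` (default 0.2) assumes linear excitation; it is
explicitly configurable because the appropriate correction is
instrument-specific. Because both the calibration spots and the event ROIs
integrate over a 5x5 core, the fraction of the PSF outside the core (~1%
at the default optics) cancels in the ratio.

## Detection

Candidate sites are local maxima of the per-pixel temporal standard
deviation of the movie above `median + 6 MAD`, non-maximum-suppressed and
refined to the 5x5 centroid. Sites whose 1.5-um background regions are
contaminated by a neighbouring detection are flagged and dropped by
default — the automated counterpart of excluding overlapping events by
hand. Single-particle detection smooths each frame with a Gaussian of
about the PSF scale before thresholding at `median + 5 MAD` (a matched
filter; thresholds are in robust units so they transfer across intensity
scales). A MAD threshold is degenerate on noise-free synthetic frames —
fine in practice, since cameras are never noise-free.

## Tracking, residency and mobility

Linking is greedy mutual-nearest-neighbour within 0.3 um/frame (about five
times the RMS frame step for D = 0.03 um^2/s at 63 fps) with single-frame
gap bridging. Ambiguous assignments — a second candidate inside the search
radius, as when two spots cross — terminate the tracks involved rather
than guess; the cost is a slightly broken track-length distribution, the
benefit is no identity swaps.

Track duration uses the presence-time convention `n_frames x
frame_interval`. The off-rate is the maximum-likelihood exponential rate
for left-truncated data, `k = 1/(mean(d) - d_min)` over durations above the
truncation `d_min` (2 frames by default). Applied to frame-quantized
durations this closed form carries a modest (+6-8% at 63 fps and
k ~ 8 1/s) discretization bias, well inside the tolerances used here; it
is kept because it is exact in the continuous limit and transparent.

Mobility is the ensemble mean-squared displacement over the first 4 lags,
fitted by a weighted line with a free intercept; the slope is `4D` and the
intercept absorbs static localization noise. The intercept route was
chosen over covariance-based estimators as simpler and adequate at these
signal-to-noise ratios.

## Sequential two-site binding with ligand depletion

Calmodulin binds the two IQ motifs strictly sequentially — occupancy of
IQ1 is required before IQ2 can be occupied; there is no IQ2-only species.
With free ligand L the species weights are `1 : L/K1 : L^2/(K1 K2)`, and
the observable is `F = F0 + dF1 f1 + dF2 f2` where `f1` is the fraction
with at least one site occupied and `f2` the fraction with both. Because
titrations are run at reporter concentrations comparable to the
affinities, free ligand is obtained from the mass-conservation closure by
bracketed bisection to 1e-10 relative tolerance (the left side is strictly
increasing, so the root is unique).

Fitting minimizes residuals scaled by the model prediction — the
maximum-likelihood weighting for constant-CV fluorescence noise — with
32 seeded log-uniform multistarts over the dissociation constants.
When the fitted K1 falls below `reporter_total/5` the first site is
stoichiometric: the data bound K1 but cannot locate it, and K1 and K2 are
strongly correlated, which would inflate the K2 variance several-fold. The
fit is therefore repeated with K1 profiled at a representative tight value
(`reporter_total/100`; any sufficiently tight value predicts the same
curve) and K1 is reported as the upper bound `< reporter_total/5` — the
same statement the wet-lab analysis makes when binding is too tight to
measure. An identifiability analysis (Fisher information at the packaged
design: 12 points to 10 uM, 0.5 uM reporter, 2% noise) puts the best
achievable relative SD of K2 near 12-16% even with this profiling; K2
estimates from a single titration at these conditions should be read with
that spread in mind, and the residual-bootstrap CI reported by
`fit_titration` makes it visible.

Calcium dependence is modelled phenomenologically at the titration level,
`Y(pCa) = Ymin + (Ymax - Ymin)/(1 + 10^(n (pCa50 - pCa)))`, with the
transition direction inferred from the data — not via microscopic EF-hand
site constants, for which no parameters are available. FRET efficiencies
convert to distances through `R = R0 (1/E - 1)^(1/6)` with the CyPet-YPet
Forster radius `R0 = 5.301 nm` (the printed value 53.01 is read as
Angstroms, the only physically plausible unit; configurable).

## Multi-exponential transients

Stopped-flow records are fitted with `y(t) = offset + sum A_i exp(-k_i t)`
by Levenberg-Marquardt with seeded multistart: trial rate sets are drawn
log-uniformly over the resolvable range (bounded by the record length and
sampling interval), amplitudes and offset are first solved linearly given
the trial rates, then everything is refined. Amplitude signs are
unconstrained (indicator signals can rise or fall). The number of phases
is chosen by a sequential extra-sum-of-squares F-test at alpha = 0.01
(smallest n not rejected against n+1), with AIC reported alongside; rate
pairs closer than about 2x are not reliably separable and the test suite
asserts that failure as a documented negative control.

## What the generators emulate — and what they do not

The synthetic movies and traces reproduce the statistical structure the
analyses assume: trapezoidal accumulation/disassembly at immobile sites
with event-to-event variability, abrupt single-frame scission loss,
temporally offset two-colour events, Poisson-arriving single molecules
with exponential dwell times and Brownian mobility, pixel-integrated
Gaussian PSFs (sigma 0.09 um, the diffraction-limited value for ~510-nm
emission at NA 1.45; with this sigma at most ~1% of a spot's light falls
outside its 5x5 ROI, so ROI sums conserve flux to within 2% as the tests
require), a constant camera baseline, Poisson shot noise on expected
counts and Gaussian read noise — the standard EMCCD approximation.

Defaults encode the study conditions: 20 fps endocytosis scenes and 63 fps
single-molecule scenes at 0.1 um/pixel; event kinetics per preset (for the
wild-type myosin: 4.42-s rise at 537 AU/s to 2373 AU ~ 45 molecules,
5.24-s plateau, 4.19-s fall, total 13.84 s; scaled analogously for the
Cam1, S742A and Cam2 presets); single molecules at off-rate 7.8 1/s and
D = 0.03 um^2/s; titration and transient presets as in
`inst/extdata/presets.json`. Event-to-event variability is a symmetric
truncated-normal (+/-1.7 SD) scale factor on phase durations plus an
independent factor on peak copy number (CV 0.2) — symmetric truncation
keeps cohort means unbiased by construction; the duration CVs are set so
cohort SEMs at the study sample sizes match the reported ones.

Not emulated: axial optics and the evanescent-field depth (presence is
binary), photobleaching beyond the off-rate, sigmoidal ramp shoulders,
camera gain registers, drift, flat-field structure, and cellular
background heterogeneity beyond a constant offset. Passing tests therefore
demonstrate correctness of the estimators under the stated statistical
model, not robustness to every artefact of real microscopy.

## Problem sizes and reproducibility

Every generator takes an explicit seed and is bitwise reproducible; run
configurations round-trip through YAML and run reports record materialized
parameters and per-trace exclusions. The packaged analyses use the study's
sample sizes (50/52/67 event traces, 65 two-colour pairs, >= 150
single-molecule tracks from a 20-s, 12.8-um scene, 36-site event movies,
12-point titrations, 8-point pCa curves, ~1000-point transients), which
keep any single script or test block in the seconds-to-a-minute range on
one CPU.
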