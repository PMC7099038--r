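---
title: "Quantifying beta-band dynamics under optogenetic perturbation"
author: "BetaOpto authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying beta-band dynamics under optogenetic perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BetaOpto)
```

## The scientific problem

In parkinsonism, cortico-basal-ganglia circuits express exaggerated
synchronised oscillations in the beta band (12--30 Hz) together with firing
rate changes in the subthalamic nucleus (STN) and globus pallidus (GP).
Dissecting which structure *generates* these dynamics requires perturbing
one node at a time with optogenetics while recording a cortical field
potential (ECoG) and single units, and then asking, epoch by epoch: did
beta power change? did firing rates change? did spike--field phase locking
change? BetaOpto implements that analysis chain as composable, tested
functions:

* laser events to Pre/OFF/ON analysis windows with inclusion rules,
* beta-burst detection by envelope percentile thresholding,
* epoch-wise beta power as the area between the spectrum and its band chord
  (beta-AUC), and its per-stimulation difference distributions,
* spike-phase assignment from detected beta peaks and circular statistics
  (Rayleigh test, Watson--Williams F),
* peri-stimulus time histograms (PSTHs) with a 2 SD / 3-consecutive-bin
  response rule and the firing-rate modulation index,
* spike--field coherence with a spike-thinning control for its firing-rate
  bias,
* a synthetic-data generator that emulates the recording conditions, so the
  whole chain is testable end to end without any recording on disk.

## Epoch design

The pulse protocol delivers 2 s of light every 10 s. Each stimulation
contributes three half-open windows: Pre `[onset-4, onset-2)`, OFF
`[onset-2, onset)` and ON `[onset, onset+2)`; a spike or burst on a
boundary belongs to the later window, so nothing is double counted.
Sessions enter the beta analyses only with at least 30 stimulations (60 s
of OFF and of ON). The sinusoidal protocol (20 s of 20 Hz patterned light,
at least 3 blocks) uses the 20 s before onset as OFF baseline and defines
no Pre window; the beta-AUC difference analysis is therefore pulse-only.
Optogenetic control of a structure is accepted only when at least ten
opto-tested cells yielded strictly more than 60% significantly modulated
responses.

## Spectra, beta-AUC and bursts

Field traces are decimated to 500 Hz (staged anti-alias filtering) and
high-pass filtered at 0.5 Hz. Spectra are averaged modified periodograms:
Hann window, 512-point segments, 50% overlap, giving 500/512 = 0.977 Hz
bins; per-bin powers are scaled so that their sum tracks the signal
variance. All analysis filters are 3rd-order Butterworth run
forward--backward: the squared magnitude response costs a slightly softer
band edge but guarantees zero phase, which matters because burst timings
and spike phases are read off filtered traces.

The beta-AUC statistic draws the straight chord between the interpolated
spectrum values at 12 and 30 Hz and integrates the signed difference
between spectrum and chord over the band. The chord absorbs any component
linear in frequency, so a broadband tilt of the background contributes
nothing; a beta bump contributes its full area. Per 2 s epoch the spectrum
uses the same 512-point segment convention (two 50%-overlapping segments
per 1000-sample window); whether the original analysis windowed or
zero-padded its per-epoch FFTs is not documented anywhere we know of, so
this convention is stated here and used consistently.

Bursts are excursions of the beta-band analytic-signal envelope above its
75th percentile, the percentile being computed over the entire recording,
that last strictly longer than 50 ms. Two consequences of that convention
are worth keeping in mind. First, it is scale-free: multiplying the trace
by any constant leaves the burst set unchanged. Second, it is only a
burst/background separatrix when bursts occupy an appreciable fraction of
the recording: if beta is present, say, 2% of the time, the 75th
percentile sits inside the background-envelope distribution and threshold
crossings of the (smooth, band-limited) background routinely exceed 50 ms.
The generator's default burst occupancy (about a quarter of the recording,
see below) reflects the prominent-beta epochs on which such recordings are
selected, and is the regime in which the convention behaves well. The
first and last 0.5 s of the envelope are excluded from thresholding and
detection because the analytic signal is unreliable at the edges.

## Phase locking and circular statistics

Spike phases are assigned cycle by cycle: beta peaks are local maxima of
the 12--30 Hz filtered ECoG exceeding 1 SD of the trace (the source
recordings' threshold is not documented; it is exposed as a parameter),
at least 1/30 s apart; a spike's phase interpolates linearly between the
flanking peaks (peak = 0/360 degrees), and cycles whose period falls
outside 1/30--1/12 s are discarded as non-beta. Peak-referenced
interpolation, rather than analytic-signal phase, is robust to
within-burst frequency jitter.

The circular toolbox is intentionally small: the mean resultant vector
(mean angle, vector length R), the Rayleigh test with `Z = n R^2` and the
standard small-sample corrected p approximation
`exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))`, and the multi-sample
Watson--Williams F test with the `1 + 3/(8 kappa)` correction, kappa
estimated from the pooled within-group resultant. Sampling theory sets
what "recovering" a preferred phase can mean: the asymptotic SD of the
mean direction is `1/sqrt(n kappa A1(kappa))` radians, i.e. 3.8 degrees
at kappa = 1 and n = 500 but under 2.2 degrees for kappa >= 2 — so a
plus-or-minus 5 degree recovery band is reliable from kappa = 2 upward,
and the tests assert exactly that (with the kappa = 1 coverage checked
against its closed-form value instead).

A phase lag converts to a conduction delay as
`delay_ms = lag/360 * 1000/f`; at 20 Hz, 57 and 42 degree lags correspond
to 7.9 and 5.8 ms.

## Rates, PSTHs and the coherence control

PSTHs span [-2, +4) s around laser onset at 50 ms bins; baseline mean and
SD come from the 40 OFF bins. A unit is inhibited (excited) when at least
three consecutive bins within the first 400 ms after onset fall below
(above) baseline by more than 2 SD; when both patterns occur, the
earlier-onset one wins, which matches a response-latency reading of the
histogram. The rule operates on counts, as defined; rates are counts
divided by `n_events * 0.05 s`, so the label would be identical either
way. The modulation index `(f_ON - f_OFF)/(f_ON + f_OFF)` is bounded in
[-1, 1] and antisymmetric.

Spike--field coherence (Welch cross-spectra between the binarised spike
train and the field at 0.977 Hz resolution) increases with firing rate for
a fixed locking strength, so a rate drop alone can masquerade as
desynchronisation. The control is to thin the spike train uniformly at
random (20% or 50%) and re-measure: coherence falls while the circular
mean of the retained spikes is an unbiased subsample of the original.

## What the generator emulates, and what it does not

`genSession()` produces an ECoG as 1/f^2 background (50 microvolt SD) plus
20 Hz bursts with Gaussian envelopes (SD = duration/4, support truncated
at 2 SD), Poisson onsets at 1/s, durations 300 +/- 100 ms, peak amplitude
250 microvolts. These defaults are the package's study conditions, chosen
once: the 1/f^2 slope is the typical cortical field-potential decay above
the low-frequency knee; a quarter-of-the-recording burst occupancy and a
5x-background burst amplitude describe the prominent-beta epochs the
protocols select for. Overlapping bursts are logged as one ground-truth
excursion because they are one excursion in the emitted envelope.

Spike trains are inhomogeneous Poisson, thinned from the rate ceiling,
with rate `base * exp(kappa_eff cos(phase - mu)) / I0(kappa_eff)`. The
concentration is gated by the instantaneous beta envelope
(`kappa_eff = kappa * env/burst_amp`, each sample carrying its own Bessel
normalisation): a unit cannot be entrained by an oscillation that is not
there, and the per-sample normalisation keeps the expected rate equal to
`base` regardless of how sparse the beta is. With a constant weight the
generator reduces to the textbook von Mises modulated process, which is
what `genSpikeTrain()` does when called directly. Laser effects are
multiplicative and instantaneous at epoch edges (opsin kinetics are fast
on the 50 ms bin scale): rates scale by `on_rate_factor`, the beta
component by `on_beta_factor`, inside ON windows only.

The generator is phenomenological. It contains no STN--GP network, no
brain-state transitions, no spike-sorting artefacts, no line noise, and
its background is Gaussian. Passing tests therefore demonstrate that the
analysis chain measures what it claims to measure on data with the assumed
statistical structure -- not that any particular biological conclusion
holds in new recordings.

## Numerical choices and degenerate inputs

* Percentile thresholds use R's default quantile definition; threshold
  crossings are strict, so a constant envelope contains no bursts.
* Burst duration is counted from first to last supra-threshold sample
  inclusive; a one-sample sub-threshold gap splits a burst (no merging
  rule is defined, so none is applied).
* `circMeanR` on an antipodal sample returns R = 0 with an undefined
  (NaN) angle; the Rayleigh p is clamped to (0, 1].
* A zero baseline SD in the PSTH classifies a flat histogram as
  not-modulated, and otherwise classifies against the mean with a warning
  about the degenerate baseline.
* Multiple spikes landing in one 2 ms field sample are clipped to one in
  the coherence binarisation, with a message counting the clips.
* Epochs extending beyond the recording are dropped (with a count), never
  truncated.

## Problem sizes in the tests

The test-suite and the acceptance script run on synthetic sessions of
200--310 s at 500 Hz with 19--30 stimulations and 1--8 units, 1000-replicate
type-I simulations at n = 100, and 20-session null batches; these sizes
put each check's sampling error comfortably inside its assertion band
while keeping a full run in the minutes range on one core.

## Known limitations

* The per-epoch beta-AUC difference CDF comparison inherits a mild
  anticonservatism from the shared OFF epoch in the two difference
  samples; under the null, the two-sample KS test rejects around 7% of
  sessions at the 5% level rather than 5%.
* The burst detector's measured durations are biased slightly short
  whenever burst occupancy exceeds the percentile tail mass (the threshold
  then cuts into burst flanks); at the default conditions the bias is
  under 10%.
* Normalised power spectra as plotted in typical figures are not
  reproduced; the package exposes raw per-bin power (and beta-AUC), since
  plot normalisations are rarely documented.
* No multitaper spectra, artifact rejection, or acquisition-system file
  parsers; sessions enter through the documented directory layout
  (`writeSession`/`readSession`), and an adapter for a vendor format
  should produce that layout.
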