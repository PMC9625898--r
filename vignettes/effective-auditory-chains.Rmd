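---
title: "Effective auditory model chains: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective auditory model chains: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earmod)
```

## The modelling problem

`earmod` simulates monaural auditory processing from the eardrum to the
inferior colliculus with *effective* model chains: small stacks of
functional stages, each of which stands for a physiological process
without simulating its biophysics.  The chain order is fixed — input
level convention, optional middle-ear bandpass, cochlear filterbank,
optional instantaneous compression, inner-hair-cell (IHC) envelope
extraction, auditory-nerve (AN) adaptation, subcortical modulation
selectivity — and each stage is exchangeable through a small spec object.
The package also ships the complete measurement battery used to compare
such chains: excitation patterns, input–output (I/O) curves, Q-factor
estimation from frozen noise, filter counting, AC/DC phase-locking
metrics, adaptation and rate-level analyses, a synchrony-capture
envelope metric, modulation transfer functions (MTFs) and click-train
responses.

The central assumption of the effective family is linearity wherever the
data allow it: the gammatone filterbank is linear and time-invariant, so
cochlear tuning is level-independent by construction, and all
level-dependent behaviour enters through three explicitly nonlinear
elements — the broken-stick compressor, the half-wave rectifier, and the
divisive adaptation loops.

## Stages and their parameters

### Level conventions

Waveforms are sound pressures in Pascal; levels are rms re 20 µPa
(dB SPL).  Chains of the dau1997/king2019/osses2021 style interpret ±1 Pa
as ±0.5 full scale, so `run_chain()` applies a factor 0.5 (−6 dB) to the
input exactly once, tracked in the stimulus metadata; applying it twice
is an error.  This matters because the adaptation loops and the
compressor knee are calibrated in absolute units.

### Cochlear filterbank

The gammatone is realised as a cascade of four identical complex one-pole
resonators (an all-pole design); the real part of the cascade output is
the channel waveform and each channel is normalised to 0 dB gain at its
CF.  The per-section decay is chosen so the filter's equivalent
rectangular bandwidth equals `ERB_N(CF) = 24.7·(4.37·CF/1000 + 1)` Hz,
which puts the −3 dB bandwidth analytically at 0.886·ERB_N (the unit
tests verify the digital realisation against this closed form).  The
default CF grid is 31 channels spaced one ERB-number step apart between
80 and 8000 Hz.

A 401-section human place map
`CF_n = A0·10^(−a·x_n/1000) − A·k` (defaults `A0 = 20682` Hz,
`a = 61.765` 1/m, `k = 0.85`, `A = 165.4188` Hz, `Δx = 0.068` mm,
`x1 = 3.74` mm) provides the section-indexed CFs used by several
analyses; its end points are 12010 Hz and 113 Hz.

### Middle ear and group delay

The middle-ear stage is a Butterworth bandpass (second order per skirt)
matched to the −3 dB cutoffs and passband gain of the published filters
(osses2021-style: 0 dB, 474.8–1230.2 Hz).  Only the cutoffs and mid-band
gain are contractual; the detailed magnitude between them is an
approximation, and waveform-level comparisons through this stage should
be read accordingly.  The osses2021-style chain additionally advances
each channel by its gammatone group delay at CF (`order/(2π·b)` seconds,
truncated at the signal end) to roughly align channel onsets; this is a
documented approximation, not a sample-exact alignment.

### Compression

The broken-stick element is instantaneous and sign-preserving: identity
below the knee, `|y| = knee^(1−c)·|x|^c` above it with `c = 0.3`,
continuous at the knee.  The knee is an instantaneous-amplitude
threshold equal to the peak amplitude of a 30-dB SPL sinusoid *after*
the 0.5 input convention — the published chains state a "calibrated knee
point" without defining the referent, so this package fixes it
explicitly and the I/O tests (0.3 dB/dB growth far above the knee,
1 dB/dB below) pin the behaviour down.

### IHC envelope extraction

Half-wave rectification followed by a lowpass cascade.  Cascade presets
follow the published per-model configurations
(`ihc_preset()`): 1 × order-1 @ 1000 Hz (dau1997, king2019),
7 × order-1 @ 3000 Hz (zilany2014/bruce2018-style), 5 × order-1 @
2000 Hz (osses2021), one order-2 section @ 1000 Hz either as two
cascaded first-order poles (verhulst2015-style, total cutoff ≈ 642 Hz)
or as a maximally flat Butterworth section (relanoiborra2019-style,
total cutoff 1000 Hz) — the distinction matters because the printed
total-structure cutoffs differ while the nominal section parameters
coincide.  `lp_cascade_cutoff()` measures the −3 dB point of the digital
cascade on a fine grid with linear interpolation; its default rate is
100 kHz, the native rate of the high-rate AN implementations these
multi-section cascades describe (at lower rates the bilinear warp moves
the cascade cutoff upward by ~1%).  Within the chains the filters always
run at the chain's own sampling rate.

### Adaptation

Two variants.  The *adaptation loops* are five cascaded divisive
feedback stages with time constants 5/50/129/253/500 ms; each stage
divides the signal by a lowpass-filtered copy of its own output.  The
input floor is the pressure-equivalent amplitude of a 0-dB SPL signal
under the 0.5 convention (`1e-5`); the stationary divisors initialise
the loop states so that silence maps to exactly 0 model units (MU) and a
stationary full-scale input to 100 MU.  Onset overshoots are limited by
a smooth sigmoidal limiter expressed as a multiple of the steady-state
response — 10 for the dau1997-style chain, 5 for the osses2021-style
chain.  These internals follow the canonical published formulation of
the loops; since the constants are not part of this package's own
contract they are all spec fields, and tests that anchor on MU values
carry ±10% tolerances.  With these defaults the onset ceiling of the
dau1997-style chain comes out at ≈1443 MU (the rate-level tests measure
it), emerging from the limiter arithmetic rather than being set
anywhere.

The king2019-style alternative is a first-order 3-Hz highpass, which
removes the envelope DC in steady state and creates onset/offset
transients without saturation.

### Subcortical modulation stage

Resonator modulation filters are second-order complex resonators
(two cascaded identical complex one-poles) with overall −3 dB bandwidth
`BMF/Q`.  The dau-style bank (Q = 2) places centres so adjacent filters
meet at their −3 dB points, which forces the centre ratio
`(2Q+1)/(2Q−1) = 5/3` from 10 Hz upward; the fifth centre lands at
77.16 Hz and is the filter used when a chain targets a best modulation
frequency (BMF) near 80 Hz.  The king-style bank (Q = 1) uses ten
geometrically spaced, 50%-overlapped filters up to 120 Hz; since no
published construction pins its spacing exactly, the package uses
adjacent spacing equal to half the bandwidth (ratio 1 + 1/(2Q)) and does
not anchor any test on that bank's nominal BMF.  Filters with BMF ≥
10 Hz return the phase-insensitive envelope magnitude ("venelope",
nonnegative by construction); below 10 Hz the signed output is returned.
The osses2021-style bank additionally lowpasses its input at 150 Hz and
drops filters whose BMF is not below CF/4.

The SFIE stage convolves its nonnegative drive with unit-area alpha
kernels `t·e^(−t/τ)/τ²`, subtracts the delayed, scaled inhibition and
half-wave rectifies; CN feeds IC.  Unit-area normalisation is a
deliberate choice: the published parameter sets give only τ/D/S, and
normalising the kernels to unit DC gain makes the BMF — the only printed
observable — well defined.  `sfie_bmf()` evaluates the linearised
cascade magnitude `|H_CN·H_IC|`, `H = E − S·I·e^(−j2πfD)`,
`E, I = 1/(1+j2πfτ)²`, on a 1–500 Hz grid at 0.1-Hz resolution.  The
time-domain and analytic routes are cross-checked against each other in
the tests.  Two caveats are worth stating plainly: the idealised alpha
cascade puts the BMF of the inhibition-dominated parameterisation
(CN 0.5/2 ms, D 1 ms, S 0.6; IC 0.5/2 ms, D 2 ms, S 1.5) at 81.6 Hz and
of the excitation-dominated one (IC 1.11/1.67 ms, D 1.1 ms, S 0.9) at
87.2 Hz, about 1% and 4% away from the nominal values quoted for the
original implementations (82.4 and 83.9 Hz).  We probed alternative
kernel normalisations, kernel orders, delays, and rectified time-domain
simulations with peak, rate and synchrony metrics; no single convention
reproduces both quoted values, so the package keeps the clean unit-area
convention and documents the offsets rather than hiding them in a
fitted constant.

## The synthetic-stimulus generator

All experiments run on stimuli the package generates itself:

* pure and AM tones with raised-cosine ramps, calibrated so the rms of
  the *steady (unramped) portion* equals the nominal dB SPL (scaling is
  applied before ramping; with ramps at or below 10% of the duration the
  whole-signal level is within a few tenths of a dB of nominal);
* frozen noise synthesised in the frequency domain — unit magnitude in
  the band, uniformly random phases drawn from a seed — so the long-term
  spectrum is flat by construction and regeneration is bit-identical;
* three-component complex tones with equal component peak amplitudes and
  calibrated total level;
* click trains of alternating polarity (first click positive) whose
  click amplitude is the *peak-to-peak-equivalent* of a sinusoid at the
  stated dB peSPL (`A = 20e-6·10^(peSPL/20)·2√2`; 0.1789 Pa at 70 dB).

What the generator emulates is the stimulus ensemble of a physiology/
psychoacoustics bench: deterministic, narrow-purpose signals.  What it
does not emulate is natural sound — speech, reverberation, free-field
transfer functions — so green tests here demonstrate correctness of the
stages and their interactions under calibrated laboratory stimuli, not
validity of any chain as a model of real-world hearing.

## Measurement procedures and numerical choices

* **Steady-state windows.**  I/O curves and excitation patterns use the
  final 50% of the tone excluding the offset ramp; AC/DC metrics use a
  window starting 30 ms into a 100-ms tone; rate-level traces carry
  50 ms of leading silence so the tone occupies 50–350 ms and the
  plateau window is 300–340 ms; MTFs use 190–290 ms of a 300-ms tone;
  the synchrony metric uses 220–250 ms.
* **Q estimation.**  Six 500-ms non-overlapping windows of a 3-s frozen
  noise; magnitude-squared spectra averaged across windows; a 1/24-octave
  moving average suppresses the residual ripple; −3 dB points found by
  linear interpolation from the smoothed peak outward.  The narrow
  smoother is deliberate: a 1/6-octave average is comparable in width to
  the filters above ~2 kHz and inflates their measured bandwidth by up
  to 40%, while 1/24 octave leaves the measured bandwidth within ~1% of
  the analytic 0.886·ERB_N (the ideal-rectangular-filter test bounds the
  estimator's intrinsic bias).  Channels without a −3 dB crossing are
  flagged, not fatal.
* **Filter counting.**  Greedy covering: the first filter's lower −3 dB
  edge sits at the start frequency; each next CF is placed (by fixed-point
  iteration) so its lower edge equals the previous upper edge; placement
  stops with the first filter reaching the stop frequency.  Bandwidths
  between measured CFs are interpolated linearly in log-CF vs log-Q.
  Note that this construction ties the filter count to the mean
  bandwidth: 34 filters over 126–8000 Hz implies a mean bandwidth near
  0.88 ERB_N, so count and mean cannot be set independently.
* **AC/DC metrics.**  `V_AC = V_peak,max − V_peak,min`,
  `V_DC = (V_peak,max + V_peak,min)/2 − V_rest`, extremes taken over the
  steady window, `V_rest = 0` for these chains.  A consequence worth
  knowing: a half-wave-rectified, first-order-lowpassed response is
  nonnegative, so its ratio is capped at exactly 2 — the low-frequency
  plateau of the dau1997-style chain sits on this cap, and only IHC
  stages that can undershoot (higher-order or biophysical) exceed it.
* **Synchrony metric.**  Local maxima above the window mean, connected
  by linear interpolation on the sample grid; the metric is the standard
  deviation of that envelope divided by scale/30 (scale 800 MU for
  adaptation-loop chains).  Fewer than two qualifying maxima yield 0
  with a warning.
* **Click responses.**  Stage-6 outputs averaged unweighted across the
  31-channel grid; peak-to-peak measured in 50-ms windows after the
  onsets of the last positive and last negative clicks.
* **Degenerate inputs.**  Zero-modulation AM tones equal pure tones;
  single-component complex tones equal pure tones; silence maps to 0 MU
  through the loops; empty chain lists produce empty battery summaries.

## Known limitations

* The middle-ear magnitude response between its cutoffs, and therefore
  absolute waveform shape through that stage, is approximate.
* The SFIE BMFs of the idealised alpha cascade sit ~1–4% from the values
  quoted for the original discrete-time implementations (see above).
* The king-style modulation bank's spacing is a documented convention,
  not a reproduction of the original construction.
* Click-response asymmetries between opposite polarities are sub-1% for
  the osses2021-style chain and their *sign* is not robust at that
  magnitude — it depends on phase details of stages whose exact published
  realisations are not part of this package.
* Biophysical cochleae (transmission lines), chirp-filterbank C1/C2
  paths, diffusion-synapse/spike-generator AN models and
  hearing-impairment configurations are out of scope; where the battery
  refers to such models it only measures the implemented components
  (e.g. their IHC lowpass cascades).

## Problem sizes

All analyses are desk-scale by design: 48-kHz sampling, 31-channel CF
grids, 3-s noises for Q estimation (32 CFs), 25-point MTF grids, 1-s
click trains.  The full battery for one chain completes in seconds on a
single CPU; the entire test suite runs in well under a minute.
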