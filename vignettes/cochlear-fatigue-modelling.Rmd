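---
title: "Modelling noise-induced hearing loss as cochlear fatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling noise-induced hearing loss as cochlear fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Gradually developing noise-induced hearing loss (the kind produced by
years of 85-100 dBA occupational exposure, as opposed to acute acoustic
trauma) can be treated as *high-cycle mechanical fatigue* of the organ of
Corti: each basilar-membrane (BM) vibration cycle is a small load, no
single cycle is damaging, and damage accumulates over very large cycle
counts. `cochfat` implements that idea as a pipeline with three stages.

**1. Outer and middle ear.** Ear-canal pressure `P_EX` is mapped to
tympanic-membrane pressure through an external-ear gain `G_e(f)` and then
to linear stapes velocity `V_S` through the stapes velocity transfer
function SVTF(f) = `V_S / P_TM` ((m/s)/Pa); the stapes footplate area
(2 mm^2) links volume and linear velocity. Both stages are magnitude
curves only, so the package applies them as zero-phase frequency-domain
multiplications with log-frequency interpolation of the tabulated
magnitudes and endpoint clamping. Whether the phase of these stages
matters for fatigue metrics is unknown; zero phase is an explicit
assumption. The packaged chinchilla tables
(`ear_chinchilla_synthetic.yaml`) are *constructed* curves reproducing the
qualitative shape of published chinchilla measurements (band-pass SVTF
peaking near 1 kHz at ~3e-4 (m/s)/Pa, external gain strongly decayed
below 1 kHz, peaking ~10 dB near 4-6 kHz); they are stand-ins, clearly
labelled synthetic, and should be replaced with measured tables for
quantitative cross-species work.

**2. Triple-path nonlinear (TRNL) filterbank.** Each tonotopic channel
models BM velocity at one cochlear place as the sum of three parallel
paths driven by stapes velocity:

* a *linear* path: gain `g`, a cascade of 5 gammatone bandpass sections
  (`cf_lin`, `bw_lin`) and 7 second-order low-pass sections (`lp_lin`);
* a *nonlinear* path: 3 gammatone sections (`cf_nl`, `bw_nl`), a
  broken-stick compressor `y = sign(x) min(a|x|, b|x|^c)`, 3 more
  gammatone sections, and 4 low-pass sections (`lp_nl`);
* an *all-pass* path: a broadband low gain `k`.

The broken stick is linear (slope `a`) below the knee
`|x| = (b/a)^(1/(1-c))` and compressive above it, growing as `|x|^c` with
`c = 0.25`: a 4 dB input increment yields a 1 dB output increment, the
canonical BM compression slope. Channel parameters come from seven
published chinchilla anchor columns (800 Hz-14 kHz,
`trnl_chinchilla.yaml`) interpolated linearly in log frequency; outside
the anchor span the *frequency-valued* fields (CFs, bandwidths, low-pass
cutoffs) scale proportionally with the requested CF while gains are
clamped. The proportional extrapolation is a deliberate design choice:
clamping every field would make all channels below 800 Hz identical
copies of the 800 Hz column, destroying tonotopy at the apex; scaling
with CF is the convention of the DRNL-family literature from which this
filter descends.

Realisation choices that the parameter table does not fix:

* Gammatone sections are complex one-pole resonator cascades (the
  standard all-pole gammatone realisation), normalised analytically so
  each cascade has exactly unit gain at its CF. Real-coefficient biquad
  resonators were rejected: at low CF their conjugate pole boosts the
  below-CF skirt so strongly that a channel responds better one ERB below
  its CF than at it.
* Per-section 3-dB bandwidth equals the tabulated BW; the cascade is
  correspondingly narrower than a single section.
* Low-pass sections are second-order Butterworth (unit DC gain,
  `1/sqrt(2)` at cutoff per section). With the cutoff at CF and 7
  sections, the *composite* channel response peaks 10-25% below the
  nominal CF; this best-frequency shift is a known property of this
  filter family and is why tonotopy tests assert "within one channel"
  rather than exact alignment.
* The all-pass path is a pure broadband gain with zero added delay (no
  cutoff or phase data exist for it).
* Channels sit on the Glasberg-Moore ERB-rate scale, by default 40
  channels from 250 Hz to 16 kHz. A chinchilla-specific ERB map would be
  preferable but is not tabulated; the human scale is the documented
  default.
* The first 50 ms of channel output is discarded for steady-state
  measurements (filter transients); long-signal metrics include
  transients, which are negligible at exposure durations.
* Input units are stapes velocity in m/s; table gains are used verbatim.
  Since both fatigue metrics are referenced (to `V0`/`H0`), a global unit
  rescaling cancels.

**3. Fatigue metrics.** With `V(i, j)` the velocity of ERB channel `i` at
sample `j`:

* **EVL** (equal velocity level, S-N-curve energy metric):
  `L_i = 10 log10( sum_j V(i,j)^2 / V0^2 )`, and for an octave band `I`,
  `L_I = 10 log10( sum_{i in I} sum_j V(i,j)^2 / V0^2 )`.
* **CVL** (complex velocity level, Miner-rule metric): each channel's
  velocity history is reduced by four-point rainflow counting to cycles
  characterised by amplitude (half the peak-valley range) and absolute
  mean of the pair; cycles are binned on a 32 x 32 amplitude x mean grid
  spanning `[0, max observed]` per channel; Miner damage is
  `H_i = sum_cells N * A * M` (count times cell-centre amplitude times
  cell-centre mean), and `L_i = 10 log10(H_i^2 / H0^2)`, with band levels
  summing `H_i^2/H0^2` over member channels. The per-category
  failure-cycle counts of the underlying Miner identity are never
  available numerically; the damage form above *is* the model.

A channel belongs to the octave band centred at `c` iff its CF lies in
`[c/sqrt(2), c*sqrt(2))`. Rainflow residuals count as half-cycles (0.5),
the standard convention. Analysis windows default to 40 s; a series
shorter than one window is analysed whole, longer series are cut into
full windows and window levels are averaged arithmetically. EVL sums run
over raw samples (not envelopes) and rainflow operates on turning points;
both choices are documented defaults where the model statement is silent.

**References V0 and H0.** Both are operationally defined as the
corresponding quantity computed, over one analysis window, from the
channel nearest 1 kHz responding to a calibrated 1 kHz tone (94 dB SPL
by default); `calibrate_references()` computes them, and both can instead
be set as plain constants. By construction the reference condition scores
exactly 0 dB. The choice only shifts all levels by a constant, so it
cancels in regressions against hearing-loss indices — which is also why
the unresolved absolute unit convention of the filter gains is harmless.

Degenerate inputs are handled explicitly: silent input gives `-Inf` with
a warning (EVL and L_Aeq), a constant series gives an empty rainflow
histogram (zero damage), and a perfectly zero-mean steady tone has
near-zero Miner damage because every cycle mean is ~0 — CVL is a metric
of *transitions*, and in practice onset transients and noise give
nonzero means.

## The synthetic-noise family

The validation data come from 22 chinchilla groups exposed to 320-s
noises: 3 Gaussian continuous noises (90, 95, 100 dBA) and 19 complex
noises built by adding impulsive components to a Gaussian bed (one at
95 dBA, two at 90 dBA, sixteen at 100 dBA). The recordings themselves are
not available, so `noise_recipe()`/`generate_noise()` *emulate* the
family: seeded white Gaussian noise calibrated to a target L_Aeq within
0.1 dB; linear chirps; and Gaussian beds plus exponentially decaying tone
bursts (default 5 ms decay, 2 kHz carrier) rescaled to the target L_Aeq,
which raises sample kurtosis above the Gaussian value as impulse peaks
grow. The emulation reproduces the *structure* (level, impulsiveness,
duration) but not the waveforms: impulse repetition rates, spectra and
room acoustics of the original exposures are unknown. Consequently,
passing tests show the pipeline's internal consistency and qualitative
behaviour on this family — they do not certify the published
regression coefficients, which would require the original recordings.
Generator defaults follow the study conditions (320 s duration, the
printed dBA targets); tests and examples use seconds-long scaled
versions, and the methods are duration-invariant by construction
(time-average L_Aeq, windowed metrics).

## Validation machinery

The packaged dataset `chinchilla_hair_cell_loss.csv` holds, for each of
the 22 groups, the exposure L_Aeq and percentage outer/inner hair-cell
loss at the six octave bands 0.5-16 kHz, integrity-checked by MD5 on
load. Per-group PTS/TTS values were not published alongside and are
deliberately absent rather than imputed. The "1248" summary of any index
is the arithmetic mean of its 1, 2, 4 and 8 kHz values. Metrics are
related to indices by single-variable OLS (`y = c0 + c1 x`), with r^2 and
a two-sided t-test on the slope (n-2 degrees of freedom); per-group
pooling (n = 22) is used. `correlate_metrics()` joins metric tables to
the records by group, excludes unmatched groups with a warning, and
degrades gracefully for indices with no stored values.

## Problem sizes and numerical choices

The internal sampling rate is 48 kHz (Nyquist comfortably above the
highest 15 kHz channel); inputs are resampled on load by polyphase
resampling with a rational rate approximation. A-weighting is evaluated
from the analytic IEC pole formula in the frequency domain, normalised to
exactly 0 dB at 1 kHz, making L_Aeq independent of filter-design
toolboxes and (for band-limited signals) of sampling rate. The acceptance
script and test suite run the filterbank at 24-40 channels on 0.25-4 s
stimuli and emulate the exposure family at 4 s per group; these sizes were
chosen so the whole analysis reruns in minutes on a laptop, and all
reported quantities are either closed forms (independent of size) or
qualitative statistics that are stable at these durations.
`run_pipeline()` processes each waveform whole and reduces per-channel
output to metrics immediately, rather than chunking with carried filter
state: at 48 kHz a 320-s exposure occupies ~120 MB per channel-row batch,
well within modern memory, and whole-signal processing keeps the
nonlinear path exactly reproducible regardless of chunk boundaries.

Impulse-response durations are measured as the full width at half maximum
of the Hilbert envelope smoothed over four carrier periods of the channel
CF. The smoothing is not cosmetic: the all-pass path feeds the input
impulse through as a one-sample spike of height `k` (up to 20), which at
low-CF channels rivals the narrowband ringing peak, and a fixed-width
window cannot serve 250 Hz and 16 kHz channels simultaneously.

## Known limitations

* The ear-stage tables are synthetic stand-ins; absolute BM velocities
  (and hence unreferenced levels) are not quantitative.
* The published regression coefficients against hearing-loss indices are
  not reproducible without the original exposure recordings; the
  package's end-to-end regressions on emulated noise demonstrate the
  machinery, not the published effect sizes.
* Recovery/intermittency effects, efferent feedback, two-tone
  suppression and low-cycle (acoustic-trauma) fatigue are out of scope.
* The best-frequency shift below nominal CF (low-pass cutoff at CF) means
  band assignment by nominal CF is approximate at the band edges.
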