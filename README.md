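# cochfat

Auditory-fatigue modelling of gradually developing noise-induced hearing
loss (NIHL). Occupational noise at 85-100 dBA rarely injures the ear in a
single event; damage accumulates over millions of basilar-membrane (BM)
vibration cycles, like high-cycle mechanical fatigue of a material.
`cochfat` turns calibrated acoustic recordings into BM velocity histories
with a chinchilla auditory model, and summarises those histories with two
fatigue-based exposure metrics that can be regressed against hearing-loss
data. It is aimed at hearing-conservation researchers who want a
physically motivated alternative to purely energy-based metrics such as
L_Aeq.

## The model

The pipeline has three stages:

1. **Outer/middle ear** — ear-canal pressure is mapped through an
   external-ear gain G_e(f) and a stapes velocity transfer function
   SVTF(f) = V_S/P_TM to linear stapes velocity (m/s), both applied as
   zero-phase magnitude filters from tabulated curves.
2. **TRNL cochlear filterbank** — each ERB-spaced channel models BM
   velocity at one cochlear place as the sum of three parallel paths: a
   linear gammatone/low-pass path (gain g), a nonlinear path whose
   broken-stick compressor y = sign(x)·min(a|x|, b|x|^c) gives the
   canonical c = 0.25 BM compression, and a broadband low-gain path (k).
   Channel parameters interpolate seven published chinchilla anchor
   columns (800 Hz-14 kHz).
3. **Fatigue metrics** — from the channel-by-time velocity map V(i, j):
   * **EVL** (equal velocity level):
     `L_I,EVL = 10 log10( Σ_{i∈I} Σ_j V(i,j)² / V0² )` per octave band —
     an S-N-curve energy metric;
   * **CVL** (complex velocity level): four-point rainflow counting
     reduces each channel's history to cycles with amplitude A and
     absolute mean M; Miner damage `H_i = Σ_cells N·A·M` gives
     `L_I,CVL = 10 log10( Σ_{i∈I} H_i² / H0² )` — sensitive to the
     *transitions* between loads that make impulsive noise more damaging
     than its energy suggests.

A noise synthesizer (seeded Gaussian noise at a target dBA, chirps,
impulse trains, Gaussian-plus-impulse mixtures) emulates the structure of
the 22 chinchilla exposure noises used for validation, and a packaged
dataset carries each group's exposure level and outer/inner hair-cell
loss at the six octave bands 0.5-16 kHz, together with OLS regression
utilities (r², slope t-test).

## Worked example

```r
library(cochfat)

# a 4-s impulsive exposure at 100 dBA, like the complex noises of the
# validation study (seconds-long stand-in for a 320-s exposure)
rec <- noise_recipe("complex_mix", duration_s = 4, target_dba = 100,
                    impulse_times = c(0.5, 1.5, 2.5, 3.5),
                    impulse_peak_pa = 40, seed = 17)
w <- generate_noise(rec)
compute_leq_a(w)
#> [1] 100

cfg <- run_config(n_channels = 24, out_dir = tempfile("demo_"), seed = 17)
res <- run_pipeline(cfg, list(w), save_maps = FALSE)
subset(res$metrics, band_hz %in% c(500, 1000, 4000))
#>                   file metric band_hz level_db window_s reference
#> 1  complex_100dBA_4imp    EVL     500 -1.49355       40 6.4740576
#> 2  complex_100dBA_4imp    EVL    1000  9.42139       40 6.4740576
#> 4  complex_100dBA_4imp    EVL    4000  7.16108       40 6.4740576
#> 7  complex_100dBA_4imp    CVL     500 28.71180       40 0.0159819
#> 8  complex_100dBA_4imp    CVL    1000 42.61248       40 0.0159819
#> 10 complex_100dBA_4imp    CVL    4000 36.12824       40 0.0159819
```

Band levels are dB re the 1 kHz reference condition (a calibrated 94 dB
SPL tone scores 0 dB by construction). The 500 Hz band sits ~11 dB below
the 1 kHz band under both metrics — the chinchilla external ear strongly
attenuates low frequencies, so little of the exposure's low-frequency
energy ever loads the apex. CVL levels are far above EVL levels for the
same exposure because the impulsive transitions dominate Miner damage;
the two scales are referenced differently (V0 vs H0) and are compared to
hearing loss via regression, where the reference offsets cancel.

Regressing metrics against the packaged hair-cell-loss records:

```r
records <- load_hearing_loss_data()
head(records[, 1:5], 3)
#>   group  laeq ohc_500 ohc_1000 ohc_2000
#> 1   G44 100.6    20.8     38.1     67.9
#> 2   G49 101.0    43.8     54.6     78.3
#> 3   G50 100.5    11.8     21.7     15.0
linear_regression(records$laeq, records$ohc_4000)
#> <regression_result> y = -522.6 + 5.793 x, r^2 = 0.450, p = 0.00063, n = 22
```

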