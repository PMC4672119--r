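# SYNTHETIC chinchilla outer/middle-ear transfer tables.
#
# These curves are constructed stand-ins, not digitized measurements: they
# reproduce the qualitative features reported for chinchilla — an
# external-ear pressure gain that is strongly decayed at low frequency and
# peaks ~10 dB around 4-6 kHz, and a band-pass stapes velocity transfer
# function peaking near 1 kHz at ~3e-4 (m/s)/Pa — but the magnitudes are
# smooth idealisations. Replace with measured tables for quantitative work.
#
# external_ear: [frequency_hz, linear pressure gain P_TM/P_EX]
# middle_ear_svtf: [frequency_hz, (m/s)/Pa]
external_ear:
  - [50, 0.05]
  - [100, 0.10]
  - [250, 0.25]
  - [500, 0.50]
  - [1000, 1.00]
  - [2000, 1.80]
  - [4000, 3.20]
  - [6000, 3.50]
  - [8000, 3.20]
  - [10000, 2.50]
  - [12000, 2.00]
  - [16000, 1.20]
  - [20000, 0.80]
middle_ear_svtf:
  - [50, 2.0e-5]
  - [100, 5.0e-5]
  - [250, 1.5e-4]
  - [500, 2.5e-4]
  - [1000, 3.0e-4]
  - [2000, 2.5e-4]
  - [4000, 1.5e-4]
  - [8000, 8.0e-5]
  - [12000, 5.0e-5]
  - [16000, 3.0e-5]
  - [20000, 2.0e-5]
footplate_area_mm2: 2.0
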