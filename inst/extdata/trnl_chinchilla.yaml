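# Chinchilla TRNL filterbank parameters: seven published anchor columns.
# Frequencies in Hz; gains dimensionless. Cascade orders are constant
# across anchors (5 gammatone + 7 low-pass linear path, 3 gammatone +
# 4 low-pass nonlinear path).
trnl_anchors:
  - {freq: 800,   n_gt_lin: 5, n_lp_lin: 7, cf_lin: 750,   bw_lin: 450,  lp_lin: 750,   g: 500,
     n_gt_nl: 3, n_lp_nl: 4, cf_nl: 730,   bw_nl: 350,  lp_nl: 730,   a: 850,   b: 0.03,  c: 0.25, k: 10}
  - {freq: 5500,  n_gt_lin: 5, n_lp_lin: 7, cf_lin: 5000,  bw_lin: 3000, lp_lin: 6000,  g: 190,
     n_gt_nl: 3, n_lp_nl: 4, cf_nl: 5850,  bw_nl: 1800, lp_nl: 5850,  a: 3000,  b: 0.04,  c: 0.25, k: 0.4}
  - {freq: 7250,  n_gt_lin: 5, n_lp_lin: 7, cf_lin: 7400,  bw_lin: 2500, lp_lin: 7400,  g: 3000,
     n_gt_nl: 3, n_lp_nl: 4, cf_nl: 7800,  bw_nl: 2275, lp_nl: 7800,  a: 15000, b: 0.06,  c: 0.25, k: 20}
  - {freq: 9750,  n_gt_lin: 5, n_lp_lin: 7, cf_lin: 9000,  bw_lin: 3000, lp_lin: 9000,  g: 300,
     n_gt_nl: 3, n_lp_nl: 4, cf_nl: 9800,  bw_nl: 1650, lp_nl: 9800,  a: 9000,  b: 0.05,  c: 0.25, k: 1}
  - {freq: 10000, n_gt_lin: 5, n_lp_lin: 7, cf_lin: 9000,  bw_lin: 3500, lp_lin: 8800,  g: 500,
     n_gt_nl: 3, n_lp_nl: 4, cf_nl: 10000, bw_nl: 1800, lp_nl: 10000, a: 15000, b: 0.06,  c: 0.25, k: 2}
  - {freq: 12000, n_gt_lin: 5, n_lp_lin: 7, cf_lin: 11000, bw_lin: 5000, lp_lin: 12000, g: 500,
     n_gt_nl: 3, n_lp_nl: 4, cf_nl: 12000, bw_nl: 2000, lp_nl: 12000, a: 22500, b: 0.07,  c: 0.25, k: 20}
  - {freq: 14000, n_gt_lin: 5, n_lp_lin: 7, cf_lin: 13000, bw_lin: 4000, lp_lin: 13500, g: 350,
     n_gt_nl: 3, n_lp_nl: 4, cf_nl: 15000, bw_nl: 3200, lp_nl: 15000, a: 3000,  b: 0.045, c: 0.25, k: 20}
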