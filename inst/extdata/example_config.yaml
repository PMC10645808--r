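out_dir: runs/demo
seed: 1
cofactor: 5.0
som_grid:
- 10.0
- 10.0
som_epochs: 10.0
k_range:
- 2
- 3
- 4
- 5
- 6
- 7
- 8
- 9
- 10
- 11
- 12
- 13
- 14
- 15
- 16
- 17
- 18
- 19
- 20
elbow_frac: 0.05
simulate: yes
input_files: ~
patient12_alt: no
include_donors: no
run_expression: yes
thresholds:
  acq_nmad: 5.0
  acq_quantiles: ~
  barcode_cut: 2.0
  osmium_cut: 2.0
  cd45_low: 2.0
  lineage_low: 1.5
  panck_min: 2.0
  auto_marker_cuts: yes
  background_ctc_threshold: 4.0
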