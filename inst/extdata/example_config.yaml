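# Example run configuration for `cc-organotrait run --config ...`.
# Omitted keys fall back to package defaults; `params` entries override
# individual sim_params() fields.
seed: 42
out_dir: study_out
feature_set: paper-text      # or table-caption
label_percentile: 70
heatmaps: true
cv:
  k: 4
  stratified: true
regression:
  iterations: 100
  train_frac: 0.70
params:
  liver:
    sigma_line: 0.15
    sigma_e: 0.10
  glucose:
    hfd_clearance_mult: 1.35
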