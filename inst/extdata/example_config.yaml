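# Example pipeline configuration. Unset fields keep package defaults
# (see ?pipeline_config).
seed: 1
out_dir: tpd-output
coeff_source: two_factor   # two_factor | two_factor_rounded | three_factor | fit
p_target: 0.75
n_bundles: 400
sampling_step_um: 20
mse_bound: 20          # contour acceptance bound, uA (RMSE)
threshold_range: [177, 660]
convention: center     # center | disk_surface | rim
ablations: [none, no_damage, no_lift, neither]
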