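# Example pipeline configuration (all keys optional; defaults shown).
schema_version: 1
seed: 1
n_folds: 10
n_iterations: 10
tau: 0.01
bag_min: 5
selectors:
- elastic_net
- info_gain
- mc_subspace
alpha: 0.5
lambda: auto
n_bins: 10
s_mc: 300
t_mc: 1
mc_depth: 2
svm_cost: 1.0
max_missing: 0.2
keep_snp: true
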