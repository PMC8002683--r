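# Reduced-scale SGAA benchmark configuration.
# Rates default to the benchmark values; any subset may be overridden under
# 'rates:'.  Times in seconds.
circuit: sgaa
t_end: 216000        # 48 h recorded + 12 h burn-in
delta_t: 300
n_trajectories: 20
n_replicates: 2
burn_in: 43200
seed: 42
models: [dm, cgm, maxcal]
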