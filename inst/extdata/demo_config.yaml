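# Demo pipeline configuration: a small synthetic cohort and short sampler
# runs, suitable for a single CPU in well under a minute.
seed: 3
out_dir: mtess_demo_run
simulate:
  "n": 300          # quoted: a bare `n` is YAML-1.1 shorthand for false
  n_compounds: 12
sampler:
  n_sweeps: 3000
  burn_in: 1000
network:
  K: 50
fdr:
  permutations: 5
effect_rounds: 100
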