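# Demo pipeline configuration: 93 synthetic participants, all three model
# families, stratified, 100 Monte-Carlo repetitions.
generator:
  n_participants: 93
  outcome_noise_sd: 300
analyses: [absolute, coda, pls]
stratify: yes
mc_reps: 100
mc_holdout: 0.5
reallocation_max: 30
seed: 11
out_dir: movecomp_demo
figures: yes
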