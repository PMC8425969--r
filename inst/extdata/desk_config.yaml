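# Desk-scale run configuration: a small cohort and a reduced MCMC budget,
# suitable for smoke tests and recovery checks on one CPU.
cohort:
  n_per_group:
    high_sham: 5
    high_stim: 5
    low_sham: 5
    low_stim: 5
  effects: demo
  subject_sd:
    alpha: 0.5
    beta: 0.5
    pi: 0.5
    b_go: 0.5
  n_reps: 40
  contingency: 0.7
  contingency_mode: fixed
task:
  reward_scale: 0.1
mcmc:
  n_chains: 2
  warmup: 300
  draws: 300
  rhat_threshold: 1.05
seeds:
  simulate: 101
  fit: 202
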