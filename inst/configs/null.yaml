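# Global-null calibration: no treatment effects anywhere; every
# significant call is a false positive.
seed: 1
alpha: 0.05
design:
  n_removal: 5
  n_step2: 3
  replicates: 10
simulate:
  generator: parametric
  n_otus: 100
  n_affected: 0
  effect_size: 0
  sigma2: 0.2
rarefy:
  depth: 8000
diversity:
  enabled: false
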