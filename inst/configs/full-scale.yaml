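# Full experimental scale: 515 dominant OTUs, 19 Step-1 groups x 10
# replicates (190 samples) and 21 Step-2 groups x 10 replicates (210
# samples). Heavy: several hours of per-OTU fits on one core.
seed: 1
alpha: 0.05
design:
  n_removal: 18
  n_step2: 10
  replicates: 10
simulate:
  generator: parametric
  n_otus: 515
  n_affected: 120
  effect_size: 1.5
  sigma2: 0.2
rarefy:
  depth: 9000
diversity:
  enabled: true
  n_perm: 999
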