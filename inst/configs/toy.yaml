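# Small smoke-test run: 20 OTUs, 3 removal treatments, 5 replicates.
seed: 1
alpha: 0.05
design:
  n_removal: 3
  n_step2: 2
  replicates: 5
# few affected OTUs at moderate effect, so the compositional shift of
# the unaffected majority stays small
simulate:
  generator: parametric
  n_otus: 30
  n_affected: 3
  effect_size: 1.5
  sigma2: 0.2
rarefy:
  depth: 500
contrasts:
  nsim: 10000
diversity:
  enabled: true
  n_perm: 199
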