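# Example configuration overrides for the corneal epithelium simulator.
# Any value omitted here keeps the package default (see ?cornea_config);
# the defaults already carry the model's standard constants: a 200x90
# voxel lattice at 2 um/voxel, 240 MCS per simulated day, EGF diffusion
# 186 voxel^2/MCS with 0.5/MCS decay and the 20/20/0 barrier map, 25/50 px
# division volumes, a 5-pixel basal contact threshold and 1/720 sloughing.

run:
  seed: 1
  replicates: 3
  sample_every: 10

# example: a slightly warmer, more fluid tissue
potts:
  temperature: 7

# contact-energy adjustments use explicit type pairs
j_overrides:
  - a: SUPER
    b: TEAR
    value: 12
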