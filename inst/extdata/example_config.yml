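# Example pipeline configuration for the mangrovewave command-line wrapper.
generator:
  n_sites: 2000
  seed: 42
mda:
  n_select: 50
ensemble:
  forest_length: 6000
  dx: 5
  max_width: 2000
drag:
  a: 2.2
  b: -0.3
solver:
  gamma_break: 0.73
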