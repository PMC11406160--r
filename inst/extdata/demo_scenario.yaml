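# Demo warming scenario: a small synthetic ant-plant community.
# All synthetic values are invented stand-ins, not measurements.
synthetic:
  n_consumers: 3            # colonies of one species
  n_resources: 50           # plants with known required cutting forces
  consumer_mass_median: 30  # mg
  consumer_mass_sigma: 0.4  # log-scale sd
  allometry_prefactor: 10   # mN at 1 mg
  allometry_exponent: 0.666666666666667  # area-like force scaling
  cutting_force_median: 90  # mN
  cutting_force_sigma: 0.6  # log-scale sd
  alpha: 0.9                # body-mass factor per +1 degree C
  reference_temperature: 20 # degrees C
  seed: 1
rule:
  alpha: 0.9
  reference_temperature: 20
t_grid: "20:30:0.5"
robustness:
  strategy: random
  n_replicates: 100
  seed: 1
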