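# Two-pool tissue presets for 64 mT simulations.
#
# These are literature-informed estimates chosen to reproduce the
# qualitative behaviour of the corresponding materials at ultra-low field
# (shorter tissue T1 than at clinical field; conditioner-like > cream-like
# > water bound fractions). They are NOT measured reference values; exact
# two-pool parameters for these materials at 64 mT have not been published.
# Units: t1_free/t2_free/t1_bound in ms, t2_bound in us, exchange_rate in
# 1/s, bound_fraction and proton_density dimensionless.

water:
  t1_free: 3000
  t2_free: 2000
  bound_fraction: 0
  proton_density: 1.0

csf_like:
  t1_free: 3700
  t2_free: 2000
  bound_fraction: 0
  proton_density: 1.0

wm_like:
  t1_free: 350
  t2_free: 90
  bound_fraction: 0.13
  exchange_rate: 35
  t1_bound: 350
  t2_bound: 11
  lineshape: gaussian
  proton_density: 0.85

cream_like:
  t1_free: 500
  t2_free: 180
  bound_fraction: 0.05
  exchange_rate: 30
  t1_bound: 500
  t2_bound: 12
  lineshape: gaussian
  proton_density: 1.0

conditioner_like:
  t1_free: 600
  t2_free: 120
  bound_fraction: 0.12
  exchange_rate: 30
  t1_bound: 600
  t2_bound: 12
  lineshape: gaussian
  proton_density: 1.0
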