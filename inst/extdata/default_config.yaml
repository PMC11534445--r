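# Default scavsim run configuration.
#
# Every section is optional; omitted values fall back to the package
# defaults shown here. Unknown keys are rejected before any run starts.

# Parameter overrides, keyed by model symbol (see ?scav_params).
# Densities in ton/ha, rates in 1/year, fractions dimensionless.
params: {}
#  C_VS: 0.036        # vegetation-to-scavenger conversion
#  M_W: 0.2           # wolf death rate

# Numerical run settings (see ?run_settings).
settings:
  t_end: 250          # years
  output_step: 1.0    # years
  rtol: 1.0e-8
  atol: 1.0e-10

# Scenario grid: presence combinations x hunting targets x leftovers.
# Targets are T_D = T_B (ton/ha); leftovers are L_D = L_B.
grid:
  targets: [0.0, 0.5, 1.0]     # zero / medium / high hunting target
  leftovers: [0.0, 0.5, 1.0]   # fraction of hunted biomass left afield
  hunting_rate: 1.0            # H_D = H_B (1/year)
  # presence defaults to all four boar x wolf combinations
  # initial defaults to V=5, D=0.5, B=0.5, S=0.1, W=0.05 ton/ha

# Factorial sensitivity sweep (used by `scavsim sensitivity`).
sensitivity:
  varied: [C_VS]
  factors: [0.7, 1.0, 1.3]
  # scenario: boar+wolf_T0.5_L0.5   # a grid label; default medium full

# Output bundle destination.
output: scavsim-output
verbose: false
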