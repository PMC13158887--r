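# Simplified age-dependent biokinetic model for ingested radium and its
# decay progeny. Structure: a lumped alimentary-contents pool, blood/plasma,
# one soft-tissue pool, exchangeable bone surface, bone volume, plus two
# sinks (excreta, exhaled air). Transfer coefficients are illustrative:
# chosen to reproduce the qualitative behaviour of reference radium
# biokinetics (bone-seeking deposition, higher skeletal uptake and lower
# urinary excretion in adolescents, slow bone-volume turnover), not
# transcribed from any reference dataset. Units: 1/d throughout.
#
# Fractional alimentary absorption fA enters through the alimentary pool:
# outflow to blood is fA * alimentary_transit_rate and outflow to excreta is
# (1 - fA) * alimentary_transit_rate, so the absorbed fraction is exactly fA.
name: simplified-radium-default
compartments: [alimentary, blood, soft_tissue, bone_surface, bone_volume]
sinks: [excreta, exhaled]
reference_ages: [15, 25]
fA:
  "15": 0.30
  "25": 0.20
alimentary_transit_rate_per_d: 2.0
radium_transfers:
  - {from: blood, to: bone_surface, rate: {"15": 9.0, "25": 6.0}}
  - {from: blood, to: soft_tissue, rate: {"15": 2.0, "25": 2.0}}
  - {from: blood, to: excreta, rate: {"15": 7.0, "25": 12.0}}
  - {from: soft_tissue, to: blood, rate: {"15": 0.002, "25": 0.002}}
  - {from: bone_surface, to: blood, rate: {"15": 0.003, "25": 0.003}}
  - {from: bone_surface, to: bone_volume, rate: {"15": 0.0015, "25": 0.0005}}
  - {from: bone_volume, to: blood, rate: {"15": 0.0002, "25": 0.00008}}
# First-order escape of radon gas from each compartment to the exhaled-air
# sink; competes with radioactive decay, so the emanating fraction is a model
# output rather than an assumption.
radon_escape_per_d:
  alimentary: 1.0
  blood: 2.0
  soft_tissue: 2.0
  bone_surface: 0.4
  bone_volume: 0.18
progeny_mode: independent_kinetics
# Chain members with half-life below this cutoff are reported in secular
# equilibrium with in-compartment Rn-222 instead of being propagated.
equilibrium_cutoff_hours: 1.0
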