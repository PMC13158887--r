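# Illustrative dosimetry tables: charged-particle emission energies per
# decay, absorbed fractions for (source region, target tissue) pairs, and
# target masses. Alpha energies and mean beta energies are order-of-magnitude
# transcriptions from standard nuclide data; absorbed fractions are
# ILLUSTRATIVE values constructed so that bone-surface sources dominate
# endosteal dose and soft-tissue self-irradiation is small, not values from
# any reference absorbed-fraction compendium. Masses approximate an adult
# female reference.
name: illustrative-default
targets:
  bone_endosteum: {mass_kg: 0.06}
  red_marrow: {mass_kg: 1.17}
  brain: {mass_kg: 1.30}
  lung: {mass_kg: 0.95}
  heart_wall: {mass_kg: 0.25}
  breast: {mass_kg: 0.50}
# Mapping from biokinetic model compartments to dosimetric source regions;
# sinks (excreta, exhaled) are outside the body and never sources.
source_map:
  alimentary: alimentary_contents
  blood: blood
  soft_tissue: soft_tissue
  bone_surface: bone_surface
  bone_volume: bone_volume
# Charged-particle emissions per decay: MeV and yield.
emissions:
  Ra-226: [{type: alpha, energy_MeV: 4.78, yield: 1.0}]
  Rn-222: [{type: alpha, energy_MeV: 5.49, yield: 1.0}]
  Po-218: [{type: alpha, energy_MeV: 6.00, yield: 1.0}]
  Pb-214: [{type: beta, energy_MeV: 0.22, yield: 1.0}]
  Bi-214: [{type: beta, energy_MeV: 0.64, yield: 1.0}]
  Po-214: [{type: alpha, energy_MeV: 7.69, yield: 1.0}]
  Pb-210: [{type: beta, energy_MeV: 0.038, yield: 1.0}]
  Bi-210: [{type: beta, energy_MeV: 0.39, yield: 1.0}]
  Po-210: [{type: alpha, energy_MeV: 5.30, yield: 1.0}]
# Absorbed fractions for charged particles; pairs not listed contribute no
# dose by explicit omission (the pair is absent, not silently zero: direct
# S-coefficient lookups for absent pairs raise an error).
absorbed_fractions:
  - {source: bone_surface, target: bone_endosteum, af: 0.04}
  - {source: bone_volume, target: bone_endosteum, af: 0.0015}
  - {source: bone_surface, target: red_marrow, af: 0.06}
  - {source: bone_volume, target: red_marrow, af: 0.006}
  - {source: blood, target: red_marrow, af: 0.004}
  - {source: soft_tissue, target: brain, af: 0.030}
  - {source: soft_tissue, target: lung, af: 0.017}
  - {source: soft_tissue, target: heart_wall, af: 0.004}
  - {source: soft_tissue, target: breast, af: 0.0056}
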