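# Bipolar 'np' nanopore in 1 M NaCl at +200 mV (ON state).
# Lengths in nm, charges in e, concentrations in mol/L, voltage in mV.
species:
  - {name: "Na+", valence: 1, radius: 0.095, d_bulk: 1.334e-9, d_pore: 0.40e-9}
  - {name: "Cl-", valence: -1, radius: 0.181, d_bulk: 2.032e-9, d_pore: 0.61e-9}
baths:
  left:  {"Na+": 1.0, "Cl-": 1.0}
  right: {"Na+": 1.0, "Cl-": 1.0}
  dielectric: 78.45
  temperature: 298.15
geometry:
  pore_radius: 0.97
  pore_length: 6.4
  cell_radius: 3.0
  cell_half_length: 6.0
charges:
  type: regions
  sigma_left: -0.4835
  sigma_right: 0.4835
  sigma_ref: 0.4835
  x_left: 0.5
  grid_dz: 0.2
run:
  voltage_mV: 200
  nz: 20
  nr: 4
  sweeps: 2000
  equilibration: 500
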