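# Two-solute demonstration study: a methane-like solute (unfavourable
# 11.79 kJ/mol interior plateau) and an acid-gas-like solute (favourable
# -7.84 kJ/mol interior) on the same slab geometry. Protocol mirrors the
# reference umbrella-sampling study: 6 windows separated by 1.0 nm,
# staggered over 10 offsets of 0.1 nm, k = 2000 kJ/mol/nm^2, 4 ns per
# window, 25 replicate profiles, 300 K.
solutes:
  methane_like:
    pmf_params:
      well_depth: -2.0
      plateau: 11.79
      z_int: 2.0
      interface_width: 0.25
      slab_half_width: 2.0
    diff_params:
      d_vapor: 5.0e-3
      d_bulk: 2.0e-3
      transition_width: 0.25
    density_params:
      rho_bulk: 1100.0
      interface_width: 0.3
  acid_gas_like:
    pmf_params:
      well_depth: -4.0
      plateau: -7.84
      z_int: 2.0
      interface_width: 0.25
      slab_half_width: 2.0
    diff_params:
      d_vapor: 2.5e-3
      d_bulk: 1.0e-3
      transition_width: 0.25
    density_params:
      rho_bulk: 1100.0
      interface_width: 0.3
protocol:
  window_spacing: 1.0
  n_windows: 6
  n_offsets: 10
  force_constant: 2000.0
  n_steps: 400000
  dt: 0.01
  thin: 10
  n_replicates: 25
  z_min: 0.0
analysis:
  bin_width: 0.01
  discard_fraction: 0.1
  tol: 1.0e-7
  max_iter: 100000
  truncation: first-zero
  n_boot: 50
ranges:
  full: [-3.0, 3.0]
  interface: [1.5, 3.0]
temperature: 300.0
seed: 20260922
box_half_length: 7.0
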