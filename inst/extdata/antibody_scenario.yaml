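scenario:
  name: antibody
  stimulus_scale: 1.0
  contact_protrusion_scale: 0.0
  attraction_on: yes
  tension_rest_mN_per_m: 0.025
  tension_plateau_mN_per_m: 0.15
  ramp_onset_s: 10.0
  ramp_duration_s: 60.0
  viscosity_ramp_factor: 1.0
  t_end_s: 150.0
  resolution: 1.0
  cell_radius_um: 4.25
  target_radius_um: 1.6
  seed: 1
params:
  mu_solvent_pN_s_per_um2: 1.0
  mu_network_0_pN_s_per_um2: 30000.0
  drag_coeff_pN_s_per_um4: 1000.0
  k_poly_per_au_s: 1.2
  k_depoly_per_s: 0.12
  theta_base: 0.05
  theta_max: 0.5
  D_m_um2_per_s: 0.8
  k_decay_per_s: 3.0
  source_strength_au_um_per_s: 1.0
  sigma_protrude_pN_per_um2: 2000.0
  sigma_attract_pN_per_um2: 120.0
  attract_range_um: 0.3
  contact_zone_gap_um: 0.45
  bending_stab_pN_per_um: 0.0
  zip_speed_um_per_s: 0.25
  zip_speed_attract_um_per_s: 0.1
  zip_stiffness_pN_s_per_um: 80000.0
  zip_wrap_boost: 0.0
  zip_bead_coupling: 1.0
  tau_transient_s: 10.0
  leading_edge_width_nodes: 2.0
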