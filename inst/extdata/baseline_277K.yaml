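# Validation scenario: 2 mm cocoa-butter droplet in 277 K air at 1 bar,
# relative drop-gas speed 83 cm/s.
material:
  rho_kg_m3: 894
  cp_liquid_J_kgK: 2200
  cp_solid_J_kgK: 1250
  latent_heat_J_kg: 157000
  T_freeze_K: 291
  T_solidus_K: 273
  k_thermal_W_mK: 0.18
droplet:
  d_m: 2.0e-3
  T_init_K: 318
ambient:
  Ta_K: 277
  p_Pa: 1.0e+5
  Vdg_m_s: 0.83
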