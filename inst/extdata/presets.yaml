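# Preset registry: spectral templates for named tracer systems, one
# representative physical preset, and the default dietary contaminant.
# Units are spelled out in key names. Template amplitudes are relative to
# A3; phases are degrees with the negative-lag convention.
vsop:
  mode: template
  template_amps: {3: 1.0, 5: 0.10, 7: 0.02, 9: 0.005}
  template_phases_deg: {3: -2.0, 5: -2.0, 7: -2.0, 9: -2.0}
  specific_a3_am2_per_kg: 0.2
endorem:
  mode: template
  template_amps: {3: 1.0, 5: 0.20, 7: 0.06, 9: 0.02}
  template_phases_deg: {3: -10.0, 5: -12.0, 7: -14.0, 9: -16.0}
  specific_a3_am2_per_kg: 0.3
mcp_resovist:
  mode: template
  template_amps: {3: 1.0, 5: 0.30, 7: 0.12, 9: 0.05}
  template_phases_deg: {3: -30.0, 5: -34.0, 7: -38.0, 9: -42.0}
  specific_a3_am2_per_kg: 0.45
vsop_physical:
  mode: physical
  d_med_m: 5.0e-9
  sigma_d: 0.25
  m_s_a_per_m: 3.0e+5
  tau_s: 2.0e-7
contaminant_diet:
  kind: contaminant
  m_c_am2: 1.0e-9
  b_c_t: 12.5e-3
  b_w_t: 3.0e-3
  jitter:
    m_c_rel: 0.5
    b_c_t: 7.5e-3
    b_w_t: 2.0e-3
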