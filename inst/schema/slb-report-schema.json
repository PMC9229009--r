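{
  "title": "SLB deposition analysis report",
  "required": {
    "signature": "object",
    "warnings": "array",
    "config": "object",
    "version": "string"
  },
  "signature_required": [
    "label", "f_final", "D_final", "initial_slope",
    "rinse_delta_f", "rinse_delta_D", "rigid"
  ],
  "signature_numeric": [
    "f_final", "D_final", "f_min", "t_min", "initial_slope",
    "overtone_spread_final", "rinse_delta_f", "rinse_delta_D"
  ],
  "labels": [
    "vesicle_layer", "two_step_slb", "one_step_slb",
    "incomplete_bilayer", "indeterminate"
  ],
  "packing_numeric": [
    "delta_f", "areal_mass", "corrected_mass", "mw_avg", "M_L",
    "density_total", "N_L", "a_L", "v_L_avg", "h_L"
  ]
}
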