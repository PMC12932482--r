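# Demo run configuration: 100 mg oral talinolol with the in-vivo gut
# kinetics (apical uptake 0.838 uL/min/cm2; efflux clearances preserved
# from the monolayer deconvolution, saturation thresholds scaled to the
# in-vivo linear range; basolateral efflux clearance 15 uL/min/cm2 at pH
# 7.4 by calibration). Units are encoded in the field names.
compound:
  name: talinolol
  ionization_class: monoprotic_base
  pka: 9.45
  fu_cell: 1.0
  fu_plasma: 0.45
  mol_weight_g_mol: 363.5
kinetics:
  cl_diff_ul_min_cm2: 9.44
  cl_ac_ul_min_cm2: 0.838
  cl_bc_ul_min_cm2: 0.0391
  vmax_ca_pmol_min_cm2: 11400.0
  km_ca_um: 567.0
  vmax_cb_pmol_min_cm2: 53350.6
  km_cb_um: 48200.0
  alpha_ac: 0.0
  alpha_ca: 19.3
  alpha_bc: 4.65
  alpha_cb: 20.1
  ph_ref: 6.5
doses:
  - route: oral
    amount_mg: 100
    start_time_h: 0
simulation:
  t_end_h: 24
  dt_h: 0.05
  rtol: 1.0e-8
  atol: 1.0e-8
run:
  seed: 1
  output_dir: results
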