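# Demo run: 48x48 two-species phantom, full adaptive pipeline.
seed: 7
outdir: flimadapt-demo
phantom:
  generator: two_species
  shape: [48, 48]
  bright_rate: 8.71      # detected photons/us; 871 counts at 100 us dwell
  dim_rate: 1.17         # 117 counts at 100 us dwell
  tau_bright: 0.8        # ns, short-lived bright species
  tau_dim: 2.5           # ns, long-lived dim species
  dcr: 100               # detector dark counts per second
acquisition:
  rep_rate: 2.0e+7       # 20 MHz -> 50 ns decay window
  bin_width_ps: 100
  irf_sigma_ps: 40
  t0_ns: 0.55
planner:
  t_prescan: 100         # us
  i_target: 250          # photons per pixel
  t_min: 50              # us
  t_max: 600             # us
  step: 1                # us
  block: 16
  roi_mode: auto
scan:
  vs_volts: 0.01
  f_hz: 1.0e+7
  beta_factor: 0.02
  smooth_window: 5
experiment:
  mode: enhance
  estimator: cmm
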