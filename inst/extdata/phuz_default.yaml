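# Default configuration of the PhuZ spindle positioning model.
#
# Kinetic values are an illustrative calibrated set obtained with the
# package's own distribution-RMSD calibration against a control-like
# nucleus-position distribution in 3.5 um cells; they are not measured
# values. All speeds in um/s, times in s, lengths in um.
simulation:
  dt: 0.01            # integration time step (s)
  duration: 1800      # 30 simulated minutes post infection
  n_runs: 500         # ensemble size per condition
  seed: 1             # master seed; per-run streams are derived from it
  record_trajectory: false
  record_stride: 100  # record every stride-th step when recording
  resample_interval: .inf   # re-sample speeds at phase changes only
kinetics:
  v_poly_mean: 0.073  # polymerization speed (fitted)
  v_poly_sd: 0.012
  v_depoly_mean: 0.01 # depolymerization speed during growth
  v_depoly_sd: 0.004
  v_cat_mean: 0.5     # catastrophic depolymerization speed
  v_cat_sd: 0.075
  t_cat_mean: 25.5    # growth duration before catastrophe (fitted)
  t_cat_sd: 2
  t_rec_mean: 6       # catastrophe duration before recovery
  t_rec_sd: 0.9
cell:
  length: 3.5               # cell length L (um)
  nucleus_radius: 0.5       # collision half-length of the nucleus
  nucleus_init_frac: 0.9    # nucleus starts at 90% of L (polar injection)
  stokes_radius: 1          # hydrodynamic radius; sets the Stokes-Einstein D
  # effective cytoplasmic diffusion of a micron-scale compartment; the
  # Stokes-Einstein water value (~0.227) overestimates mobility in
  # crowded cytoplasm by orders of magnitude
  nucleus_diffusion_coeff: 0.001
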