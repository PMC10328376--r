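# Shared fixtures: small, fast configurations used across test files.

# deterministic kinetics: no variability anywhere
quiet_kinetics <- function(v_poly = 0, v_depoly = 0, v_cat = 0,
                           t_cat = 1e6, t_rec = 1e6) {
  kinetic_params(v_poly_mean = v_poly, v_poly_sd = 0,
                 v_depoly_mean = v_depoly, v_depoly_sd = 0,
                 v_cat_mean = v_cat, v_cat_sd = 0,
                 t_cat_mean = t_cat, t_cat_sd = 0,
                 t_rec_mean = t_rec, t_rec_sd = 0)
}

still_cell <- function(length = 3.5, radius = 0.5, init_frac = 0.9) {
  cell_config(length, nucleus_radius = radius,
              nucleus_diffusion_coeff = 0, nucleus_init_frac = init_frac)
}

# short stochastic config for invariant churning
churn_config <- function(seed = 1, duration = 30, n_runs = 5, dt = 0.01,
                         length = 3.5) {
  sim_config(dt = dt, duration = duration, n_runs = n_runs, seed = seed,
             kinetics = kinetic_params(),
             cell = cell_config(length))
}

# independent rule-table implementation of one collision-resolved update,
# written case-by-case from the push/jam rules; deliberately structured
# differently from the production kernel (explicit case enumeration).
oracle_resolve <- function(tipL, tipR, center, dL, dR, ddiff, r, L) {
  tl <- max(0, tipL + dL)
  tr <- min(L, tipR + dR)
  crossL <- tl > center - r
  crossR <- tr < center + r
  if (crossL && crossR) {
    # both advancing tips would cross: jam; tips stop at contact
    tl <- center - r
    tr <- center + r
  } else if (crossL) {
    overshoot <- tl - (center - r)
    # nucleus takes the overshoot, limited by the opposite tip and the wall
    allowed <- min(overshoot, (tr - r) - center, (L - r) - center)
    center <- center + allowed
    tl <- center - r
  } else if (crossR) {
    overshoot <- (center + r) - tr
    allowed <- min(overshoot, center - (tl + r), center - r)
    center <- center - allowed
    tr <- center + r
  }
  # diffusion clamped between contacts and walls
  target <- center + ddiff
  lo <- max(r, tl + r)
  hi <- min(L - r, tr - r)
  center <- min(max(target, lo), hi)
  c(tip_left = tl, tip_right = tr, center = center)
}
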