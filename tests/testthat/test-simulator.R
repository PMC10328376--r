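test_that("zero-variance speed draws are exact and negative draws truncate", {
  expect_identical(sample_speed(0.05, 0), 0.05)
  expect_identical(sample_speed(0, 0), 0)
  expect_error(sample_speed(-0.1, 0.1), "must be >= 0")
  set.seed(42)
  draws <- sample_speed(0.01, 0.05, n = 1e5)
  expect_true(all(draws >= 0))
  expect_gt(mean(draws == 0), 0)   # truncation mass is present
})

test_that("truncated speed draws match a quadrature oracle for the mean", {
  m <- 0.05; s <- 0.02
  oracle_mean <- integrate(function(x) x * dnorm(x, m, s), 0, Inf)$value
  set.seed(7)
  draws <- sample_speed(m, s, n = 1e5)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - oracle_mean), 3 * se)
})

test_that("Stokes-Einstein diffusion coefficient matches the closed form", {
  kB <- 1.380649e-23
  direct <- kB * 310 / (6 * pi * 0.001 * 1e-6) * 1e12
  expect_equal(stokes_einstein_D(1, 310, 0.001), direct)
  expect_equal(stokes_einstein_D(1), 0.227, tolerance = 0.01)
  expect_equal(stokes_einstein_D(1, viscosity = 0.002),
               stokes_einstein_D(1) / 2)
  expect_equal(stokes_einstein_D(2), stokes_einstein_D(1) / 2)
  expect_error(stokes_einstein_D(0), "must all be > 0")
})

test_that("displacement kernel agrees with the rule-table oracle on all enumerated configurations", {
  L <- 4; r <- 0.5; cc <- 2
  # per filament: {far, touching} x {no-move, grow-small (no cross),
  # grow-large (cross), shrink} minus redundant pairs = 6 cases per side
  left_cases <- list(
    list(tip = 0.8, d = 0),       # far, idle
    list(tip = 0.8, d = 0.3),     # far, grows, stays clear
    list(tip = 0.8, d = 1.0),     # far, would cross
    list(tip = 1.5, d = 0),       # touching, idle
    list(tip = 1.5, d = 0.4),     # touching, would cross
    list(tip = 1.5, d = -0.6))    # touching, shrinks away
  right_cases <- lapply(left_cases, function(cs)
    list(tip = L - cs$tip, d = -cs$d))
  n_checked <- 0
  for (lc in left_cases) for (rc in right_cases) {
    for (dd in c(0, 0.8, -0.8)) {
      got <- resolve_step_cpp(lc$tip, rc$tip, cc, lc$d, rc$d, dd, r, L)
      want <- oracle_resolve(lc$tip, rc$tip, cc, lc$d, rc$d, dd, r, L)
      expect_equal(unname(got), unname(want), tolerance = 1e-12,
                   info = sprintf("tips (%g, %g), d (%g, %g), diff %g",
                                  lc$tip, rc$tip, lc$d, rc$d, dd))
    }
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 36)
})

test_that("displacement kernel agrees with the oracle on random configurations", {
  set.seed(11)
  for (i in 1:500) {
    L <- runif(1, 2, 12); r <- runif(1, 0.2, 0.8)
    cc <- runif(1, r, L - r)
    tl <- runif(1, 0, cc - r)
    tr <- runif(1, cc + r, L)
    dl <- runif(1, -1, 1); dr <- runif(1, -1, 1); dd <- runif(1, -1, 1)
    got <- resolve_step_cpp(tl, tr, cc, dl, dr, dd, r, L)
    want <- oracle_resolve(tl, tr, cc, dl, dr, dd, r, L)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("a step with no dynamics changes only the clock", {
  cell <- still_cell()
  st <- init_sim_state(cell, quiet_kinetics(), dt = 0.01)
  st2 <- pz_step(st, quiet_kinetics(), 0.01)
  expect_equal(st2$t, 0.01)
  expect_equal(st2$nucleus_center, st$nucleus_center)
  expect_equal(st2$left$tip, st$left$tip)
  expect_equal(st2$right$tip, st$right$tip)
  expect_error(pz_step(st, quiet_kinetics(), 0), "dt must be > 0")
})

test_that("a two-sided contact jams nucleus and tips", {
  kin <- quiet_kinetics(v_poly = 0.05)
  cell <- still_cell(length = 4, init_frac = 0.5)
  st <- init_sim_state(cell, kin, dt = 0.01)
  st$left$tip <- st$nucleus_center - 0.5
  st$right$tip <- st$nucleus_center + 0.5
  st2 <- pz_step(st, kin, 0.01)
  expect_equal(st2$nucleus_center, st$nucleus_center)
  expect_equal(st2$left$tip, st$left$tip)
  expect_equal(st2$right$tip, st$right$tip)
})

test_that("an unobstructed growing tip advances by exactly v_poly * dt", {
  kin <- quiet_kinetics(v_poly = 0.05)
  cell <- still_cell(length = 10, init_frac = 0.9)
  st <- init_sim_state(cell, kin, dt = 0.01)
  st2 <- pz_step(st, kin, 0.01)
  expect_equal(st2$left$tip, 5e-4)
})

test_that("zero-duration runs report the clamped initial position", {
  cfg <- sim_config(duration = 0, seed = 1, kinetics = quiet_kinetics(),
                    cell = still_cell(3.5), record_trajectory = TRUE)
  run <- run_simulation(cfg)
  expect_equal(run$nucleus_center, min(0.9 * 3.5, 3.5 - 0.5))
  expect_equal(nrow(run$trajectory), 1L)
  # start fraction beyond the wall clamp
  cfg2 <- sim_config(duration = 0, seed = 1, kinetics = quiet_kinetics(),
                     cell = still_cell(3, init_frac = 0.99))
  expect_equal(run_simulation(cfg2)$nucleus_center, 2.5)
})

test_that("frozen dynamics leave the nucleus at its clamped start for the whole run", {
  cfg <- sim_config(duration = 10, seed = 3, kinetics = quiet_kinetics(),
                    cell = still_cell(3.5))
  expect_equal(run_simulation(cfg)$nucleus_center, 3.0)
})

test_that("runs are deterministic in (config, seed) and ensembles are counter-stable", {
  cfg <- sim_config(duration = 20, n_runs = 8, seed = 5)
  a <- run_simulation(cfg, run_seed = 99)
  b <- run_simulation(cfg, run_seed = 99)
  expect_identical(a$nucleus_center, b$nucleus_center)
  e1 <- run_ensemble(cfg)
  e2 <- run_ensemble(cfg)
  expect_identical(e1, e2)
  # growing the ensemble must not change earlier runs
  cfg2 <- cfg; cfg2$n_runs <- 4L
  e3 <- run_ensemble(cfg2)
  expect_identical(e3$final_position_um, e1$final_position_um[1:4])
})

test_that("R-level stepping and the compiled loop agree on deterministic dynamics", {
  kin <- quiet_kinetics(v_poly = 0.05, v_depoly = 0.01)
  cell <- still_cell(length = 6, init_frac = 0.9)
  cfg <- sim_config(dt = 0.01, duration = 2, seed = 1, kinetics = kin,
                    cell = cell, record_trajectory = TRUE, record_stride = 1)
  cpp <- run_simulation(cfg)
  st <- init_sim_state(cell, kin, dt = 0.01)
  for (i in 1:200) st <- pz_step(st, kin, 0.01)
  expect_equal(st$nucleus_center,
               cpp$trajectory$nucleus_center_um[201], tolerance = 1e-10)
  expect_equal(st$left$tip, cpp$trajectory$left_tip_um[201], tolerance = 1e-10)
  expect_equal(st$right$tip, cpp$trajectory$right_tip_um[201], tolerance = 1e-10)
})

test_that("confinement and non-interpenetration hold along stochastic trajectories", {
  set.seed(21)
  for (i in 1:20) {
    L <- runif(1, 2.5, 12)
    kin <- kinetic_params(v_poly_mean = runif(1, 0, 0.2), v_poly_sd = runif(1, 0, 0.05),
                          v_depoly_mean = runif(1, 0, 0.05), v_depoly_sd = runif(1, 0, 0.02),
                          v_cat_mean = runif(1, 0, 0.6), v_cat_sd = runif(1, 0, 0.1),
                          t_cat_mean = runif(1, 2, 40), t_cat_sd = runif(1, 0, 10),
                          t_rec_mean = runif(1, 1, 20), t_rec_sd = runif(1, 0, 5))
    cell <- cell_config(L, nucleus_diffusion_coeff = runif(1, 0, 0.3))
    cfg <- sim_config(duration = 5, seed = i, kinetics = kin, cell = cell,
                      record_trajectory = TRUE, record_stride = 1)
    tr <- run_simulation(cfg)$trajectory
    r <- cell$nucleus_radius
    expect_true(all(tr$nucleus_center_um >= r - 1e-9))
    expect_true(all(tr$nucleus_center_um <= L - r + 1e-9))
    expect_true(all(tr$left_tip_um >= -1e-12 & tr$left_tip_um <= L + 1e-12))
    expect_true(all(tr$right_tip_um >= -1e-12 & tr$right_tip_um <= L + 1e-12))
    expect_true(all(tr$left_tip_um <= tr$nucleus_center_um - r + 1e-9))
    expect_true(all(tr$right_tip_um >= tr$nucleus_center_um + r - 1e-9))
  }
})

test_that("a jam persists unchanged until a catastrophe releases it", {
  # deterministic growth, first catastrophe at 150 s: the system jams
  # and must stay frozen from jam formation until the phase change
  kin <- kinetic_params(v_poly_mean = 0.05, v_poly_sd = 0,
                        v_depoly_mean = 0, v_depoly_sd = 0,
                        v_cat_mean = 0.3, v_cat_sd = 0,
                        t_cat_mean = 150, t_cat_sd = 0,
                        t_rec_mean = 10, t_rec_sd = 0)
  cell <- still_cell(length = 4, init_frac = 0.5)
  cfg <- sim_config(duration = 149, seed = 2, kinetics = kin, cell = cell,
                    record_trajectory = TRUE, record_stride = 1)
  tr <- run_simulation(cfg)$trajectory
  jammed <- which(abs(tr$left_tip_um - (tr$nucleus_center_um - 0.5)) < 1e-9 &
                    abs(tr$right_tip_um - (tr$nucleus_center_um + 0.5)) < 1e-9)
  expect_gt(length(jammed), 100)          # the jam forms well before 149 s
  seg <- tr[min(jammed):nrow(tr), ]
  expect_equal(max(seg$nucleus_center_um) - min(seg$nucleus_center_um), 0)
  expect_equal(max(seg$left_tip_um) - min(seg$left_tip_um), 0)
})

test_that("mirrored runs are exact reflections of each other", {
  cfg <- sim_config(duration = 60, seed = 17,
                    cell = cell_config(3.5, nucleus_diffusion_coeff = 0.05),
                    record_trajectory = TRUE, record_stride = 10)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg, mirror = TRUE)
  L <- 3.5
  expect_equal(b$trajectory$nucleus_center_um,
               L - a$trajectory$nucleus_center_um, tolerance = 1e-9)
  expect_equal(b$trajectory$left_tip_um,
               L - a$trajectory$right_tip_um, tolerance = 1e-9)
  expect_equal(b$trajectory$right_tip_um,
               L - a$trajectory$left_tip_um, tolerance = 1e-9)
  expect_identical(b$trajectory$left_phase, a$trajectory$right_phase)
})

test_that("coarsening the time step stays within the seed-to-seed noise floor", {
  # documented convergence check: dt = 0.05 s endpoint distributions are
  # indistinguishable from dt = 0.01 s beyond ensemble sampling noise
  cfg <- phuz_default_config()
  cfg$n_runs <- 500L
  h <- function(dt, seed) {
    c2 <- cfg; c2$dt <- dt; c2$seed <- seed
    position_histogram(run_ensemble(c2)$normalized_position, 10)
  }
  a1 <- h(0.01, 1); a2 <- h(0.01, 2); b <- h(0.05, 3)
  noise_floor <- rmsd_between_distributions(a1, a2)
  cross <- rmsd_between_distributions(a1, b)
  expect_lt(cross, 2 * noise_floor + 0.01)
})

test_that("infeasible geometry is rejected", {
  expect_error(cell_config(0.8, nucleus_radius = 0.5), "must exceed twice")
  cfg <- sim_config(duration = 1, seed = 1)
  expect_error(run_simulation(cfg, cell_length = 0.9), "must exceed twice")
  expect_error(sim_config(dt = 0), "dt must be > 0")
  expect_error(kinetic_params(v_poly_mean = -1), "must be a single finite value >= 0")
})

test_that("ensemble length samplers are applied with rejection and recorded", {
  cfg <- sim_config(duration = 5, n_runs = 30, seed = 8)
  ens <- run_ensemble(cfg, function(n) rnorm(n, 3.5, 1.5))
  expect_true(all(ens$cell_length_um > 1))
  expect_equal(ens$normalized_position,
               ens$final_position_um / ens$cell_length_um)
  expect_error(run_ensemble(sim_config(duration = 1, n_runs = 2, seed = 1),
                            function(n) rep(0.5, n)),
               "feasible length")
})
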