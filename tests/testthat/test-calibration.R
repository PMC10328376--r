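# small, fast simulation setup shared by the objective tests
cal_config <- function(seed = 1, n_runs = 80) {
  sim_config(dt = 0.02, duration = 240, n_runs = n_runs, seed = seed,
             kinetics = kinetic_params(),
             cell = cell_config(3.5, nucleus_diffusion_coeff = 0.02))
}

test_that("finite-difference gradients match the quadratic closed form", {
  target <- c(a = 1.5, b = -2)
  f <- function(x, tag) sum((x - target)^2)
  x0 <- c(a = 3, b = 1)
  g <- estimate_gradient(f, x0, lower = -10, upper = 10,
                         perturbation_scale = 1e-4)
  expect_equal(g, 2 * (x0 - target), tolerance = 0.01)
  gmin <- estimate_gradient(f, target, lower = -10, upper = 10,
                            perturbation_scale = 1e-4)
  expect_lt(sqrt(sum(gmin^2)), 1e-6)
  # linear objective: constant gradient wherever evaluated
  lin <- function(x, tag) sum(c(2, -3) * x)
  g1 <- estimate_gradient(lin, c(a = 0, b = 0), lower = -10, upper = 10)
  g2 <- estimate_gradient(lin, c(a = 5, b = -4), lower = -10, upper = 10)
  expect_equal(g1, c(a = 2, b = -3), tolerance = 1e-8)
  expect_equal(g1, g2, tolerance = 1e-8)
})

test_that("gradient estimation falls back to one-sided differences at bounds", {
  f <- function(x, tag) sum(x^2)
  g <- estimate_gradient(f, c(a = 0), lower = 0, upper = 10,
                         perturbation_scale = 0.01)
  expect_true(is.finite(g))
  expect_error(estimate_gradient(f, c(a = -1), lower = 0, upper = 10),
               "outside bounds")
})

test_that("the minimizer recovers a deterministic quadratic minimum", {
  target <- c(v = 0.07, t = 13)
  f <- function(x, tag) sum(((x - target) / c(0.1, 30))^2)
  for (s in c(3, 9)) {
    fit <- sfd_minimize(f, c(v = 0.02, t = 40),
                        lower = c(0.001, 1), upper = c(0.2, 60),
                        control = list(max_iterations = 120,
                                       convergence_tol = 0, seed = s))
    expect_lt(max(abs(fit$par - target) / target), 1e-3)
  }
})

test_that("the best-seen trace is non-increasing, bounded and reproducible", {
  f <- function(x, tag) sum(x^2) + 0.1 * sin(sum(100 * x))
  a <- sfd_minimize(f, c(p = 2, q = -3), lower = -5, upper = 5,
                    control = list(max_iterations = 40, seed = 7))
  b <- sfd_minimize(f, c(p = 2, q = -3), lower = -5, upper = 5,
                    control = list(max_iterations = 40, seed = 7))
  expect_identical(a$trace, b$trace)
  expect_true(all(diff(a$trace$value) <= 0))
  expect_true(all(a$par >= -5 & a$par <= 5))
})

test_that("the RMSD objective is zero on self-comparison and positive for wrong kinetics", {
  cfg <- cal_config()
  eval_seed <- 77
  rep_seed <- as.integer(run_child_seed_cpp(eval_seed, 1, 9))
  cfg_meas <- cfg; cfg_meas$seed <- rep_seed
  measured <- position_histogram(run_ensemble(cfg_meas)$normalized_position, 10)
  self <- objective_rmsd(c(v_poly_mean = cfg$kinetics$v_poly_mean), measured,
                         cfg, replicates = 1, eval_seed = eval_seed)
  expect_equal(self, 0)
  # noise floor: same kinetics, independent seeds
  floor_vals <- vapply(2:6, function(k) {
    objective_rmsd(c(v_poly_mean = cfg$kinetics$v_poly_mean), measured,
                   cfg, replicates = 1, eval_seed = 100 + k)
  }, numeric(1))
  noise_floor <- max(floor_vals)
  # frozen filaments cannot reproduce a centered distribution
  wrong <- objective_rmsd(c(v_poly_mean = 0, v_cat_mean = 0), measured,
                          cfg, replicates = 1, eval_seed = 301)
  expect_gt(wrong, noise_floor)
  expect_error(objective_rmsd(c(not_a_param = 1), measured, cfg),
               "unknown kinetic")
})

test_that("replicate averaging tightens the objective's spread", {
  cfg <- cal_config(n_runs = 40)
  measured <- position_histogram(run_ensemble(cfg)$normalized_position, 10)
  v1 <- vapply(1:6, function(k)
    objective_rmsd(c(v_poly_mean = 0.05), measured, cfg,
                   replicates = 1, eval_seed = 500 + k), numeric(1))
  v3 <- vapply(1:6, function(k)
    objective_rmsd(c(v_poly_mean = 0.05), measured, cfg,
                   replicates = 4, eval_seed = 600 + k), numeric(1))
  expect_lt(sd(v3), sd(v1))
})

test_that("Delaunay barycentric interpolation reproduces linear surfaces exactly", {
  set.seed(23)
  x <- runif(60); y <- runif(60)
  z <- 2 + 3 * x - 5 * y
  qx <- runif(200, 0.2, 0.8); qy <- runif(200, 0.2, 0.8)
  got <- phuzsim:::interp_linear(x, y, z, qx, qy)
  expect_true(all(is.finite(got)))
  expect_equal(got, 2 + 3 * qx - 5 * qy, tolerance = 1e-8)
})

test_that("surface sampling finds a quadratic minimum within sample spacing", {
  f <- function(v) (v[["x"]] - 0.4)^2 + (v[["y"]] - 0.6)^2
  surf <- rmsd_surface("x", "y", lower = c(0, 0), upper = c(1, 1),
                       n_points = 200, fn = f, seed = 5)
  expect_equal(nrow(surf$samples), 200)
  grid <- interp_surface(surf, nx = 40, ny = 40)
  idx <- which(grid$z == min(grid$z, na.rm = TRUE), arr.ind = TRUE)
  # average nearest-neighbor spacing of 200 uniform points in the unit
  # square is ~1/sqrt(200); allow one spacing
  spacing <- 1 / sqrt(200)
  expect_lt(abs(grid$x[idx[1]] - 0.4), 2 * spacing)
  expect_lt(abs(grid$y[idx[2]] - 0.6), 2 * spacing)
  # constant objective: flat surface
  flat <- rmsd_surface("x", "y", c(0, 0), c(1, 1), n_points = 50,
                       fn = function(v) 1, seed = 2)
  g2 <- interp_surface(flat, 10, 10)
  expect_true(all(abs(g2$z[is.finite(g2$z)] - 1) < 1e-9))
})

test_that("calibration against a simulated target improves the RMSD from a wrong start", {
  cfg <- cal_config(seed = 2)
  truth <- cfg$kinetics$v_poly_mean
  target <- position_histogram(run_ensemble(cfg)$normalized_position, 10)
  fit <- optimize_parameters(
    target, c(v_poly_mean = truth * 2),
    opt_config = list(max_iterations = 8, replicates_per_eval = 2, seed = 4,
                      lower = c(v_poly_mean = truth / 4),
                      upper = c(v_poly_mean = truth * 4)),
    sim_config = cfg)
  expect_lt(fit$value, fit$trace$value[1])
  expect_true(all(diff(fit$trace$value) <= 0))
})
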