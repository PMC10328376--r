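#' Stokes-Einstein diffusion coefficient
#'
#' \eqn{D = k_B T / (6 \pi \eta r)}, returned in um^2/s. Used for the
#' default diffusion coefficient of the phage nucleus, modeled as a
#' sphere with a 1 um Stokes radius.
#'
#' @param radius Hydrodynamic radius (um).
#' @param temperature Absolute temperature (K); default 310 K (37 C).
#' @param viscosity Dynamic viscosity (Pa s); default that of water,
#'   0.001 Pa s. Cytoplasmic crowding would lower D; the coefficient can
#'   be overridden directly in [cell_config()].
#' @return Diffusion coefficient (um^2/s).
#' @examples
#' stokes_einstein_D(1)          # ~0.227 um^2/s
#' stokes_einstein_D(2)          # half of the above
#' @export
stokes_einstein_D <- function(radius, temperature = 310, viscosity = 0.001) {
  if (radius <= 0 || temperature <= 0 || viscosity <= 0)
    stop("radius, temperature and viscosity must all be > 0", call. = FALSE)
  kB <- 1.380649e-23                       # J/K
  d_m2s <- kB * temperature / (6 * pi * viscosity * radius * 1e-6)
  d_m2s * 1e12                             # m^2/s -> um^2/s
}

#' Draw a filament speed
#'
#' Gaussian draw with the given mean and standard deviation, truncated
#' below at zero (a negative draw is replaced by zero). Uses R's RNG.
#'
#' @param mean,sd Mean and standard deviation (um/s), both >= 0.
#' @param n Number of draws.
#' @return Numeric vector of non-negative speeds.
#' @examples
#' set.seed(1)
#' sample_speed(0.05, 0.02, n = 3)
#' sample_speed(0.05, 0)   # exactly 0.05
#' @export
sample_speed <- function(mean, sd, n = 1) {
  if (mean < 0 || sd < 0) stop("mean and sd must be >= 0", call. = FALSE)
  pmax(0, rnorm(n, mean, sd))
}

draw_interval <- function(mean, sd, dt) {
  pmax(dt, pmax(0, rnorm(1, mean, sd)))
}

#' Initial simulation state
#'
#' Builds a `sim_state` at t = 0: both filaments at their poles in the
#' growing phase with freshly sampled speeds and catastrophe times, the
#' nucleus centre at `nucleus_init_frac * L` clamped to
#' `[r, L - r]`. Uses R's RNG for the initial draws.
#'
#' @param cell A [cell_config()].
#' @param kinetics A [kinetic_params()].
#' @param dt Time step (s), used to floor interval draws.
#' @return An object of class `sim_state`: fields `t`, `left`, `right`
#'   (each with `tip`, `phase`, sampled speeds and `next_change`),
#'   `nucleus_center`, `cell`.
#' @export
init_sim_state <- function(cell, kinetics, dt = 0.01) {
  stopifnot(inherits(cell, "cell_config"), inherits(kinetics, "kinetic_params"))
  L <- cell$length; r <- cell$nucleus_radius
  c0 <- min(max(cell$nucleus_init_frac * L, r), L - r)
  new_fil <- function(tip) {
    list(tip = tip, phase = "growing",
         v_poly = sample_speed(kinetics$v_poly_mean, kinetics$v_poly_sd),
         v_depoly = sample_speed(kinetics$v_depoly_mean, kinetics$v_depoly_sd),
         v_cat = sample_speed(kinetics$v_cat_mean, kinetics$v_cat_sd),
         next_change = draw_interval(kinetics$t_cat_mean, kinetics$t_cat_sd, dt))
  }
  structure(list(t = 0, left = new_fil(0), right = new_fil(L),
                 nucleus_center = c0, cell = cell),
            class = "sim_state")
}

check_sim_state <- function(state) {
  L <- state$cell$length; r <- state$cell$nucleus_radius
  c0 <- state$nucleus_center
  tol <- 1e-9
  if (c0 < r - tol || c0 > L - r + tol)
    stop("invalid state: nucleus centre outside [r, L - r]", call. = FALSE)
  if (state$left$tip < -tol || state$right$tip > L + tol)
    stop("invalid state: filament tip outside the cell", call. = FALSE)
  if (state$left$tip > c0 - r + tol || state$right$tip < c0 + r - tol)
    stop("invalid state: filament tip overlaps the nucleus", call. = FALSE)
  invisible(state)
}

#' Advance the simulation by one time step
#'
#' Applies, in order: phase bookkeeping (growth -> catastrophe draws a
#' recovery time; catastrophe -> growth re-samples speeds and draws the
#' next catastrophe time), tip displacement
#' `(v_poly - v_depoly - [catastrophe] v_cat) * dt` toward midcell,
#' collision resolution (push, limited by the opposite tip: a two-sided
#' contact jams all movement), and clamped nucleus diffusion. Stochastic
#' draws use R's RNG. This is the reference one-step interface; the
#' ensemble path runs the same displacement kernel in compiled code.
#'
#' @param state A `sim_state` (see [init_sim_state()]).
#' @param kinetics A [kinetic_params()].
#' @param dt Time step (s), > 0.
#' @return The advanced `sim_state`.
#' @export
pz_step <- function(state, kinetics, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  check_sim_state(state)
  cell <- state$cell
  advance_phase <- function(f) {
    if (state$t >= f$next_change) {
      if (f$phase == "growing") {
        f$phase <- "catastrophe"
        f$next_change <- state$t +
          draw_interval(kinetics$t_rec_mean, kinetics$t_rec_sd, dt)
      } else {
        f$phase <- "growing"
        f$v_poly <- sample_speed(kinetics$v_poly_mean, kinetics$v_poly_sd)
        f$v_depoly <- sample_speed(kinetics$v_depoly_mean, kinetics$v_depoly_sd)
        f$v_cat <- sample_speed(kinetics$v_cat_mean, kinetics$v_cat_sd)
        f$next_change <- state$t +
          draw_interval(kinetics$t_cat_mean, kinetics$t_cat_sd, dt)
      }
    }
    f
  }
  state$left <- advance_phase(state$left)
  state$right <- advance_phase(state$right)
  net <- function(f) f$v_poly - f$v_depoly -
    if (f$phase == "catastrophe") f$v_cat else 0
  d_left <- net(state$left) * dt
  d_right <- -net(state$right) * dt
  d_diff <- sqrt(2 * cell$nucleus_diffusion_coeff * dt) * rnorm(1)
  res <- resolve_step_cpp(state$left$tip, state$right$tip,
                          state$nucleus_center, d_left, d_right, d_diff,
                          cell$nucleus_radius, cell$length)
  state$left$tip <- res[["tip_left"]]
  state$right$tip <- res[["tip_right"]]
  state$nucleus_center <- res[["center"]]
  state$t <- state$t + dt
  state
}

#' Run a single simulation
#'
#' Iterates the stochastic step for `duration / dt` steps in compiled
#' code. Identical `(config, cell_length, run_seed)` give identical
#' output.
#'
#' @param config A [sim_config()].
#' @param cell_length Optional cell length (um) overriding
#'   `config$cell$length`.
#' @param run_seed Optional seed for this run; default derives run 0
#'   from the master seed.
#' @param mirror Internal flag: reflect the initial condition
#'   (`x -> L - x`), swap the filament RNG streams and negate the
#'   diffusion stream. With `mirror = TRUE` the output is the exact
#'   mirror image of the `mirror = FALSE` run, which the test suite uses
#'   to check that the update rule carries no left/right bias.
#' @return A list with class `phuz_run`: final `t`, `tip_left`,
#'   `tip_right`, `nucleus_center`, phases, and (when
#'   `config$record_trajectory`) a `trajectory` data.frame with columns
#'   `t_s, left_tip_um, right_tip_um, nucleus_center_um, left_phase,
#'   right_phase`.
#' @examples
#' cfg <- sim_config(duration = 60, seed = 7,
#'                   cell = cell_config(3.5), record_trajectory = TRUE)
#' run <- run_simulation(cfg)
#' run$nucleus_center
#' @export
run_simulation <- function(config, cell_length = NULL, run_seed = NULL,
                           mirror = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  cell <- config$cell
  if (!is.null(cell_length)) {
    if (cell_length <= 2 * cell$nucleus_radius)
      stop("cell_length (", cell_length, " um) must exceed twice the nucleus radius",
           call. = FALSE)
    cell$length <- cell_length
  }
  if (is.null(run_seed)) run_seed <- config$seed
  out <- simulate_run_cpp(cell$length, cell$nucleus_radius,
                          cell$nucleus_diffusion_coeff,
                          cell$nucleus_init_frac,
                          config$dt, config$duration,
                          unlist(unclass(config$kinetics)),
                          as.double(run_seed), 0,
                          if (config$record_trajectory) config$record_stride else 0L,
                          config$resample_interval, isTRUE(mirror))
  if (!is.null(out$trajectory)) {
    tr <- as.data.frame(out$trajectory)
    names(tr) <- c("t_s", "left_tip_um", "right_tip_um",
                   "nucleus_center_um", "left_phase", "right_phase")
    tr$left_phase <- ifelse(tr$left_phase == 1, "catastrophe", "growing")
    tr$right_phase <- ifelse(tr$right_phase == 1, "catastrophe", "growing")
    out$trajectory <- tr
  }
  out$cell_length <- cell$length
  class(out) <- "phuz_run"
  out
}

#' @export
print.phuz_run <- function(x, ...) {
  cat(sprintf("PhuZ run: L = %.2f um, t = %.0f s, nucleus centre %.3f um (%.3f of L)\n",
              x$cell_length, x$t, x$nucleus_center,
              x$nucleus_center / x$cell_length))
  invisible(x)
}

#' Run an ensemble of simulations
#'
#' Runs `config$n_runs` independent simulations, optionally drawing a
#' cell length per run from `cell_length_sampler`, and records the final
#' nucleus position of each. Per-run RNG streams are derived from the
#' master seed and the run counter, so the ensemble is reproducible and
#' run i does not change when `n_runs` does.
#'
#' @param config A [sim_config()].
#' @param cell_length_sampler Optional `function(n)` returning `n` cell
#'   lengths (um); called once per run on a run-specific R RNG substream.
#'   Lengths not exceeding twice the nucleus radius are re-drawn, up to
#'   100 retries. `NULL` uses the fixed `config$cell$length`.
#' @return An object of class `endpoint_ensemble`: a data.frame with
#'   columns `run, seed, cell_length_um, final_position_um,
#'   normalized_position`.
#' @examples
#' cfg <- sim_config(duration = 60, n_runs = 20, seed = 3)
#' ens <- run_ensemble(cfg)
#' mean(ens$normalized_position)
#' @export
run_ensemble <- function(config, cell_length_sampler = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_runs
  r2 <- 2 * config$cell$nucleus_radius
  lengths <- numeric(n)
  seeds <- numeric(n)
  finals <- numeric(n)
  for (i in seq_len(n)) {
    seeds[i] <- run_child_seed_cpp(config$seed, i, 0)
    if (is.null(cell_length_sampler)) {
      len <- config$cell$length
    } else {
      restore <- save_rng_state()
      set.seed(seeds[i])
      len <- cell_length_sampler(1)
      tries <- 0
      while (length(len) != 1 || !is.finite(len) || len <= r2) {
        tries <- tries + 1
        if (tries > 100)
          stop("cell_length_sampler failed to produce a feasible length (> ",
               r2, " um) after 100 retries", call. = FALSE)
        len <- cell_length_sampler(1)
      }
      restore()
    }
    lengths[i] <- len
    run <- run_simulation_raw(config, len, config$seed, i)
    finals[i] <- run$nucleus_center
  }
  out <- data.frame(run = seq_len(n), seed = seeds,
                    cell_length_um = lengths,
                    final_position_um = finals,
                    normalized_position = finals / lengths)
  attr(out, "master_seed") <- config$seed
  class(out) <- c("endpoint_ensemble", "data.frame")
  out
}

# minimal-state run: no trajectory, explicit run index under the master seed
run_simulation_raw <- function(config, cell_length, master_seed, run_index) {
  cell <- config$cell
  simulate_run_cpp(cell_length, cell$nucleus_radius,
                   cell$nucleus_diffusion_coeff, cell$nucleus_init_frac,
                   config$dt, config$duration,
                   unlist(unclass(config$kinetics)),
                   as.double(master_seed), as.double(run_index),
                   0L, config$resample_interval, FALSE)
}

# save/restore the global R RNG state; returns a restore closure
save_rng_state <- function() {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (had) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' @export
print.endpoint_ensemble <- function(x, ...) {
  cat(sprintf("Endpoint ensemble: %d runs, mean normalized position %.3f, central-20%% fraction %.3f\n",
              nrow(x), mean(x$normalized_position),
              centering_fraction(x)))
  invisible(x)
}
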