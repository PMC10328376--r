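#' Kinetic parameters of PhuZ filament dynamic instability
#'
#' Each filament movement rate is described by the mean and standard
#' deviation of a Gaussian; speeds are re-sampled at every phase change
#' (catastrophe onset and recovery) and negative draws are truncated to
#' zero. During growth a tip drifts at `v_poly - v_depoly` toward
#' midcell; during a catastrophe the catastrophic depolymerization speed
#' `v_cat` is subtracted as well. Growth intervals (time to catastrophe)
#' and catastrophe durations (time to recovery) are Gaussian draws,
#' truncated at zero and floored at one time step.
#'
#' The defaults are an illustrative calibrated set, obtained with the
#' package's own RMSD calibration against a control-like nucleus-position
#' distribution in 3.5 um cells (see the methods vignette); they are not
#' measured values.
#'
#' @param v_poly_mean,v_poly_sd Polymerization speed (um/s).
#' @param v_depoly_mean,v_depoly_sd Depolymerization speed during growth
#'   (um/s).
#' @param v_cat_mean,v_cat_sd Catastrophic depolymerization speed, active
#'   only during the catastrophe phase (um/s).
#' @param t_cat_mean,t_cat_sd Growth duration before catastrophe (s).
#' @param t_rec_mean,t_rec_sd Catastrophe duration before recovery (s).
#' @return An object of class `kinetic_params` (named list of the ten
#'   values).
#' @examples
#' kin <- kinetic_params(v_poly_mean = 0.04, v_poly_sd = 0.008)
#' kin$v_poly_mean
#' @export
kinetic_params <- function(v_poly_mean = 0.073, v_poly_sd = 0.012,
                           v_depoly_mean = 0.01, v_depoly_sd = 0.004,
                           v_cat_mean = 0.5, v_cat_sd = 0.075,
                           t_cat_mean = 25.5, t_cat_sd = 2,
                           t_rec_mean = 6, t_rec_sd = 0.9) {
  kin <- list(v_poly_mean = v_poly_mean, v_poly_sd = v_poly_sd,
              v_depoly_mean = v_depoly_mean, v_depoly_sd = v_depoly_sd,
              v_cat_mean = v_cat_mean, v_cat_sd = v_cat_sd,
              t_cat_mean = t_cat_mean, t_cat_sd = t_cat_sd,
              t_rec_mean = t_rec_mean, t_rec_sd = t_rec_sd)
  for (nm in names(kin)) {
    v <- kin[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("kinetic parameter '", nm, "' must be a single finite value >= 0",
           call. = FALSE)
  }
  structure(kin, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("PhuZ filament kinetics (Gaussian mean +/- sd):\n")
  cat(sprintf("  v_poly   %.4f +/- %.4f um/s\n", x$v_poly_mean, x$v_poly_sd))
  cat(sprintf("  v_depoly %.4f +/- %.4f um/s\n", x$v_depoly_mean, x$v_depoly_sd))
  cat(sprintf("  v_cat    %.4f +/- %.4f um/s\n", x$v_cat_mean, x$v_cat_sd))
  cat(sprintf("  t_cat    %.1f +/- %.1f s\n", x$t_cat_mean, x$t_cat_sd))
  cat(sprintf("  t_rec    %.1f +/- %.1f s\n", x$t_rec_mean, x$t_rec_sd))
  invisible(x)
}

kinetics_fields <- function() names(unclass(kinetic_params()))

#' Cell geometry and nucleus transport properties
#'
#' @param length Cell length L (um); must exceed twice the nucleus
#'   radius so that the nucleus fits inside the cell.
#' @param nucleus_radius Physical half-length of the nucleus used for
#'   collision geometry (um). Exposed separately from the Stokes radius:
#'   the hydrodynamic radius only sets the diffusion coefficient.
#' @param nucleus_diffusion_coeff Diffusion coefficient of the nucleus
#'   (um^2/s). Default `NULL` computes the Stokes-Einstein value for a
#'   sphere of `stokes_radius` at 310 K in water ([stokes_einstein_D()]).
#' @param nucleus_init_frac Initial nucleus centre as a fraction of cell
#'   length (default 0.9, near the pole where phage DNA is injected);
#'   the implied centre is clamped to `[r, L - r]`.
#' @param stokes_radius Hydrodynamic radius used only for the default
#'   diffusion coefficient (um).
#' @return An object of class `cell_config`.
#' @examples
#' cell_config(length = 3.5)
#' @export
cell_config <- function(length = 3.5, nucleus_radius = 0.5,
                        nucleus_diffusion_coeff = NULL,
                        nucleus_init_frac = 0.9,
                        stokes_radius = 1) {
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length))
    stop("cell length must be a single finite number", call. = FALSE)
  if (nucleus_radius <= 0)
    stop("nucleus_radius must be > 0", call. = FALSE)
  if (length <= 2 * nucleus_radius)
    stop("cell length (", length, " um) must exceed twice the nucleus radius (",
         2 * nucleus_radius, " um)", call. = FALSE)
  if (nucleus_init_frac <= 0 || nucleus_init_frac >= 1)
    stop("nucleus_init_frac must lie strictly between 0 and 1", call. = FALSE)
  if (is.null(nucleus_diffusion_coeff))
    nucleus_diffusion_coeff <- stokes_einstein_D(stokes_radius)
  if (nucleus_diffusion_coeff < 0)
    stop("nucleus_diffusion_coeff must be >= 0", call. = FALSE)
  structure(list(length = length, nucleus_radius = nucleus_radius,
                 nucleus_diffusion_coeff = nucleus_diffusion_coeff,
                 nucleus_init_frac = nucleus_init_frac,
                 stokes_radius = stokes_radius),
            class = "cell_config")
}

#' @export
print.cell_config <- function(x, ...) {
  cat(sprintf("Cell: L = %.2f um, nucleus radius %.2f um, D = %.4f um^2/s, start at %.0f%% of L\n",
              x$length, x$nucleus_radius, x$nucleus_diffusion_coeff,
              100 * x$nucleus_init_frac))
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles kinetics, cell geometry and run control for
#' [run_simulation()] and [run_ensemble()].
#'
#' @param dt Time step (s). The model was designed around 0.01 s;
#'   coarser steps trade accuracy for speed (see the methods vignette
#'   for a convergence check).
#' @param duration Simulated time (s); default 1800 s = 30 minutes post
#'   infection, the endpoint at which nucleus positions are scored.
#' @param n_runs Ensemble size (default 500).
#' @param seed Master seed; per-run RNG streams are derived from it by a
#'   counter-based scheme so earlier runs are unchanged when `n_runs`
#'   grows.
#' @param kinetics A [kinetic_params()] object.
#' @param cell A [cell_config()] object.
#' @param record_trajectory If `TRUE`, [run_simulation()] returns the
#'   time series of tips and nucleus centre.
#' @param record_stride Record every this-many steps (plus the initial
#'   and final state) when recording a trajectory.
#' @param resample_interval Optional fixed interval (s) at which filament
#'   speeds are re-sampled in addition to phase changes; `Inf` (default)
#'   re-samples at phase changes only.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(duration = 60, n_runs = 10, seed = 1)
#' @export
sim_config <- function(dt = 0.01, duration = 1800, n_runs = 500, seed = 1,
                       kinetics = kinetic_params(), cell = cell_config(),
                       record_trajectory = FALSE, record_stride = 100,
                       resample_interval = Inf) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  if (duration > 0 && duration < dt)
    stop("duration must be 0 or >= dt", call. = FALSE)
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  if (!inherits(kinetics, "kinetic_params"))
    stop("kinetics must be a kinetic_params object", call. = FALSE)
  if (!inherits(cell, "cell_config"))
    stop("cell must be a cell_config object", call. = FALSE)
  if (record_stride < 1) stop("record_stride must be >= 1", call. = FALSE)
  if (!(is.infinite(resample_interval) || resample_interval > 0))
    stop("resample_interval must be > 0 or Inf", call. = FALSE)
  structure(list(dt = dt, duration = duration, n_runs = as.integer(n_runs),
                 seed = as.integer(seed), kinetics = kinetics, cell = cell,
                 record_trajectory = isTRUE(record_trajectory),
                 record_stride = as.integer(record_stride),
                 resample_interval = resample_interval),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation: dt = %g s, duration = %g s (%.1f min), n_runs = %d, seed = %d\n",
              x$dt, x$duration, x$duration / 60, x$n_runs, x$seed))
  print(x$cell)
  print(x$kinetics)
  invisible(x)
}
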