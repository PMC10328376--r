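#' Define a sweep axis
#'
#' @param name `"cell_length"` or a kinetic parameter field (e.g.
#'   `"v_poly_mean"`).
#' @param from,to Axis range.
#' @param n_steps Number of grid values (>= 2).
#' @return A `sweep_axis` list.
#' @export
sweep_axis <- function(name, from, to, n_steps) {
  if (!(name == "cell_length" || name %in% kinetics_fields()))
    stop("unknown sweep axis '", name,
         "'; use \"cell_length\" or a kinetic parameter field", call. = FALSE)
  if (n_steps < 2) stop("n_steps must be >= 2", call. = FALSE)
  if (!(to > from)) stop("axis range must have to > from", call. = FALSE)
  structure(list(name = name, values = seq(from, to, length.out = n_steps)),
            class = "sweep_axis")
}

apply_axis <- function(config, axis_name, value) {
  if (axis_name == "cell_length") {
    config$cell$length <- value
  } else {
    kin <- unclass(config$kinetics)
    kin[[axis_name]] <- value
    config$kinetics <- do.call(kinetic_params, kin)
  }
  config
}

#' Centering phase-space sweep
#'
#' For every combination of two axis values (typically cell length and
#' polymerization rate), runs an endpoint ensemble and records the
#' fraction of final nucleus positions inside the central window. Cells
#' are classified as "centering" when that fraction strictly exceeds
#' `centered_threshold` (default > 0.8, the heatmap criterion for
#' efficient centering within the central 20% of the cell).
#'
#' @param axis_x,axis_y [sweep_axis()] objects. A `cell_length` axis
#'   must stay above twice the nucleus radius.
#' @param sim_config Base [sim_config()]; its `n_runs` is replaced by
#'   `runs_per_cell`.
#' @param runs_per_cell Ensemble size per grid cell (default 100;
#'   raise toward 500 for production-quality maps).
#' @param window Central window width (fraction of cell length).
#' @param centered_threshold Classification threshold on the centering
#'   fraction.
#' @param seed Master seed; each grid cell gets a derived child seed.
#' @return A `centering_sweep` object: `fraction` and `centered`
#'   matrices (rows = x axis, columns = y axis), the axes, and a long
#'   data.frame `long` with columns `axis1, axis2,
#'   centering_fraction, centered`.
#' @export
centering_sweep <- function(axis_x, axis_y, sim_config,
                            runs_per_cell = 100, window = 0.2,
                            centered_threshold = 0.8, seed = 1) {
  stopifnot(inherits(axis_x, "sweep_axis"), inherits(axis_y, "sweep_axis"),
            inherits(sim_config, "sim_config"))
  if (window <= 0 || window >= 1) stop("window must be in (0, 1)", call. = FALSE)
  if (centered_threshold <= 0 || centered_threshold >= 1)
    stop("centered_threshold must be in (0, 1)", call. = FALSE)
  r2 <- 2 * sim_config$cell$nucleus_radius
  if (axis_x$name == "cell_length" && any(axis_x$values <= r2))
    stop("cell_length axis values must exceed twice the nucleus radius",
         call. = FALSE)
  if (axis_y$name == "cell_length" && any(axis_y$values <= r2))
    stop("cell_length axis values must exceed twice the nucleus radius",
         call. = FALSE)
  nx <- length(axis_x$values); ny <- length(axis_y$values)
  frac <- matrix(NA_real_, nx, ny,
                 dimnames = list(signif(axis_x$values, 6),
                                 signif(axis_y$values, 6)))
  cell_idx <- 0L
  cfg0 <- sim_config
  cfg0$n_runs <- as.integer(runs_per_cell)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      cell_idx <- cell_idx + 1L
      cfg <- apply_axis(apply_axis(cfg0, axis_x$name, axis_x$values[i]),
                        axis_y$name, axis_y$values[j])
      cfg$seed <- as.integer(run_child_seed_cpp(seed, cell_idx, 31))
      ens <- run_ensemble(cfg)
      frac[i, j] <- centering_fraction(ens, window = window)
    }
  }
  long <- expand.grid(axis1 = axis_x$values, axis2 = axis_y$values,
                      KEEP.OUT.ATTRS = FALSE)
  long$centering_fraction <- as.vector(frac)
  long$centered <- long$centering_fraction > centered_threshold
  structure(list(fraction = frac, centered = frac > centered_threshold,
                 axis_x = axis_x, axis_y = axis_y, long = long,
                 window = window, centered_threshold = centered_threshold,
                 runs_per_cell = runs_per_cell, seed = seed),
            class = "centering_sweep")
}

#' @export
print.centering_sweep <- function(x, ...) {
  cat(sprintf("Centering sweep: %s (%d) x %s (%d), %d runs/cell; %d of %d cells centered (> %.0f%% in central %.0f%%)\n",
              x$axis_x$name, length(x$axis_x$values),
              x$axis_y$name, length(x$axis_y$values), x$runs_per_cell,
              sum(x$centered), length(x$centered),
              100 * x$centered_threshold, 100 * x$window))
  invisible(x)
}
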