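#' Treatment profile for synthetic single-cell data
#'
#' Describes one treatment condition: a Gaussian cell-length population
#' and how nucleus positions are generated. In `"simulator"` mode each
#' cell's position comes from a full spindle simulation; in
#' `"parametric"` mode positions are drawn from a mixture of a centered
#' Gaussian (weight `1 - w`, sd `center_sd` around midcell, rejected to
#' `[0, 1]`) and a uniform component on
#' `[uniform_min, uniform_max]` (weight `w`), which isolates the
#' statistics pipeline from the simulator.
#'
#' @param label Treatment label.
#' @param length_mean,length_sd Gaussian cell-length parameters (um).
#' @param n_cells Number of cells.
#' @param mode `"parametric"` or `"simulator"`.
#' @param w Mixture weight of the uniform component, in `[0, 1]`.
#' @param center_sd SD of the centered Gaussian component (fraction of
#'   cell length).
#' @param uniform_min,uniform_max Support of the uniform component
#'   (fractions of cell length); the defaults exclude the outermost 5%
#'   at each pole, where the nucleus centre cannot physically sit.
#' @return A `treatment_profile`.
#' @export
treatment_profile <- function(label, length_mean, length_sd, n_cells,
                              mode = c("parametric", "simulator"),
                              w = 0, center_sd = 0.08,
                              uniform_min = 0.05, uniform_max = 0.95) {
  mode <- match.arg(mode)
  if (length_mean <= 0 || length_sd < 0)
    stop("length_mean must be > 0 and length_sd >= 0", call. = FALSE)
  if (w < 0 || w > 1) stop("w must lie in [0, 1]", call. = FALSE)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (!(uniform_min < uniform_max) || uniform_min < 0 || uniform_max > 1)
    stop("uniform support must satisfy 0 <= uniform_min < uniform_max <= 1",
         call. = FALSE)
  structure(list(label = label, length_mean = length_mean,
                 length_sd = length_sd, n_cells = as.integer(n_cells),
                 mode = mode, w = w, center_sd = center_sd,
                 uniform_min = uniform_min, uniform_max = uniform_max),
            class = "treatment_profile")
}

#' Sample cell lengths for a treatment profile
#'
#' Gaussian draws, rejection-resampled until each length exceeds twice
#' the nucleus radius (the nucleus must fit in the cell). Uses R's RNG.
#'
#' @param profile A [treatment_profile()].
#' @param nucleus_radius Nucleus radius (um) defining the feasibility
#'   bound.
#' @param n Number of lengths; default `profile$n_cells`.
#' @return Numeric vector of feasible cell lengths (um).
#' @export
sample_cell_lengths <- function(profile, nucleus_radius = 0.5, n = NULL) {
  stopifnot(inherits(profile, "treatment_profile"))
  if (is.null(n)) n <- profile$n_cells
  lo <- 2 * nucleus_radius
  if (profile$length_sd == 0 && profile$length_mean <= lo)
    stop("infeasible profile: fixed length <= 2 * nucleus_radius", call. = FALSE)
  out <- numeric(n)
  for (i in seq_len(n)) {
    len <- rnorm(1, profile$length_mean, profile$length_sd)
    tries <- 0
    while (len <= lo) {
      tries <- tries + 1
      if (tries > 1000)
        stop("infeasible profile '", profile$label,
             "': could not draw a length > ", lo, " um in 1000 tries",
             call. = FALSE)
      len <- rnorm(1, profile$length_mean, profile$length_sd)
    }
    out[i] <- len
  }
  out
}

# one parametric normalized position (mixture draw), rejected to [0, 1]
draw_parametric_position <- function(profile) {
  if (runif(1) < profile$w) {
    runif(1, profile$uniform_min, profile$uniform_max)
  } else {
    p <- rnorm(1, 0.5, profile$center_sd)
    while (p < 0 || p > 1) p <- rnorm(1, 0.5, profile$center_sd)
    p
  }
}

#' Expected off-center fraction of a parametric profile
#'
#' Closed-form expectation of [off_center_fraction()] under the
#' parametric position mixture: the uniform component contributes the
#' fraction of its support outside the central window, the centered
#' Gaussian its truncated-to-`[0, 1]` tail mass beyond
#' `central_width / 2`.
#'
#' @param profile A [treatment_profile()] (parametric fields used).
#' @param central_width Central window width.
#' @return Expected off-center fraction.
#' @export
expected_off_center_parametric <- function(profile, central_width = 0.2) {
  half <- central_width / 2
  lo <- profile$uniform_min; hi <- profile$uniform_max
  inside <- max(0, min(hi, 0.5 + half) - max(lo, 0.5 - half))
  p_unif <- 1 - inside / (hi - lo)
  s <- profile$center_sd
  if (s == 0) {
    p_gauss <- 0
  } else {
    z_tot <- pnorm(0.5 / s) - pnorm(-0.5 / s)          # mass in [0, 1]
    z_in <- pnorm(half / s) - pnorm(-half / s)         # mass in the window
    p_gauss <- 1 - z_in / z_tot
  }
  profile$w * p_unif + (1 - profile$w) * p_gauss
}

#' Tune the uniform mixture weight for a target off-center fraction
#'
#' Inverts [expected_off_center_parametric()] for `w`.
#'
#' @param target Desired expected off-center fraction.
#' @param center_sd,uniform_min,uniform_max Mixture shape parameters.
#' @param central_width Central window width.
#' @return Weight `w` in `[0, 1]`.
#' @export
tune_uniform_weight <- function(target, center_sd = 0.08,
                                uniform_min = 0.05, uniform_max = 0.95,
                                central_width = 0.2) {
  p0 <- expected_off_center_parametric(
    treatment_profile("tmp", 1, 0, 1, w = 0, center_sd = center_sd,
                      uniform_min = uniform_min, uniform_max = uniform_max),
    central_width)
  p1 <- expected_off_center_parametric(
    treatment_profile("tmp", 1, 0, 1, w = 1, center_sd = center_sd,
                      uniform_min = uniform_min, uniform_max = uniform_max),
    central_width)
  if (target < min(p0, p1) || target > max(p0, p1))
    stop("target off-center fraction ", target,
         " is not reachable with this mixture shape (range ",
         signif(min(p0, p1), 3), " to ", signif(max(p0, p1), 3), ")",
         call. = FALSE)
  (target - p0) / (p1 - p0)
}

#' Generate a synthetic single-cell measurement table
#'
#' Emulates a deposited per-cell measurement table: one row per cell
#' with treatment label, timepoint, cell length and nucleus position
#' (um from the left pole). Positions come either from full spindle
#' simulations at each sampled cell length (`mode = "simulator"`) or
#' from the parametric mixture. Optional Gaussian measurement noise is
#' added to the position and clamped to `[0, length]`.
#'
#' @param profiles A [treatment_profile()] or list of them.
#' @param sim_config A [sim_config()]; required for simulator-mode
#'   profiles and supplying the nucleus radius for length feasibility.
#' @param seed Master seed.
#' @param timepoint_min Timepoint recorded for all rows (minutes post
#'   infection); default 30.
#' @param measurement_noise_sd Gaussian noise on the measured position
#'   (um); default 0.
#' @return Data.frame with columns `treatment, timepoint_min,
#'   cell_length_um, nucleus_position_um`, with the generating profiles
#'   attached as attribute `"ground_truth"`.
#' @export
generate_measurement_table <- function(profiles, sim_config = NULL,
                                       seed = 1, timepoint_min = 30,
                                       measurement_noise_sd = 0) {
  if (is.null(sim_config)) sim_config <- phuzsim::sim_config()
  if (inherits(profiles, "treatment_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "treatment_profile")))
  restore <- save_rng_state()
  on.exit(restore())
  tabs <- lapply(seq_along(profiles), function(k) {
    pr <- profiles[[k]]
    set.seed(run_child_seed_cpp(seed, k, 41))
    lens <- sample_cell_lengths(pr, sim_config$cell$nucleus_radius)
    pos <- numeric(pr$n_cells)
    for (i in seq_len(pr$n_cells)) {
      if (pr$mode == "simulator") {
        run <- run_simulation_raw(sim_config, lens[i],
                                  run_child_seed_cpp(seed, k, 43), i)
        pos[i] <- run$nucleus_center
      } else {
        pos[i] <- draw_parametric_position(pr) * lens[i]
      }
      if (measurement_noise_sd > 0)
        pos[i] <- min(max(pos[i] + rnorm(1, 0, measurement_noise_sd), 0), lens[i])
    }
    data.frame(treatment = pr$label, timepoint_min = timepoint_min,
               cell_length_um = lens, nucleus_position_um = pos)
  })
  out <- do.call(rbind, tabs)
  attr(out, "ground_truth") <- profiles
  out
}

#' Write a deterministic suite of synthetic fixtures
#'
#' Generates four illustrative parametric treatment tables -- a
#' control-like condition in normal-length cells, two
#' elongation-like conditions with increasing cell length and
#' off-center fraction (ceftazidime- and piperacillin-like), and a
#' division-blocked (SulA-like) condition whose positions are uniform
#' over the cell interior and excluded from the poles -- plus a JSON
#' manifest recording every file and its generating parameters. The
#' per-treatment means are illustrative choices, not measured values;
#' the control and piperacillin-like off-center fractions are tuned to
#' the reported 24% and 60%.
#'
#' @param seed Master seed; the same seed yields byte-identical files.
#' @param out_dir Output directory (created if needed).
#' @param n_cells Cells per treatment (default 400).
#' @return Invisibly, the manifest as a list.
#' @export
make_fixture_suite <- function(seed, out_dir, n_cells = 400) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- fixture_profiles(n_cells)
  files <- character(0)
  for (pr in profiles) {
    tab <- generate_measurement_table(pr, seed = seed)
    f <- file.path(out_dir, paste0(tolower(pr$label), ".csv"))
    write_measurements(tab, f)
    files <- c(files, basename(f))
  }
  manifest <- list(
    seed = seed, n_cells = n_cells, files = files,
    note = paste("synthetic single-cell fixtures; per-treatment length",
                 "means are illustrative, not measured values"),
    ground_truth = lapply(profiles, unclass))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# illustrative per-treatment profiles: control ~3.5 um, elongated
# conditions 2-4x longer; control and PIP-like off-center fractions are
# tuned to the reported 24% and 60%
fixture_profiles <- function(n_cells = 400) {
  list(
    treatment_profile("control", 3.5, 0.6, n_cells,
                      w = tune_uniform_weight(0.24, center_sd = 0.08),
                      center_sd = 0.08),
    treatment_profile("ceft_like", 7, 2, n_cells,
                      w = tune_uniform_weight(0.45, center_sd = 0.11),
                      center_sd = 0.11),
    treatment_profile("pip_like", 9, 2.5, n_cells,
                      w = tune_uniform_weight(0.60, center_sd = 0.13),
                      center_sd = 0.13),
    treatment_profile("sula_like", 12, 4, n_cells, w = 1)
  )
}
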