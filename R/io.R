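#' Load a simulation configuration from YAML
#'
#' Reads a YAML file with the optional top-level sections `simulation`,
#' `kinetics` and `cell`; missing keys take the package defaults
#' (dt = 0.01 s, duration = 1800 s, n_runs = 500, and the illustrative
#' calibrated kinetics). Unknown keys at any level are rejected,
#' naming every offending key.
#'
#' @param path Path to a YAML configuration file; see
#'   `system.file("extdata", "phuz_default.yaml", package = "phuzsim")`
#'   for a fully documented example.
#' @return A validated [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_keys(raw, c("simulation", "kinetics", "cell"), "top level")
  sim <- raw$simulation %||% list()
  check_keys(sim, c("dt", "duration", "duration_min", "n_runs", "seed",
                    "record_trajectory", "record_stride", "resample_interval"),
             "simulation")
  if (!is.null(sim[["duration"]]) && !is.null(sim[["duration_min"]]))
    stop("specify either duration (s) or duration_min, not both", call. = FALSE)
  if (!is.null(sim[["duration_min"]])) sim$duration <- sim[["duration_min"]] * 60
  sim[["duration_min"]] <- NULL
  kin <- raw$kinetics %||% list()
  check_keys(kin, kinetics_fields(), "kinetics")
  cellraw <- raw$cell %||% list()
  check_keys(cellraw, c("length", "nucleus_radius", "nucleus_diffusion_coeff",
                        "nucleus_init_frac", "stokes_radius"), "cell")
  args <- sim
  args$kinetics <- do.call(kinetic_params, kin)
  args$cell <- do.call(cell_config, cellraw)
  do.call(sim_config, args)
}

#' Shipped default configuration
#'
#' Loads the packaged configuration file
#' (`inst/extdata/phuz_default.yaml`): the illustrative calibrated
#' kinetic set, 3.5 um cells and the standard run control (dt = 0.01 s,
#' 30 min, 500 runs).
#'
#' @return A [sim_config()].
#' @export
phuz_default_config <- function() {
  load_config(system.file("extdata", "phuz_default.yaml", package = "phuzsim",
                          mustWork = TRUE))
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  invisible(x)
}

#' Save a simulation configuration as YAML
#'
#' Writes the full resolved configuration (all defaults filled in), so
#' the file round-trips through [load_config()].
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- list(
    simulation = list(dt = config$dt, duration = config$duration,
                      n_runs = config$n_runs, seed = config$seed,
                      record_trajectory = config$record_trajectory,
                      record_stride = config$record_stride,
                      resample_interval = config$resample_interval),
    kinetics = unclass(config$kinetics),
    cell = unclass(config$cell))
  yaml::write_yaml(out, path)
  invisible(path)
}

measurement_columns <- c("treatment", "timepoint_min", "cell_length_um",
                         "nucleus_position_um")

#' Read a single-cell measurement table
#'
#' Reads a delimited table of per-cell nucleus measurements with
#' columns `treatment, timepoint_min, cell_length_um,
#' nucleus_position_um` (positions in um from the reference pole).
#' Other column names can be mapped onto the canonical schema with
#' `column_mapping`. Rows violating the invariants (non-positive
#' length, position outside `[0, length]`, missing values) are dropped
#' with a per-row warning.
#'
#' @param path CSV file with a header.
#' @param column_mapping Optional named character vector mapping
#'   canonical names to the file's column names, e.g.
#'   `c(cell_length_um = "Length")`.
#' @return Data.frame with the canonical columns.
#' @export
read_measurements <- function(path, column_mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_mapping)) {
    for (canon in names(column_mapping)) {
      src <- column_mapping[[canon]]
      if (!src %in% names(tab))
        stop("mapped column '", src, "' not present in ", path, call. = FALSE)
      names(tab)[names(tab) == src] <- canon
    }
  }
  missing_cols <- setdiff(measurement_columns, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  tab <- tab[measurement_columns]
  ok <- is.finite(tab$cell_length_um) & tab$cell_length_um > 0 &
    is.finite(tab$nucleus_position_um) & tab$nucleus_position_um >= 0 &
    tab$nucleus_position_um <= tab$cell_length_um
  if (any(!ok)) {
    warning("rejected ", sum(!ok), " invalid row(s): ",
            paste(utils::head(which(!ok), 10), collapse = ", "),
            if (sum(!ok) > 10) ", ..." else "")
    tab <- tab[ok, , drop = FALSE]
  }
  if (!nrow(tab)) stop("no valid rows in ", path, call. = FALSE)
  rownames(tab) <- NULL
  tab
}

#' Write a single-cell measurement table
#'
#' @param measurements Data.frame with the canonical measurement
#'   columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  stopifnot(all(measurement_columns %in% names(measurements)))
  write.csv(measurements[measurement_columns], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Write an endpoint ensemble as CSV
#'
#' Columns: `run, seed, cell_length_um, final_position_um,
#' normalized_position`.
#'
#' @param ensemble An `endpoint_ensemble` from [run_ensemble()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "endpoint_ensemble"))
  write.csv(as.data.frame(ensemble), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a recorded trajectory as CSV
#'
#' Columns: `t_s, left_tip_um, right_tip_um, nucleus_center_um,
#' left_phase, right_phase`.
#'
#' @param run A `phuz_run` with a recorded trajectory.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(run, path) {
  stopifnot(inherits(run, "phuz_run"))
  if (is.null(run$trajectory))
    stop("run has no recorded trajectory; set record_trajectory = TRUE",
         call. = FALSE)
  write.csv(run$trajectory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to re-run an invocation bit-identically
#' with the same build: the subcommand, the fully resolved
#' configuration, the master seed, package version, MD5 digests of the
#' input and output files, and wall-clock metadata.
#'
#' @param path Output JSON path.
#' @param subcommand Name of the operation performed.
#' @param config The resolved [sim_config()] (or `NULL`).
#' @param seed Master seed used.
#' @param inputs,outputs Character vectors of file paths to digest.
#' @param extra Optional named list of additional fields.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, subcommand, config = NULL, seed = NULL,
                           inputs = character(0), outputs = character(0),
                           extra = list()) {
  digest <- function(files) {
    files <- files[file.exists(files)]
    as.list(tools::md5sum(files))
  }
  manifest <- c(list(
    subcommand = subcommand,
    package = "phuzsim",
    version = as.character(utils::packageVersion("phuzsim")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (!is.null(config)) list(
      simulation = list(dt = config$dt, duration = config$duration,
                        n_runs = config$n_runs, seed = config$seed,
                        resample_interval = config$resample_interval),
      kinetics = unclass(config$kinetics),
      cell = unclass(config$cell)),
    input_digests = digest(inputs),
    output_digests = digest(outputs)), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
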