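#' Normalize nucleus positions to cell length
#'
#' Converts measured nucleus positions (um from the reference pole) to
#' fractions of cell length. Records with non-positive cell length or a
#' position outside `[0, length]` are dropped with a warning.
#'
#' @param measurements A data.frame of single-cell measurements with
#'   columns `cell_length_um` and `nucleus_position_um` (as returned by
#'   [read_measurements()] or [generate_measurement_table()]).
#' @param fold If `TRUE`, map `p -> min(p, 1 - p)` so positions are
#'   measured from the nearer pole (range `[0, 0.5]`); use when the pole
#'   identity of the reference is unknown. Default unfolded.
#' @return Numeric vector of normalized positions.
#' @examples
#' m <- data.frame(cell_length_um = c(4, 5), nucleus_position_um = c(2, 4.5))
#' normalize_positions(m)            # 0.5 0.9
#' normalize_positions(m, fold = TRUE)  # 0.5 0.1
#' @export
normalize_positions <- function(measurements, fold = FALSE) {
  stopifnot(is.data.frame(measurements),
            all(c("cell_length_um", "nucleus_position_um") %in% names(measurements)))
  len <- measurements$cell_length_um
  pos <- measurements$nucleus_position_um
  bad <- !is.finite(len) | !is.finite(pos) | len <= 0 | pos < 0 | pos > len
  if (any(bad)) {
    warning(sum(bad), " record(s) rejected (non-positive length or position outside [0, length])")
    len <- len[!bad]; pos <- pos[!bad]
  }
  if (!length(len)) stop("no valid measurements", call. = FALSE)
  p <- pos / len
  if (fold) p <- pmin(p, 1 - p)
  p
}

#' Fraction of nuclei outside the central window
#'
#' A nucleus at normalized position p is off-center when
#' `|p - 0.5| > central_width / 2` (strict: landing exactly on the
#' boundary counts as centered). With the default window of 0.2 this is
#' the "outside the middle 20% of the cell" statistic used to quantify
#' antibiotic-induced mispositioning.
#'
#' @param normalized_positions Numeric vector in `[0, 1]`.
#' @param central_width Width of the central window as a fraction of
#'   cell length, in (0, 1); default 0.2.
#' @return Fraction in `[0, 1]`.
#' @examples
#' off_center_fraction(c(0.45, 0.55, 0.30, 0.70))  # 0.5
#' @export
off_center_fraction <- function(normalized_positions, central_width = 0.2) {
  p <- normalized_positions
  if (!length(p)) stop("empty position vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("normalized positions must lie in [0, 1]", call. = FALSE)
  if (central_width <= 0 || central_width >= 1)
    stop("central_width must lie strictly between 0 and 1", call. = FALSE)
  mean(abs(p - 0.5) > central_width / 2)
}

#' Fraction of endpoints inside the central window
#'
#' Complement of [off_center_fraction()]; the Fig-7D-style centering
#' efficiency of an ensemble.
#'
#' @param x An `endpoint_ensemble` (from [run_ensemble()]) or a numeric
#'   vector of normalized positions.
#' @param window Central window width (fraction of cell length).
#' @return Fraction in `[0, 1]`.
#' @export
centering_fraction <- function(x, window = 0.2) {
  p <- if (inherits(x, "endpoint_ensemble")) x$normalized_position else x
  1 - off_center_fraction(p, central_width = window)
}

#' Binned probability distribution of normalized positions
#'
#' Equal-width bins on `[0, 1]` (final bin right-closed), probability
#' normalized. This is the histogram compared between model and
#' measurement and the unit of the RMSD calibration objective.
#'
#' @param normalized_positions Numeric vector in `[0, 1]`.
#' @param n_bins Number of bins (>= 2); default 10.
#' @return An object of class `position_distribution`: list with
#'   `bin_edges` (length `n_bins + 1`), `probabilities` (sum 1),
#'   `counts`, `n`.
#' @examples
#' d <- position_histogram(c(0.5, 0.52, 0.9), n_bins = 10)
#' sum(d$probabilities)  # 1
#' @export
position_histogram <- function(normalized_positions, n_bins = 10) {
  p <- normalized_positions
  if (!length(p)) stop("empty position vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("normalized positions must lie in [0, 1]", call. = FALSE)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(floor(p * n_bins) + 1L, n_bins)   # [k/n, (k+1)/n), last closed
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, probabilities = counts / length(p),
                 counts = counts, n = length(p)),
            class = "position_distribution")
}

#' @export
print.position_distribution <- function(x, ...) {
  cat(sprintf("Position distribution: %d bins, n = %d\n",
              length(x$probabilities), x$n))
  print(round(x$probabilities, 3))
  invisible(x)
}

#' RMSD between two binned position distributions
#'
#' Root mean squared difference of the per-bin probabilities,
#' `sqrt(mean((a_i - b_i)^2))`. The two distributions must share bin
#' edges. This is the calibration objective comparing modeled and
#' measured nucleus-position histograms.
#'
#' @param a,b `position_distribution` objects with identical
#'   `bin_edges`.
#' @return Non-negative RMSD; 0 iff the distributions are identical.
#' @examples
#' a <- position_histogram(c(0.1, 0.9), n_bins = 2)
#' b <- position_histogram(c(0.1, 0.2), n_bins = 2)
#' rmsd_between_distributions(a, b)  # 0.5
#' @export
rmsd_between_distributions <- function(a, b) {
  stopifnot(inherits(a, "position_distribution"),
            inherits(b, "position_distribution"))
  if (length(a$bin_edges) != length(b$bin_edges) ||
      any(abs(a$bin_edges - b$bin_edges) > 1e-12))
    stop("distributions must share identical bin edges", call. = FALSE)
  sqrt(mean((a$probabilities - b$probabilities)^2))
}

#' Correlation between cell length and nucleus mispositioning
#'
#' Pearson correlation between per-cell length and the centering
#' deviation `|p - 0.5|` of the normalized nucleus position (default),
#' or the raw normalized position with `use_deviation = FALSE`. The
#' deviation convention is monotone with mispositioning, so longer cells
#' having poorer centering shows up as r > 0.
#'
#' @param measurements Data.frame with `cell_length_um` and
#'   `nucleus_position_um`.
#' @param use_deviation Correlate length with `|p - 0.5|` (default) or
#'   with p itself.
#' @return Pearson r.
#' @export
length_position_correlation <- function(measurements, use_deviation = TRUE) {
  p <- suppressWarnings(normalize_positions(measurements))
  # normalize_positions drops invalid rows; align lengths with the same mask
  keep <- with(measurements,
               is.finite(cell_length_um) & is.finite(nucleus_position_um) &
                 cell_length_um > 0 & nucleus_position_um >= 0 &
                 nucleus_position_um <= cell_length_um)
  len <- measurements$cell_length_um[keep]
  y <- if (use_deviation) abs(p - 0.5) else p
  if (length(len) < 3) stop("need at least 3 valid records", call. = FALSE)
  if (sd(len) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance in length or position", call. = FALSE)
  cor(len, y)
}

#' Per-treatment summary of single-cell measurements
#'
#' One row per treatment label (sorted): number of cells, mean and SD of
#' cell length, off-center fraction at the given window, and the
#' length-mispositioning Pearson r (NA when undefined, e.g. fewer than 3
#' cells or zero variance).
#'
#' @param measurements Data.frame with columns `treatment`,
#'   `cell_length_um`, `nucleus_position_um`.
#' @param central_width Central window width for the off-center
#'   fraction.
#' @return Data.frame with columns `treatment, n, mean_length_um,
#'   sd_length_um, off_center_fraction, length_position_r`.
#' @export
treatment_summary <- function(measurements, central_width = 0.2) {
  stopifnot(is.data.frame(measurements), "treatment" %in% names(measurements))
  labs <- sort(unique(as.character(measurements$treatment)))
  rows <- lapply(labs, function(lab) {
    m <- measurements[measurements$treatment == lab, , drop = FALSE]
    p <- suppressWarnings(normalize_positions(m))
    r <- tryCatch(length_position_correlation(m), error = function(e) NA_real_)
    data.frame(treatment = lab, n = length(p),
               mean_length_um = mean(m$cell_length_um),
               sd_length_um = if (nrow(m) > 1) sd(m$cell_length_um) else 0,
               off_center_fraction = off_center_fraction(p, central_width),
               length_position_r = r)
  })
  do.call(rbind, rows)
}
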