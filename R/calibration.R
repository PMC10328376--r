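#' RMSD objective for kinetic-parameter calibration
#'
#' Evaluates how well a candidate parameter set reproduces a measured
#' nucleus-position distribution: the named values override fields of
#' the configured [kinetic_params()], an endpoint ensemble is simulated,
#' binned on the measured distribution's edges, and the RMSD between the
#' two histograms is returned, averaged over `replicates` independent
#' ensembles to damp Monte-Carlo noise.
#'
#' @param values Named numeric vector; names must be kinetic parameter
#'   fields (e.g. `v_poly_mean`).
#' @param measured A `position_distribution` ([position_histogram()]).
#' @param sim_config A [sim_config()]; its `n_runs`, `dt`, `duration`
#'   and cell settings define one ensemble.
#' @param length_sampler Optional per-run cell-length sampler
#'   (see [run_ensemble()]).
#' @param replicates Ensembles averaged per evaluation (default 3).
#' @param eval_seed Seed for this evaluation; replicate seeds are
#'   derived from it. Default uses `sim_config$seed`.
#' @return Mean RMSD (>= 0).
#' @export
objective_rmsd <- function(values, measured, sim_config, length_sampler = NULL,
                           replicates = 3, eval_seed = NULL) {
  stopifnot(inherits(measured, "position_distribution"),
            inherits(sim_config, "sim_config"))
  bad <- setdiff(names(values), kinetics_fields())
  if (length(bad))
    stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(values < 0)) stop("kinetic parameters must be >= 0", call. = FALSE)
  if (is.null(eval_seed)) eval_seed <- sim_config$seed
  kin <- unclass(sim_config$kinetics)
  kin[names(values)] <- values
  cfg <- sim_config
  cfg$kinetics <- do.call(kinetic_params, kin)
  n_bins <- length(measured$probabilities)
  vapply(seq_len(replicates), function(k) {
    cfg$seed <- as.integer(run_child_seed_cpp(eval_seed, k, 9))
    ens <- run_ensemble(cfg, length_sampler)
    rmsd_between_distributions(
      position_histogram(ens$normalized_position, n_bins), measured)
  }, numeric(1)) |> mean()
}

default_scale <- function(x, lower, upper) {
  s <- upper - lower
  inf <- !is.finite(s)
  s[inf] <- pmax(abs(x[inf]), 1)
  s
}

#' Finite-difference gradient of a (noisy) objective
#'
#' Estimates the partial derivatives of `fn` at `point` by central
#' differences with per-parameter step `perturbation_scale * scale`,
#' falling back to a one-sided difference when a perturbation would
#' leave the bounds. In `"spsa"` mode a single random simultaneous
#' perturbation (Rademacher signs) estimates all partials from two
#' evaluations. Both evaluations of a difference pair are passed the
#' same `tag`, so an objective that derives its seeds from the tag uses
#' common random numbers across the pair.
#'
#' @param fn Objective, called as `fn(x, tag)`.
#' @param point Named numeric vector within bounds.
#' @param lower,upper Bounds (recycled to length of `point`).
#' @param perturbation_scale Relative step for the difference.
#' @param scale Per-parameter scales; default `upper - lower` where
#'   finite, else `max(|x|, 1)`.
#' @param method `"central"` (default) or `"spsa"`.
#' @param tag Integer identifying this evaluation batch (for common
#'   random numbers).
#' @return Numeric vector of partial-derivative estimates.
#' @export
estimate_gradient <- function(fn, point, lower = -Inf, upper = Inf,
                              perturbation_scale = 0.05, scale = NULL,
                              method = c("central", "spsa"), tag = 0L) {
  method <- match.arg(method)
  d <- length(point)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  if (any(point < lower | point > upper))
    stop("point outside bounds", call. = FALSE)
  if (is.null(scale)) scale <- default_scale(point, lower, upper)
  h <- perturbation_scale * scale
  if (method == "spsa") {
    delta <- sample(c(-1, 1), d, replace = TRUE)
    xp <- pmin(upper, point + h * delta)
    xm <- pmax(lower, point - h * delta)
    df <- fn(xp, tag) - fn(xm, tag)
    return((df / (xp - xm)) * 1)
  }
  g <- numeric(d)
  for (j in seq_len(d)) {
    xp <- point; xm <- point
    xp[j] <- min(upper[j], point[j] + h[j])
    xm[j] <- max(lower[j], point[j] - h[j])
    if (xp[j] == xm[j]) { g[j] <- 0; next }
    g[j] <- (fn(xp, tag + j) - fn(xm, tag + j)) / (xp[j] - xm[j])
  }
  names(g) <- names(point)
  g
}

#' Stochastic finite-difference descent
#'
#' Minimizes a (possibly noisy) objective by the loop: randomly mutate
#' the best-seen point; estimate the gradient by finite differences;
#' take a bounded, normalized descent step; keep whichever candidate
#' improves the best-seen value. Step and mutation sizes decay
#' geometrically; the best-seen trace is non-increasing by
#' construction. Fully reproducible from `control$seed`.
#'
#' @param fn Objective, called as `fn(x, tag)` with an integer tag that
#'   is shared across the two evaluations of a finite-difference pair
#'   (use it to derive seeds for common random numbers; deterministic
#'   objectives may ignore it).
#' @param init Named numeric start vector.
#' @param lower,upper Bounds (recycled).
#' @param control List: `max_iterations` (30), `perturbation_scale`
#'   (0.1), `step_size` (0.25, as a fraction of the parameter scale),
#'   `step_decay` (0.9), `mutation_scale` (0.15), `convergence_tol`
#'   (0.01, relative best-RMSD improvement; 0 disables), `patience` (5
#'   iterations over which the improvement is assessed), `seed` (1),
#'   `gradient_method` ("central" or "spsa").
#' @return List with `par` (best-seen parameters), `value`, `trace`
#'   (data.frame `iter, value, <parameters>`), `converged`, `n_evals`.
#' @examples
#' sq <- function(x, tag) sum((x - c(2, -1))^2)
#' fit <- sfd_minimize(sq, c(a = 0, b = 0), lower = -5, upper = 5,
#'                     control = list(max_iterations = 60))
#' fit$par
#' @export
sfd_minimize <- function(fn, init, lower = -Inf, upper = Inf, control = list()) {
  ctl <- modifyList(list(max_iterations = 30, perturbation_scale = 0.1,
                         step_size = 0.25, step_decay = 0.9,
                         mutation_scale = 0.15, convergence_tol = 0.01,
                         patience = 5, seed = 1,
                         gradient_method = "central"), control)
  d <- length(init)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  if (any(init < lower | init > upper)) stop("init outside bounds", call. = FALSE)
  scale <- default_scale(init, lower, upper)
  restore <- save_rng_state()
  on.exit(restore())
  set.seed(ctl$seed)
  clamp <- function(x) setNames(pmin(upper, pmax(lower, x)), names(init))
  n_evals <- 0L
  evalf <- function(x, tag) { n_evals <<- n_evals + 1L; fn(x, tag) }
  x_best <- init
  f_best <- evalf(init, 0L)
  trace <- data.frame(iter = 0L, value = f_best, t(init))
  step <- ctl$step_size
  mut <- ctl$mutation_scale
  converged <- FALSE
  for (it in seq_len(ctl$max_iterations)) {
    base_tag <- it * 1000L
    # random mutation of the best-seen point
    xm <- clamp(x_best + rnorm(d) * mut * scale)
    fm <- evalf(xm, base_tag + 1L)
    if (fm < f_best) { x_best <- xm; f_best <- fm }
    # finite-difference descent step from the best-seen point
    g <- estimate_gradient(evalf, x_best, lower, upper,
                           perturbation_scale = ctl$perturbation_scale * step /
                             ctl$step_size,
                           scale = scale, method = ctl$gradient_method,
                           tag = base_tag + 10L)
    if (any(g != 0)) {
      # per-coordinate sign step: robust to ill-scaled or noisy gradient
      # magnitudes; the decaying step length controls the resolution
      xg <- clamp(x_best - sign(g) * step * scale)
      fg <- evalf(xg, base_tag + 20L)
      if (fg < f_best) { x_best <- xg; f_best <- fg }
    }
    step <- step * ctl$step_decay
    mut <- mut * ctl$step_decay
    trace <- rbind(trace, data.frame(iter = it, value = f_best, t(x_best)))
    if (ctl$convergence_tol > 0 && it > ctl$patience) {
      prev <- trace$value[it + 1L - ctl$patience]
      if (prev > 0 && (prev - f_best) / prev < ctl$convergence_tol) {
        converged <- TRUE
        break
      }
    }
  }
  list(par = x_best, value = f_best, trace = trace,
       converged = converged, n_evals = n_evals)
}

#' Calibrate free kinetic parameters against a measured distribution
#'
#' Fits the named free parameters by minimizing [objective_rmsd()] with
#' [sfd_minimize()]: random mutation, finite-difference gradient
#' estimation with common random numbers across each difference pair,
#' and bounded descent steps, tracking the best-seen parameters.
#'
#' @param measured Target `position_distribution`.
#' @param init Named numeric vector of starting values for the free
#'   kinetic parameters; all other kinetics come from
#'   `sim_config$kinetics`.
#' @param opt_config List merged over the [sfd_minimize()] control
#'   defaults, plus `replicates_per_eval` (default 3) and optional
#'   `lower` / `upper` named bound vectors (defaults `init / 4` and
#'   `init * 4`).
#' @param sim_config A [sim_config()] defining one ensemble per
#'   replicate.
#' @param length_sampler Optional cell-length sampler.
#' @return As [sfd_minimize()], plus `init` and `bounds`.
#' @export
optimize_parameters <- function(measured, init, opt_config = list(),
                                sim_config, length_sampler = NULL) {
  stopifnot(length(names(init)) == length(init))
  reps <- opt_config$replicates_per_eval %||% 3
  lower <- opt_config$lower %||% (init / 4)
  upper <- opt_config$upper %||% (init * 4)
  opt_config$replicates_per_eval <- NULL
  opt_config$lower <- NULL; opt_config$upper <- NULL
  seed <- opt_config$seed %||% sim_config$seed
  fn <- function(x, tag) {
    objective_rmsd(setNames(x, names(init)), measured, sim_config,
                   length_sampler, replicates = reps,
                   eval_seed = run_child_seed_cpp(seed, tag, 17))
  }
  opt_config$seed <- seed
  out <- sfd_minimize(fn, init, lower = lower, upper = upper,
                      control = opt_config)
  out$init <- init
  out$bounds <- list(lower = lower, upper = upper)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample and interpolate an RMSD surface over two parameters
#'
#' Draws `n_points` uniform random points in the bounding box of two
#' parameters, evaluates the RMSD objective (or an arbitrary `fn`) at
#' each, and returns the scatter together with a piecewise-linear
#' interpolant (Delaunay triangulation with barycentric interpolation)
#' for visualizing the parameter space, e.g. the polymerization- vs
#' depolymerization-rate valley of near-constant net growth.
#'
#' @param param_x,param_y Parameter names (kinetic fields when the
#'   default objective is used).
#' @param lower,upper Length-2 bounds `c(x, y)`; must be finite and
#'   non-degenerate.
#' @param n_points Number of random samples (default 200).
#' @param fn Optional objective `fn(values)` taking a named length-2
#'   vector; default evaluates [objective_rmsd()].
#' @param measured,sim_config,length_sampler,replicates Passed to
#'   [objective_rmsd()] when `fn` is `NULL`.
#' @param seed RNG seed for the sample locations and evaluation seeds.
#' @return An `rmsd_surface` object: data.frame `samples` with columns
#'   `x, y, value`, parameter names, and bounds. Use
#'   [interp_surface()] to evaluate it on a grid.
#' @export
rmsd_surface <- function(param_x, param_y, lower, upper, n_points = 200,
                         fn = NULL, measured = NULL, sim_config = NULL,
                         length_sampler = NULL, replicates = 1, seed = 1) {
  stopifnot(length(lower) == 2, length(upper) == 2)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(upper <= lower))
    stop("bounds must be finite with upper > lower", call. = FALSE)
  restore <- save_rng_state()
  on.exit(restore())
  set.seed(seed)
  xs <- runif(n_points, lower[1], upper[1])
  ys <- runif(n_points, lower[2], upper[2])
  if (is.null(fn)) {
    stopifnot(!is.null(measured), !is.null(sim_config))
    fn <- function(v, tag) objective_rmsd(v, measured, sim_config, length_sampler,
                                          replicates = replicates,
                                          eval_seed = run_child_seed_cpp(seed, tag, 23))
  } else {
    fn_user <- fn
    fn <- function(v, tag) fn_user(v)
  }
  vals <- vapply(seq_len(n_points), function(i) {
    fn(setNames(c(xs[i], ys[i]), c(param_x, param_y)), i)
  }, numeric(1))
  structure(list(samples = data.frame(x = xs, y = ys, value = vals),
                 param_x = param_x, param_y = param_y,
                 lower = lower, upper = upper),
            class = "rmsd_surface")
}

#' Evaluate an RMSD surface on a regular grid
#'
#' Piecewise-linear interpolation of the sampled scatter: Delaunay
#' triangulation of the sample locations, barycentric interpolation
#' within each triangle. Grid nodes outside the convex hull are `NA`.
#'
#' @param surface An `rmsd_surface`.
#' @param nx,ny Grid resolution.
#' @return List `x` (nx), `y` (ny), `z` (nx by ny matrix).
#' @export
interp_surface <- function(surface, nx = 50, ny = 50) {
  stopifnot(inherits(surface, "rmsd_surface"))
  s <- surface$samples
  gx <- seq(min(s$x), max(s$x), length.out = nx)
  gy <- seq(min(s$y), max(s$y), length.out = ny)
  grid <- expand.grid(x = gx, y = gy)
  z <- interp_linear(s$x, s$y, s$value, grid$x, grid$y)
  list(x = gx, y = gy, z = matrix(z, nrow = nx, ncol = ny))
}

# ---- scattered-data piecewise-linear interpolation ------------------------

# Bowyer-Watson Delaunay triangulation; returns a matrix of vertex-index
# triples. O(n^2), intended for the ~200-point surface samples.
delaunay_triangulate <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  cx <- mean(range(x)); cy <- mean(range(y))
  d <- max(diff(range(x)), diff(range(y)), 1e-8) * 25
  px <- c(x, cx - d, cx + d, cx)
  py <- c(y, cy - d / 2, cy - d / 2, cy + d)
  circum <- function(tr) {
    ax <- px[tr[1]]; ay <- py[tr[1]]
    bx <- px[tr[2]]; by <- py[tr[2]]
    cx2 <- px[tr[3]]; cy2 <- py[tr[3]]
    den <- 2 * (ax * (by - cy2) + bx * (cy2 - ay) + cx2 * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy2) + (bx^2 + by^2) * (cy2 - ay) +
             (cx2^2 + cy2^2) * (ay - by)) / den
    uy <- ((ax^2 + ay^2) * (cx2 - bx) + (bx^2 + by^2) * (ax - cx2) +
             (cx2^2 + cy2^2) * (bx - ax)) / den
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), ncol = 3)
  cc <- matrix(circum(tris[1, ]), ncol = 3)
  for (i in seq_len(n)) {
    inside <- (px[i] - cc[, 1])^2 + (py[i] - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12)
    inside[is.na(inside)] <- FALSE
    if (!any(inside)) next   # degenerate (duplicate point); skip
    bad <- tris[inside, , drop = FALSE]
    edges <- rbind(bad[, c(1, 2), drop = FALSE],
                   bad[, c(2, 3), drop = FALSE],
                   bad[, c(3, 1), drop = FALSE])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[!inside, , drop = FALSE]
    cc <- cc[!inside, , drop = FALSE]
    for (e in seq_len(nrow(boundary))) {
      newt <- c(boundary[e, 1], boundary[e, 2], i)
      ccn <- circum(newt)
      if (!all(is.finite(ccn))) next   # collinear; skip sliver
      tris <- rbind(tris, newt)
      cc <- rbind(cc, ccn)
    }
  }
  keep <- apply(tris, 1, function(tr) all(tr <= n))
  unname(tris[keep, , drop = FALSE])
}

# barycentric piecewise-linear interpolation at query points (NA outside
# the convex hull of the samples)
interp_linear <- function(x, y, z, qx, qy) {
  tris <- delaunay_triangulate(x, y)
  out <- rep(NA_real_, length(qx))
  todo <- rep(TRUE, length(qx))
  for (t in seq_len(nrow(tris))) {
    if (!any(todo)) break
    v <- tris[t, ]
    x1 <- x[v[1]]; y1 <- y[v[1]]
    x2 <- x[v[2]]; y2 <- y[v[2]]
    x3 <- x[v[3]]; y3 <- y[v[3]]
    den <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (!is.finite(den) || den == 0) next
    l1 <- ((y2 - y3) * (qx - x3) + (x3 - x2) * (qy - y3)) / den
    l2 <- ((y3 - y1) * (qx - x3) + (x1 - x3) * (qy - y3)) / den
    l3 <- 1 - l1 - l2
    eps <- 1e-9
    hit <- todo & l1 >= -eps & l2 >= -eps & l3 >= -eps
    if (any(hit)) {
      out[hit] <- l1[hit] * z[v[1]] + l2[hit] * z[v[2]] + l3[hit] * z[v[3]]
      todo[hit] <- FALSE
    }
  }
  out
}
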