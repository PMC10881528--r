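#' PSO hyperparameter configuration
#'
#' Constriction-style global-best particle swarm settings. Velocities are
#' clamped per dimension to half the search range and particles reflect off
#' the bounds.
#'
#' @param swarm_size Particles per swarm (default 20).
#' @param iterations Iterations per restart (default 60).
#' @param inertia Inertia weight (default 0.729).
#' @param cognitive,social Acceleration coefficients (default 1.49445 each).
#' @param restarts Independent restarts (default 50); the median over restart
#'   optima is the reported estimate.
#' @param seed Master seed; restart and evaluation seeds derive from it.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 20, iterations = 60, inertia = 0.729,
                       cognitive = 1.49445, social = 1.49445,
                       restarts = 50, seed = 1) {
  if (swarm_size < 2) stop("swarm_size must be >= 2")
  if (iterations < 1) stop("iterations must be >= 1")
  if (restarts < 1) stop("restarts must be >= 1")
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 inertia = inertia, cognitive = cognitive, social = social,
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "pso_config")
}

# Evaluate expr while protecting the caller's RNG stream from any set.seed()
# performed inside (simulation runs re-seed; the swarm updates must not be
# affected by how many simulations a cost evaluation runs).
with_preserved_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  expr
}

#' Minimize a function with restarted global-best PSO
#'
#' Standard global-best particle swarm optimization with per-dimension
#' velocity clamping (half the range) and reflecting bounds, run as
#' `config$restarts` independent restarts. The objective may be stochastic;
#' it receives the candidate vector and the current iteration number (so
#' callers can use common random numbers across candidates within an
#' iteration).
#'
#' @param fn Objective: `function(x, iteration)` returning a scalar cost
#'   (extra arguments are ignored if `fn` only takes `x`).
#' @param lower,upper Numeric bound vectors (finite, `lower < upper`).
#' @param config A [pso_config()].
#' @return A list of class `pcabm_fit` with `per_restart` (data frame of
#'   restart optima and costs), `median` and `iqr` (per-parameter over
#'   restarts), `best` (overall best vector), and `best_cost`.
#' @export
pso_optimize <- function(fn, lower, upper, config = pso_config()) {
  stopifnot(length(lower) == length(upper))
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper")
  d <- length(lower)
  nm <- names(lower)
  if (is.null(nm)) nm <- paste0("x", seq_len(d))
  takes_iter <- length(formals(fn)) >= 2
  evalfn <- if (takes_iter) fn else function(x, iteration) fn(x)
  rng <- upper - lower
  vmax <- 0.5 * rng
  n <- config$swarm_size

  run_restart <- function(restart) {
    set.seed(derive_seed(config$seed, restart))
    x <- matrix(stats::runif(n * d), n, d)
    x <- sweep(sweep(x, 2, rng, "*"), 2, lower, "+")
    v <- matrix(stats::runif(n * d, -1, 1), n, d)
    v <- sweep(v, 2, vmax, "*")
    pbest <- x
    pcost <- rep(Inf, n)
    gbest <- x[1, ]
    gcost <- Inf
    trace <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      r1 <- matrix(stats::runif(n * d), n, d)
      r2 <- matrix(stats::runif(n * d), n, d)
      cost <- with_preserved_rng(
        vapply(seq_len(n), function(i) evalfn(
          stats::setNames(x[i, ], nm), it), numeric(1)))
      improved <- cost < pcost
      pbest[improved, ] <- x[improved, , drop = FALSE]
      pcost[improved] <- cost[improved]
      if (min(pcost) < gcost) {
        gcost <- min(pcost)
        gbest <- pbest[which.min(pcost), ]
      }
      trace[it] <- gcost
      v <- config$inertia * v +
        config$cognitive * r1 * (pbest - x) +
        config$social * r2 * (sweep(-x, 2, gbest, "+"))
      v <- pmin(pmax(v, matrix(-vmax, n, d, byrow = TRUE)),
                matrix(vmax, n, d, byrow = TRUE))
      x <- x + v
      # reflect off the box
      for (j in seq_len(d)) {
        lo <- x[, j] < lower[j]
        x[lo, j] <- pmin(2 * lower[j] - x[lo, j], upper[j])
        hi <- x[, j] > upper[j]
        x[hi, j] <- pmax(2 * upper[j] - x[hi, j], lower[j])
        v[lo | hi, j] <- -v[lo | hi, j]
      }
    }
    list(par = stats::setNames(gbest, nm), cost = gcost, trace = trace)
  }

  restarts <- lapply(seq_len(config$restarts), run_restart)
  pars <- do.call(rbind, lapply(restarts, function(r) r$par))
  costs <- vapply(restarts, function(r) r$cost, numeric(1))
  per_restart <- data.frame(restart = seq_len(config$restarts),
                            cost = costs)
  per_restart[nm] <- pars
  med <- apply(pars, 2, stats::median)
  iqr <- apply(pars, 2, stats::IQR)
  best_i <- which.min(costs)
  structure(list(per_restart = per_restart,
                 median = stats::setNames(med, nm),
                 iqr = stats::setNames(iqr, nm),
                 best = restarts[[best_i]]$par,
                 best_cost = costs[best_i],
                 traces = lapply(restarts, function(r) r$trace)),
            class = "pcabm_fit")
}

#' @export
print.pcabm_fit <- function(x, ...) {
  cat(sprintf("<pcabm_fit> %d restart(s); best cost %.6g\n",
              nrow(x$per_restart), x$best_cost))
  s <- data.frame(median = x$median, iqr = x$iqr)
  print(s)
  invisible(x)
}

#' Mean squared error between a model curve and a data curve
#'
#' Curves may be numeric vectors on a shared grid or data frames with columns
#' `time_h` and `value`. For data frames, each data time is matched to the
#' nearest model time; a mismatch larger than half a tick is an error.
#'
#' @param model_curve,data_curve Numeric vectors or data frames
#'   (`time_h`, `value`).
#' @param tick_hours Tick duration in hours used for the matching tolerance
#'   (default 4).
#' @return The mean of squared differences over the shared time points.
#' @export
mse_cost <- function(model_curve, data_curve, tick_hours = 4) {
  if (is.numeric(model_curve) && is.numeric(data_curve)) {
    if (length(model_curve) != length(data_curve) ||
        length(model_curve) == 0)
      stop("curves must be non-empty and of equal length")
    return(mean((model_curve - data_curve)^2))
  }
  stopifnot(is.data.frame(model_curve), is.data.frame(data_curve))
  if (nrow(data_curve) == 0 || nrow(model_curve) == 0)
    stop("empty curve: no overlapping time points")
  idx <- vapply(data_curve$time_h, function(t) {
    i <- which.min(abs(model_curve$time_h - t))
    if (abs(model_curve$time_h[i] - t) > tick_hours / 2)
      stop(sprintf("data time %g h is more than half a tick from any model time",
                   t))
    i
  }, integer(1))
  mean((model_curve$value[idx] - data_curve$value)^2)
}

#' Calibration specification
#'
#' Names the free parameters (with box bounds), the fixed parameter set they
#' are embedded in, the scenario simulated per cost evaluation, the
#' population compared against the data, and the number of simulation
#' replicates averaged per evaluation.
#'
#' @param free_params Named list of `c(lower, upper)` bounds, e.g.
#'   `list(TUpprol = c(0, 0.5))`; `NULL` entries take [default_bounds()].
#' @param fixed_params A [pcabm_params()] object supplying every parameter
#'   not being fitted.
#' @param scenario A [scenario_config()] (or catalog name).
#' @param target_kind Population compared: `"tumor_total"` or
#'   `"fibroblast"` (or any agent kind).
#' @param n_sim_rep Simulations averaged per cost evaluation (default 3).
#' @param t0_hours Normalization time of the growth curves (default 24).
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(free_params, fixed_params, scenario,
                     target_kind = "tumor_total", n_sim_rep = 3,
                     t0_hours = 24) {
  stopifnot(inherits(fixed_params, "pcabm_params"))
  if (is.character(scenario)) scenario <- build_scenario(scenario)
  stopifnot(inherits(scenario, "scenario_config"))
  if (is.character(free_params))
    free_params <- stats::setNames(vector("list", length(free_params)),
                                   free_params)
  bad <- setdiff(names(free_params), names(fixed_params))
  if (length(bad) > 0)
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  bounds <- lapply(names(free_params), function(nm) {
    b <- free_params[[nm]]
    if (is.null(b)) b <- default_bounds(nm)
    if (length(b) != 2 || any(!is.finite(b)) || b[1] >= b[2])
      stop("bounds for ", nm, " must be finite with lower < upper")
    if (nm %in% .prob_fields && (b[1] < 0 || b[2] > 1))
      stop("bounds for probability ", nm, " must lie within [0, 1]")
    b
  })
  names(bounds) <- names(free_params)
  structure(list(free_params = bounds, fixed_params = fixed_params,
                 scenario = scenario, target_kind = target_kind,
                 n_sim_rep = as.integer(n_sim_rep), t0_hours = t0_hours),
            class = "fit_spec")
}

#' Default search bounds for a model parameter
#'
#' Probabilities search `[0, 0.5]` (the M2 growth bonus `[0, 0.3]`);
#' capacities `[1, 20]`, except the resistant proliferation capacity
#' `[1, 60]`.
#'
#' @param name Parameter name.
#' @return Numeric `c(lower, upper)`.
#' @export
default_bounds <- function(name) {
  if (name == "M2TUadd") return(c(0, 0.3))
  if (name %in% .prob_fields) return(c(0, 0.5))
  if (name == "TUpmaxres") return(c(1, 60))
  if (name %in% .count_fields) return(c(1, 20))
  stop("no default bounds for ", name)
}

# Integer capacities are searched on a continuous scale and rounded at
# evaluation time, so vanilla PSO can handle the mixed search space.
.apply_candidate <- function(vec, spec) {
  p <- unclass(spec$fixed_params)
  for (nm in names(vec)) {
    v <- vec[[nm]]
    if (nm %in% .count_fields) v <- round(v)
    p[[nm]] <- v
  }
  validate_params(p)
}

# Mean relative curve of the target population over n_sim_rep runs.
.mean_model_curve <- function(params, spec, seed) {
  curves <- lapply(seq_len(spec$n_sim_rep), function(j) {
    traj <- run_simulation(spec$scenario, params,
                           seed = derive_seed(seed, j))
    relative_growth(traj, kind = spec$target_kind,
                    t0_hours = spec$t0_hours)
  })
  data.frame(time_h = curves[[1]]$time_h,
             value = rowMeans(do.call(cbind,
                                      lapply(curves, `[[`, "value"))))
}

# Replicate-mean data curve: technical replicates averaged per time point.
.mean_data_curve <- function(dataset) {
  m <- vapply(split(dataset$relative_count, dataset$time_h), mean, numeric(1))
  t <- as.numeric(names(m))
  o <- order(t)
  data.frame(time_h = t[o], value = unname(m)[o])
}

#' Cost of one candidate parameter vector
#'
#' Runs `n_sim_rep` simulations with seeds derived from `seed`, averages the
#' target population's relative growth curves, and returns the mean squared
#' error against the dataset's replicate-mean curve. Deterministic given
#' `(param_vector, fit_spec, dataset, seed)`.
#'
#' @param param_vector Named numeric vector of free-parameter values (within
#'   the spec's bounds; integer capacities are rounded).
#' @param spec A [fit_spec()].
#' @param dataset Growth dataset rows to fit against (typically one
#'   biological replicate; technical replicates are averaged).
#' @param seed Evaluation seed.
#' @param data_curve Precomputed replicate-mean curve (internal fast path;
#'   computed from `dataset` when `NULL`).
#' @return The MSE cost (non-negative scalar).
#' @export
evaluate_candidate <- function(param_vector, spec, dataset, seed = 1,
                               data_curve = NULL) {
  stopifnot(inherits(spec, "fit_spec"))
  for (nm in names(spec$free_params)) {
    if (!nm %in% names(param_vector))
      stop("param_vector is missing ", nm)
    b <- spec$free_params[[nm]]
    v <- param_vector[[nm]]
    if (v < b[1] - 1e-9 || v > b[2] + 1e-9)
      stop(sprintf("%s = %g outside bounds [%g, %g]", nm, v, b[1], b[2]))
  }
  params <- .apply_candidate(param_vector, spec)
  model <- .mean_model_curve(params, spec, seed)
  if (is.null(data_curve)) data_curve <- .mean_data_curve(dataset)
  mse_cost(model, data_curve)
}

#' Fit free parameters to growth data with restarted PSO
#'
#' Runs `config$restarts` independent particle swarms minimizing
#' [evaluate_candidate()]. Within an iteration all candidates share the same
#' evaluation seed (common random numbers), reducing the noise the swarm has
#' to fight.
#'
#' @param spec A [fit_spec()].
#' @param dataset Growth dataset rows to fit against.
#' @param config A [pso_config()].
#' @return A `pcabm_fit` (see [pso_optimize()]) with an extra
#'   `cost_at_median` element: the cost of the per-parameter median vector.
#' @export
run_pso <- function(spec, dataset, config = pso_config()) {
  stopifnot(inherits(spec, "fit_spec"))
  validate_growth_dataset(dataset, check_conditions = FALSE)
  lower <- vapply(spec$free_params, `[`, numeric(1), 1)
  upper <- vapply(spec$free_params, `[`, numeric(1), 2)
  data_curve <- .mean_data_curve(dataset)
  fn <- function(x, iteration) {
    evaluate_candidate(x, spec, dataset,
                       seed = derive_seed(config$seed, 500000 + iteration),
                       data_curve = data_curve)
  }
  fit <- pso_optimize(fn, lower, upper, config)
  fit$cost_at_median <- with_preserved_rng(
    evaluate_candidate(fit$median, spec, dataset,
                       seed = derive_seed(config$seed, 999999),
                       data_curve = data_curve))
  fit
}
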