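# Deterministic derivation of sub-stream seeds from one master seed.
# Small-modulus arithmetic keeps everything exact in doubles and the result
# strictly below 2^31 so it is a valid set.seed() argument.
derive_seed <- function(seed, stream) {
  seed <- as.numeric(seed %% 50021)
  ((seed * 40009 + as.numeric(stream) * 7919 + 12345) %% 2147483629) + 1
}

.growth_columns <- c("time_h", "condition", "bio_rep", "tech_rep",
                     "population", "relative_count")

#' Validate a growth-curve dataset
#'
#' A growth dataset is a long-format data frame with columns `time_h`,
#' `condition` (`"DMSO"` or `"R1881"`), `bio_rep`, `tech_rep`, `population`,
#' and `relative_count`, mirroring the structure of live-cell imaging
#' experiments: 7-day curves sampled every 4 h, three biological replicates
#' with six technical replicates each, two hormone conditions, counts
#' normalized to the 24-h time point.
#'
#' @param dataset A data frame.
#' @param check_conditions Require condition labels in `{DMSO, R1881}`.
#' @return The dataset, invisibly, after validation.
#' @export
validate_growth_dataset <- function(dataset, check_conditions = TRUE) {
  missing <- setdiff(.growth_columns, names(dataset))
  if (length(missing) > 0)
    stop("growth dataset is missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(dataset) == 0) stop("growth dataset is empty")
  if (!is.numeric(dataset$time_h))
    stop("time_h must be numeric")
  if (!is.numeric(dataset$relative_count))
    stop("relative_count must be numeric")
  if (check_conditions) {
    bad <- setdiff(unique(dataset$condition), c("DMSO", "R1881"))
    if (length(bad) > 0)
      stop("unknown condition label(s): ", paste(bad, collapse = ", "),
           " (use check_conditions = FALSE to override)")
  }
  invisible(dataset)
}

#' Generate a smooth synthetic growth dataset from a logistic curve
#'
#' A fast stand-in for fluorescence-derived growth curves: the mean follows
#' logistic growth `n(t) = K / (1 + ((K - n0) / n0) exp(-r t))`, each
#' observation gets independent multiplicative log-normal noise (scale
#' proportional error, as in fluorescence counts), and every series is then
#' renormalized to its value at `t0_hours`.
#'
#' @param K Carrying capacity (relative units).
#' @param r Growth rate per hour; a named vector `c(DMSO = , R1881 = )` gives
#'   condition-specific rates.
#' @param n0 Initial value; must satisfy `0 < n0 < K`.
#' @param noise_sd Standard deviation of the log-normal noise on the log
#'   scale (default 0.05).
#' @param n_bio,n_tech Numbers of biological and technical replicates
#'   (defaults 3 and 6, the design of the emulated experiments).
#' @param times Sampling grid in hours (default 0 to 168 every 4).
#' @param conditions Condition labels to generate.
#' @param population Population label for the generated series.
#' @param t0_hours Normalization time (default 24).
#' @param seed Optional integer seed.
#' @return A growth dataset (see [validate_growth_dataset()]).
#' @export
generate_logistic_dataset <- function(K = 10, r = c(DMSO = 0.012,
                                                    R1881 = 0.03),
                                      n0 = 1, noise_sd = 0.05,
                                      n_bio = 3, n_tech = 6,
                                      times = seq(0, 168, by = 4),
                                      conditions = c("DMSO", "R1881"),
                                      population = "tumor",
                                      t0_hours = 24, seed = NULL) {
  if (any(n0 <= 0) || any(n0 >= K))
    stop("need 0 < n0 < K for logistic growth")
  if (!t0_hours %in% times)
    stop("t0_hours must be one of the sampled times")
  if (is.null(names(r))) r <- stats::setNames(rep(r[1], length(conditions)),
                                              conditions)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (cond in conditions) {
    mean_curve <- K / (1 + ((K - n0) / n0) * exp(-r[[cond]] * times))
    for (b in seq_len(n_bio)) for (tr in seq_len(n_tech)) {
      y <- mean_curve * exp(stats::rnorm(length(times), 0, noise_sd))
      y <- y / y[times == t0_hours]
      out[[length(out) + 1]] <- data.frame(
        time_h = times, condition = cond, bio_rep = b, tech_rep = tr,
        population = population, relative_count = y)
    }
  }
  validate_growth_dataset(do.call(rbind, out))
}

#' Generate a growth dataset by running the simulator
#'
#' Each technical replicate is one full simulation with a seed derived
#' deterministically from `seed`, converted to a relative growth curve with
#' [relative_growth()] (normalized at `t0_hours`). This is the ground-truth
#' generator for parameter-recovery experiments: the data-generating
#' parameters are known exactly.
#'
#' @param params A [pcabm_params()] object.
#' @param scenario A [scenario_config()] (or catalog name).
#' @param n_bio,n_tech Replicate structure (defaults 3 and 6).
#' @param seed Integer master seed.
#' @param kind Population to extract (default `"tumor_total"`, reported under
#'   the label `"tumor"`).
#' @param t0_hours Normalization time (default 24).
#' @return A growth dataset (see [validate_growth_dataset()]).
#' @export
generate_simulated_dataset <- function(params, scenario, n_bio = 3,
                                       n_tech = 6, seed = 1,
                                       kind = "tumor_total",
                                       t0_hours = 24) {
  if (is.character(scenario)) scenario <- build_scenario(scenario)
  stopifnot(inherits(scenario, "scenario_config"))
  label <- if (kind == "tumor_total") "tumor" else kind
  out <- list()
  for (b in seq_len(n_bio)) for (tr in seq_len(n_tech)) {
    s <- derive_seed(seed, (b - 1) * n_tech + tr)
    traj <- run_simulation(scenario, params, seed = s)
    g <- relative_growth(traj, kind = kind, t0_hours = t0_hours)
    out[[length(out) + 1]] <- data.frame(
      time_h = g$time_h, condition = scenario$condition, bio_rep = b,
      tech_rep = tr, population = label, relative_count = g$value)
  }
  validate_growth_dataset(do.call(rbind, out))
}
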