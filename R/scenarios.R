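#' Scenario configuration
#'
#' Bundles everything needed to start a run: the lattice, the number of agents
#' of each kind seeded at tick 0, the hormone condition (which selects the
#' default parameter preset), the run length in 4-hour ticks, and the fraction
#' of seeded tumor cells that are castration resistant.
#'
#' @param name Label for the scenario.
#' @param lattice A [lattice_config()].
#' @param counts Named numeric vector with entries `tumor`, `fibroblast`,
#'   `M1`, `M2` (missing entries default to 0).
#' @param condition `"DMSO"` (hormone deprived) or `"R1881"` (proficient).
#' @param ticks Number of 4-hour ticks (default 42, i.e. 7 days).
#' @param resistant_fraction Fraction of seeded tumor cells that are
#'   resistant, in `[0, 1]`.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name, counts, condition = c("DMSO", "R1881"),
                            lattice = lattice_config(), ticks = 42L,
                            resistant_fraction = 0) {
  condition <- match.arg(condition)
  full <- c(tumor = 0, fibroblast = 0, M1 = 0, M2 = 0)
  extra <- setdiff(names(counts), names(full))
  if (length(extra) > 0)
    stop("unknown count names: ", paste(extra, collapse = ", "))
  full[names(counts)] <- counts
  if (any(full < 0) || any(full != round(full)))
    stop("counts must be non-negative integers")
  ticks <- as.integer(ticks)
  if (is.na(ticks) || ticks < 1L) stop("ticks must be >= 1")
  if (resistant_fraction < 0 || resistant_fraction > 1)
    stop("resistant_fraction must be in [0, 1]")
  structure(list(name = name, lattice = lattice,
                 counts = as.integer(full[c("tumor", "fibroblast",
                                            "M1", "M2")]) |>
                   stats::setNames(c("tumor", "fibroblast", "M1", "M2")),
                 condition = condition, ticks = ticks,
                 resistant_fraction = resistant_fraction),
            class = "scenario_config")
}

#' Split a total agent count by a seeding ratio
#'
#' @param ratio Named numeric vector of ratio parts, e.g.
#'   `c(tumor = 4, fibroblast = 1, M1 = 1)`.
#' @param total Total number of agents.
#' @return Named integer vector of counts summing to `total` (largest
#'   remainder rounding).
#' @export
counts_from_ratio <- function(ratio, total) {
  exact <- total * ratio / sum(ratio)
  n <- floor(exact)
  rem <- total - sum(n)
  if (rem > 0) {
    up <- order(exact - n, decreasing = TRUE)[seq_len(rem)]
    n[up] <- n[up] + 1
  }
  stats::setNames(as.integer(n), names(ratio))
}

# Catalog of co-culture compositions. Counts are per 1000 seeded tumor cells
# (~6.4% occupancy of the default 125 x 125 grid); ratio suffixes follow the
# listing order of the scenario name (e.g. M1_TU_F_141 = M1:TU:F at 1:4:1).
.scenario_catalog <- list(
  LNCaP_mono    = list(counts = c(tumor = 1000)),
  LNCaP_F_41    = list(counts = c(tumor = 1000, fibroblast = 250)),
  LNCaP_F_11    = list(counts = c(tumor = 1000, fibroblast = 1000)),
  LNCaP_F_M1_411 = list(counts = c(tumor = 1000, fibroblast = 250, M1 = 250)),
  LNCaP_F_M2_411 = list(counts = c(tumor = 1000, fibroblast = 250, M2 = 250)),
  LNCaP_M1_41   = list(counts = c(tumor = 1000, M1 = 250)),
  LNCaP_M2_41   = list(counts = c(tumor = 1000, M2 = 250)),
  M1_TU_F_141   = list(counts = c(tumor = 1000, fibroblast = 250, M1 = 250)),
  M1_TU_F_111   = list(counts = c(tumor = 1000, fibroblast = 1000, M1 = 1000)),
  M2_TU_F_141   = list(counts = c(tumor = 1000, fibroblast = 250, M2 = 250)),
  M2_TU_F_111   = list(counts = c(tumor = 1000, fibroblast = 1000, M2 = 1000)),
  Fibroblast_mono = list(counts = c(fibroblast = 1000)),
  LNCaPabl_mono = list(counts = c(tumor = 1000), rf = 1),
  CRPC          = list(counts = c(tumor = 1000), rf = 1/101),
  CRPC_F_41     = list(counts = c(tumor = 1000, fibroblast = 250),
                       rf = 1/101),
  CRPC_F_11     = list(counts = c(tumor = 1000, fibroblast = 1000),
                       rf = 1/101),
  CRPC_M1_141   = list(counts = c(tumor = 1000, fibroblast = 250, M1 = 250),
                       rf = 1/101),
  CRPC_M1_111   = list(counts = c(tumor = 1000, fibroblast = 1000, M1 = 1000),
                       rf = 1/101),
  CRPC_M2_141   = list(counts = c(tumor = 1000, fibroblast = 250, M2 = 250),
                       rf = 1/101),
  CRPC_M2_111   = list(counts = c(tumor = 1000, fibroblast = 1000, M2 = 1000),
                       rf = 1/101)
)

#' List the named scenario catalog
#'
#' Every base composition exists in both hormone conditions; the full scenario
#' name is `<base>_<condition>`, e.g. `"LNCaP_F_M1_411_R1881"`. CRPC scenarios
#' seed 1 resistant per 100 sensitive tumor cells.
#'
#' @return Character vector of all valid scenario names.
#' @export
scenario_catalog <- function() {
  as.vector(t(outer(names(.scenario_catalog), c("DMSO", "R1881"),
                    paste, sep = "_")))
}

#' Build a named scenario from the catalog
#'
#' @param name A catalog name (see [scenario_catalog()]), e.g.
#'   `"LNCaP_mono_R1881"` or `"CRPC_DMSO"`.
#' @param ticks Run length in 4-hour ticks (default 42 = 7 days).
#' @param tumor_seed Number of seeded tumor cells; all other counts scale
#'   proportionally from the catalog's per-1000 composition.
#' @param lattice A [lattice_config()].
#' @return A [scenario_config()].
#' @export
build_scenario <- function(name, ticks = 42L, tumor_seed = 1000L,
                           lattice = lattice_config()) {
  m <- regmatches(name, regexec("^(.*)_(DMSO|R1881)$", name))[[1]]
  base <- if (length(m) == 3) m[2] else ""
  if (!base %in% names(.scenario_catalog))
    stop("unknown scenario '", name, "'; catalog:\n  ",
         paste(scenario_catalog(), collapse = "\n  "))
  entry <- .scenario_catalog[[base]]
  scale <- tumor_seed / 1000
  counts <- round(entry$counts * scale)
  scenario_config(
    name = name, counts = counts, condition = m[3], lattice = lattice,
    ticks = ticks,
    resistant_fraction = if (is.null(entry$rf)) 0 else entry$rf)
}

#' Serialize or restore a scenario configuration as JSON
#'
#' @param config A [scenario_config()].
#' @param path File path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()` the
#'   restored [scenario_config()].
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- list(name = config$name,
            lattice = unclass(config$lattice),
            counts = as.list(config$counts),
            condition = config$condition,
            ticks = config$ticks,
            resistant_fraction = config$resistant_fraction)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario_config(name = x$name, counts = unlist(x$counts),
                  condition = x$condition,
                  lattice = lattice_config(x$lattice$width, x$lattice$height,
                                           x$lattice$cell_area),
                  ticks = x$ticks,
                  resistant_fraction = x$resistant_fraction)
}

#' Relative growth curve from a trajectory
#'
#' Normalizes per-tick counts to the count at a reference time, matching the
#' normalization applied to live-cell imaging data ("time point zero" at
#' t = 24 h, i.e. tick 6 at 4-hour ticks).
#'
#' @param trajectory A `pcabm_trajectory` from [run_simulation()].
#' @param kind One of `"tumor_total"` (sensitive + resistant, default),
#'   `"tumor"`, `"tumor_resistant"`, `"fibroblast"`, `"M1"`, `"M2"`.
#' @param t0_hours Normalization time in hours (default 24).
#' @return A data frame with columns `time_h`, `value` (relative count,
#'   1 at `t0_hours`) and `kind`.
#' @export
relative_growth <- function(trajectory, kind = "tumor_total",
                            t0_hours = 24) {
  stopifnot(inherits(trajectory, "pcabm_trajectory"))
  cts <- trajectory$counts
  y <- if (kind == "tumor_total") cts$tumor + cts$tumor_resistant
       else if (kind %in% .kind_levels) cts[[kind]]
       else stop("unknown kind '", kind, "'")
  i0 <- which(cts$time_h == t0_hours)
  if (length(i0) != 1)
    stop(sprintf("t0 = %g h does not correspond to a recorded tick", t0_hours))
  if (y[i0] == 0)
    stop(sprintf("count of '%s' at t0 = %g h is zero; normalization undefined",
                 kind, t0_hours))
  data.frame(time_h = cts$time_h, value = y / y[i0], kind = kind)
}

#' Fold change between two values
#'
#' @param value_a Numerator.
#' @param value_b Denominator; must be positive.
#' @return The ratio `value_a / value_b`.
#' @export
fold_change <- function(value_a, value_b) {
  if (!is.numeric(value_b) || any(value_b <= 0))
    stop("fold_change denominator must be positive")
  value_a / value_b
}

#' Hormone-condition fold changes of the calibrated parameters
#'
#' Computes the fold differences between the hormone-proficient (R1881) and
#' hormone-deprived (DMSO) calibrated values that summarize the model's
#' androgen response: tumor proliferation and M1 killing from the co-culture
#' presets, and the tumor-macrophage-only refits from
#' [nofibroblast_refits()].
#'
#' @return A data frame with one row per comparison: `comparison`,
#'   `numerator`, `denominator`, `fold`, and `fold_rounded` (nearest integer).
#' @export
report_fold_changes <- function() {
  r <- preset_params("R1881")
  d <- preset_params("DMSO")
  nf <- nofibroblast_refits()
  rows <- list(
    c("TUpprol_R1881_vs_DMSO", r$TUpprol, d$TUpprol),
    c("M1pkill_R1881_vs_DMSO", r$M1pkill, d$M1pkill),
    c("M1pkill_nofib_R1881_vs_DMSO",
      nf$M1$macrophage_kill$M1pkill[["R1881"]],
      nf$M1$macrophage_kill$M1pkill[["DMSO"]]),
    c("TUpprol_M2context_R1881_vs_DMSO",
      nf$M2$macrophage_kill$TUpprol[["R1881"]],
      nf$M2$macrophage_kill$TUpprol[["DMSO"]]),
    c("M2pkill_R1881_vs_DMSO",
      nf$M2$macrophage_kill$M2pkill[["R1881"]],
      nf$M2$macrophage_kill$M2pkill[["DMSO"]])
  )
  out <- data.frame(
    comparison = vapply(rows, function(x) x[1], character(1)),
    numerator = as.numeric(vapply(rows, function(x) x[2], character(1))),
    denominator = as.numeric(vapply(rows, function(x) x[3], character(1)))
  )
  out$fold <- fold_change(out$numerator, out$denominator)
  out$fold_rounded <- round(out$fold)
  out
}

#' Nearest-neighbor clustering index
#'
#' A Clark-Evans-style statistic for spatial aggregation on the lattice: the
#' ratio of the observed mean nearest-neighbor (Euclidean) distance among
#' agents of one kind to its expectation under uniform random placement of
#' the same number of agents on the same grid (estimated by Monte Carlo).
#' Values below 1 indicate clustering, above 1 overdispersion. A lower-tail
#' Monte Carlo p-value against the uniform-placement null is included.
#'
#' @param snapshot Integer-coded snapshot matrix (see
#'   [as_snapshot_matrix()]) or a `pcabm_state`.
#' @param kind Agent kind to test (name or integer code).
#' @param n_null Number of Monte Carlo null placements (default 199). Draws
#'   from the current RNG stream; seed beforehand for reproducibility.
#' @return A list of class `nn_clustering` with elements `index`, `observed`,
#'   `expected`, `p_value`, `n`, and `n_null`.
#' @export
nearest_neighbor_clustering <- function(snapshot, kind = "tumor_resistant",
                                        n_null = 199) {
  if (inherits(snapshot, "pcabm_state")) snapshot <- as_snapshot_matrix(snapshot)
  stopifnot(is.matrix(snapshot))
  code <- if (is.character(kind)) kind_code(kind) else as.integer(kind)
  h <- nrow(snapshot); w <- ncol(snapshot)
  ij <- which(snapshot == code, arr.ind = TRUE)
  n <- nrow(ij)
  if (n < 2)
    stop(sprintf(
      "clustering index undefined: %d agent(s) of kind '%s' (need >= 2)",
      n, if (is.character(kind)) kind else kind_name(code)))
  observed <- cpp_mean_nn_distance(ij[, 1] - 1L, ij[, 2] - 1L, w, h)
  null_means <- vapply(seq_len(n_null), function(i) {
    pos <- sample.int(w * h, n) - 1L
    cpp_mean_nn_distance(pos %/% w, pos %% w, w, h)
  }, numeric(1))
  expected <- mean(null_means)
  structure(list(index = observed / expected, observed = observed,
                 expected = expected,
                 p_value = (1 + sum(null_means <= observed)) / (n_null + 1),
                 n = n, n_null = n_null),
            class = "nn_clustering")
}

#' @export
print.nn_clustering <- function(x, ...) {
  cat(sprintf(
    paste0("<nn_clustering> index = %.3f (observed %.3f / expected %.3f),",
           " n = %d, p = %.4f [%s]\n"),
    x$index, x$observed, x$expected, x$n, x$p_value,
    if (x$index < 1) "clustered" else "not clustered"))
  invisible(x)
}
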