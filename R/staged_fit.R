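# Staged, replicate-aware calibration of the model against growth-curve data.
#
# Each stage frees a small set of parameters and fixes everything previously
# calibrated. Per biological replicate the PSO is restarted `config$restarts`
# times; the per-replicate median of restart optima is taken, and the median
# across biological replicates becomes the fixed value fed to later stages.

.default_stage_scenarios <- function(ticks = 42L, tumor_seed = 1000L,
                                     lattice = lattice_config()) {
  sc <- function(base, cond) build_scenario(paste(base, cond, sep = "_"),
                                            ticks = ticks,
                                            tumor_seed = tumor_seed,
                                            lattice = lattice)
  list(
    tumor_mono = list(DMSO = sc("LNCaP_mono", "DMSO"),
                      R1881 = sc("LNCaP_mono", "R1881")),
    fibroblast = list(R1881 = sc("Fibroblast_mono", "R1881")),
    tu_f_m1 = list(DMSO = sc("LNCaP_F_M1_411", "DMSO"),
                   R1881 = sc("LNCaP_F_M1_411", "R1881")),
    tu_f_m2 = list(DMSO = sc("LNCaP_F_M2_411", "DMSO"),
                   R1881 = sc("LNCaP_F_M2_411", "R1881")),
    tu_m1 = list(DMSO = sc("LNCaP_M1_41", "DMSO"),
                 R1881 = sc("LNCaP_M1_41", "R1881")),
    tu_m2 = list(DMSO = sc("LNCaP_M2_41", "DMSO"),
                 R1881 = sc("LNCaP_M2_41", "R1881")),
    resistant = list(DMSO = sc("LNCaPabl_mono", "DMSO"))
  )
}

# One calibration unit: fit `free` on `dataset` (possibly several biological
# replicates), restarting the swarm per replicate. Returns the median-of-
# replicate-medians vector (capacities rounded) plus all per-replicate fits.
.fit_stage <- function(free, base_params, scenario, dataset, config,
                       n_sim_rep, target_kind = "tumor_total") {
  spec <- fit_spec(free, base_params, scenario, target_kind = target_kind,
                   n_sim_rep = n_sim_rep)
  reps <- sort(unique(dataset$bio_rep))
  fits <- lapply(seq_along(reps), function(i) {
    rep_data <- dataset[dataset$bio_rep == reps[i], ]
    rep_config <- config
    rep_config$seed <- derive_seed(config$seed, 7000 + i)
    run_pso(spec, rep_data, rep_config)
  })
  names(fits) <- paste0("bio_rep_", reps)
  per_rep <- do.call(rbind, lapply(fits, `[[`, "median"))
  value <- apply(per_rep, 2, stats::median)
  value[names(value) %in% .count_fields] <-
    round(value[names(value) %in% .count_fields])
  list(value = value, per_replicate = per_rep, fits = fits)
}

.stage_data <- function(datasets, stage, condition = NULL) {
  d <- datasets[[stage]]
  if (is.null(d))
    stop("staged_fit: no dataset provided for stage '", stage, "'")
  if (!is.null(condition)) {
    d <- d[d$condition == condition, ]
    if (nrow(d) == 0)
      stop("staged_fit: stage '", stage, "' has no rows for condition '",
           condition, "'")
  }
  d
}

.set_params <- function(params, values) {
  p <- unclass(params)
  p[names(values)] <- as.list(values)
  validate_params(p)
}

#' Staged calibration protocol
#'
#' Executes the calibration stages in their dependency order, feeding fitted
#' medians forward as frozen values:
#'
#' 1. `tumor_mono` (R1881): fit `TUpprol` and `TUpmax` on tumor monoculture
#'    curves. The proliferation capacity is assumed hormone independent and
#'    estimated only here.
#' 2. `tumor_mono` (DMSO): fit `TUpprol` with `TUpmax` frozen from stage 1.
#' 3. `fibroblast` (R1881 only): fit `Fpprol` and `Fpdeath` (optionally
#'    `Fpmax`) on fibroblast curves; fibroblast growth is hormone
#'    insensitive, so the values are copied to both conditions.
#' 4. `tu_f_m1`: fit `M1pkill` and `M1kmax` under R1881 (killing capacity at
#'    its maximum there); under DMSO fit `M1pkill` only, `M1kmax` frozen.
#' 5. `tu_f_m2`: fit `M2pkill` and `M2TUadd` per condition, with `M2kmax`
#'    set equal to the fitted `M1kmax`.
#' 6. `tu_m1` / `tu_m2` (optional): tumor + macrophage co-cultures without
#'    fibroblasts, refit under DMSO with two alternative freezing schemes --
#'    `tumor_prolif` (free `TUpprol`, killing frozen at the R1881 values) and
#'    `macrophage_kill` (free `Mpkill`, proliferation frozen at the DMSO
#'    value). Both variants are reported with their costs; neither feeds
#'    forward.
#' 7. `resistant` (DMSO): fit `TUpprolres` and `TUpmaxres` on
#'    castration-resistant monoculture curves.
#'
#' Per biological replicate the swarm is restarted `config$restarts` times;
#' per-replicate medians are aggregated by the across-replicate median.
#'
#' @param datasets Named list of growth datasets keyed by stage name
#'   (`tumor_mono`, `fibroblast`, `tu_f_m1`, `tu_f_m2`, `tu_m1`, `tu_m2`,
#'   `resistant`). Only the stages listed in `stages` are required.
#' @param config A [pso_config()].
#' @param stages Character vector of stages to run, in protocol order
#'   (default: the stages for which data was supplied).
#' @param scenarios Per-stage scenario configurations (see source for the
#'   default catalog mapping); override to calibrate at other problem sizes.
#' @param init_params Named list with starting [pcabm_params()] per condition
#'   (defaults to the presets; frozen parameters keep these values).
#' @param n_sim_rep Simulations averaged per cost evaluation.
#' @param fit_fpmax Also free `Fpmax` in the fibroblast stage.
#' @return A list with `params` (calibrated [pcabm_params()] per condition)
#'   and `fits` (per-stage fit objects with per-restart tables).
#' @export
staged_fit <- function(datasets, config = pso_config(),
                       stages = NULL,
                       scenarios = .default_stage_scenarios(),
                       init_params = list(DMSO = preset_params("DMSO"),
                                          R1881 = preset_params("R1881")),
                       n_sim_rep = 3, fit_fpmax = FALSE) {
  order_all <- c("tumor_mono", "fibroblast", "tu_f_m1", "tu_f_m2",
                 "tu_m1", "tu_m2", "resistant")
  if (is.null(stages)) stages <- intersect(order_all, names(datasets))
  unknown <- setdiff(stages, order_all)
  if (length(unknown) > 0)
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  stages <- intersect(order_all, stages)
  params <- init_params
  fits <- list()

  if ("tumor_mono" %in% stages) {
    d <- .stage_data(datasets, "tumor_mono", "R1881")
    f <- .fit_stage(c("TUpprol", "TUpmax"), params$R1881,
                    scenarios$tumor_mono$R1881, d, config, n_sim_rep)
    params$R1881 <- .set_params(params$R1881, f$value)
    fits$tumor_mono_R1881 <- f

    params$DMSO <- .set_params(params$DMSO,
                               c(TUpmax = unname(f$value["TUpmax"])))
    d <- .stage_data(datasets, "tumor_mono", "DMSO")
    f <- .fit_stage("TUpprol", params$DMSO, scenarios$tumor_mono$DMSO, d,
                    config, n_sim_rep)
    params$DMSO <- .set_params(params$DMSO, f$value)
    fits$tumor_mono_DMSO <- f
  }

  if ("fibroblast" %in% stages) {
    d <- .stage_data(datasets, "fibroblast", "R1881")
    free <- c("Fpprol", "Fpdeath", if (fit_fpmax) "Fpmax")
    f <- .fit_stage(free, params$R1881, scenarios$fibroblast$R1881, d,
                    config, n_sim_rep, target_kind = "fibroblast")
    params$R1881 <- .set_params(params$R1881, f$value)
    params$DMSO <- .set_params(params$DMSO, f$value)   # hormone insensitive
    fits$fibroblast <- f
  }

  if ("tu_f_m1" %in% stages) {
    d <- .stage_data(datasets, "tu_f_m1", "R1881")
    f <- .fit_stage(c("M1pkill", "M1kmax"), params$R1881,
                    scenarios$tu_f_m1$R1881, d, config, n_sim_rep)
    params$R1881 <- .set_params(params$R1881, f$value)
    fits$tu_f_m1_R1881 <- f

    params$DMSO <- .set_params(params$DMSO,
                               c(M1kmax = unname(f$value["M1kmax"])))
    d <- .stage_data(datasets, "tu_f_m1", "DMSO")
    f <- .fit_stage("M1pkill", params$DMSO, scenarios$tu_f_m1$DMSO, d,
                    config, n_sim_rep)
    params$DMSO <- .set_params(params$DMSO, f$value)
    fits$tu_f_m1_DMSO <- f
  }

  if ("tu_f_m2" %in% stages) {
    for (cond in c("R1881", "DMSO")) {
      params[[cond]] <- .set_params(
        params[[cond]], c(M2kmax = unname(params[[cond]]$M1kmax)))
      d <- .stage_data(datasets, "tu_f_m2", cond)
      f <- .fit_stage(c("M2pkill", "M2TUadd"), params[[cond]],
                      scenarios$tu_f_m2[[cond]], d, config, n_sim_rep)
      params[[cond]] <- .set_params(params[[cond]], f$value)
      fits[[paste0("tu_f_m2_", cond)]] <- f
    }
  }

  for (stage in intersect(c("tu_m1", "tu_m2"), stages)) {
    kill_param <- if (stage == "tu_m1") "M1pkill" else "M2pkill"
    d <- .stage_data(datasets, stage, "DMSO")
    # variant A: tumor proliferation free, killing frozen at R1881 values
    base_a <- .set_params(params$DMSO, stats::setNames(
      c(params$R1881[[kill_param]]), kill_param))
    fa <- .fit_stage("TUpprol", base_a, scenarios[[stage]]$DMSO, d,
                     config, n_sim_rep)
    # variant B: killing free, tumor proliferation frozen at the DMSO value
    fb <- .fit_stage(kill_param, params$DMSO, scenarios[[stage]]$DMSO, d,
                     config, n_sim_rep)
    fits[[paste0(stage, "_tumor_prolif")]] <- fa
    fits[[paste0(stage, "_macrophage_kill")]] <- fb
  }

  if ("resistant" %in% stages) {
    d <- .stage_data(datasets, "resistant", "DMSO")
    f <- .fit_stage(c("TUpprolres", "TUpmaxres"), params$DMSO,
                    scenarios$resistant$DMSO, d, config, n_sim_rep)
    params$DMSO <- .set_params(params$DMSO, f$value)
    fits$resistant <- f
  }

  list(params = params, fits = fits, stages = stages)
}

#' Serialize a fit result to JSON (and its restart table to CSV)
#'
#' @param fit A `pcabm_fit` from [run_pso()] or [pso_optimize()].
#' @param path Output JSON path; the per-restart table goes to the same path
#'   with extension `.csv` when `restarts_csv = TRUE`.
#' @param restarts_csv Also write the per-restart table as CSV.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, restarts_csv = TRUE) {
  stopifnot(inherits(fit, "pcabm_fit"))
  x <- list(median = as.list(fit$median), iqr = as.list(fit$iqr),
            best = as.list(fit$best), best_cost = fit$best_cost,
            cost_at_median = fit$cost_at_median,
            n_restarts = nrow(fit$per_restart))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (restarts_csv)
    utils::write.csv(fit$per_restart, sub("\\.json$", ".csv", path),
                     row.names = FALSE)
  invisible(path)
}
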