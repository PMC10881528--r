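#' Model parameter set
#'
#' Construct the full set of rate constants driving the lattice model: per-tick
#' action probabilities, proliferation/killing capacities, and macrophage
#' movement sub-step counts. A tick represents 4 hours of culture time.
#'
#' Probabilities are per-agent, per-tick chances of attempting an action
#' (proliferate, migrate, die, kill). Capacities are integers: `TUpmax` /
#' `TUpmaxres` / `Fpmax` bound the number of divisions per lineage counter and
#' `M1kmax` / `M2kmax` the number of kills per macrophage before exhaustion.
#' `M1speed` / `M2speed` are single-cell movement sub-steps per tick, and the
#' engagement durations are sub-steps of post-kill paralysis (an engagement of
#' 60 sub-steps at speed 40 immobilizes a macrophage for 2 ticks). `M2TUadd`
#' is the system-wide bonus added to sensitive tumor proliferation whenever at
#' least one live M2 macrophage is present.
#'
#' @param TUpprol,TUpmig,TUpdeath,TUrwalk Tumor cell proliferation, migration
#'   and spontaneous death probabilities, and the probability that a migration
#'   step is random rather than directed towards the nearest fibroblast.
#' @param TUpmax Tumor proliferation capacity (maximum divisions).
#' @param TUpres Probability that a newborn sensitive tumor cell is resistant.
#' @param TUpprolres,TUpmigres,TUpmaxres Resistant tumor cell proliferation and
#'   migration probabilities and proliferation capacity.
#' @param M1pkill,M1pmig,M1rwalk,M1kmax,M1speed,M1engagementDuration M1
#'   macrophage kill/migration probabilities, random-walk weight, killing
#'   capacity, movement sub-steps per tick, and post-kill engagement sub-steps.
#' @param M2pkill,M2pmig,M2rwalk,M2kmax,M2speed,M2engagementDuration As for M1,
#'   for M2 macrophages.
#' @param M2TUadd Addition to sensitive tumor proliferation probability while
#'   any live M2 macrophage is present in the system.
#' @param Fpprol,Fpmig,Fpdeath,Frwalk Fibroblast action probabilities; directed
#'   fibroblast migration targets the nearest tumor cell.
#' @param Fpmax Fibroblast proliferation capacity; `Inf` (default) = unlimited.
#' @param Mpdeath Macrophage spontaneous death probability (default 0).
#' @return An object of class `pcabm_params` (a validated named list).
#' @seealso [preset_params()] for the calibrated hormone-condition presets.
#' @export
pcabm_params <- function(TUpprol = 0, TUpmig = 0, TUpdeath = 0, TUrwalk = 0.5,
                         TUpmax = 4, TUpres = 0, TUpprolres = 0,
                         TUpmigres = 0, TUpmaxres = 0,
                         M1pkill = 0, M1pmig = 0, M1rwalk = 0.8, M1kmax = 11,
                         M1speed = 40, M1engagementDuration = 60,
                         M2pkill = 0, M2pmig = 0, M2rwalk = 0.8, M2kmax = 11,
                         M2speed = 40, M2engagementDuration = 60,
                         M2TUadd = 0,
                         Fpprol = 0, Fpmig = 0, Fpdeath = 0, Frwalk = 0.5,
                         Fpmax = Inf, Mpdeath = 0) {
  p <- list(TUpprol = TUpprol, TUpmig = TUpmig, TUpdeath = TUpdeath,
            TUrwalk = TUrwalk, TUpmax = TUpmax, TUpres = TUpres,
            TUpprolres = TUpprolres, TUpmigres = TUpmigres,
            TUpmaxres = TUpmaxres,
            M1pkill = M1pkill, M1pmig = M1pmig, M1rwalk = M1rwalk,
            M1kmax = M1kmax, M1speed = M1speed,
            M1engagementDuration = M1engagementDuration,
            M2pkill = M2pkill, M2pmig = M2pmig, M2rwalk = M2rwalk,
            M2kmax = M2kmax, M2speed = M2speed,
            M2engagementDuration = M2engagementDuration,
            M2TUadd = M2TUadd,
            Fpprol = Fpprol, Fpmig = Fpmig, Fpdeath = Fpdeath,
            Frwalk = Frwalk, Fpmax = Fpmax, Mpdeath = Mpdeath)
  validate_params(p)
}

.prob_fields <- c("TUpprol", "TUpmig", "TUpdeath", "TUrwalk", "TUpres",
                  "TUpprolres", "TUpmigres", "M1pkill", "M1pmig", "M1rwalk",
                  "M2pkill", "M2pmig", "M2rwalk", "M2TUadd",
                  "Fpprol", "Fpmig", "Fpdeath", "Frwalk", "Mpdeath")
.count_fields <- c("TUpmax", "TUpmaxres", "M1kmax", "M1speed",
                   "M1engagementDuration", "M2kmax", "M2speed",
                   "M2engagementDuration", "Fpmax")

validate_params <- function(p) {
  missing <- setdiff(c(.prob_fields, .count_fields), names(p))
  if (length(missing) > 0)
    stop("parameter set is missing: ", paste(missing, collapse = ", "))
  for (f in .prob_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(sprintf("%s must be a probability in [0, 1], got %s",
                   f, format(p[[f]])))
  }
  for (f in .count_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop(sprintf("%s must be a non-negative count, got %s", f, format(v)))
    if (is.finite(v) && v != round(v))
      stop(sprintf("%s must be an integer, got %s", f, format(v)))
  }
  if (!is.finite(p$Fpmax) && p$Fpmax != Inf)
    stop("Fpmax must be a non-negative integer or Inf")
  if (p$TUpprol + p$M2TUadd > 1)
    stop("TUpprol + M2TUadd must not exceed 1")
  structure(p[c(.prob_fields[1:4], "TUpmax", .prob_fields[5:7], "TUpmaxres",
                "M1pkill", "M1pmig", "M1rwalk", "M1kmax", "M1speed",
                "M1engagementDuration",
                "M2pkill", "M2pmig", "M2rwalk", "M2kmax", "M2speed",
                "M2engagementDuration", "M2TUadd",
                "Fpprol", "Fpmig", "Fpdeath", "Frwalk", "Fpmax", "Mpdeath")],
            class = "pcabm_params")
}

#' Calibrated parameter presets for the two hormone conditions
#'
#' Returns the calibrated rate constants for one hormone condition:
#' `"DMSO"` (vehicle control in hormone-stripped medium, emulating androgen
#' deprivation) or `"R1881"` (synthetic androgen, hormone proficient). The
#' androgen response is dominated by a roughly threefold difference in tumor
#' proliferation (`TUpprol` 0.1144 vs 0.0389) and a roughly 22-fold difference
#' in M1 macrophage killing (`M1pkill` 0.1116 vs 0.005). Resistance parameters
#' (`TUpres`, `TUpprolres`, `TUpmigres`, `TUpmaxres`) are active only under
#' deprivation, where castration-resistant clones have a growth advantage.
#'
#' @param condition `"DMSO"` or `"R1881"`.
#' @return A [pcabm_params()] object.
#' @export
preset_params <- function(condition = c("DMSO", "R1881")) {
  condition <- match.arg(condition)
  if (condition == "DMSO") {
    pcabm_params(
      TUpprol = 0.0389, TUpmig = 0.1, TUpdeath = 0.00248, TUrwalk = 0.5,
      TUpmax = 4, TUpres = 0.002, TUpprolres = 0.0596, TUpmigres = 0.1167,
      TUpmaxres = 50,
      M1pkill = 0.005, M1pmig = 0.2667, M1rwalk = 0.8, M1kmax = 11,
      M1speed = 40, M1engagementDuration = 60,
      M2pkill = 0.0348, M2pmig = 0.2667, M2rwalk = 0.8, M2kmax = 11,
      M2speed = 40, M2engagementDuration = 60,
      M2TUadd = 0,
      Fpprol = 0.0838, Fpmig = 0.4, Fpdeath = 0.0018, Frwalk = 0.5)
  } else {
    pcabm_params(
      TUpprol = 0.1144, TUpmig = 0.1167, TUpdeath = 0.00248, TUrwalk = 0.5,
      TUpmax = 4, TUpres = 0, TUpprolres = 0, TUpmigres = 0, TUpmaxres = 0,
      M1pkill = 0.1116, M1pmig = 0.2667, M1rwalk = 0.8, M1kmax = 11,
      M1speed = 40, M1engagementDuration = 60,
      M2pkill = 0.0223, M2pmig = 0.2667, M2rwalk = 0.8, M2kmax = 11,
      M2speed = 40, M2engagementDuration = 60,
      M2TUadd = 0.0995,
      Fpprol = 0.0838, Fpmig = 0.4, Fpdeath = 0.0018, Frwalk = 0.5)
  }
}

#' Parameter values refit in tumor-macrophage co-cultures without fibroblasts
#'
#' When the model is calibrated on tumor + macrophage co-cultures (fibroblasts
#' excluded to remove their confounding spatial effects), two alternative
#' freezing schemes exist per macrophage subtype: refit the tumor proliferation
#' probability with killing frozen, or refit the killing probability with
#' proliferation frozen at its vehicle value. This returns the calibrated
#' values for both schemes, used by [report_fold_changes()].
#'
#' @return A nested list with elements `M1` and `M2`, each containing the two
#'   refit variants with their fitted values per hormone condition.
#' @export
nofibroblast_refits <- function() {
  list(
    M1 = list(
      tumor_prolif = list(TUpprol = c(DMSO = 0.1550, R1881 = 0.1144)),
      macrophage_kill = list(M1pkill = c(DMSO = 0.005, R1881 = 0.2034),
                             TUpprol_frozen = c(DMSO = 0.0389))
    ),
    M2 = list(
      tumor_prolif = list(TUpprol = c(DMSO = 0.1341), TUpmax = c(DMSO = 5)),
      macrophage_kill = list(TUpprol = c(DMSO = 0.0384, R1881 = 0.1128),
                             M2pkill = c(DMSO = 0.0219, R1881 = 0.0441))
    )
  )
}

#' @export
print.pcabm_params <- function(x, ...) {
  cat("<pcabm_params>\n")
  vals <- vapply(unclass(x), format, character(1))
  cat(paste0("  ", format(names(vals), width = 22), vals, collapse = "\n"),
      "\n", sep = "")
  invisible(x)
}

#' Serialize or restore a parameter set as JSON
#'
#' Field names in the JSON mirror the parameter names exactly (`TUpprol`,
#' `M1pkill`, ...); `Fpmax = Inf` is stored as the string `"Inf"`.
#'
#' @param params A [pcabm_params()] object.
#' @param path File path to write to / read from.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   a validated [pcabm_params()] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "pcabm_params"))
  p <- unclass(params)
  if (!is.finite(p$Fpmax)) p$Fpmax <- "Inf"
  jsonlite::write_json(p, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(p$Fpmax, "Inf")) p$Fpmax <- Inf
  do.call(pcabm_params, p)
}
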