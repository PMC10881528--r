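.params_for_cpp <- function(params) {
  p <- unclass(params)
  p$Fpmax <- if (is.finite(p$Fpmax)) as.integer(p$Fpmax) else -1L
  int_fields <- c("TUpmax", "TUpmaxres", "M1kmax", "M1speed",
                  "M1engagementDuration", "M2kmax", "M2speed",
                  "M2engagementDuration")
  p[int_fields] <- lapply(p[int_fields], as.integer)
  p
}

.state_for_cpp <- function(state) {
  list(kind = as.integer(state$kind), row = as.integer(state$row),
       col = as.integer(state$col), divs = as.integer(state$divs),
       kills = as.integer(state$kills), engage = as.integer(state$engage),
       alive = state$alive, tick = as.integer(state$tick))
}

.state_from_cpp <- function(cpp_state, template) {
  structure(c(list(lattice = template$lattice), cpp_state,
              list(tick_hours = template$tick_hours)),
            class = "pcabm_state")
}

.events_df <- function(ev) {
  ev$event <- c("birth", "death", "kill")[ev$event]
  ev$kind <- kind_name(ev$kind)
  ev
}

#' Effective tumor proliferation probability
#'
#' Sensitive tumor cells proliferate with probability `TUpprol`, raised by
#' `M2TUadd` whenever at least one live M2 macrophage is present anywhere in
#' the system (a global, paracrine-like growth stimulus). Resistant cells use
#' `TUpprolres` and receive no M2 bonus. The result is clamped to `[0, 1]`.
#'
#' @param params A [pcabm_params()] object.
#' @param state A `pcabm_state`.
#' @param is_resistant Whether the acting cell is castration resistant.
#' @return A probability.
#' @export
effective_tumor_pprol <- function(params, state, is_resistant = FALSE) {
  stopifnot(inherits(params, "pcabm_params"))
  if (is_resistant) return(min(1, params$TUpprolres))
  m2_present <- any(state$alive & state$kind == 5L)
  min(1, params$TUpprol + if (m2_present) params$M2TUadd else 0)
}

#' Resolve a single agent's action
#'
#' Runs one agent through the same sequential stochastic decision scheme used
#' inside the tick loop (tumor/fibroblast: death, then proliferation, then
#' migration, else idle; macrophage: engagement recovery, death, kill,
#' migration, else idle), mutating the state accordingly. Mostly useful for
#' testing and for stepping through dynamics interactively; draws from the
#' current RNG stream.
#'
#' @param state A `pcabm_state`.
#' @param agent Index of a live agent (1-based).
#' @param params A [pcabm_params()] object.
#' @return A list with elements `state` (the mutated state) and `events`
#'   (data frame of births/deaths/kills caused by the action).
#' @export
resolve_agent_action <- function(state, agent, params) {
  stopifnot(inherits(state, "pcabm_state"))
  out <- cpp_resolve_agent(state$lattice$width, state$lattice$height,
                           .state_for_cpp(state), .params_for_cpp(params),
                           as.integer(agent))
  list(state = .state_from_cpp(out$state, state),
       events = .events_df(out$events))
}

#' Advance the simulation by whole ticks
#'
#' One tick represents 4 hours. Agent groups act in the fixed order
#' tumor cells, fibroblasts, M1 macrophages, M2 macrophages; within each group
#' the order is reshuffled every tick, and agents born during a tick idle
#' until the next one.
#'
#' @param state A `pcabm_state`.
#' @param params A [pcabm_params()] object.
#' @param n_ticks Number of ticks to advance (default 1).
#' @param record_events Record per-event bookkeeping (births, deaths, kills)
#'   in the `events` attribute of the returned state.
#' @return The advanced `pcabm_state`; with `record_events = TRUE`, attributes
#'   `events` (data frame) and `counts` (per-tick counts matrix) are attached.
#' @export
advance_one_tick <- function(state, params, n_ticks = 1L,
                             record_events = FALSE) {
  stopifnot(inherits(state, "pcabm_state"))
  out <- cpp_simulate(state$lattice$width, state$lattice$height,
                      .state_for_cpp(state), .params_for_cpp(params),
                      as.integer(n_ticks), integer(0), record_events)
  new_state <- .state_from_cpp(out$state, state)
  if (record_events) {
    attr(new_state, "events") <- .events_df(out$events)
    attr(new_state, "counts") <- cbind(tick = out$ticks, out$counts)
  }
  new_state
}

#' Run a full simulation
#'
#' Initializes a state from the scenario configuration and advances it for
#' `config$ticks` ticks of 4 hours, recording per-tick population counts and,
#' optionally, occupancy snapshots and an event ledger. Identical
#' `(config, params, seed)` triples give byte-identical trajectories.
#'
#' @param config A [scenario_config()] (or catalog name via
#'   [build_scenario()]).
#' @param params A [pcabm_params()] object; defaults to the preset for the
#'   scenario's hormone condition.
#' @param seed Integer seed for the run.
#' @param snapshot_ticks Integer vector of tick numbers at which to store
#'   integer-coded grid snapshots (0 = initial state).
#' @param record_events Record the per-event ledger (slower, more memory).
#' @return A `pcabm_trajectory`: list with `counts` (data frame of per-tick
#'   live counts per kind plus `time_h`), `snapshots`, `events`,
#'   `final_state`, `config`, and `seed`.
#' @export
run_simulation <- function(config, params = NULL, seed = NULL,
                           snapshot_ticks = integer(0),
                           record_events = FALSE) {
  if (is.character(config)) config <- build_scenario(config)
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(params)) params <- preset_params(config$condition)
  stopifnot(inherits(params, "pcabm_params"))
  if (config$ticks < 1) stop("config$ticks must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  state <- initialize_state(config, params)
  out <- cpp_simulate(state$lattice$width, state$lattice$height,
                      .state_for_cpp(state), .params_for_cpp(params),
                      as.integer(config$ticks),
                      as.integer(snapshot_ticks), record_events)
  counts <- as.data.frame(out$counts)
  counts <- cbind(tick = out$ticks,
                  time_h = out$ticks * state$tick_hours, counts)
  structure(list(
    counts = counts,
    snapshots = out$snapshots,
    events = if (record_events) .events_df(out$events) else NULL,
    final_state = .state_from_cpp(out$state, state),
    config = config,
    seed = seed
  ), class = "pcabm_trajectory")
}

#' @export
print.pcabm_trajectory <- function(x, ...) {
  last <- x$counts[nrow(x$counts), ]
  cat(sprintf("<pcabm_trajectory> scenario '%s' (%s), %d ticks (%g h)\n",
              x$config$name, x$config$condition,
              nrow(x$counts) - 1L, max(x$counts$time_h)))
  cat("  final counts:",
      paste(sprintf("%s=%d", .kind_levels,
                    unlist(last[.kind_levels])), collapse = ", "), "\n")
  invisible(x)
}
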