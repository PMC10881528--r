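#' @useDynLib pcabm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Agent kind codes shared with the C++ core and snapshot CSVs:
# 0 empty, 1 tumor, 2 resistant tumor, 3 fibroblast, 4 M1, 5 M2
.kind_levels <- c("tumor", "tumor_resistant", "fibroblast", "M1", "M2")

kind_code <- function(kind) {
  i <- match(kind, .kind_levels)
  if (anyNA(i))
    stop("unknown agent kind: ", paste(kind[is.na(i)], collapse = ", "),
         " (expected one of ", paste(.kind_levels, collapse = ", "), ")")
  i
}

kind_name <- function(code) .kind_levels[code]

#' Initialize a simulation state
#'
#' Scatters the requested number of agents of each kind uniformly at random
#' on the grid without collisions, emulating random seeding of a culture well.
#' Tumor cells start with their full proliferation capacity
#' (`TUpmax`, resistant: `TUpmaxres`), fibroblasts with `Fpmax` (unlimited by
#' default), and macrophages with their full killing capacity and no
#' engagement. A fraction `resistant_fraction` of the seeded tumor cells
#' (rounded to the nearest whole cell) is seeded as resistant.
#'
#' @param config A [scenario_config()].
#' @param params A [pcabm_params()] object (supplies initial capacities).
#' @param seed Optional integer seed; when given, placement is reproducible.
#' @return An object of class `pcabm_state`.
#' @export
initialize_state <- function(config, params, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(params, "pcabm_params"))
  if (!is.null(seed)) set.seed(seed)
  lat <- config$lattice
  counts <- config$counts
  n_res <- round(counts[["tumor"]] * config$resistant_fraction)
  n_per_kind <- c(counts[["tumor"]] - n_res, n_res, counts[["fibroblast"]],
                  counts[["M1"]], counts[["M2"]])
  total <- sum(n_per_kind)
  capacity <- lat$width * lat$height
  if (total > capacity)
    stop(sprintf("requested %d agents exceed lattice capacity %d",
                 total, capacity))
  pos <- sample.int(capacity, total) - 1L
  kind <- rep.int(1:5, n_per_kind)
  fdivs <- if (is.finite(params$Fpmax)) as.integer(params$Fpmax) else -1L
  divs <- c(as.integer(params$TUpmax), as.integer(params$TUpmaxres),
            fdivs, 0L, 0L)[kind]
  kills <- c(0L, 0L, 0L, as.integer(params$M1kmax),
             as.integer(params$M2kmax))[kind]
  structure(list(
    lattice = lat,
    kind = kind,
    row = pos %/% lat$width,
    col = pos %% lat$width,
    divs = divs,
    kills = kills,
    engage = integer(total),
    alive = rep(TRUE, total),
    tick = 0L,
    tick_hours = 4
  ), class = "pcabm_state")
}

#' Live agent counts per kind
#'
#' @param state A `pcabm_state`.
#' @return Named integer vector over the five agent kinds.
#' @export
live_counts <- function(state) {
  stopifnot(inherits(state, "pcabm_state"))
  n <- tabulate(state$kind[state$alive], nbins = 5L)
  names(n) <- .kind_levels
  n
}

#' Integer-coded occupancy snapshot
#'
#' @param state A `pcabm_state`.
#' @return An integer matrix (`height` x `width`); 0 empty, 1 tumor,
#'   2 resistant tumor, 3 fibroblast, 4 M1, 5 M2.
#' @export
as_snapshot_matrix <- function(state) {
  stopifnot(inherits(state, "pcabm_state"))
  m <- matrix(0L, nrow = state$lattice$height, ncol = state$lattice$width)
  live <- state$alive
  m[cbind(state$row[live] + 1L, state$col[live] + 1L)] <- state$kind[live]
  m
}

#' @export
print.pcabm_state <- function(x, ...) {
  n <- live_counts(x)
  cat(sprintf("<pcabm_state> %d x %d grid, tick %d (%g h)\n",
              x$lattice$height, x$lattice$width, x$tick,
              x$tick * x$tick_hours))
  cat("  live agents:",
      paste(sprintf("%s=%d", names(n), n), collapse = ", "), "\n")
  invisible(x)
}
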