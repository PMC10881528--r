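# Build a simulation state with agents at exact positions (bypassing random
# seeding), for forced-branch tests of the action rules.
make_state <- function(kind, row, col, divs = NULL, kills = NULL,
                       engage = NULL, width = 9, height = 9, tick = 0L) {
  code <- match(kind, c("tumor", "tumor_resistant", "fibroblast", "M1", "M2"))
  stopifnot(!anyNA(code))
  n <- length(code)
  if (is.null(divs)) divs <- ifelse(code %in% 1:2, 4L, ifelse(code == 3L, -1L, 0L))
  if (is.null(kills)) kills <- ifelse(code %in% 4:5, 11L, 0L)
  if (is.null(engage)) engage <- integer(n)
  structure(list(
    lattice = lattice_config(width, height),
    kind = as.integer(code), row = as.integer(row), col = as.integer(col),
    divs = as.integer(divs), kills = as.integer(kills),
    engage = as.integer(engage), alive = rep(TRUE, n),
    tick = as.integer(tick), tick_hours = 4
  ), class = "pcabm_state")
}

# All-probability-zero parameter set: agents always idle.
null_params <- function(...) pcabm_params(...)

# Small scenario on a small grid for fast whole-run tests.
small_scenario <- function(counts = c(tumor = 30), condition = "R1881",
                           ticks = 10L, width = 25, height = 25,
                           resistant_fraction = 0) {
  scenario_config("small_test", counts, condition = condition,
                  lattice = lattice_config(width, height), ticks = ticks,
                  resistant_fraction = resistant_fraction)
}

# Random parameter set with moderate action probabilities, used by the
# invariant property tests.
random_params <- function() {
  pcabm_params(
    TUpprol = stats::runif(1, 0, 0.3), TUpmig = stats::runif(1, 0, 0.3),
    TUpdeath = stats::runif(1, 0, 0.05), TUrwalk = stats::runif(1),
    TUpmax = sample(2:6, 1), TUpres = stats::runif(1, 0, 0.05),
    TUpprolres = stats::runif(1, 0, 0.3),
    TUpmigres = stats::runif(1, 0, 0.3), TUpmaxres = sample(2:10, 1),
    M1pkill = stats::runif(1, 0, 0.5), M1pmig = stats::runif(1, 0, 0.5),
    M1rwalk = stats::runif(1), M1kmax = sample(1:11, 1),
    M1speed = sample(c(1L, 5L, 40L), 1),
    M1engagementDuration = sample(c(0L, 10L, 60L), 1),
    M2pkill = stats::runif(1, 0, 0.3), M2pmig = stats::runif(1, 0, 0.5),
    M2rwalk = stats::runif(1), M2kmax = sample(1:11, 1),
    M2speed = sample(c(1L, 5L, 40L), 1),
    M2engagementDuration = sample(c(0L, 10L, 60L), 1),
    M2TUadd = stats::runif(1, 0, 0.2),
    Fpprol = stats::runif(1, 0, 0.3), Fpmig = stats::runif(1, 0, 0.5),
    Fpdeath = stats::runif(1, 0, 0.02), Frwalk = stats::runif(1),
    Mpdeath = stats::runif(1, 0, 0.02))
}
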