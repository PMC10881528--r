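#' Read a growth-curve CSV
#'
#' The expected schema (header names) is
#' `time_h,condition,bio_rep,tech_rep,population,relative_count`; unknown
#' extra columns are preserved. This is also the schema expected for
#' user-supplied experimental data.
#'
#' @param path CSV file path.
#' @param check_conditions Require condition labels in `{DMSO, R1881}`
#'   (default `TRUE`); set `FALSE` to accept other labels.
#' @return A growth dataset data frame.
#' @export
read_growth_csv <- function(path, check_conditions = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("empty or unreadable growth dataset: ", path))
  if (nrow(d) == 0) stop("empty growth dataset: ", path)
  missing <- setdiff(.growth_columns, names(d))
  if (length(missing) > 0)
    stop("growth CSV is missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("time_h", "relative_count")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v))
      stop(sprintf("non-numeric %s at row %d of %s", col,
                   which(is.na(v))[1] + 1L, path))  # file row incl. header
    d[[col]] <- v
  }
  validate_growth_dataset(d, check_conditions = check_conditions)
  d
}

#' Write a growth-curve CSV
#'
#' @param dataset A growth dataset (see [validate_growth_dataset()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(dataset, path) {
  validate_growth_dataset(dataset, check_conditions = FALSE)
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export or import an integer-coded snapshot matrix
#'
#' Snapshots are plain CSV integer matrices (no header), one row per lattice
#' row, using the shared code map: 0 empty, 1 tumor, 2 resistant tumor,
#' 3 fibroblast, 4 M1, 5 M2.
#'
#' @param snapshot Integer matrix or `pcabm_state`.
#' @param path File path.
#' @return `export_snapshot()` returns `path` invisibly;
#'   `import_snapshot()` the integer matrix.
#' @export
export_snapshot <- function(snapshot, path) {
  if (inherits(snapshot, "pcabm_state")) snapshot <- as_snapshot_matrix(snapshot)
  stopifnot(is.matrix(snapshot))
  utils::write.table(snapshot, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname export_snapshot
#' @export
import_snapshot <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Plot a snapshot with the standard color legend
#'
#' Renders the occupancy grid with the fixed palette: tumor red, resistant
#' tumor dark red, fibroblast green, M1 dark blue, M2 light blue.
#'
#' @param snapshot Integer snapshot matrix or `pcabm_state`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the snapshot matrix.
#' @export
plot_snapshot <- function(snapshot, ...) {
  if (inherits(snapshot, "pcabm_state")) snapshot <- as_snapshot_matrix(snapshot)
  pal <- c("white", "red", "darkred", "green3", "darkblue", "lightblue")
  codes <- sort(unique(as.vector(snapshot)))
  graphics::image(t(snapshot[nrow(snapshot):1, , drop = FALSE]),
                  col = pal[codes + 1], axes = FALSE, asp = 1,
                  breaks = c(codes - 0.5, max(codes) + 0.5), ...)
  invisible(snapshot)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-exactly: the resolved
#' scenario, the parameter set, the seed, the package version, and the output
#' paths (plus wall time, which is informational only).
#'
#' @param config A [scenario_config()].
#' @param params A [pcabm_params()] object.
#' @param seed Integer seed used.
#' @param outputs Named list/vector of output file paths.
#' @param path Manifest JSON path.
#' @param wall_time_s Elapsed wall time in seconds.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, params, seed, outputs, path,
                           wall_time_s = NA_real_) {
  p <- unclass(params)
  if (!is.finite(p$Fpmax)) p$Fpmax <- "Inf"
  x <- list(
    package = "pcabm",
    version = as.character(utils::packageVersion("pcabm")),
    seed = seed,
    scenario = list(name = config$name, lattice = unclass(config$lattice),
                    counts = as.list(config$counts),
                    condition = config$condition, ticks = config$ticks,
                    resistant_fraction = config$resistant_fraction),
    params = p,
    outputs = as.list(outputs),
    wall_time_s = wall_time_s)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
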