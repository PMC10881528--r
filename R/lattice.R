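#' Lattice configuration
#'
#' The simulation domain is a bounded rectangular grid (no wraparound,
#' modelling a culture well); each grid cell holds at most one agent and has
#' the footprint of one tumor cell.
#'
#' @param width,height Grid dimensions in cells (default 125 x 125, scaled to
#'   a 96-well culture surface).
#' @param cell_area Area of one grid cell in square micrometres (default
#'   142.89, one tumor cell).
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(width = 125L, height = 125L, cell_area = 142.89) {
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.na(width) || width < 1L || is.na(height) || height < 1L)
    stop("width and height must be integers >= 1")
  if (!is.numeric(cell_area) || cell_area <= 0)
    stop("cell_area must be positive")
  structure(list(width = width, height = height, cell_area = cell_area),
            class = "lattice_config")
}

#' Moore neighborhood of a lattice position
#'
#' Returns all in-bounds positions at Chebyshev distance 1 from `position`
#' (up to 8: fewer at edges and corners; the grid does not wrap).
#'
#' @param position Integer vector `c(row, col)`, 0-based.
#' @param lattice A [lattice_config()].
#' @return An integer matrix with columns `row` and `col`, one neighbor per
#'   row, 0-based.
#' @export
moore_neighbors <- function(position, lattice = lattice_config()) {
  stopifnot(length(position) == 2)
  r <- as.integer(position[1]); c <- as.integer(position[2])
  if (r < 0 || r >= lattice$height || c < 0 || c >= lattice$width)
    stop(sprintf("position (%d, %d) outside %d x %d grid",
                 r, c, lattice$height, lattice$width))
  d <- expand.grid(dr = -1:1, dc = -1:1)
  d <- d[!(d$dr == 0 & d$dc == 0), ]
  rr <- r + d$dr; cc <- c + d$dc
  keep <- rr >= 0 & rr < lattice$height & cc >= 0 & cc < lattice$width
  cbind(row = rr[keep], col = cc[keep])
}
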