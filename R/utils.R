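#' @keywords internal
#' @importFrom data.table data.table setorder fread .N
"_PACKAGE"

.datatable.aware <- TRUE

#' Floor a coordinate to its 0.5-degree cell lower corner
#'
#' The grid is anchored at integer degrees and tiles the plane with half-open
#' `[lower, lower + 0.5)` intervals, so a record sitting exactly on a cell
#' boundary belongs to the cell whose lower corner it names.
#'
#' @param x numeric vector of decimal degrees.
#' @return numeric vector of cell lower corners (multiples of 0.5).
#' @examples
#' floor_half(c(-33.87, -34.00, 151.21))
#' @export
floor_half <- function(x) floor(2 * x) / 2

#' Build a cell identifier from lower-corner coordinates
#'
#' @param lower_lat,lower_lon lower-corner coordinates (multiples of 0.5).
#' @return character vector like `"-34_151"`.
#' @export
cell_id <- function(lower_lat, lower_lon) {
  paste(format_half(lower_lat), format_half(lower_lon), sep = "_")
}

# fixed-format half-degree label: no scientific notation, one decimal only
# when needed, stable across locales
format_half <- function(x) {
  ifelse(x == round(x), sprintf("%.0f", x), sprintf("%.1f", x))
}

#' Derive deterministic child seeds from a master seed
#'
#' All stochastic stages draw their seeds from one master seed through this
#' helper, so a whole pipeline run is reproducible from a single integer.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @export
spawn_seeds <- function(master, n) {
  withr::with_seed(as.integer(master), sample.int(.Machine$integer.max - 1L, n))
}

# stop() wrapper that keeps call noise out of user-facing errors
abort <- function(...) stop(..., call. = FALSE)
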