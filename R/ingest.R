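# Ingest: occurrence reading, record filters, 0.5-degree gridding, cell
# filters, and assembly of the cell x species incidence-count matrix.

#' Read point occurrence records from delimited text
#'
#' Reads a Darwin-Core-like occurrence table. Coordinate columns are kept as
#' *text*: stated coordinate precision (the number of decimal places in the
#' recorded string, trailing zeros included) is a property of the string, not
#' of the parsed float, and the record filter operates on it directly.
#'
#' @param path path to a CSV/TSV file.
#' @param col_map named list mapping the roles `name`, `lat`, `lon` (and
#'   optionally `id`) to column names in the file. Defaults to the Darwin
#'   Core names `scientificName`, `decimalLatitude`, `decimalLongitude`.
#' @return a `data.frame` with columns `taxon_name`, `lat`, `lon` (character)
#'   and `source_id`.
#' @export
read_occurrences <- function(path,
                             col_map = list(name = "scientificName",
                                            lat  = "decimalLatitude",
                                            lon  = "decimalLongitude",
                                            id   = "occurrenceID")) {
  raw <- data.table::fread(path, colClasses = "character", data.table = FALSE)
  for (role in c("name", "lat", "lon")) {
    if (is.null(col_map[[role]]) || !col_map[[role]] %in% names(raw))
      abort("occurrence file lacks mapped column for '", role, "'")
  }
  out <- data.frame(taxon_name = raw[[col_map$name]],
                    lat = raw[[col_map$lat]],
                    lon = raw[[col_map$lon]],
                    stringsAsFactors = FALSE)
  out$source_id <- if (!is.null(col_map$id) && col_map$id %in% names(raw))
    raw[[col_map$id]] else as.character(seq_len(nrow(raw)))
  out
}

#' Read the per-cell environmental table
#'
#' The table is keyed by cell lower-corner coordinates (`lower_lat`,
#' `lower_lon`) and carries the eight climatological variables used
#' throughout: mean annual sea-surface temperature and its annual standard
#' deviation (degrees C), mean annual salinity and its annual standard
#' deviation (PSU), dissolved oxygen (ml/l), and nitrate, silicate and
#' phosphate (umol/l).
#'
#' @param path path to a CSV file.
#' @return a `data.frame` with a `cell_id` column plus the variables.
#' @export
read_env <- function(path) {
  env <- data.table::fread(path, data.table = FALSE)
  if (!all(c("lower_lat", "lower_lon") %in% names(env)))
    abort("environmental table must carry 'lower_lat' and 'lower_lon' columns")
  env$cell_id <- cell_id(env$lower_lat, env$lower_lon)
  env
}

#' The eight environmental variable names, in table order
#' @return character vector of length 8.
#' @export
env_variables <- function() {
  c("sst_mean", "sst_sd", "sal_mean", "sal_sd",
    "oxygen", "nitrate", "silicate", "phosphate")
}

# decimal places stated in a coordinate string; NA when unparseable.
# trailing zeros count: "151.20" states 2 decimals of precision.
decimal_places <- function(txt) {
  txt <- trimws(txt)
  ok <- grepl("^[+-]?[0-9]+(\\.[0-9]+)?$", txt)
  dp <- rep(NA_integer_, length(txt))
  has_dot <- ok & grepl("\\.", txt)
  dp[ok & !has_dot] <- 0L
  dp[has_dot] <- nchar(sub("^[^.]*\\.", "", txt[has_dot]))
  dp
}

#' Default taxon-name validity check: a two-word Latin binomial
#'
#' Accepts names of the form `Genus epithet` (a capitalized genus followed by
#' one lower-case epithet). This is the pluggable stand-in for a live
#' nomenclatural registry query; a file-backed validity list can be supplied
#' to [filter_records()] in its place.
#'
#' @param name character vector of taxon names.
#' @return logical vector.
#' @export
is_binomial <- function(name) {
  grepl("^[A-Z][a-z]+ [a-z][a-z-]+$", trimws(name))
}

#' Filter occurrence records on name completeness and coordinate precision
#'
#' Retains only records that (i) carry a full species-level binomial accepted
#' by `name_validator` and (ii) state both coordinates to at least
#' `min_decimals` decimal places. Records whose coordinates cannot be parsed
#' at all are rejected with reason `"malformed"` rather than aborting the
#' run. Order is preserved and per-reason rejection counts are attached.
#'
#' @param records data.frame from [read_occurrences()] (columns `taxon_name`,
#'   `lat`, `lon` as character; numeric coordinates are tolerated but then
#'   trailing zeros cannot be seen, so text input is preferred).
#' @param name_validator predicate on taxon names; defaults to
#'   [is_binomial()].
#' @param min_decimals minimum stated decimal places per coordinate
#'   (default 2).
#' @return the retained records, with an attribute `"rejections"`: a named
#'   integer vector of counts for reasons `no_species_name`, `malformed`,
#'   `low_precision`.
#' @export
filter_records <- function(records, name_validator = is_binomial,
                           min_decimals = 2L) {
  lat_txt <- as.character(records$lat)
  lon_txt <- as.character(records$lon)
  name_ok <- name_validator(records$taxon_name)
  dp_lat <- decimal_places(lat_txt)
  dp_lon <- decimal_places(lon_txt)
  malformed <- is.na(dp_lat) | is.na(dp_lon) |
    is.na(suppressWarnings(as.numeric(lat_txt))) |
    is.na(suppressWarnings(as.numeric(lon_txt)))
  in_range <- !malformed &
    abs(suppressWarnings(as.numeric(lat_txt))) <= 90 &
    abs(suppressWarnings(as.numeric(lon_txt))) <= 180
  malformed <- malformed | (!malformed & !in_range)
  low_prec <- !malformed & (dp_lat < min_decimals | dp_lon < min_decimals)

  keep <- name_ok & !malformed & !low_prec
  rejections <- c(
    no_species_name = sum(!name_ok),
    malformed       = sum(name_ok & malformed),
    low_precision   = sum(name_ok & low_prec)
  )
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  out
}

#' Pool filtered records into 0.5-degree grid cells
#'
#' Each record is assigned to the half-open cell
#' `[floor_half(lat), floor_half(lat) + 0.5) x [floor_half(lon), ... + 0.5)`.
#' Within a cell, the per-species *incidence count* is the number of records
#' of that species; occurrence databases record presences, so these counts
#' are a sampling-effort proxy for abundance, not true abundance.
#'
#' @param records filtered records (see [filter_records()]).
#' @return an object of class `occ_grid`: a list with
#'   \describe{
#'     \item{counts}{data.frame `(cell_id, species, count)` sparse triplets}
#'     \item{cells}{data.frame per cell: `cell_id`, `lower_lat`, `lower_lon`,
#'       `center_lat`, `center_lon`, `n` (records), `S` (species),
#'       `s1`, `s2` (species with exactly 1 or 2 records)}
#'   }
#' @export
grid_records <- function(records) {
  lat <- as.numeric(as.character(records$lat))
  lon <- as.numeric(as.character(records$lon))
  stopifnot(!anyNA(lat), !anyNA(lon))
  lo_lat <- floor_half(lat)
  lo_lon <- floor_half(lon)
  dt <- data.table::data.table(
    cell_id = cell_id(lo_lat, lo_lon),
    lower_lat = lo_lat, lower_lon = lo_lon,
    species = as.character(records$taxon_name)
  )
  counts <- dt[, list(count = .N), by = c("cell_id", "species")]
  data.table::setorder(counts, cell_id, species)
  cells <- counts[, list(
    n = sum(count), S = .N,
    s1 = sum(count == 1L), s2 = sum(count == 2L)
  ), by = "cell_id"]
  corners <- unique(dt[, c("cell_id", "lower_lat", "lower_lon")])
  cells <- merge(cells, corners, by = "cell_id")
  cells$center_lat <- cells$lower_lat + 0.25
  cells$center_lon <- cells$lower_lon + 0.25
  data.table::setorder(cells, cell_id)
  structure(list(counts = as.data.frame(counts),
                 cells = as.data.frame(cells)),
            class = "occ_grid")
}

#' @export
print.occ_grid <- function(x, ...) {
  cat("occ_grid:", nrow(x$cells), "cells,",
      length(unique(x$counts$species)), "species,",
      sum(x$cells$n), "records\n")
  invisible(x)
}

#' Exclude poorly sampled cells
#'
#' Drops any cell with fewer than `min_species` species or fewer than
#' `min_records` records. The default thresholds (10 species, 150 records)
#' reflect the sample size at which the estimators stabilize (see
#' [size_profile()]).
#'
#' @param grid an `occ_grid`.
#' @param min_species,min_records inclusive lower bounds on S and n.
#' @return the filtered `occ_grid`, with attribute `"excluded"`: a data.frame
#'   of dropped cells and the rule(s) each violated.
#' @export
filter_cells <- function(grid, min_species = 10L, min_records = 150L) {
  cells <- grid$cells
  keep <- cells$S >= min_species & cells$n >= min_records
  if (!any(keep)) abort("no cells survive filters")
  excluded <- cells[!keep, c("cell_id", "n", "S")]
  excluded$reason <- paste0(
    ifelse(excluded$S < min_species, "few_species", ""),
    ifelse(excluded$S < min_species & excluded$n < min_records, "+", ""),
    ifelse(excluded$n < min_records, "few_records", "")
  )
  out <- list(counts = grid$counts[grid$counts$cell_id %in%
                                     cells$cell_id[keep], , drop = FALSE],
              cells = cells[keep, , drop = FALSE])
  rownames(out$counts) <- rownames(out$cells) <- NULL
  structure(out, class = "occ_grid", excluded = excluded)
}

#' Build the cell x species incidence-count matrix, joined to environment
#'
#' @param grid a filtered `occ_grid`.
#' @param env environmental table with a `cell_id` column (see [read_env()]).
#'   Cells lacking environmental data are dropped with a warning; a
#'   duplicated `cell_id` in `env` is an error.
#' @return a list of class `cell_matrix`:
#'   \describe{
#'     \item{x}{numeric matrix, rows = cells (rownames `cell_id`),
#'       columns = species, entries = incidence counts}
#'     \item{cells}{cell metadata aligned to rows of `x`}
#'     \item{env}{environmental rows aligned to rows of `x`}
#'   }
#' @export
build_matrix <- function(grid, env) {
  if (anyDuplicated(env$cell_id))
    abort("duplicate cell_id in environmental table: ",
          paste(unique(env$cell_id[duplicated(env$cell_id)]), collapse = ", "))
  cells <- grid$cells
  have_env <- cells$cell_id %in% env$cell_id
  if (!all(have_env)) {
    warning(sum(!have_env), " retained cell(s) lack environmental data ",
            "and were dropped: ",
            paste(utils::head(cells$cell_id[!have_env], 5), collapse = ", "),
            call. = FALSE)
    cells <- cells[have_env, , drop = FALSE]
  }
  if (nrow(cells) == 0L) abort("no cells with environmental data")
  counts <- grid$counts[grid$counts$cell_id %in% cells$cell_id, , drop = FALSE]
  species <- sort(unique(counts$species))
  x <- matrix(0, nrow(cells), length(species),
              dimnames = list(cells$cell_id, species))
  x[cbind(match(counts$cell_id, cells$cell_id),
          match(counts$species, species))] <- counts$count
  env_aligned <- env[match(cells$cell_id, env$cell_id), , drop = FALSE]
  rownames(env_aligned) <- env_aligned$cell_id
  rownames(cells) <- cells$cell_id
  structure(list(x = x, cells = cells, env = env_aligned),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("cell_matrix:", nrow(x$x), "cells x", ncol(x$x), "species;",
      sum(x$x), "records\n")
  invisible(x)
}

#' Run the full ingest stage
#'
#' Convenience wrapper: filter records, grid them, apply cell filters, and
#' join the environmental table.
#'
#' @inheritParams filter_records
#' @inheritParams filter_cells
#' @param env environmental table (see [read_env()]).
#' @return a `cell_matrix` (see [build_matrix()]); rejection and exclusion
#'   logs are carried in the `"log"` attribute.
#' @export
ingest <- function(records, env, name_validator = is_binomial,
                   min_decimals = 2L, min_species = 10L, min_records = 150L) {
  filtered <- filter_records(records, name_validator, min_decimals)
  grid <- grid_records(filtered)
  grid <- filter_cells(grid, min_species, min_records)
  out <- build_matrix(grid, env)
  attr(out, "log") <- list(rejections = attr(filtered, "rejections"),
                           excluded_cells = attr(grid, "excluded"))
  out
}
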