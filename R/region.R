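#' Build a region model from cells, populations and a neighbour ordering
#'
#' A region is a set of `I` administrative cells, each with a (possibly
#' stratified) population and, for every cell, a total ordering of the
#' remaining cells by increasing centroid distance. The ordering drives the
#' nearest-neighbour combination used by all cluster tests: cell `i` combined
#' with its `ell` nearest neighbours has population `n[i:ell]`.
#'
#' @param cell_ids character vector of unique cell identifiers (treated as
#'   opaque strings).
#' @param populations numeric vector of per-cell populations, or a matrix with
#'   one row per cell and one column per stratum. Entries must be
#'   non-negative integers.
#' @param neighbour_order integer or character matrix with one row per cell
#'   and `I - 1` columns; row `i` lists the other cells in increasing distance
#'   from cell `i` (closest first), as indices into `cell_ids` or as ids.
#'   Usually produced by [order_neighbours()].
#' @param strata optional character vector of stratum names; defaults to the
#'   column names of `populations` or a single stratum `"all"`.
#'
#' @return An object of class `region_data` with elements `cell_ids`,
#'   `populations` (I x S matrix), `pop_cell` (per-cell totals), `n` (total
#'   population), `strata`, `n_cells`, and `neighbour_order` (I x (I-1)
#'   integer matrix).
#' @seealso [order_neighbours()], [combined_population()], [event_counts()]
#' @export
#' @examples
#' nb <- order_neighbours(c("a", "b", "c"), coords = cbind(x = c(0, 1, 5), y = 0))
#' reg <- region_data(c("a", "b", "c"), c(100, 200, 300), nb)
#' combined_population(reg, 1, 1)  # a + b
region_data <- function(cell_ids, populations, neighbour_order, strata = NULL) {
  cell_ids <- as.character(cell_ids)
  I <- length(cell_ids)
  if (I < 1L) stop("at least one cell is required")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids: ",
    paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))

  if (is.null(dim(populations))) populations <- matrix(populations, ncol = 1L)
  populations <- as.matrix(populations)
  if (nrow(populations) != I) stop("populations must have one row per cell")
  if (is.null(strata)) {
    strata <- colnames(populations)
    if (is.null(strata)) strata <- if (ncol(populations) == 1L) "all" else
      paste0("s", seq_len(ncol(populations)))
  }
  colnames(populations) <- strata
  rownames(populations) <- cell_ids
  check_counts(populations, "populations")

  neighbour_order <- resolve_neighbour_order(neighbour_order, cell_ids)

  structure(list(
    cell_ids = cell_ids,
    n_cells = I,
    populations = populations,
    pop_cell = rowSums(populations),
    n = sum(populations),
    strata = strata,
    n_strata = length(strata),
    neighbour_order = neighbour_order
  ), class = "region_data")
}

# validate/convert a neighbour-order matrix to cell indices
resolve_neighbour_order <- function(neighbour_order, cell_ids) {
  I <- length(cell_ids)
  if (I == 1L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  nb <- as.matrix(neighbour_order)
  if (nrow(nb) != I || ncol(nb) != I - 1L)
    stop("neighbour_order must be an I x (I-1) matrix")
  if (is.character(nb)) {
    idx <- match(nb, cell_ids)
    if (anyNA(idx)) stop("neighbour_order contains unknown cell ids")
    nb <- matrix(idx, nrow = I)
  }
  storage.mode(nb) <- "integer"
  for (i in seq_len(I)) {
    if (!setequal(nb[i, ], setdiff(seq_len(I), i)))
      stop("neighbour_order row ", i,
           " is not a permutation of the other cells")
  }
  rownames(nb) <- cell_ids
  nb
}

#' @export
print.region_data <- function(x, ...) {
  cat("Region:", x$n_cells, "cells, total population", x$n, "\n")
  if (x$n_strata > 1L)
    cat("Strata:", paste(x$strata, collapse = ", "), "\n")
  invisible(x)
}

#' Order each cell's neighbours by increasing centroid distance
#'
#' Given centroid coordinates or a full pairwise distance matrix, produces for
#' every cell the permutation of the remaining cells sorted by increasing
#' distance. Ties are broken by ascending cell identifier so the ordering is
#' deterministic and invariant to the input row order.
#'
#' @param cell_ids character vector of unique cell identifiers.
#' @param coords optional two-column matrix of cell centroids, one row per
#'   cell. Interpreted as longitude/latitude in decimal degrees when
#'   `coord_type = "lonlat"` (great-circle haversine distances) or as planar
#'   x/y when `coord_type = "xy"` (Euclidean distances).
#' @param distances optional complete symmetric non-negative distance matrix
#'   (overrides `coords`).
#' @param coord_type `"lonlat"` or `"xy"`; declares how `coords` are measured.
#'
#' @return An `I x (I-1)` integer matrix of neighbour indices, closest first,
#'   with `cell_ids` as row names; suitable for [region_data()].
#' @export
order_neighbours <- function(cell_ids, coords = NULL, distances = NULL,
                             coord_type = c("lonlat", "xy")) {
  coord_type <- match.arg(coord_type)
  cell_ids <- as.character(cell_ids)
  I <- length(cell_ids)
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (is.null(distances)) {
    if (is.null(coords)) stop("either coords or distances must be supplied")
    coords <- as.matrix(coords)
    if (nrow(coords) != I || ncol(coords) != 2L)
      stop("coords must be a two-column matrix with one row per cell")
    if (anyNA(coords)) stop("missing coordinates for some cells")
    distances <- if (coord_type == "lonlat") {
      geosphere::distm(coords, fun = geosphere::distHaversine)
    } else {
      as.matrix(stats::dist(coords))
    }
  } else {
    distances <- as.matrix(distances)
    if (nrow(distances) != I || ncol(distances) != I)
      stop("distance matrix must be square with one row per cell")
    if (anyNA(distances)) stop("distance matrix has missing entries")
    if (any(distances < 0)) stop("distances must be non-negative")
    if (!isTRUE(all.equal(distances, t(distances), tolerance = 1e-8,
                          check.attributes = FALSE)))
      stop("distance matrix must be symmetric")
  }
  nb <- matrix(NA_integer_, nrow = I, ncol = max(I - 1L, 0L))
  for (i in seq_len(I)) {
    others <- setdiff(seq_len(I), i)
    if (length(others))
      nb[i, ] <- others[order(distances[i, others], cell_ids[others])]
  }
  rownames(nb) <- cell_ids
  nb
}

# resolve a cell argument (index or id) to an index
cell_index <- function(region, i) {
  if (is.character(i)) {
    idx <- match(i, region$cell_ids)
    if (is.na(idx)) stop("unknown cell id: ", i)
    return(idx)
  }
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > region$n_cells) stop("cell index out of range")
  i
}

# indices of cell i and its first `ell` nearest neighbours
combined_cells <- function(region, i, ell) {
  i <- cell_index(region, i)
  ell <- as.integer(ell)
  if (is.na(ell) || ell < 0L || ell > region$n_cells - 1L)
    stop("ell must be between 0 and I-1")
  c(i, region$neighbour_order[i, seq_len(ell)])
}

#' Population of a cell combined with its nearest neighbours
#'
#' @param region a [region_data()] object.
#' @param i cell index or id.
#' @param ell number of nearest neighbours to combine (0 to I-1).
#' @param by_stratum if `TRUE`, return the per-stratum population vector
#'   instead of the total.
#' @return `n[i:ell]`, the population of cell `i` and its `ell` nearest
#'   neighbours (scalar, or a named vector per stratum).
#' @export
combined_population <- function(region, i, ell, by_stratum = FALSE) {
  idx <- combined_cells(region, i, ell)
  if (by_stratum) colSums(region$populations[idx, , drop = FALSE])
  else sum(region$pop_cell[idx])
}

#' Event (or case) total of a cell combined with its nearest neighbours
#'
#' @inheritParams combined_population
#' @param events an [event_counts()] object on the same cells.
#' @param what `"events"` or `"cases"`.
#' @return combined count over cell `i` and its `ell` nearest neighbours.
#' @export
combined_events <- function(region, events, i, ell, by_stratum = FALSE,
                            what = c("events", "cases")) {
  what <- match.arg(what)
  if (!identical(events$cell_ids, region$cell_ids))
    stop("events and region refer to different cells")
  m <- if (what == "events") events$events else {
    if (is.null(events$cases)) stop("case counts are not available")
    events$cases
  }
  idx <- combined_cells(region, i, ell)
  if (by_stratum) colSums(m[idx, , drop = FALSE]) else sum(m[idx, ])
}

# shared validator: non-negative integer-valued counts
check_counts <- function(x, what) {
  if (anyNA(x)) stop(what, " contain missing values")
  if (any(x < 0)) stop(what, " must be non-negative")
  if (any(abs(x - round(x)) > 1e-8)) stop(what, " must be integers")
  invisible(TRUE)
}
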