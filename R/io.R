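#' Read cells, events and neighbour information from CSV files
#'
#' Input schemas (UTF-8 CSV with a header row; identifiers are opaque
#' strings):
#'
#' * **cells**: columns `cell_id, population` plus optional `stratum` (one
#'   row per cell-by-stratum) and optional centroid coordinates, either
#'   `lon, lat` (decimal degrees, great-circle distances) or `x, y` (planar,
#'   Euclidean distances).
#' * **events**, one of two layouts: a case histogram `cell_id, y, count`
#'   (optional `stratum`), where `count` is the number of cases with exactly
#'   `y` events; or aggregate totals `cell_id, events` (optional `stratum`).
#'   The two layouts must not be mixed.
#' * **neighbours** (optional): `cell_id, rank, neighbour_id` with rank 1 the
#'   closest; overrides any computed ordering.
#' * **distances** (optional): square matrix CSV, first column `cell_id`,
#'   remaining columns one per cell in the same order.
#'
#' @param cells path to the cells CSV.
#' @param events path to the events CSV, or `NULL`.
#' @param neighbours path to an explicit neighbour-order CSV, or `NULL`.
#' @param distances path to a distance-matrix CSV, or `NULL`.
#' @param verbose print a short summary of what was read.
#' @return list with `region` ([region_data()]) and `events`
#'   ([event_counts()] or `NULL`).
#' @export
read_inputs <- function(cells, events = NULL, neighbours = NULL,
                        distances = NULL, verbose = FALSE) {
  cel <- read_cells(cells)
  nb <- if (!is.null(neighbours)) {
    read_neighbour_order(neighbours, cel$cell_ids)
  } else if (!is.null(distances)) {
    order_neighbours(cel$cell_ids,
                     distances = read_distance_matrix(distances,
                                                      cel$cell_ids))
  } else {
    if (is.null(cel$coords))
      stop("cells file has no coordinates; supply neighbours or distances")
    order_neighbours(cel$cell_ids, coords = cel$coords,
                     coord_type = cel$coord_type)
  }
  region <- region_data(cel$cell_ids, cel$populations, nb,
                        strata = cel$strata)
  ev <- if (!is.null(events)) read_events(events, region) else NULL
  if (verbose) {
    message("Read ", region$n_cells, " cells, total population ", region$n,
            ", ", region$n_strata, " stratum/strata")
    if (!is.null(ev))
      message("Events: v = ", ev$events_total,
              if (!is.na(ev$cases_total))
                paste0(", c = ", ev$cases_total, ", Y = ", ev$Y))
  }
  list(region = region, events = ev)
}

read_cells <- function(path) {
  df <- read_csv_file(path, c("cell_id", "population"))
  has_stratum <- "stratum" %in% names(df)
  ids <- unique(as.character(df$cell_id))
  strata <- if (has_stratum) unique(as.character(df$stratum)) else "all"
  pop <- matrix(0, length(ids), length(strata),
                dimnames = list(ids, strata))
  key <- paste(df$cell_id, if (has_stratum) df$stratum else "all")
  if (anyDuplicated(key)) stop("duplicate (cell, stratum) rows in ", path)
  pop[cbind(match(as.character(df$cell_id), ids),
            if (has_stratum) match(as.character(df$stratum), strata) else 1L)] <-
    df$population

  coord_cols <- if (all(c("lon", "lat") %in% names(df))) c("lon", "lat")
    else if (all(c("x", "y") %in% names(df))) c("x", "y") else NULL
  coords <- NULL
  coord_type <- "xy"
  if (!is.null(coord_cols)) {
    first <- !duplicated(df$cell_id)
    coords <- as.matrix(df[first, coord_cols])
    rownames(coords) <- as.character(df$cell_id[first])
    coords <- coords[ids, , drop = FALSE]
    if (anyNA(coords)) stop("missing coordinates for some cells in ", path)
    coord_type <- if (identical(coord_cols, c("lon", "lat"))) "lonlat" else "xy"
  }
  list(cell_ids = ids, populations = pop, strata = strata,
       coords = coords, coord_type = coord_type)
}

read_events <- function(path, region) {
  df <- read_csv_file(path, "cell_id")
  is_hist <- all(c("y", "count") %in% names(df))
  is_aggr <- "events" %in% names(df)
  if (is_hist && is_aggr)
    stop("events file mixes histogram (y, count) and aggregate (events) ",
         "columns")
  if (!is_hist && !is_aggr)
    stop("events file needs either (y, count) or (events) columns")
  unknown <- setdiff(as.character(df$cell_id), region$cell_ids)
  if (length(unknown))
    stop("events file refers to unknown cell id(s): ",
         paste(unknown, collapse = ", "))
  has_stratum <- "stratum" %in% names(df)
  strata <- if (has_stratum) region$strata else "all"
  if (has_stratum) {
    bad <- setdiff(as.character(df$stratum), strata)
    if (length(bad)) stop("unknown stratum in events file: ",
                          paste(bad, collapse = ", "))
  }
  ci <- match(as.character(df$cell_id), region$cell_ids)
  si <- if (has_stratum) match(as.character(df$stratum), strata) else
    rep(1L, nrow(df))
  if (is_hist) {
    check_counts(df$count, "event histogram counts")
    check_counts(df$y, "event multiplicities y")
    if (any(df$y < 1)) stop("event multiplicities y must be at least 1")
    if (anyDuplicated(cbind(ci, si, df$y)))
      stop("duplicate (cell, stratum, y) rows in ", path)
    Y <- max(df$y)
    h <- array(0L, dim = c(region$n_cells, Y, length(strata)))
    h[cbind(ci, df$y, si)] <- df$count
    event_counts(region$cell_ids, histogram = h, strata = strata)
  } else {
    check_counts(df$events, "aggregate event counts")
    if (anyDuplicated(cbind(ci, si)))
      stop("duplicate (cell, stratum) rows in ", path)
    v <- matrix(0L, region$n_cells, length(strata))
    v[cbind(ci, si)] <- df$events
    event_counts(region$cell_ids, aggregate = v, strata = strata)
  }
}

read_neighbour_order <- function(path, cell_ids) {
  df <- read_csv_file(path, c("cell_id", "rank", "neighbour_id"))
  I <- length(cell_ids)
  nb <- matrix(NA_character_, I, I - 1L)
  ci <- match(as.character(df$cell_id), cell_ids)
  if (anyNA(ci)) stop("neighbours file refers to unknown cell ids")
  rk <- as.integer(df$rank)
  if (any(rk < 1L | rk > I - 1L)) stop("neighbour rank out of range")
  nb[cbind(ci, rk)] <- as.character(df$neighbour_id)
  if (anyNA(nb)) stop("neighbours file is incomplete")
  nb
}

read_distance_matrix <- function(path, cell_ids) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  d <- as.matrix(df[, -1L, drop = FALSE])
  if (!setequal(ids, cell_ids) || !setequal(colnames(d), cell_ids))
    stop("distance matrix cells do not match the cells file")
  rownames(d) <- ids
  d[cell_ids, cell_ids]
}

read_csv_file <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Write cluster test results to CSV
#'
#' One row per cell: `cell_id, method, k_star, ell, observed, expected,
#' oe_ratio, p_value, significant, w_stopped`. p-values are printed with
#' three decimals; the full-precision value is kept in `p_value_full`.
#'
#' @param x a [test_region()] result.
#' @param path output CSV path.
#' @export
write_results <- function(x, path) {
  stopifnot(inherits(x, "cluster_test"))
  df <- x$results
  df$p_value_full <- df$p_value
  df$p_value <- sprintf("%.3f", df$p_value)
  df$expected <- round(df$expected, 4)
  df$oe_ratio <- round(df$oe_ratio, 4)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a neighbour ordering to CSV
#'
#' Long format `cell_id, rank, neighbour_id`, readable back by
#' [read_inputs()].
#'
#' @param nb neighbour-order matrix from [order_neighbours()] (row names are
#'   cell ids).
#' @param path output CSV path.
#' @export
write_neighbour_order <- function(nb, path) {
  ids <- rownames(nb)
  df <- data.frame(
    cell_id = rep(ids, each = ncol(nb)),
    rank = rep(seq_len(ncol(nb)), times = nrow(nb)),
    neighbour_id = ids[t(nb)])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
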