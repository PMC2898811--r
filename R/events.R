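#' Per-cell event data: case-by-event-count histograms or aggregate totals
#'
#' Holds the event side of an analysis. Cases are individuals with at least
#' one disease-related event during the study period; a case may have many
#' events (e.g. repeated emergency-department presentations). Two levels of
#' detail are supported:
#'
#' * a **histogram** `c[i, y]` (optionally `c[i, y, s]` per stratum) counting
#'   the cases in cell `i` with exactly `y` events, `y = 1..Y` — required by
#'   the exact event (EE) and compound Poisson event (CPE) tests;
#' * **aggregate** per-cell event totals `v[i]` (`v[i, s]`) — sufficient for
#'   the aggregate event (AE) occupancy test.
#'
#' When a histogram is given, the aggregate totals, case counts and
#' region-wide class marginals are derived from it.
#'
#' @param cell_ids character vector of cell identifiers, matching the region.
#' @param histogram optional `I x Y` matrix or `I x Y x S` array of case
#'   counts by number of events (column `y` = cases with exactly `y` events).
#' @param aggregate optional vector (length `I`) or `I x S` matrix of per-cell
#'   event totals; ignored when `histogram` is given.
#' @param strata optional stratum names.
#'
#' @return An object of class `event_counts` with elements `events`
#'   (`I x S` matrix of `v[i, s]`), `events_cell` (per-cell totals `v[i]`),
#'   `cases` and `class_marginals` (`Y x S` matrix of region-wide counts
#'   `C.y[s]` of cases with exactly `y` events; `NULL` without a histogram),
#'   `histogram`, `Y`, `cases_total` (`c`), `events_total` (`v`),
#'   `events_by_stratum` (`V.s`), `strata`.
#' @export
#' @examples
#' # 3 cells, at most 2 events per case
#' h <- rbind(c(4, 1), c(2, 0), c(0, 3))
#' ev <- event_counts(c("a", "b", "c"), histogram = h)
#' ev$events_cell   # 6, 2, 6
event_counts <- function(cell_ids, histogram = NULL, aggregate = NULL,
                         strata = NULL) {
  cell_ids <- as.character(cell_ids)
  I <- length(cell_ids)
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (is.null(histogram) && is.null(aggregate))
    stop("either a case histogram or aggregate event totals are required")

  if (!is.null(histogram)) {
    if (length(dim(histogram)) == 2L)
      histogram <- array(as.matrix(histogram),
                         dim = c(dim(histogram), 1L))
    if (length(dim(histogram)) != 3L || dim(histogram)[1L] != I)
      stop("histogram must be I x Y (x S) with one row per cell")
    check_counts(histogram, "case histogram counts")
    Y <- dim(histogram)[2L]
    S <- dim(histogram)[3L]
    if (is.null(strata)) strata <- dimnames(histogram)[[3L]]
    if (is.null(strata)) strata <- if (S == 1L) "all" else paste0("s", 1:S)
    dimnames(histogram) <- list(cell_ids, seq_len(Y), strata)
    ymult <- seq_len(Y)
    events <- apply(histogram, 3L, function(h) as.matrix(h) %*% ymult)
    events <- matrix(events, nrow = I, dimnames = list(cell_ids, strata))
    cases <- apply(histogram, 3L, rowSums)
    cases <- matrix(cases, nrow = I, dimnames = list(cell_ids, strata))
    class_marginals <- apply(histogram, 3L, colSums)
    class_marginals <- matrix(class_marginals, nrow = Y,
                              dimnames = list(seq_len(Y), strata))
  } else {
    if (is.null(dim(aggregate))) aggregate <- matrix(aggregate, ncol = 1L)
    aggregate <- as.matrix(aggregate)
    if (nrow(aggregate) != I) stop("aggregate must have one row per cell")
    check_counts(aggregate, "aggregate event counts")
    if (is.null(strata)) strata <- colnames(aggregate)
    if (is.null(strata)) strata <- if (ncol(aggregate) == 1L) "all" else
      paste0("s", seq_len(ncol(aggregate)))
    dimnames(aggregate) <- list(cell_ids, strata)
    events <- aggregate
    Y <- NA_integer_
    cases <- NULL
    class_marginals <- NULL
  }

  structure(list(
    cell_ids = cell_ids,
    strata = strata,
    n_strata = length(strata),
    Y = Y,
    histogram = histogram,
    events = events,
    events_cell = rowSums(events),
    cases = cases,
    cases_cell = if (is.null(cases)) NULL else rowSums(cases),
    class_marginals = class_marginals,
    events_by_stratum = colSums(events),
    cases_total = if (is.null(cases)) NA_integer_ else sum(cases),
    events_total = sum(events)
  ), class = "event_counts")
}

#' @export
print.event_counts <- function(x, ...) {
  cat("Event counts:", length(x$cell_ids), "cells,",
      x$events_total, "events")
  if (!is.na(x$cases_total))
    cat(",", x$cases_total, "cases (max", x$Y, "events per case)")
  cat("\n")
  invisible(x)
}

# TRUE when the EE/CPE tests are applicable
has_histogram <- function(events) !is.null(events$histogram)
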