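#' @title Per-cell cluster testing
#' @description The testing machinery shared by the four methods: the test
#'   statistic (how many neighbours must be combined to reach the cluster
#'   size), exact significance levels, the sequential cluster-size
#'   prescription, and whole-region result tables.
#' @name cluster_testing
NULL

methods_available <- c("hc", "ee", "cpe", "ae")

# tail vector (tails[k+1] = P(X >= k)) of the null distribution of the count
# in a combined population, for one method. `m` is the combined population
# (scalar, or per-stratum vector when stratified).
null_count_tails <- function(method, m, region, events, stratified = FALSE) {
  n <- region$n
  if (stratified && method %in% c("hc", "cpe"))
    stop("stratified testing is available for the ee and ae methods only")
  if (method %in% c("ee", "cpe") && !has_histogram(events))
    stop("the ", method, " method needs a case histogram (events per case); ",
         "only aggregate event totals were supplied")
  if (method == "hc" && is.null(events$cases))
    stop("the hc method needs case counts")
  pmf <- switch(method,
    hc = {
      c_tot <- events$cases_total
      hypergeom_pmf(0:min(c_tot, m), m, c_tot, n)
    },
    ee = {
      if (stratified)
        stratified_event_pmf(m, events$class_marginals,
                             colSums(region$populations))
      else
        ee_event_pmf(m, rowSums(events$class_marginals), n)
    },
    cpe = {
      c_tot <- events$cases_total
      q <- rowSums(events$class_marginals) / c_tot
      cpe_event_pmf(m, c_tot, n, q)
    },
    ae = {
      if (stratified)
        stratified_ae_pmf(m, events$events_by_stratum,
                          colSums(region$populations))
      else
        ae_event_pmf(0:events$events_total, m, events$events_total, n)
    },
    stop("unknown method: ", method))
  pmf_tails_all(pmf)
}

# smallest k >= 1 with P(X >= k) <= alpha, and that tail probability
k_star_from_tails <- function(tails, alpha) {
  ok <- which(tails <= alpha)
  ok <- ok[ok >= 2L]                    # k >= 1
  if (length(ok) == 0L)
    return(list(k = length(tails), alpha_star = 0))  # beyond support
  k <- ok[1L] - 1L
  list(k = k, alpha_star = tails[k + 1L])
}

#' Test statistic: neighbours needed to reach the cluster size
#'
#' The smallest number of nearest neighbours `L` that must be combined with
#' cell `i` so that the combined count (events, or cases for the HC method)
#' reaches at least `k_star`. Small values indicate locally concentrated
#' counts.
#'
#' @param region a [region_data()] object.
#' @param events an [event_counts()] object.
#' @param i cell index or id.
#' @param k_star the (event) cluster size, at least 1.
#' @param method one of `"hc"`, `"ee"`, `"cpe"`, `"ae"`; only distinguishes
#'   cases (`"hc"`) from events.
#' @return The statistic `L` in `0..(I-1)`, or `NA` when even the whole
#'   region holds fewer than `k_star` counts.
#' @export
test_statistic <- function(region, events, i, k_star,
                           method = c("ee", "cpe", "ae", "hc")) {
  method <- match.arg(method)
  if (k_star < 1) stop("k_star must be at least 1")
  i <- cell_index(region, i)
  counts <- if (method == "hc") {
    if (is.null(events$cases_cell)) stop("case counts are not available")
    events$cases_cell
  } else events$events_cell
  path <- c(i, region$neighbour_order[i, ])
  cum <- cumsum(counts[path])
  ell <- unname(which(cum >= k_star)[1L])
  if (is.na(ell)) NA_integer_ else ell - 1L
}

#' Exact significance level of a tested cell
#'
#' Upper-tail probability of observing at least `k_star` counts in the
#' population of cell `i` combined with its `ell` nearest neighbours, under
#' the null distribution of the chosen method. `ell` is normally the
#' observed [test_statistic()].
#'
#' @inheritParams test_statistic
#' @param ell number of combined neighbours (the observed statistic).
#' @param stratified if `TRUE`, condition on per-stratum populations
#'   (available for `"ee"` and `"ae"`).
#' @return the exact p-value in `[0, 1]`.
#' @export
significance <- function(region, events, i, k_star, ell,
                         method = c("ee", "cpe", "ae", "hc"),
                         stratified = FALSE) {
  method <- match.arg(method)
  if (k_star < 1) stop("k_star must be at least 1")
  m <- combined_population(region, i, ell, by_stratum = stratified)
  tails <- null_count_tails(method, m, region, events, stratified)
  tail_at(tails, k_star)
}

# P(X >= k) from a full tail vector, with out-of-support conventions
tail_at <- function(tails, k) {
  if (k <= 0) return(1)
  if (k + 1L > length(tails)) return(0)
  tails[k + 1L]
}

#' Choose per-cell event cluster sizes (the sequential prescription)
#'
#' For each cell `i` and each combination depth `w`, the event cluster size
#' `k*[i, w]` is the smallest count `k` whose null upper-tail probability in
#' the population of cell `i` combined with its `w` nearest neighbours is at
#' most `alpha` — the count at the 100(1 - alpha) percentile of the null
#' distribution. Because the distributions are discrete the attained tail,
#' the effective significance level `alpha*`, is at most `alpha` and is
#' recorded alongside.
#'
#' @inheritParams significance
#' @param alpha nominal per-test significance level.
#' @param w_values combination depths to prepare, default `0:2`.
#' @return An object of class `cluster_size_plan`: list with `k_star` and
#'   `effective_alpha` (`I x length(w_values)` matrices), `alpha`,
#'   `w_values`, `method`, `stratified`.
#' @export
choose_cluster_sizes <- function(region, events, alpha = 0.05,
                                 w_values = 0:2,
                                 method = c("ee", "cpe", "ae", "hc"),
                                 stratified = FALSE) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  I <- region$n_cells
  # depths beyond the region cannot be combined; keep at least w = 0
  w_values <- w_values[w_values <= I - 1L]
  if (length(w_values) == 0L) w_values <- 0L
  W <- length(w_values)
  k_star <- matrix(NA_integer_, I, W,
                   dimnames = list(region$cell_ids, paste0("w", w_values)))
  eff <- matrix(NA_real_, I, W,
                dimnames = dimnames(k_star))
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(I)) {
    for (wi in seq_len(W)) {
      m <- combined_population(region, i, w_values[wi],
                               by_stratum = stratified)
      key <- paste(m, collapse = "/")
      hit <- cache[[key]]
      if (is.null(hit)) {
        tails <- null_count_tails(method, m, region, events, stratified)
        hit <- k_star_from_tails(tails, alpha)
        cache[[key]] <- hit
      }
      k_star[i, wi] <- hit$k
      eff[i, wi] <- hit$alpha_star
    }
  }
  structure(list(k_star = k_star, effective_alpha = eff, alpha = alpha,
                 w_values = w_values, method = method,
                 stratified = stratified),
            class = "cluster_size_plan")
}

#' Sequential test of one cell
#'
#' Tests cell `i` at its cluster size for `w = w_values[1]`; if significant
#' at level `alpha`, testing stops there, otherwise the cell is retested at
#' the next depth, and so on until significance or the depths are exhausted
#' (the last test is then reported). Cells whose counts never reach the
#' cluster size anywhere in the region are reported non-significant with
#' `p = 1`.
#'
#' @inheritParams significance
#' @param plan a [choose_cluster_sizes()] plan.
#' @return One-row data frame with columns `cell_id`, `method`, `k_star`,
#'   `ell`, `observed`, `expected`, `oe_ratio`, `p_value`, `significant`,
#'   `w_stopped`. `expected` is `n[i:ell] * v / n` (with `c` in place of `v`
#'   for the HC method).
#' @export
sequential_test <- function(region, events, i, plan) {
  method <- plan$method
  i <- cell_index(region, i)
  res <- NULL
  for (wi in seq_along(plan$w_values)) {
    k <- plan$k_star[i, wi]
    ell <- test_statistic(region, events, i, k, method)
    if (is.na(ell)) {
      res <- test_record(region, events, i, k, region$n_cells - 1L,
                         p = 1, method, plan$w_values[wi])
      next
    }
    p <- significance(region, events, i, k, ell, method,
                      stratified = plan$stratified)
    res <- test_record(region, events, i, k, ell, p, method,
                       plan$w_values[wi])
    if (p <= plan$alpha) break
  }
  res$significant <- res$p_value <= plan$alpha
  res
}

test_record <- function(region, events, i, k, ell, p, method, w) {
  obs <- combined_events(region, events, i, ell,
                         what = if (method == "hc") "cases" else "events")
  tot <- if (method == "hc") events$cases_total else events$events_total
  expd <- combined_population(region, i, ell) * tot / region$n
  data.frame(cell_id = region$cell_ids[i], method = method,
             k_star = k, ell = ell, observed = obs, expected = expd,
             oe_ratio = if (expd > 0) obs / expd else NA_real_,
             p_value = p, significant = NA,
             w_stopped = w, row.names = NULL)
}

#' Test every cell of a region
#'
#' Runs the sequential test on all cells and counts `R_alpha`, the number of
#' significant cells — the statistic used by the Monte Carlo assessment of
#' overall clustering.
#'
#' @inheritParams choose_cluster_sizes
#' @param plan optional precomputed [choose_cluster_sizes()] plan.
#' @return An object of class `cluster_test` with elements `results` (one
#'   row per cell, in input cell order), `R_alpha`, `alpha`, `method`,
#'   `plan`.
#' @export
test_region <- function(region, events, alpha = 0.05,
                        method = c("ee", "cpe", "ae", "hc"),
                        stratified = FALSE, w_values = 0:2, plan = NULL) {
  method <- match.arg(method)
  if (is.null(plan))
    plan <- choose_cluster_sizes(region, events, alpha, w_values, method,
                                 stratified)
  rows <- lapply(seq_len(region$n_cells), function(i)
    sequential_test(region, events, i, plan))
  results <- do.call(rbind, rows)
  results$significant <- results$p_value <= plan$alpha
  structure(list(results = results,
                 R_alpha = sum(results$significant),
                 alpha = plan$alpha, method = method, plan = plan),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, digits = 3, ...) {
  cat("Cluster test (", toupper(x$method), "), alpha = ", x$alpha,
      ": ", x$R_alpha, " of ", nrow(x$results),
      " cells significant\n", sep = "")
  df <- x$results
  df$expected <- round(df$expected, 1)
  df$oe_ratio <- round(df$oe_ratio, 1)
  df$p_value <- round(df$p_value, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
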