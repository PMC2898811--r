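#' Integer case classes consistent with a scenario's event total
#'
#' A simulation fixes the total number of events at `v = floor(rate * n)`.
#' The implied (real-valued) case total is `c = v / sum(y * Q(y))`; the
#' class counts are obtained by flooring `c * Q(y)` and then topping up the
#' single-event class until the events sum to `v` exactly. The top-up always
#' lands on the `y = 1` class, so the rule is insensitive to floating-point
#' jitter in the floors.
#'
#' @param scenario a [scenario_distribution()].
#' @param n total population.
#' @param event_rate events per unit population; defaults to the scenario's.
#' @return list with `class_counts` (integer vector over `y = 1..Y`),
#'   `events_total` (`v`), `cases_total` (integer `sum(class_counts)`) and
#'   `cases_exact` (the real-valued `v / mean_events` used by the compound
#'   Poisson rate).
#' @export
#' @examples
#' s1 <- event_scenario("S1")
#' integerize_case_classes(s1, 68000)  # v = 136, classes 55/27/9
integerize_case_classes <- function(scenario, n, event_rate = NULL) {
  stopifnot(inherits(scenario, "scenario_distribution"))
  if (is.null(event_rate)) event_rate <- scenario$event_rate
  v <- floor(event_rate * n)
  cases_exact <- v / scenario$mean_events
  ys <- seq_len(scenario$Y)
  cl <- floor(cases_exact * scenario$q)
  deficit <- v - sum(ys * cl)
  stopifnot(deficit >= 0)
  cl[1L] <- cl[1L] + deficit
  list(class_counts = as.integer(cl), events_total = as.integer(v),
       cases_total = as.integer(sum(cl)), cases_exact = cases_exact)
}

#' Simulate one null dataset by random case allocation
#'
#' Under the null of no clustering, every case falls in cell `i` with
#' probability `n_i / n`. Each event-count class is allocated independently
#' and multinomially across the cells, so every draw conserves the class
#' totals and hence the regional event total exactly.
#'
#' @param region a [region_data()] object.
#' @param class_counts integer vector of region-wide case counts by number
#'   of events (element `y` = cases with `y` events each).
#' @return an [event_counts()] object for the simulated dataset.
#' @export
simulate_null_dataset <- function(region, class_counts) {
  h <- allocate_classes(region$pop_cell, class_counts)
  event_counts(region$cell_ids, histogram = h)
}

# multinomial allocation; returns I x Y histogram matrix
allocate_classes <- function(pop, class_counts) {
  prob <- pop / sum(pop)
  Y <- length(class_counts)
  h <- matrix(0L, nrow = length(pop), ncol = Y)
  for (y in seq_len(Y)) {
    if (class_counts[y] > 0L)
      h[, y] <- stats::rmultinom(1L, class_counts[y], prob)[, 1L]
  }
  h
}

#' Monte Carlo p-value for overall clustering
#'
#' Each cell is tested separately, so the number of significant cells
#' `R_alpha` reflects many simultaneous tests. Overall clustering is judged
#' by simulation: null datasets are generated by randomly allocating the
#' observed case classes to cells in proportion to population, the full
#' region is retested on each, and the p-value is the proportion of
#' simulations with at least as many significant cells as observed. For
#' aggregate-only data (AE method) the individual events are allocated
#' instead.
#'
#' @inheritParams test_region
#' @param observed_R observed number of significant cells.
#' @param n_sims number of null simulations.
#' @return list with `p_value`, `R_sim` (the simulated counts) and
#'   `observed_R`.
#' @export
overall_clustering_p <- function(observed_R, region, events, alpha = 0.05,
                                 method = c("ee", "cpe", "ae", "hc"),
                                 n_sims = 1000, stratified = FALSE,
                                 w_values = 0:2) {
  method <- match.arg(method)
  plan <- choose_cluster_sizes(region, events, alpha, w_values, method,
                               stratified)
  R_sim <- integer(n_sims)
  for (b in seq_len(n_sims)) {
    sim <- if (has_histogram(events)) {
      simulate_null_dataset(region, rowSums(events$class_marginals))
    } else {
      # aggregate-only data: allocate the v events individually
      v_i <- allocate_classes(region$pop_cell,
                              events$events_total)[, 1L]
      event_counts(region$cell_ids, aggregate = v_i)
    }
    R_sim[b] <- test_region(region, sim, alpha, method,
                            stratified = stratified, plan = plan)$R_alpha
  }
  list(p_value = mean(R_sim >= observed_R), R_sim = R_sim,
       observed_R = observed_R)
}

#' Type I error simulation harness
#'
#' Reproduces the null simulation study: a region of exchangeable cells (or
#' any supplied populations), case classes fixed by a scenario and an event
#' rate of `floor(rate * n)` events, and 1000 null datasets in which every
#' cell is tested once at its cell-alone cluster size `k*[i]` (depth
#' `w = 0`). A cell rejects when its own events reach `k*[i]`, which by
#' construction of the cluster size happens with null probability
#' `alpha*[i]`, the effective significance level.
#'
#' @param scenario a [scenario_distribution()].
#' @param cell_population scalar (constant cells) or vector of populations.
#' @param n_cells number of cells when `cell_population` is scalar.
#' @param reps number of simulated datasets.
#' @param alpha nominal significance level.
#' @param methods subset of `"ee"`, `"cpe"`, `"ae"`.
#' @param event_rate events per unit population; defaults to the scenario's.
#' @param seed optional RNG seed.
#' @return An object of class `type1_summary`: per-method rows with the
#'   effective level `alpha_star` (mean and SD across cells, percent) and
#'   the empirical rejection percentage (mean and SD across cells over the
#'   replications); per-cell rates in `attr(x, "cell_rates")`.
#' @export
#' @examples
#' \donttest{
#' type1_harness(event_scenario("S1"), 1000, reps = 200, seed = 1)
#' }
type1_harness <- function(scenario, cell_population, n_cells = 68,
                          reps = 1000, alpha = 0.05,
                          methods = c("ee", "cpe"), event_rate = NULL,
                          seed = NULL) {
  stopifnot(inherits(scenario, "scenario_distribution"), reps >= 1)
  methods <- match.arg(methods, c("ee", "cpe", "ae"), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  pop <- if (length(cell_population) == 1L)
    rep(cell_population, n_cells) else cell_population
  I <- length(pop)
  n <- sum(pop)
  iz <- integerize_case_classes(scenario, n, event_rate)

  # cell-alone cluster sizes per method, cached over distinct populations
  k_star <- eff <- matrix(NA_real_, I, length(methods),
                          dimnames = list(NULL, methods))
  for (mth in methods) {
    cache <- new.env(parent = emptyenv())
    for (i in seq_len(I)) {
      key <- as.character(pop[i])
      hit <- cache[[key]]
      if (is.null(hit)) {
        tails <- switch(mth,
          ee = pmf_tails_all(ee_event_pmf(pop[i], iz$class_counts, n)),
          cpe = pmf_tails_all(cpe_event_pmf(pop[i], iz$cases_exact, n,
                                            scenario$q)),
          ae = pmf_tails_all(ae_event_pmf(0:iz$events_total, pop[i],
                                          iz$events_total, n)))
        hit <- k_star_from_tails(tails, alpha)
        cache[[key]] <- hit
      }
      k_star[i, mth] <- hit$k
      eff[i, mth] <- hit$alpha_star
    }
  }

  rejections <- matrix(0L, I, length(methods), dimnames = list(NULL, methods))
  ys <- seq_len(scenario$Y)
  for (b in seq_len(reps)) {
    h <- allocate_classes(pop, iz$class_counts)
    v_i <- as.vector(h %*% ys)
    for (mth in methods)
      rejections[, mth] <- rejections[, mth] + (v_i >= k_star[, mth])
  }
  rates <- 100 * rejections / reps

  summary <- data.frame(
    method = methods,
    alpha_star = 100 * colMeans(eff),
    alpha_star_sd = 100 * apply(eff, 2L, stats::sd),
    sim_mean = colMeans(rates),
    sim_sd = apply(rates, 2L, stats::sd),
    row.names = NULL)
  structure(summary, class = c("type1_summary", "data.frame"),
            cell_rates = rates, k_star = k_star, reps = reps,
            scenario = scenario$name, events_total = iz$events_total)
}

#' @export
print.type1_summary <- function(x, ...) {
  cat("Type I error simulation (", attr(x, "reps"), " replications",
      if (!is.null(attr(x, "scenario")))
        paste0(", scenario ", attr(x, "scenario")),
      ", ", attr(x, "events_total"), " events)\n", sep = "")
  df <- as.data.frame(x)
  df[-1L] <- lapply(df[-1L], round, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
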