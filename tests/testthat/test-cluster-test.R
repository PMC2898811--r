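# 4-cell line region used throughout: neighbour order of cell 1 is 2, 3, 4
toy_region <- function() line_region(c(10, 20, 30, 40))

toy_events <- function() {
  # per-cell events 3, 2, 4, 5 with a Y = 2 histogram
  h <- rbind(c(1, 1), c(2, 0), c(2, 1), c(3, 1))
  event_counts(sprintf("c%02d", 1:4), histogram = h)
}

test_that("test statistic is the smallest neighbour count reaching k*", {
  reg <- toy_region()
  ev <- toy_events()
  # own events 3 >= 1
  expect_equal(test_statistic(reg, ev, 1, 1, "ee"), 0L)
  # cumulative events from cell 1: 3, 5, 9, 14; k* = 6 -> two neighbours
  expect_equal(test_statistic(reg, ev, 1, 6, "ee"), 2L)
  # threshold beyond the regional total is never reached
  expect_true(is.na(test_statistic(reg, ev, 1, 15, "ee")))
  # case counting for the HC method: cases 2, 2, 3, 4
  expect_equal(test_statistic(reg, ev, 1, 3, "hc"), 1L)
  expect_error(test_statistic(reg, ev, 1, 0, "ee"), "at least 1")
})

test_that("significance matches the enumeration tail oracle", {
  reg <- line_region(c(2, 2, 2))
  # cells hold cases with 1, 1 and 2 events: C.1 = 2, C.2 = 1, n = 6
  h <- rbind(c(1, 0), c(1, 0), c(0, 1))
  ev <- event_counts(reg$cell_ids, histogram = h)
  vals <- class_population(c(2, 1), 6)
  # cell 1 with 1 neighbour: m = 4
  want <- tails_of(enum_sample_pmf(4, vals))
  expect_equal(significance(reg, ev, 1, k_star = 3, ell = 1, "ee"),
               want[4], tolerance = 1e-12)
  # AE on the same data uses a different null but its own oracle
  want_ae <- tails_of(enum_occupancy_pmf(4, 4, 6))
  expect_equal(significance(reg, ev, 1, k_star = 3, ell = 1, "ae"),
               want_ae[4], tolerance = 1e-12)
  # combining the whole region with k* <= v is certain
  expect_equal(significance(reg, ev, 1, k_star = 4, ell = 2, "ee"), 1)
})

test_that("AE and EE give different p-values even when Y = 1", {
  reg <- line_region(c(3, 3, 3))
  h <- matrix(c(2, 1, 0), ncol = 1)    # three single-event cases
  ev <- event_counts(reg$cell_ids, histogram = h)
  p_ee <- significance(reg, ev, 1, k_star = 2, ell = 0, "ee")
  p_ae <- significance(reg, ev, 1, k_star = 2, ell = 0, "ae")
  vals <- class_population(c(3), 9)
  expect_equal(p_ee, tails_of(enum_sample_pmf(3, vals))[3],
               tolerance = 1e-12)
  expect_equal(p_ae, tails_of(enum_occupancy_pmf(3, 3, 9))[3],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(p_ee, p_ae)))
})

test_that("cluster sizes match a brute-force scan over k", {
  reg <- toy_region()
  ev <- toy_events()
  alpha <- 0.1
  plan <- choose_cluster_sizes(reg, ev, alpha, w_values = 0:2, "ee")
  cc <- rowSums(ev$class_marginals)
  for (i in 1:4) {
    for (wi in 1:3) {
      m <- combined_population(reg, i, wi - 1)
      tails <- tails_of(ee_event_pmf(m, cc, reg$n))
      ks <- which(tails <= alpha) - 1
      ks <- ks[ks >= 1]
      if (length(ks) == 0) {
        # no attainable count is rare enough: k* sits just past the support
        expect_equal(plan$k_star[i, wi], length(tails))
        expect_equal(plan$effective_alpha[i, wi], 0)
        next
      }
      expect_equal(plan$k_star[i, wi], min(ks))
      expect_equal(plan$effective_alpha[i, wi], tails[min(ks) + 1],
                   tolerance = 1e-12)
      expect_lte(plan$effective_alpha[i, wi], alpha)
      # defining property of k*: the previous k exceeds alpha
      if (min(ks) > 1) expect_gt(tails[min(ks)], alpha)
    }
  }
})

test_that("constant populations give identical cluster sizes in every cell", {
  reg <- line_region(rep(50, 5))
  h <- matrix(c(3, 2, 1, 0, 2), ncol = 1)
  ev <- event_counts(reg$cell_ids, histogram = h)
  plan <- choose_cluster_sizes(reg, ev, 0.05, 0, "ee")
  expect_equal(length(unique(plan$k_star[, 1])), 1L)
})

test_that("p-value at ell = 0 with the planned k* equals the effective level", {
  reg <- toy_region()
  ev <- toy_events()
  plan <- choose_cluster_sizes(reg, ev, 0.2, 0, "ee")
  for (i in 1:4) {
    p <- significance(reg, ev, i, plan$k_star[i, 1], ell = 0, "ee")
    expect_equal(p, plan$effective_alpha[i, 1], tolerance = 1e-12)
  }
})

test_that("sequential testing stops at the first significant depth", {
  reg <- toy_region()
  ev <- toy_events()
  plan <- choose_cluster_sizes(reg, ev, alpha = 0.35, w_values = 0:2, "ee")
  res <- sequential_test(reg, ev, 3, plan)
  # hand-trace: the stopping depth w equals the reported statistic when
  # significant, and the reported row reflects exactly one test
  if (res$significant) {
    expect_equal(res$ell, res$w_stopped)
    expect_lte(res$p_value, 0.35)
  }
  # a cell that is never significant reports the last (deepest) test
  plan_strict <- choose_cluster_sizes(reg, ev, 1e-6, 0:2, "ee")
  res2 <- sequential_test(reg, ev, 2, plan_strict)
  expect_false(res2$significant)
  expect_equal(res2$w_stopped, 2)
  expect_gt(res2$ell, 2)   # had to combine more than w neighbours
})

test_that("unreachable thresholds report p = 1 at the whole region", {
  reg <- toy_region()
  ev <- event_counts(reg$cell_ids, aggregate = c(1, 0, 0, 0))
  plan <- choose_cluster_sizes(reg, ev, 0.05, 0, "ae")
  res <- sequential_test(reg, ev, 2, plan)
  expect_equal(res$p_value, 1)
  expect_equal(res$ell, reg$n_cells - 1L)
  expect_false(res$significant)
})

test_that("whole-region tables count significant cells and report E = n*v/n", {
  reg <- toy_region()
  ev <- toy_events()
  out <- test_region(reg, ev, alpha = 0.2, method = "ee")
  expect_equal(nrow(out$results), 4)
  expect_equal(out$R_alpha, sum(out$results$significant))
  for (r in seq_len(4)) {
    row <- out$results[r, ]
    m <- combined_population(reg, row$cell_id, row$ell)
    expect_equal(row$expected, m * ev$events_total / reg$n)
  }
  # all-zero events: nothing can be significant
  ev0 <- event_counts(reg$cell_ids, aggregate = rep(0, 4))
  out0 <- test_region(reg, ev0, alpha = 0.05, method = "ae")
  expect_equal(out0$R_alpha, 0L)
})

test_that("an engineered hot cell is the single flagged cluster", {
  reg <- line_region(rep(100, 6), pos = c(0, 10, 20, 30, 40, 50))
  h <- matrix(c(2, 1, 30, 1, 2, 1), ncol = 1)  # cell 3 far above its share
  ev <- event_counts(reg$cell_ids, histogram = h)
  out <- test_region(reg, ev, alpha = 0.05, method = "ee", w_values = 0)
  expect_equal(out$R_alpha, 1L)
  expect_true(out$results$significant[out$results$cell_id == "c03"])
  # at deeper depths the hot cell's neighbours join the cluster
  out2 <- test_region(reg, ev, alpha = 0.05, method = "ee", w_values = 0:2)
  expect_gt(out2$R_alpha, 1L)
  expect_true(out2$results$significant[out2$results$cell_id == "c03"])
})

test_that("stratified test with one stratum reproduces the unstratified test", {
  reg <- toy_region()
  ev <- toy_events()
  plain <- test_region(reg, ev, 0.2, "ee", stratified = FALSE)
  strat <- test_region(reg, ev, 0.2, "ee", stratified = TRUE)
  expect_identical(plain$results, strat$results)
  plain_ae <- test_region(reg, ev, 0.2, "ae", stratified = FALSE)
  strat_ae <- test_region(reg, ev, 0.2, "ae", stratified = TRUE)
  expect_identical(plain_ae$results, strat_ae$results)
})

test_that("a genuinely stratified EE test uses per-stratum populations", {
  pops <- cbind(a = c(4, 4, 4), b = c(2, 2, 2))
  nb <- order_neighbours(c("x", "y", "z"),
                         coords = cbind(0:2, 0), coord_type = "xy")
  reg <- region_data(c("x", "y", "z"), pops, nb)
  h <- array(0L, dim = c(3, 2, 2))
  h[1, , 1] <- c(1, 1)   # stratum a: one 1-event and one 2-event case in x
  h[2, , 2] <- c(1, 0)   # stratum b: one 1-event case in y
  ev <- event_counts(c("x", "y", "z"), histogram = h,
                     strata = c("a", "b"))
  p <- significance(reg, ev, 1, k_star = 2, ell = 0, "ee",
                    stratified = TRUE)
  want <- tails_of(enum_stratified_pmf(c(4, 2),
                                       matrix(c(1, 1, 1, 0), ncol = 2),
                                       c(12, 6)))
  expect_equal(p, want[3], tolerance = 1e-12)
})

test_that("HC equals EE when every case has exactly one event", {
  reg <- line_region(c(8, 8, 8, 8))
  h <- matrix(c(3, 1, 0, 2), ncol = 1)    # Y = 1
  ev <- event_counts(reg$cell_ids, histogram = h)
  out_hc <- test_region(reg, ev, 0.2, "hc")
  out_ee <- test_region(reg, ev, 0.2, "ee")
  expect_equal(out_hc$plan$k_star, out_ee$plan$k_star,
               ignore_attr = TRUE)
  expect_equal(out_hc$results$p_value, out_ee$results$p_value,
               tolerance = 1e-12)
})

test_that("methods demand the data they need", {
  reg <- toy_region()
  ev_aggr <- event_counts(reg$cell_ids, aggregate = c(3, 2, 4, 5))
  expect_error(test_region(reg, ev_aggr, 0.05, "ee"), "case histogram")
  expect_error(test_region(reg, ev_aggr, 0.05, "cpe"), "case histogram")
  expect_error(test_region(reg, toy_events(), 0.05, "hc",
                           stratified = TRUE), "ee and ae")
  expect_error(choose_cluster_sizes(reg, toy_events(), alpha = 1.2),
               "alpha")
})
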