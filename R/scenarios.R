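#' Events-per-case distributions for simulation scenarios
#'
#' A scenario pairs an events-per-case distribution `Q(y)` with a crude event
#' rate (events per unit population), and defines the conditions of a null
#' simulation: the event total is `floor(rate * n)` and the case classes are
#' derived from `Q` (see [integerize_case_classes()]).
#'
#' @param probabilities numeric vector; `probabilities[y]` is `Q(y)`, the
#'   probability that a case has exactly `y` events, `y = 1..Y` (zeros pad
#'   skipped values of `y`).
#' @param event_rate events per unit population; default 2 per 1000.
#' @param name optional label.
#' @param sum_tol probabilities must sum to 1 within this tolerance; sums off
#'   by more than `1e-8` but within tolerance are renormalized with a
#'   warning.
#' @return An object of class `scenario_distribution` with elements `q`,
#'   `Y`, `event_rate`, `mean_events` (`sum(y * Q(y))`) and `name`.
#' @seealso [event_scenario()] for the five built-in scenarios.
#' @export
scenario_distribution <- function(probabilities, event_rate = 2 / 1000,
                                  name = NULL, sum_tol = 2e-3) {
  q <- as.numeric(probabilities)
  if (any(q < 0)) stop("probabilities must be non-negative")
  if (sum(q) <= 0) stop("probabilities must not all be zero")
  dev <- abs(sum(q) - 1)
  if (dev > sum_tol)
    stop("probabilities sum to ", sum(q), ", outside tolerance ", sum_tol)
  if (dev > 1e-8) {
    warning("probabilities sum to ", sum(q), "; renormalizing")
    q <- q / sum(q)
  }
  if (event_rate < 0) stop("event_rate must be non-negative")
  ys <- seq_along(q)
  structure(list(
    q = q,
    Y = length(q),
    event_rate = event_rate,
    mean_events = sum(ys * q),
    name = name
  ), class = "scenario_distribution")
}

#' @export
print.scenario_distribution <- function(x, ...) {
  cat("Scenario", if (!is.null(x$name)) x$name else "", ": Q(y) on 1..",
      x$Y, ", mean ", signif(x$mean_events, 4), " events per case, rate ",
      x$event_rate, " events per head\n", sep = "")
  invisible(x)
}

#' Built-in simulation scenarios S1-S5
#'
#' Five events-per-case settings used by the Type I error simulation study,
#' with varying means and skewness; S5 mimics an observed self-inflicted
#' injury distribution with a long tail (up to 18 events per case) and its
#' printed probabilities sum to 0.999, so it is renormalized with a warning.
#' All use an event rate of 2 per 1000 population.
#'
#' @param name one of `"S1"` to `"S5"`.
#' @return a [scenario_distribution()] object.
#' @export
#' @examples
#' event_scenario("S1")$q   # 0.6, 0.3, 0.1
event_scenario <- function(name = c("S1", "S2", "S3", "S4", "S5")) {
  name <- match.arg(name)
  q <- switch(name,
    S1 = c(0.6, 0.3, 0.1),
    S2 = c(0.94, 0.05, 0.01),
    S3 = c(0.8, 0.1, 0.05, 0.03, 0.01, 0.01),
    S4 = c(0.8, 0.15, 0.05),
    S5 = {
      q5 <- numeric(18)
      q5[c(1, 2, 3, 4, 5, 9, 18)] <-
        c(0.929, 0.058, 0.008, 0.001, 0.001, 0.001, 0.001)
      q5
    })
  scenario_distribution(q, event_rate = 2 / 1000, name = name)
}
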