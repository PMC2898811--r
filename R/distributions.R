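#' Exact null distributions for counts in a population sample
#'
#' These kernels give the null distribution of the number of cases or events
#' observed among `m` individuals sampled without replacement from a
#' population of `n`, under the hypothesis that every individual is equally
#' likely to be a case (to have events) regardless of geography:
#'
#' * [hypergeom_pmf()] — cases, classical hypergeometric (the HC test);
#' * [ee_event_pmf()] — events, multiple hypergeometric over the case classes
#'   "exactly `y` events" (the EE test);
#' * [cpe_event_pmf()] — events, compound Poisson model (the CPE test);
#' * [ae_event_pmf()] — events, occupancy-number counting when only aggregate
#'   event totals are known (the AE test);
#' * [stratified_event_pmf()] / [stratified_ae_pmf()] — per-stratum sampling,
#'   combined by convolution.
#'
#' @name event_distributions
NULL

#' Hypergeometric case-count distribution
#'
#' Probability of exactly `x` cases among `m` individuals sampled without
#' replacement from a population of `n` containing `c` cases; the null of the
#' hypergeometric case (HC) test.
#'
#' @param x number of cases in the sample (vectorised).
#' @param m sample population.
#' @param c total cases in the region.
#' @param n total population.
#' @return `P(X = x)`; [hypergeom_tail()] gives `P(X >= k)`.
#' @export
hypergeom_pmf <- function(x, m, c, n) {
  check_hyper_args(m, c, n)
  stats::dhyper(x, c, n - c, m)
}

#' @rdname hypergeom_pmf
#' @param k case threshold.
#' @export
hypergeom_tail <- function(k, m, c, n) {
  check_hyper_args(m, c, n)
  stats::phyper(k - 1, c, n - c, m, lower.tail = FALSE)
}

check_hyper_args <- function(m, c, n) {
  if (any(c(m, c, n) < 0) || any(abs(c(m, c, n) - round(c(m, c, n))) > 1e-8))
    stop("m, c and n must be non-negative integers")
  if (m > n) stop("sample population m exceeds total population n")
  if (c > n) stop("total cases c exceeds total population n")
  invisible(TRUE)
}

#' Multiple hypergeometric event-count distribution (EE test)
#'
#' Exact pmf of the total number of events among `m` individuals sampled
#' without replacement from a population of `n` in which `class_counts[y]`
#' individuals are cases with exactly `y` events each (the remaining
#' `n - sum(class_counts)` have none). This is the null of the exact event
#' (EE) test.
#'
#' The mass function is a sum of products of binomial coefficients over all
#' feasible class draws. It is computed by a convolution over classes: the
#' joint distribution of (events so far, individuals drawn so far) is updated
#' one class at a time with the conditional hypergeometric law of that
#' class's draw, so every intermediate quantity is a probability and no
#' large binomial coefficients are ever formed. Classes are processed in
#' increasing order of size, which keeps the intermediate state small when
#' one class (typically single-event cases) dominates.
#'
#' @param m sample population.
#' @param class_counts integer vector; element `y` is the region-wide number
#'   of cases with exactly `y` events (`C.y`).
#' @param n total population.
#' @return Numeric vector `p` with `p[x + 1] = P(X = x)` for
#'   `x = 0, ..., xmax`, where `xmax` is the largest attainable event count.
#'   Sums to 1.
#' @export
#' @examples
#' # one case with 2 events in a population of 4; sample 2 individuals
#' ee_event_pmf(2, c(0, 1), 4)        # 0.5, 0, 0.5
ee_event_pmf <- function(m, class_counts, n) {
  class_counts <- check_class_counts(class_counts)
  if (any(c(m, n) < 0) || m != round(m) || n != round(n))
    stop("m and n must be non-negative integers")
  if (m > n) stop("sample population m exceeds total population n")
  if (sum(class_counts) > n) stop("more cases than population")
  ys <- which(class_counts > 0)
  if (length(ys) == 0L || m == 0L) return(1)
  ord <- ys[order(class_counts[ys])]     # largest class last
  G <- matrix(1, 1L, 1L)                 # G[x + 1, r + 1]
  n_rem <- n
  for (y in ord) {
    cy <- class_counts[y]
    xo <- nrow(G) - 1L
    ro <- ncol(G) - 1L
    jg <- min(cy, m)
    Gn <- matrix(0, xo + y * jg + 1L, ro + jg + 1L)
    for (r in 0:ro) {
      col <- G[, r + 1L]
      if (!any(col > 0) || m - r > n_rem) next
      jmax <- min(cy, m - r)
      w <- stats::dhyper(0:jmax, cy, n_rem - cy, m - r)
      for (j in 0:jmax) {
        if (w[j + 1L] == 0) next
        idx <- (y * j) + seq_len(xo + 1L)
        Gn[idx, r + j + 1L] <- Gn[idx, r + j + 1L] + col * w[j + 1L]
      }
    }
    G <- Gn
    n_rem <- n_rem - cy
  }
  rowSums(G)
}

#' @rdname ee_event_pmf
#' @param k event threshold; the tail is `P(X >= k)`, the EE significance
#'   level when `k` is the event cluster size and `m` the combined
#'   population.
#' @export
ee_event_tail <- function(k, m, class_counts, n) {
  pmf_tail(k, ee_event_pmf(m, class_counts, n))
}

check_class_counts <- function(class_counts) {
  check_counts(class_counts, "class counts")
  as.integer(round(class_counts))
}

# P(X >= k) from a pmf vector indexed 0..xmax; summed from the top for
# accuracy in small tails
pmf_tail <- function(k, pmf) {
  vapply(k, function(kk) {
    if (kk <= 0) return(1)
    if (kk > length(pmf) - 1L) return(0)
    sum(pmf[length(pmf):(kk + 1L)])
  }, numeric(1))
}

# full tail vector: tails[k + 1] = P(X >= k), k = 0..xmax
pmf_tails_all <- function(pmf) rev(cumsum(rev(pmf)))

#' Compound Poisson event-count distribution (CPE test)
#'
#' Models the number of cases in a sample of `m` as Poisson with rate
#' `m * cases / n` and the events of each case as an independent draw from
#' the events-per-case distribution `q`; the null of the compound Poisson
#' event (CPE) test. The pmf is evaluated by the Panjer recursion for
#' compound Poisson sums, which is exact up to the truncation of the
#' support: the vector is extended until the remaining upper tail falls
#' below `tol`.
#'
#' The mean equals `m * cases * sum(y * q) / n`; with `q` taken as the
#' observed class frequencies this is `m * v / n`, the same expected event
#' count as the EE null.
#'
#' @param m sample population.
#' @param cases total cases in the region; may be non-integer when derived
#'   from a rate.
#' @param n total population.
#' @param q numeric vector, `q[y] =` probability that a case has exactly `y`
#'   events (`y = 1..Y`); must sum to 1.
#' @param xmax optional minimal length of the returned support.
#' @param tol truncation tolerance for the upper tail.
#' @return Numeric vector `p` with `p[x + 1] = P(X = x)`.
#' @export
cpe_event_pmf <- function(m, cases, n, q, xmax = NULL, tol = 1e-13) {
  if (cases < 0 || n <= 0 || m < 0 || m > n) stop("invalid m, cases or n")
  if (any(q < 0)) stop("q must be non-negative")
  if (abs(sum(q) - 1) > 1e-8) stop("q must sum to 1")
  lambda <- m * cases / n
  Y <- length(q)
  yq <- seq_len(Y) * q
  # generous initial support: mean + 10 sd, extended if the tail demands
  mu <- lambda * sum(yq)
  sd <- sqrt(lambda * sum(seq_len(Y)^2 * q))
  len <- max(ceiling(mu + 10 * sd) + 1, Y + 1, 16, if (is.null(xmax)) 0 else xmax + 1)
  repeat {
    p <- numeric(len)
    p[1L] <- exp(-lambda)
    for (x in seq_len(len - 1L)) {
      yy <- seq_len(min(Y, x))
      p[x + 1L] <- (lambda / x) * sum(yq[yy] * p[x - yy + 1L])
    }
    if (1 - sum(p) < tol || len > 1e6) break
    len <- len * 2L
  }
  p
}

#' @rdname cpe_event_pmf
#' @param k event threshold; the tail is `P(X >= k)`.
#' @export
cpe_event_tail <- function(k, m, cases, n, q, tol = 1e-13) {
  pmf <- cpe_event_pmf(m, cases, n, q, xmax = max(k), tol = tol)
  vapply(k, function(kk) {
    if (kk <= 0) return(1)
    max(0, 1 - sum(pmf[seq_len(min(kk, length(pmf)))]))
  }, numeric(1))
}

#' Occupancy-number event-count distribution (AE test)
#'
#' When only the aggregate number of events `V` is known (not the events per
#' case), events are treated as indistinguishable and every way of
#' distributing the `V` events among the `n` individuals is taken as equally
#' likely. The probability that `x` of them fall on a sample of `m`
#' individuals is then a ratio of occupancy numbers,
#' `choose(m+x-1, x) * choose(n-m+V-x-1, V-x) / choose(n+V-1, V)`,
#' evaluated in log space. This is the null of the aggregate event (AE)
#' test.
#'
#' @param x number of events in the sample (vectorised, `0..V`).
#' @param m sample population.
#' @param V total events in the region.
#' @param n total population.
#' @return `P(X = x)`; [ae_event_tail()] gives `P(X >= k)`.
#' @export
ae_event_pmf <- function(x, m, V, n) {
  if (any(c(m, V, n) < 0)) stop("m, V and n must be non-negative")
  if (m > n) stop("sample population m exceeds total population n")
  out <- numeric(length(x))
  ok <- x >= 0 & x <= V & (x == V | n > m) & (x == 0 | m > 0)
  xs <- x[ok]
  out[ok] <- exp(lchoose(m + xs - 1, xs) +
                 lchoose(n - m + V - xs - 1, V - xs) -
                 lchoose(n + V - 1, V))
  out
}

#' @rdname ae_event_pmf
#' @param k event threshold.
#' @export
ae_event_tail <- function(k, m, V, n) {
  vapply(k, function(kk) {
    if (kk <= 0) return(1)
    if (kk > V) return(0)
    sum(ae_event_pmf(V:kk, m, V, n))
  }, numeric(1))
}

# direct (non-FFT) convolution of two pmf vectors indexed from 0
conv_pmf <- function(a, b) {
  if (length(a) == 1L) return(a * b)
  if (length(b) == 1L) return(b * a)
  out <- numeric(length(a) + length(b) - 1L)
  for (j in seq_along(b)) {
    if (b[j] == 0) next
    idx <- seq_along(a) + j - 1L
    out[idx] <- out[idx] + a * b[j]
  }
  out
}

#' Stratified event-count distributions
#'
#' Per-stratum sampling: stratum `s` contributes `m_s[s]` individuals drawn
#' without replacement from its own population `n_s[s]`, and the total event
#' count is the sum across strata. Since strata are sampled independently
#' under the null, the distribution of the total is the convolution of the
#' per-stratum laws: multiple hypergeometric for the stratified EE test,
#' occupancy for the stratified AE test. With a single stratum both reduce
#' exactly to their unstratified forms.
#'
#' @param m_s per-stratum sample populations.
#' @param class_counts_s `Y x S` matrix; column `s` holds the region-wide
#'   counts of stratum-`s` cases with exactly `y` events (`C.ys`).
#' @param n_s per-stratum total populations.
#' @return pmf vector over total events, `p[x + 1] = P(X = x)`.
#' @export
stratified_event_pmf <- function(m_s, class_counts_s, n_s) {
  class_counts_s <- as.matrix(class_counts_s)
  S <- ncol(class_counts_s)
  if (length(m_s) != S || length(n_s) != S)
    stop("m_s, n_s and class_counts_s must agree on the number of strata")
  pmf <- 1
  for (s in seq_len(S))
    pmf <- conv_pmf(pmf, ee_event_pmf(m_s[s], class_counts_s[, s], n_s[s]))
  pmf
}

#' @rdname stratified_event_pmf
#' @param k event threshold.
#' @export
stratified_event_tail <- function(k, m_s, class_counts_s, n_s) {
  pmf_tail(k, stratified_event_pmf(m_s, class_counts_s, n_s))
}

#' @rdname stratified_event_pmf
#' @param V_s per-stratum total events (`V.s`).
#' @export
stratified_ae_pmf <- function(m_s, V_s, n_s) {
  S <- length(V_s)
  if (length(m_s) != S || length(n_s) != S)
    stop("m_s, n_s and V_s must agree on the number of strata")
  pmf <- 1
  for (s in seq_len(S))
    pmf <- conv_pmf(pmf, ae_event_pmf(0:V_s[s], m_s[s], V_s[s], n_s[s]))
  pmf
}

#' @rdname stratified_event_pmf
#' @export
stratified_ae_tail <- function(k, m_s, V_s, n_s) {
  pmf_tail(k, stratified_ae_pmf(m_s, V_s, n_s))
}
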