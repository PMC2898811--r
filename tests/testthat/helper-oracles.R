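# Brute-force oracles for the exact distributions, independent of the
# package's convolution code. All work by exhaustive enumeration and are
# only feasible for tiny populations.

# Distribution of the total event count among m individuals sampled without
# replacement from a labelled population. `values[j]` is the number of
# events of individual j (0 for non-cases); all C(n, m) subsets are
# enumerated and weighted equally.
enum_sample_pmf <- function(m, values) {
  n <- length(values)
  stopifnot(m <= n)
  vmax <- sum(values)
  counts <- numeric(vmax + 1)
  if (m == 0) {
    counts[1] <- 1
  } else {
    subsets <- utils::combn(n, m)
    for (j in seq_len(ncol(subsets))) {
      x <- sum(values[subsets[, j]])
      counts[x + 1] <- counts[x + 1] + 1
    }
  }
  counts / sum(counts)
}

# population vector of per-individual event counts for given class counts
# (class_counts[y] individuals with y events each, rest zero)
class_population <- function(class_counts, n) {
  vals <- rep(seq_along(class_counts), class_counts)
  stopifnot(length(vals) <= n)
  c(vals, rep(0, n - length(vals)))
}

# All ways to distribute V indistinguishable events among n individuals
# (occupancy configurations), each equally likely; P(first m individuals
# hold x events in total).
enum_occupancy_pmf <- function(m, V, n) {
  comps <- compositions(V, n)          # one row per configuration
  x <- if (m == 0) rep(0, nrow(comps)) else
    rowSums(comps[, seq_len(m), drop = FALSE])
  tabulate(x + 1, nbins = V + 1) / nrow(comps)
}

# all non-negative integer n-vectors summing to total
compositions <- function(total, n) {
  if (n == 1) return(matrix(total, ncol = 1))
  out <- list()
  for (first in 0:total) {
    rest <- compositions(total - first, n - 1)
    out[[first + 1]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

# joint enumeration over independently sampled strata: all combinations of
# per-stratum subsets, summing events across strata
enum_stratified_pmf <- function(m_s, class_counts_s, n_s) {
  S <- length(m_s)
  pmfs <- lapply(seq_len(S), function(s)
    enum_sample_pmf(m_s[s], class_population(class_counts_s[, s], n_s[s])))
  out <- 1
  for (p in pmfs) {
    new <- numeric(length(out) + length(p) - 1)
    for (j in seq_along(p))
      if (p[j] > 0) {
        idx <- seq_along(out) + j - 1
        new[idx] <- new[idx] + out * p[j]
      }
    out <- new
  }
  out
}

enum_stratified_ae_pmf <- function(m_s, V_s, n_s) {
  S <- length(m_s)
  out <- 1
  for (s in seq_len(S)) {
    p <- enum_occupancy_pmf(m_s[s], V_s[s], n_s[s])
    new <- numeric(length(out) + length(p) - 1)
    for (j in seq_along(p))
      if (p[j] > 0) {
        idx <- seq_along(out) + j - 1
        new[idx] <- new[idx] + out * p[j]
      }
    out <- new
  }
  out
}

# tails[k+1] = P(X >= k) from a pmf indexed 0..xmax
tails_of <- function(pmf) rev(cumsum(rev(pmf)))

# small planar region on a line: cell i at position pos[i]
line_region <- function(pops, pos = seq_along(pops) - 1,
                        ids = sprintf("c%02d", seq_along(pops))) {
  nb <- order_neighbours(ids, coords = cbind(x = pos, y = 0),
                         coord_type = "xy")
  region_data(ids, pops, nb)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "eventclust", mustWork = TRUE)
}
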