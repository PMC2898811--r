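---
title: "Detecting geographic aggregations of repeated disease events"
author: "eventclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting geographic aggregations of repeated disease events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventclust)
```

## Why events, not cases

Surveillance of health-service use often cares about *events* — individual
emergency-department presentations, admissions, dispensings — rather than
the number of distinct individuals involved. When one case can generate
many events, a case-based cluster test treats a person with one
presentation and a person with ten identically and can only find areas
with excess *people*. `eventclust` tests each administrative cell for an
excess of *events*, combining the cell with its nearest neighbours in the
Besag–Newell fashion, and computes the significance level exactly rather
than through a Poisson or normal approximation.

## The testing procedure

The region has `I` cells with populations $n_i$ (total $n$). For cell $i$,
its neighbours are ranked by increasing centroid distance
($i_1, i_2, \dots$), and $n_{i:\ell}$ denotes the population of the cell
together with its $\ell$ nearest neighbours. Given an event cluster size
$k^*$, the test statistic

$$L_i = \min\{\ell : \text{events in } i, i_1, \dots, i_\ell \ge k^*\}$$

is small when events are locally concentrated, and the p-value is the null
probability that a population of $n_{i:L_i}$ individuals holds at least
$k^*$ events. Everything therefore reduces to the null distribution of the
event count $X$ in a sample of $m$ individuals drawn without replacement
from the region; the four choices are described next.

### The four null models

**HC (hypergeometric case).** The classical test on case counts: with $c$
cases in total, $X \sim$ Hypergeometric$(n, c, m)$. Computed with
`stats::dhyper`/`phyper`.

**EE (exact event).** If the histogram of cases by their number of events
is known — $C_y$ cases with exactly $y$ events, $y = 1..Y$ — the event
total in the sample follows a multiple hypergeometric distribution over
the classes. `ee_event_pmf()` evaluates it by a convolution: classes are
absorbed one at a time, tracking the joint distribution of (events so far,
individuals drawn so far). The update for a class uses the conditional
hypergeometric law of that class's draw given the individuals already
drawn, so every intermediate value is a probability in $[0, 1]$; no
binomial coefficient is ever formed, which is what makes populations in
the hundreds of thousands numerically safe. Classes are processed in
increasing order of size: the dominant single-event class then arrives
last, when the state space is still only (events, draws) over the small
classes, and the whole computation for $m = 8000$, $n = 544{,}000$,
$v = 1088$ takes well under a second.

**CPE (compound Poisson event).** The parametric alternative: the sampled
case count is Poisson with rate $mc/n$, each case drawing its events
independently from the events-per-case distribution $Q(y)$. The pmf is
evaluated by the Panjer recursion for compound Poisson sums,
$p(x) = \frac{\lambda}{x}\sum_y y\,Q(y)\,p(x-y)$ with
$p(0) = e^{-\lambda}$, which is exact term by term; the support is
extended until the remaining upper tail falls below `tol = 1e-13`
(configurable), so truncation error is bounded by that tail. The case
total may be non-integer here (it is a rate), which the exact methods do
not allow. EE and CPE share the mean $mv/n$ but are distinct
distributions; their cluster sizes can differ by one at the same $\alpha$,
which is exactly where the two analyses disagree on borderline cells.

**AE (aggregate event).** When only per-cell event totals are recorded,
events are treated as indistinguishable and all
$\binom{n+V-1}{V}$ ways of distributing the $V$ events among the $n$
individuals are taken as equally likely, giving the occupancy-number pmf

$$P(x, m) = \binom{m+x-1}{x}\binom{n-m+V-x-1}{V-x}\Big/\binom{n+V-1}{V},$$

computed via `lchoose` in log space. This discards the case structure —
a deliberate information loss that makes analysis possible for coarser
administrative extracts.

### Stratification

Populations can differ in composition (sex, age group) across cells.
The stratified EE and AE tests condition on per-stratum populations:
stratum $s$ contributes $m_s$ individuals sampled from its own $n_s$, and
since strata are independent under the null the total-event distribution
is the convolution of the per-stratum laws. In the class-draw formulation
the per-stratum draws $r_{ys}$ range over $0 \le r_{ys} \le C_{\cdot ys}$,
the same inequality constraint as the unstratified set. With one stratum
both variants reduce bit-for-bit to the unstratified tests (this is
asserted in the test suite). Stratification is not defined here for HC or
CPE; requesting it raises an error.

### Choosing the cluster size

The real cluster size is unknown, so it is prescribed from the null
itself: $k^*_i(w)$ is the smallest $k$ whose upper-tail probability in the
population $n_{i:w}$ is at most $\alpha$ — the count at the
$100(1-\alpha)$ percentile. Cell $i$ is tested at $k^*_i(0)$; if not
significant, at $k^*_i(1)$; then $k^*_i(2)$, reporting the last test when
none succeeds. A significant cell necessarily has $L_i = w$ at the depth
where testing stopped, while cells without enough events must combine
more than $w$ neighbours. The default depths $w \in \{0, 1, 2\}$ keep the
combined populations from growing so large that significance becomes
unattainable anyway; the depth vector is configurable, and depths beyond
$I - 1$ are clipped. Because the counts are discrete the attained tail,
the *effective significance level* $\alpha^* \le \alpha$, is recorded in
the plan; the per-test p-value at the stopping depth equals $\alpha^*$
when the cell is significant alone, which also means reported p-values
for significant cells sit close to $\alpha$ — an inherent feature of the
sequential prescription, not a bug.

Two degenerate situations have fixed conventions: if no attainable count
is rare enough, $k^*$ is set one past the support (the cell can never be
significant), and if a cell's threshold is not reached even by the whole
region, the cell is reported non-significant with $p = 1$ and
$\ell = I - 1$.

### Multiple testing and overall clustering

No correction is applied to per-cell p-values. Instead, the number of
significant cells $R_\alpha$ is referred to its null distribution by
simulation: the observed case classes are re-allocated multinomially to
cells with probabilities $n_i/n$, the full sequential analysis is rerun,
and the overall p-value is the proportion of simulations with at least as
many significant cells. For aggregate-only data the individual events are
re-allocated instead — a multinomial surrogate for the occupancy null
that conditions on the observed total, consistent with how the AE test is
used in practice.

## The simulation harness and its generator

`type1_harness()` measures the empirical Type I error. Its generator
defines the study conditions:

* 68 cells (the default), populations constant at 1000, 5000 or 8000, or
  any supplied vector;
* an event rate of 2 per 1000 population, fixing $v = \lfloor
  \text{rate}\times n\rfloor$ events in every dataset;
* an events-per-case distribution from the built-in scenarios S1–S5
  (S1: $Q = (0.6, 0.3, 0.1)$; S4: $Q = (0.8, 0.15, 0.05)$; S5 is
  long-tailed and its stated probabilities sum to 0.999, so it is
  renormalized with a warning);
* integer case classes obtained by flooring $cQ(y)$ with
  $c = v/\sum y\,Q(y)$ and topping up the single-event class until the
  events sum to $v$ exactly — the top-up lands wholly on $y = 1$, so the
  rule is insensitive to floating-point jitter in the floors;
* each class allocated independently and multinomially across cells, so
  class totals and the event total are conserved in every draw.

Each replication tests every cell **once** at its cell-alone cluster size
$k^*_i(0)$; a cell rejects exactly when its own events reach $k^*_i$,
which under the null happens with probability $\alpha^*_i$. The harness
reports $\alpha^*$ (mean and SD across cells — the SD is zero for
constant populations) and the mean and SD across cells of each cell's
empirical rejection percentage over the replications. At 1000
replications and $\alpha^* \approx 2.5\%$ the binomial standard error is
$\sqrt{\alpha^*(1-\alpha^*)/1000} \approx 0.5$ percentage points, which
is what the across-cell SD tracks. The CPE rate uses the exact
non-integer case total $v/\sum yQ(y)$, since its null is parameterised by
a rate, while the data are generated from the integerized classes.

What the generator does **not** emulate: real geography (cells are
exchangeable, so the neighbour ordering is irrelevant under the null at
$w = 0$), spatially structured populations, overdispersion of events
beyond the scenario's $Q$, case mobility, or stratified population
imbalance. Passing the harness therefore demonstrates correct null
calibration, not detection power on real data; power comparisons between
the methods are out of scope.

A single root seed drives each harness run through R's default RNG
stream; runs are bit-reproducible at a fixed seed.

## Numerical choices, at a glance

* All occupancy binomials via `lchoose`; hypergeometric terms via
  `dhyper` (which is itself log-gamma based); the EE convolution works in
  probability space by construction.
* Panjer support truncation at upper tail `1e-13`; pmf normalization
  asserted to `1e-10` in tests.
* Distance ties in the neighbour ordering are broken by ascending cell
  identifier, making the ordering deterministic and invariant to input
  row order. Latitude/longitude centroids use great-circle (haversine)
  distances; planar coordinates use Euclidean; an explicit ordering file
  always overrides computation.
* Zero-population cells are retained and may be combined; they cannot
  crash the tests.
* Cluster-size searches cache the null distribution per distinct combined
  population, which collapses the work to a single distribution per depth
  when populations are constant.

## Problem sizes

The test suite enumerates every kernel exhaustively on populations up to
12 individuals and 8 events, checks the deterministic effective levels at
populations up to $68 \times 8000$, and runs the harness at 1000
replications; the whole suite completes in about half a minute, and the
acceptance script in a few seconds.

## Known limitations

* The sequential prescription makes significant cells' p-values cluster
  just below $\alpha$; interpret individual p-values qualitatively and
  lean on the Monte Carlo overall assessment.
* The AE null conditions on indistinguishable events and ignores case
  counts even when available; prefer EE whenever the histogram exists.
* The stratified CPE and HC variants are not provided.
* Power under planted clusters is not characterised here.
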