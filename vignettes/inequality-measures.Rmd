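---
title: "Measuring statistical inequality and concentration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring statistical inequality and concentration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ineqconc)
```

## The unit distribution

Every measure here summarizes one object: the **unit distribution** —
`k` components each holding `n_i >= 0` units, total `N`, unit shares
`p_i = n_i/N`. For a metric variable the components are individuals and
the units their values; for a categorical variable the components are
the categories and the units their counts, so the unit distribution is
the frequency distribution sorted ascending. `unit_distribution()`
validates this object: missing values are dropped with a reported
count, negative values abort by default (they have no meaning for
share-based measures) or are removed on request, zeros are kept.

Whether zeros then count is measure-specific and deliberate. The
deviation-model indices include null components — the maximum-inequality
benchmark "one component holds everything, k−1 hold nothing" only makes
sense if the empty components carry rank positions and deviations. The
Herfindahl-Hirschman and Shannon indices ignore nulls, as a component
with no units contributes neither a squared share nor information. A
single-component distribution is accepted; the corrected Gini and
Hoover indices raise a domain error there (their normalizer `1 − 1/k`
vanishes) while everything else returns its degenerate value.

## Curves and the deviations model

The Lorenz curve plots cumulative unit share against cumulative
component share with components sorted ascending. For discrete data it
is exactly the piecewise-linear polyline through the `k + 1` vertices
`(j/k, sum of the j smallest shares)`, so all areas in the package use
the trapezoid rule on the vertex polyline — no approximation is
involved, and the identities below hold to numerical precision rather
than asymptotically:

* Gini `G = (1/2k) Σ_i Σ_j |p_i − p_j|` equals twice the area between
  the diagonal and the curve;
* Hoover `H = ½ Σ |p_i − 1/k|` equals the maximum vertical gap at a
  vertex;
* Rosenbluth `R = 1/(2 Σ i p_(i) − 1)` (descending ranks) equals the
  reciprocal of twice the area above the concentration curve, and
  `R = 1/[k(1 − G)]`.

The Rosenbluth rank form deserves a note: rank 1 must be the *largest*
share. Both anchor cases pin this down — a point mass gives
`R = 1/(2·0.5) = 1` and a uniform distribution `R = 1/k` — and the
Gini identity then holds automatically. Ties in the ranking are broken
stably; since tied components have equal shares, `Σ i p_(i)` and hence
`R` do not depend on the tie order.

Internally the package computes `G` by the sorted-rank formula
`(2/k) Σ i p_(i) − (k+1)/k`, which is algebraically identical to the
pairwise double sum but `O(k log k)`; the tests keep an independent
`O(k²)` pairwise oracle.

The uncorrected `G` and `H` are *replication invariant*: splitting
every component into m equal parts changes neither. The corrected
forms `G′ = G/(1−1/k)` and `H′ = H/(1−1/k)` trade that invariance for
a fixed `[0, 1]` range and comparability across different `k` — the
classic absolute-versus-relative inequality distinction.

## Combinatorial and entropy measures

`HHI = Σ p_i²` is the same-component probability under drawing *with*
replacement; Simpson's `S = Σ n_i(n_i−1)/(N(N−1))` is the exact
probability *without* replacement, which is why it requires integer
counts and `N ≥ 2` and why it is the correct small-sample choice. The
two converge as `N` grows at fixed proportions; `hhi()` emits an
advisory for small categorical totals. `GS = 1 − S` and `IS = 1/S`
(with `IS = Inf` at `S = 0`, a representable value rather than an
error) change the polarity to equality/diversity.

The Shannon index defaults to base 2 — its bits-and-questions reading
("how many yes/no questions identify a random unit's component") is
the most teachable — with `exp(1)` and 10 selectable; values in
different bases differ by the constant `log` ratio.

The generalized entropy family uses exact branch selection: `alpha == 1`
evaluates the Theil form `(1/k) Σ x ln x` with the `0·ln 0 = 0` limit,
`alpha == 0` the mean log deviation `−(1/k) Σ ln x` (strictly positive
units required, as for every `alpha <= 0`), anything else the power
form `(1/(kα(α−1))) Σ (x^α − 1)`, where `x_i = k p_i = n_i/n̄`.
Tolerance windows around the special values were rejected on purpose —
they silently switch formulas for nearby `alpha` — and a continuity
test (offsets of 1e-6 around both branch points, agreement within
1e-4) guards against the discontinuity bugs exact branching could
hide. The sign of `alpha` tunes tail sensitivity: large positive
`alpha` weights inequality among the largest units, negative `alpha`
among the smallest.

## The Atkinson index and its GE link

`AI(ε) = 1 − M_{1−ε}(n)/n̄`, the shortfall of the power mean of order
`1 − ε` below the arithmetic mean. The aversion parameter `ε ≥ 0` has
no default in this package: its value changes the question being
asked, so the caller must choose it (1.5–2 is the classic
recommendation for income-type applications, surfaced in the CLI
help). `ε = 0` gives 0 for every distribution; at `ε = 1` the power
mean is the geometric mean; with any zero unit and `ε ≥ 1` the power
mean collapses and `AI = 1`, while `0 < ε < 1` remains finite — the
standard power-mean limits.

The equally-distributed-equivalent standard `n_ε = n̄(1 − AI)` inverts
usefully: given a substantively meaningful standard (a validity
threshold, a clinical cutoff), `epsilon_for_standard()` root-finds the
`ε` that makes `n_ε` equal it. Since `n_ε` is non-increasing in `ε` —
from `n̄` at `ε = 0` towards the minimum unit — the root is unique;
the implementation brackets by doubling the upper bound until the sign
changes and then calls `uniroot()`, with the achievable interval
reported when the target lies outside it.

The Atkinson and generalized entropy families are linked through
`ε = 1 − α`. The conversion formulas implemented here are derived
directly from the definitions via
`(1/k) Σ (k p_i)^α = 1 + α(α−1)·GE(α)`:

* `ε = 1`: `AI = 1 − exp(−GE(0))` — note the partner is the **mean log
  deviation**, since `ε = 1` corresponds to `α = 0`, not the Theil
  index;
* `0 < ε ≠ 1`: `AI = 1 − [1 + ε(ε−1)·GE(1−ε)]^{1/(1−ε)}`.

Renderings of this link elsewhere sometimes drop the leading `1 +` or
pair `ε = 1` with the Theil index; both variants fail an immediate
numerical check (for `(360, 250, 150)`, `1 − e^{−Theil} = 0.05698`
whereas the direct value is `0.06009 = 1 − e^{−MLD}`). Because the
conversion exists precisely to move between metrics without error,
`atkinson_ge_link()` optionally takes the originating distribution and
raises a consistency error whenever the converted value disagrees with
the direct computation beyond 1e-8 — a wrong-`alpha` input surfaces
immediately instead of propagating.

## Tail ratios

Share ratios (Palma: top 10% vs bottom 40%; S80:S20: top vs bottom
fifth) are read off the Lorenz polyline with linear interpolation at
the fractional cut points. The alternative — rounding to whole
components — makes the estimator jump as `k` changes and is
ill-defined when, say, the richest 20% of three components is wanted;
interpolation keeps it continuous and agrees exactly with component
sums whenever the cuts fall on component boundaries (k a multiple of
10, respectively 5). A caution is emitted when `k` is smaller than the
reciprocal of the smaller tail fraction. At perfect equality the Palma
ratio is 10/40 = 1/4 and the others are 1 — those are the lower
limits recorded in the catalog.

Percentile ratios (P90:P10, P50:P10 and user-specified pairs) use the
linear-interpolation quantile convention (`stats::quantile` type 7),
recorded as an attribute on every result, since percentile ratios are
only reproducible when the quantile rule travels with the number. A
zero denominator (low quantile, or empty bottom tail share) yields
`Inf` with a warning rather than an error: the datum "the bottom holds
nothing" is a legitimate, maximally unequal answer.

## Tables, files, aliquot merging

`distribution_table()` reports per-component shares and cumulative
shares as percentages (0–100); internally everything is on the 0–1
scale and conversion happens only at display. Exported measure tables
carry values rounded to 5 decimals *plus* a full-precision
`value_full` column, so a round-trip through CSV is lossless.

For display only, distributions with more than 20 components are
merged into 20 aliquot slices of the ascending-sorted components (5%
each); when `k` is not divisible by 20, boundary components are split
proportionally so each slice holds exactly `k/20`
component-equivalents and the total is conserved. Merging is never
applied before computing a measure — the contract is enforced by
keeping the merge out of every index code path and verified by test.

## The fixture generators and what tests do (and do not) show

`generate_distribution()` supplies the package's entire test surface:
uniform and point-mass benchmarks (the equality/inequality extremes of
every measure), a two-level family for replication-structure
checks, lognormal and Pareto-like families (heavy-tailed positive
values, the realistic shape for reaction-time or income-like data),
Dirichlet-uniform random shares, and multinomial integer counts for
the categorical-only measures. Seeded draws are bit-reproducible.

Property suites run the measures over hundreds of such draws
(`k` from 2 to 50 with occasional zero components, counts up to a few
hundred) checking the cross-index identities to 1e-10, the Table-style
theoretical limits, monotonicity under regressive transfers, scale
invariance, and agreement with naive `O(k²)`/`O(N²)` oracles that
share no code with the implementations. These sizes exercise every
code path and keep the whole suite under a minute; the identities are
algebraic, so larger `k` adds rounding noise, not information. What
the synthetic families do *not* emulate: sampling variability of real
designs (no standard errors or confidence intervals are provided —
point description only), weighted or grouped observations, negative
values (net-wealth-style applications are out of scope), and
measurement error. A green suite therefore certifies the arithmetic
and the documented conventions, not the inferential behavior of the
measures on any particular real dataset.

## Numerical choices, in one place

* Exact branch selection for `GE` (`alpha == 0`, `== 1`) and Atkinson
  (`epsilon == 0`, `== 1`); continuity guarded by test.
* `0·ln 0 = 0` convention at `alpha = 1`; domain errors (naming the
  offending components) for zero units at `alpha <= 0`.
* Trapezoid areas on vertex polylines — exact for discrete data.
* Stable ascending sort everywhere; tie order never affects a value.
* Quantiles: type 7, recorded in output metadata.
* Table display at 5 decimals; full precision in machine-readable
  columns; shares internally on 0–1.
* `Inf` (not an error) for `1/S` at `S = 0` and for tail ratios with
  empty bottom tails, each with a warning.
* Root finding for `epsilon_for_standard()`: bracket doubling +
  `uniroot`, tolerance `1e-8·n̄` on the standard.

## Known limitations

Subgroup decompositions (Theil/GE within-between splits), standard
errors and bootstrap intervals, weighted observations, and SPSS `.sav`
input are intentionally absent. The Herfindahl-Hirschman index is
reported for metric data without complaint, but its with-replacement
model makes it an approximation for small categorical totals — the
advisory steers those cases to the Simpson family.
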