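---
title: "Methods: germination time-course statistics and multi-temporal landscape accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germination time-course statistics and multi-temporal landscape accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedtrends)
```

seedtrends supports conservation studies of narrow-endemic plants that
combine two lines of evidence: laboratory germination trials (the
endogenous, seed-biology side) and multi-temporal accounting of the
pressures acting on the species' range — climate trends, land-cover
change and desertification sensitivity (the exogenous side). The study
system it was written around is a morpho-physiologically dormant
Mediterranean mountain endemic whose achenes germinate late (after four
to five weeks), sparsely (14–32% per treatment) and mostly turn out to
be embryoless on dissection; but every routine is generic over its
inputs.

## Germination schedules and indices

The unit of observation is the *dish schedule*: `n_i` seeds newly
germinated (radicle ≥ 1 mm) on day `t_i = i` of a `k`-day trial, out of
`N` seeds sown. Day 1 is the first 24-hour check after sowing; counts
are daily increments, and cumulative records can be converted with
`as_daily_counts()` (conversion is never applied silently, since a
non-decreasing increment series is also a legal schedule).

Ten statistics summarise a schedule, grouped by what they measure:

* **Capacity.** Final germination percentage
  $\mathrm{FGP} = 100\,\sum_i n_i / N$.
* **Time.** Mean germination time
  $\mathrm{MGT} = \sum_i n_i t_i / \sum_i n_i$; first and last day of
  germination (FDG, LDG); median germination time
  $T_{50} = t_i + \big(\tfrac{N'+1}{2} - c_i\big)\,(t_j - t_i)/(c_j - c_i)$,
  interpolating the cumulative count $c$ between the adjacent event days
  that bracket the half-count, with $N'$ the number of seeds that
  eventually germinated.
* **Rate.** Mean germination rate $\mathrm{MGR} = 1/\mathrm{MGT}$ and the
  coefficient of velocity $\mathrm{CVG} = 100\sum n_i / \sum n_i t_i$,
  identically $100\,\mathrm{MGR}$.
* **Speed (early-weighted).** The germination rate index
  $\mathrm{GRI} = \sum_d G_d / d$ with $G_d$ the daily germination
  percentage, and the germination index
  $\mathrm{GI} = \sum_d (k - d + 1)\, n_d$, the classical
  $60 n_1 + 59 n_2 + \cdots + 1\, n_{60}$ for a 60-day trial, with the
  weight generalised so trials of any duration are supported.
* **Homogeneity.** $s_t^2 = \sum_i n_i (t_i - \mathrm{MGT})^2 /
  (\sum_i n_i - 1)$ and $\mathrm{CV}_t = 100\, s_t / \mathrm{MGT}$.

Three definitional points were genuinely open and are resolved as
follows.

**The $T_{50}$ bracket.** The classical bracket condition is often
quoted as $c_i < N'/2 < c_j$, but the interpolation target in the
formula is $(N'+1)/2$; with an even count like 10 germinations split
5 + 5 over two days, only the $(N'+1)/2$ bracket yields the value the
formula's own arithmetic implies (day 10 + (5.5−5)·10/5 = 11, not an
out-of-bracket failure). The implementation therefore brackets
$(N'+1)/2$ throughout. Degenerate cases follow the continuity limit of
the interpolation: an exact cumulative hit of $(N'+1)/2$ returns that
day, and if the first event day already reaches the target (all
germination on one day, or a large first-day burst) that day is
returned. $T_{50}$ always lies within [FDG, LDG].

**The GRI's $G_d$.** "Germination percentage on day $d$" admits a daily
and a cumulative reading. The default is the daily increment
($100\,n_d/N$, the Esechie convention), which keeps GRI finitely
additive over days; the cumulative reading is available via
`germination_rate_index(s, cumulative = TRUE)` and is always at least
as large.

**Undefined indices are `NA`, never 0.** A dish with no germination has
no MGT, MGR, FDG, LDG, $T_{50}$, $\mathrm{CV}_t$ or CVG; a dish with one
germination has no dispersion. Carrying these as explicit `NA` and
excluding them from replicate means (`summarize_treatments()` reports
`n_defined` alongside) avoids the downward bias a silent zero would
inject into treatment summaries. FGP, GRI and GI are genuine zeros for
an empty dish.

Two small-sample corrections in the printed formulas — the $(N'+1)/2$
target and the $\sum n_i - 1$ denominator — mean that $T_{50}$ and
$\mathrm{CV}_t$ are only asymptotically invariant under doubling all
counts; the ratio-form indices (FGP, MGT, MGR, CVG) are exactly
invariant, and the test suite asserts exactly that split.

## Treatment comparison

The comparison scheme is rank-based throughout, dispatched by design:
two related samples use the Wilcoxon signed-ranks test, two unrelated
the Mann–Whitney U, more than two related the Friedman test, more than
two unrelated the Kruskal–Wallis H. Pairwise contrasts use the
design-appropriate two-sample test and are judged at the
Bonferroni-adapted level $\alpha_B = \alpha/k$, where $k$ counts the
contrasts actually performed in the family (per index, per table) — six
for four treatments. All tests are two-sided; ties take mid-ranks with
tie-corrected variances.

P-values are **exact permutation probabilities** whenever the
permutation space fits under `exact_limit` (default $10^5$): all splits
of the pooled sample for Mann–Whitney (12,870 for two groups of eight),
all $2^m$ sign flips for the signed-ranks test, all group assignments
for Kruskal–Wallis, all within-block rank permutations for Friedman.
Two-sided p is the probability of a deviation from the null centre at
least as large as observed (tail comparisons use a $10^{-9}$ guard
against floating-point ties); the upper tail is used for the
chi-square-type statistics. Beyond the limit the standard tie-corrected
large-sample approximations take over (normal without continuity
correction for the two-sample tests, $\chi^2_{k-1}$ for the omnibus
tests), and each result carries an `exact` flag. Null distributions are
memoised per rank configuration, which makes simulation studies with
repeated designs cheap.

The compact letter display uses insert-and-absorb: starting from one
letter covering all groups, each significant pair splits every set
containing both members into two reduced copies, then absorbed subsets
are dropped; letters are ordered by earliest member, so the procedure is
deterministic in the input group order. The defining property — two
groups share a letter *iff* their contrast is non-significant — is
exact by construction, and the suite verifies the round trip
exhaustively for every significance pattern on up to five groups.
Kendall's $\tau_b$ (via `stats::cor.test`, exact p for untied series of
up to 10 points, tie-corrected normal approximation otherwise) covers
monotonic-trend checks.

At the reference design of four dishes per treatment, the smallest
attainable exact Mann–Whitney p is $2/70 \approx 0.029 > \alpha_B =
0.0083$: Bonferroni-adapted contrasts *cannot* reject with four
replicates, whatever the data. The analysis scripts report this rather
than hide it, and the familywise-error simulation below uses eight
observations per group precisely so that rejections are attainable and
the error-rate check is informative.

## Climate windows

Annual series (year, mean temperature in °C, total rainfall in mm) are
summarised over the three 30-year climatological normals 1931–1960,
1961–1990, 1991–2020 and the full 1931–2020 period. Published
narratives of the form "increased by 0.5 °C, from 15.4 to 15.9" are
interpreted as the **fitted-endpoint difference of the window's OLS
line** — the estimator behind such trend figures is rarely stated, so
the window mean is reported alongside and either reading is checkable.
`delta = slope × (end − start)` holds by construction, and for a
complete window the fitted midpoint equals the arithmetic mean (an OLS
identity the tests assert). Windows are fitted independently, so the
three 30-year deltas need not sum to the 90-year delta; this
non-additivity is a documented non-property with its own test. Windows
with under 80% year coverage are flagged `low_coverage`; fewer than
three usable years is an error, reported per window (not fatal) in
batch summaries.

## Land-cover and desertification accounting

Land-cover input is a long class-area table: CORINE Land Cover (CLC)
level-III code, name, survey year, hectares, with `NA` for classes the
source map of that year did not record. The central accounting rule:
**`NA` never enters a denominator and is never coerced to zero.** A
year's composition divides by the sum of recorded areas; an explicit
`total_ha` override supports the alternative reading when the mapped
area is known to undershoot the territory (the shipped 1958 column is
internally inconsistent in exactly this way: its printed areas sum to
42,263 ha while its printed percentages imply ≈ 42,480 ha, so both
readings are reportable and neither is guessed). Older national
classifications are re-keyed through a user-supplied crosswalk
(`source_label → clc_code`); many-to-one mappings sum areas and total
area conservation is checked to 0.01 ha. The shipped 1958 table is
already printed under CLC codes, so its crosswalk is the identity.

Level-1 rollups group by the leading CLC digit (1 artificial, 2
agricultural, 3 forest/semi-natural, 4 wetlands, 5 water). Published
tables compute their level-1 aggregates as sums of the *printed*
(1 d.p.) class percentages, which can differ from the unrounded sum in
the last decimal (40.3 vs 40.25 for the 2018 agricultural total in the
shipped table); `rollup_level1()` therefore defaults to
printed-precision arithmetic (`digits = 1`) and offers `digits = NULL`
for the unrounded reading. Everywhere else rounding is presentation-only
and comparisons run on unrounded values. Change matrices report per-class
ha and percentage-point deltas between two years, flag classes
unrecorded in either year, and are antisymmetric by construction.

The desertification stage works on MEDALUS environmentally-sensitive-area
(ESA) class shares (not affected, potential, fragile 1–3, critical 1–3)
per survey year; computing the underlying ESAI index from
climate/soil/vegetation layers is out of scope. Per-year shares must sum
to 100 ± 0.5 (renormalisation is optional and warned). The "affected
land" aggregate sums a configurable class subset, defaulting to all
fragile plus all critical classes — a definition the source surveys
leave implicit; under it, the shipped share table yields 21.2% (2000)
and 47.3% (2020).

## What the generators emulate — and what they do not

`simulate_germination_experiment()` draws, per seed, a Bernoulli
within-trial germination (probability `p_germ`) and, for germinating
seeds, a germination day from a normal truncated to `[1, k]`
(`mu_day`, `sigma_day`), rounded half-up to an integer day; a lognormal
day law with matched mean and sd is available by flag, and both
reproduce the late-onset (≈ day 25–32), 37–42-day-span pattern of the
reference trials under suitable parameters. Non-germinating seeds split
empty/dead/viable for the cut test (defaults 80.1% / 15% / 4.9%). The
default configuration *is* the reference design: four treatments with
`p_germ` = 0.17, 0.14, 0.32, 0.23 and `mu_day` = 30.3, 36, 32.5, 34.4
(sigma set from the reported timing CVs), four dishes of 20 achenes,
60 days. The climate generator is piecewise-linear-plus-noise with the
narrative segment endpoints as defaults (noise sd 0.3 °C and 150 mm,
typical station-scale interannual variability); the land-cover generator
evolves shares by a per-period transfer matrix (defaults emulate
agricultural abandonment into forest over a 42,400-ha territory),
clipping and renormalising only under extreme noise, with a warning.

The generators deliberately do **not** model within-dish correlation
(seeds are exchangeable), spatial structure of land cover, station
inhomogeneities, autocorrelated climate noise, or secondary dormancy.
Passing parameter-recovery tests therefore shows the estimation pipeline
is consistent under the stated sampling model — not that real trials
behave this way. Recovery tolerances are the binomial/normal ones at the
simulated size: at 500 dishes of 20 seeds, mean FGP recovers within
±2 pp and MGT within ±0.5 day; at the reference four dishes, the same
estimators are unbiased but wide (an FGP standard error of ≈ 5 pp), and
the comparison stage's power caveat above applies.

## Numerical choices and problem sizes

All randomness flows through explicit integer seeds; generators save and
restore the caller's RNG state. Permutation tail comparisons use a
$10^{-9}$ tolerance; mid-rank sums are exact in floating point (halves),
so this only guards degenerate chi-square-type equalities.
`exact_limit = 1e5` switches to asymptotics roughly beyond two groups of
eight (Mann–Whitney), 17 sign flips, group assignments for 3 × 4
(Kruskal–Wallis), or four blocks of three treatments (Friedman); the
threshold is an argument everywhere. Test and verification sizes, chosen
to keep the full suite around two minutes: exhaustive index verification
over all 3,003 schedules with ≤ 6 germinations in 8 days against a
per-event-list oracle; permutation p-values cross-checked against
independent enumeration oracles for every two-sample size pair up to
8 × 8; the familywise-error simulation uses 2,000 replicates of four
groups of eight (observed rate ≈ 0.03 against the 0.06 bound, the
Bonferroni bound being conservative); letter round-trips are exhaustive
on ≤ 5 groups (1,024 matrices at n = 5).

## Known limitations

* Dispersion and speed indices are computed at daily resolution; trials
  checked at other cadences must be resampled to a daily grid first.
* The exact Friedman path enumerates $(k!)^b$ permutations and is
  practical only for small blocks-by-treatments layouts; beyond it the
  $\chi^2$ approximation is used even though block counts of 4–8 are
  where it is weakest.
* The climate module fits straight lines per window; it does not model
  breakpoints, autocorrelation or extreme-event indices, and "delta"
  statements inherit the fitted-endpoint interpretation above.
* Land-cover change is purely compositional: without the underlying
  maps, a per-class delta cannot distinguish relabelling from real
  conversion, and no transition (from–to) matrix can be derived from
  class totals alone.
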