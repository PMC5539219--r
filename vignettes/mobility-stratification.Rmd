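---
title: "Measuring social mobility and stratification in dominance hierarchies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring social mobility and stratification in dominance hierarchies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobidom)
```

`mobidom` quantifies intragenerational social mobility in small groups with
strictly linear, sex-separate dominance hierarchies, and models the
long-run stratification those mobility rates drive. This vignette is the
package's own account of the methods: the models, the assumptions behind
them, the tunable parameters, the numerical choices, and the places where
we made genuinely open design decisions.

## 1. From agonistic records to ranks

The raw datum is a decided dyadic contest: one animal aggresses, the other
submits. Annual tallies per ordered dyad form a win:loss matrix `W`, where
`W[i, j]` counts wins of `i` over `j`. Given a candidate order (rank 1 =
alpha first), a *reversal* is any win by a lower-ranked animal over a
higher-ranked one; after rearranging `W` into the candidate order the
reversal count is the below-diagonal sum. `find_rank_order()` returns the
order minimizing that count — the classical matrix-rearrangement criterion
for constructing a dominance order.

Numerical choices:

* **Exact search for N ≤ 9.** The minimum is found by dynamic programming
  over subsets (choose the top-ranked animal of every suffix set), which
  visits the same solution space as enumerating all N! orders at
  O(2^N · N²) cost. Group sizes in the motivating system are ~8 adults per
  sex, so real analyses are always exact. Above the threshold a pairwise
  swap hill climb with at least 20 seeded random restarts is used, and the
  result is flagged `method = "heuristic"`.
* **Tie-breaking.** Equally minimal orders are resolved deterministically:
  prefer the order giving rank 1 to the animal with the larger total win
  count, then rank 2, and so on; remaining ties go to the smaller
  identifier. Any stable rule is defensible here — with realistic volumes
  of interaction data, ties essentially never involve well-observed
  animals.
* **Silent animals.** Individuals present but appearing in no record cannot
  be placed by the criterion. Excluding them would silently change group
  size, so they are appended after the ranked animals, in lexicographic
  order, and listed in the result's `unobserved` field.
* **Annual matrices.** Observation effort within a year is pooled into a
  single matrix per calendar year per sex; within-year rank dynamics are
  outside scope (the hierarchy is treated as an annual snapshot).

## 2. The mobility rate and its companions

For each animal ranked in consecutive years, the pair (R(t), R(t+1)) is one
individual-year. The annual mobility rate is `1 − b`, with `b` the OLS
slope of R(t+1) on R(t): a frozen hierarchy has b = 1 and rate 0, and the
further b falls below 1 the less an animal's rank this year predicts its
rank next year. Significance is assessed through Pearson's r. The default
degrees of freedom for that test are the standard n − 2; field reports
sometimes use n − 1, so `fit_mobility(df_method = "n-1")` is available, and
no downstream quantity depends on the choice.

Around the rate sit the standard companions, each a thin, tested wrapper
over the classical procedure:

* transition classification (upward = numerically smaller rank, since rank
  1 is the alpha), with the magnitude spectrum |R(t+1) − R(t)| and the
  fraction of changes within two ranks;
* chi-square goodness-of-fit tests of two-category counts against a 50/50
  null (`stats::chisq.test`);
* slope comparison between the sex-specific regressions by the pooled
  residual-variance t test with n₁ + n₂ − 4 degrees of freedom;
* Anderson-Darling residual normality (`nortest::ad.test`) — a shortage of
  extreme residuals indicates that large annual jumps are rarer than a
  Gaussian model predicts;
* per-adult tenure tables: each adult classified once by the sign of its
  net rank change over its whole tenure, tabulated over the nested subsets
  of adults with tenure ≥ k (the per-year alternative reading — re-counting
  transitions within each tenure class — is coherent too, but the
  whole-tenure reading is the one that can produce rows where every
  long-tenured animal ends upward, and it is what we implement);
* alpha/omega spell summaries (maximal runs of consecutive years holding
  the top or bottom rank), compared between sexes by Mann-Whitney U
  (`stats::wilcox.test`: exact for small tie-free samples, otherwise the
  tie-corrected normal approximation);
* Kaplan-Meier curves of time from adulthood to first upward move with
  right-censoring at exit (`survival::survfit`), compared by log-rank test.

One caveat discovered while validating the survival comparison: in whole
simulated groups, event times within a sex are *not* independent — a single
departure promotes several survivors in the same year — and that clustering
makes the log-rank test markedly anti-conservative. Our calibration tests
therefore use independent subjects with identical hazards; when applying
the log-rank comparison to real group data, its p-values should be read
with the same caution.

Censoring convention: an animal absent in year t + 1 contributes no pair
for year t. Its disappearance is a demographic event, not a rank
transition, and conflating the two would bias every mobility statistic.

## 3. The two-stratum Markov model

To ask whether observed mobility drives the society toward a stable
structure, each sex-year hierarchy is split into an upper stratum H (the
top half) and a lower stratum L. Finer slicing (quantiles, quintiles) is
deliberately out of scope: with ~8 adults per sex the cells would be too
sparse to estimate. With an odd number of adults, the middle-ranking animal
is given two half-scores, one per stratum, so stratum totals are exactly
N/2 — and transitions involving it contribute the product
`weight_origin × weight_destination` to each cell. This product rule is the
only symmetric treatment of half-scores that conserves total transition
mass: an animal staying middle across both years adds 0.25 to all four
cells and exactly 1 in total.

Row-normalizing the fractional counts gives the annual transition matrix
`P` over {H, L}. The per-sex matrices are pooled into a combined matrix by
summing counts before renormalizing — the maximum-likelihood combination —
never by averaging probabilities.

The long-run analysis is exact for a 2-state chain:

* `matrix_power()` computes Pⁿ by repeated squaring (renormalizing rows to
  absorb ~1e-16 floating-point drift);
* `stationary_distribution()` uses the closed form
  π_H = p_LH / (p_HL + p_LH), refusing chains with an absorbing stratum
  (an off-diagonal of 0) or period 2 (both diagonals 0), and naming the
  violated condition;
* the spectral identity `Pⁿ_HH − π_H = (1 − π_H) λ₂ⁿ` with
  λ₂ = p_HH + p_LL − 1 serves as the module's analytic oracle — powering
  must agree with it to 1e-9, and does;
* `convergence_horizon()` returns the first horizon in the doubling
  sequence 2, 4, 8, ... at which both diagonals of Pⁿ are within a
  tolerance (default 0.001) of their limiting values. We compare each
  power against the analytic limit rather than against the previous power:
  successive-power differences can dip under a tolerance long before the
  limit is reached when λ₂ is close to 1, whereas distance-to-limit is the
  quantity the stabilization criterion is about. For the shipped
  combined-sex matrix this criterion is first met at the 32-year horizon,
  inside the 16-to-32-year window where such chains are expected to settle
  — roughly an adult lifespan.

`stratification_table()` reports the H-H and L-L diagonals of Pⁿ per cohort
at horizons 2–32, rounded to 4 decimals by default because that is how such
tables are conventionally printed; pass `digits = NULL` for full precision.
Recomputing published tables from their printed 4-dp matrices can disagree
with the printed deeper horizons by ~1e-4 (the original computations used
unrounded matrices), which is why our table comparisons use a 0.001
tolerance beyond the 2-year row.

## 4. What the simulator emulates

`simulate_group()` generates the longitudinal structure the analysis
assumes, with a fixed annual update cycle: (1) rank-biased departures
(sampling weight `(N − rank + 1)^bias`), survivors closing gaps; (2)
Poisson immigration into a uniform rank in the lower half — immigrant males
essentially never enter a hierarchy at the top, and entering low is the
conservative choice; (3) endogenous moves: each animal moves with a small
probability, upward with probability `up_given_move`, by 1–2 ranks unless a
large jump (≥ 3, up to `max_jump`) fires, implemented as
removal-and-reinsertion so ranks always remain a permutation of 1..N; (4)
Poisson dyadic contests from the post-update order, won by the
higher-ranked animal with probability `p_dominant_win`. One RNG stream
seeded from the config makes histories byte-reproducible. How ranks change
within a year is not observable in annual census data; remove-and-reinsert
is our modelling choice, selected as the simplest scheme that can never
create ties or gaps.

A consequence worth understanding before tuning anything: the pooled annual
statistics are *emergent*, not copies of the knobs. Every endogenous
up-move of magnitude m displaces m animals downward by one; every departure
promotes everyone below it; every immigrant demotes those it lands above.
The defaults were therefore calibrated once, by simulation, so that the
emergent statistics land on the field regularities the generator exists to
emulate, and then frozen:

| parameter | default | role |
|---|---|---|
| `n_years` | 30 | length of the longitudinal study |
| `init_adults_per_sex` | 8 | ~16 adults total, typical for the system |
| `departure_rate` | 0.045 /yr | death/emigration probability per adult |
| `departure_rank_bias` | 5 | departures concentrate at high ranks |
| `immigration_rate` | 0.36 /yr | balances departures at ~8 adults per sex |
| `move_probability` | 0.025 /yr | endogenous challenges are rare |
| `up_given_move` | 0.75 | challenges mostly succeed upward |
| `large_jump_probability` | 0.35 | chance a move is ≥ 3 ranks |
| `max_jump` | 5 | cap on endogenous move size |
| `interactions_per_dyad_per_year` | 20 | decided contests per dyad |
| `p_dominant_win` | 0.9 | steep, despotic-style hierarchies |
| `adult_age_threshold` | 7 yr | recorded for provenance |

At these values, pooled over many simulated 30-year histories, about 0.66
of individual-years show no rank change and upward changes outnumber
downward ones by about 3:1 with ~15 adults present — the structure the
mobility and stratification stages assume. Because contests do not feed
back into rank dynamics, analyses that only need ranks can set
`interactions_per_dyad_per_year = 0` and run much faster; our heavier tests
do exactly that.

What the generator does *not* reproduce: kinship and coalitions, spatial
behaviour, within-year dynamics, group fissions, provisioning effects — and
two quantitative features of real data. First, in real groups roughly a
fifth of annual changes exceed two ranks, while the simulator produces
almost none: at N ≈ 8 most animals simply have no room for a ≥ 3 jump, and
the changes that do occur are dominated by magnitude-1 departure cascades.
Second, the emergent annual mobility rate (1 − b ≈ 0.05) is lower than the
~0.15 field estimates, for the same reason — single-step cascades keep
R(t+1) tightly coupled to R(t). Passing tests on simulated data therefore
demonstrate the correctness of the estimators under the generator's
dynamics, not that the generator is a complete model of macaque social
life.

## 5. Problem sizes and reproducibility

All stochastic tests are seeded. The heavier checks use: 50 replicate
30-year histories plus one 3000-year history (~10⁵ individual-year
transitions) as the long-run expectation oracle for the pooled no-change
fraction, up-share, transition matrix, and mobility rate; 100 contest
replicates for rank-order recovery at `p_dominant_win = 0.9`; 1000 random
2-state chains for the spectral oracle; and 50 random win:loss matrices
(N ≤ 7) checked against full permutation enumeration. These sizes keep the
whole suite comfortably within a coffee break on one core while leaving
Monte-Carlo error well inside the asserted tolerances.

`run_analysis()` ties the stages together from any of three entry points —
a simulation config, interaction/rank tables, or transition matrices alone
— and records provenance (package version, seed, input hash) in the
report. The matrix-only mode is what `scripts/acceptance.R` uses to
recompute the published stratification quantities with no behavioural data.
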