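---
title: "Methods: within-season dynamics of plant–flower visitor networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-season dynamics of plant–flower visitor networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenonet)
```

## The problem

A plant–flower visitor network summed over a whole flowering season hides its
own temporal anatomy: two species recorded on the same cumulative matrix may
never have been active on the same day. `phenonet` analyses that anatomy for
quantitative (visit-count-weighted) bipartite networks sampled repeatedly
within one season, as is typical of alpine and other short-season communities
where a handful of census days spans the entire flowering period. The
pipeline answers three questions:

1. How much of the day-to-day change in species and interactions is species
   *replacement* (turnover) rather than richness difference?
2. Is the cumulative network modular, and are the modules temporal — i.e.
   sequences of co-active species rather than preference-defined blocks?
3. Does a species' phenology (the day its activity starts) predict which
   module it joins?

## Data model

All analyses start from long-format visitation records — one row per census
date, site, plant, visitor and visit count — plus optional weekly flowering
censuses. Dates are converted to day-of-year integers (1 January = day 1) for
all phenological arithmetic. Records are strictly per-site; multi-site tables
must be split before analysis.

Temporal aggregation (`build_networks()`) produces one quantitative
sub-network per non-empty window. The default window is a single census day,
which is the natural sampling unit; two-census-day and ISO-calendar-week
windows are provided to check robustness of the dissimilarity patterns to the
aggregation grain. Windows without records are omitted rather than emitted
empty, so a "season" is the ordered list of observed sub-networks.

Plant phenology pools flowering-census evidence with interaction evidence
(the earliest of either defines the start of activity), because weekly
censuses undersample a season in which daily visitation is observed; rows
where visits extend beyond the censused flowering period are flagged, and a
census-only mode is available for sensitivity analysis. Visitor phenology
comes from interaction records alone.

## Dissimilarity decomposition

For two assemblages with `a` shared elements and `b`, `c` unique elements,
the package uses the Whittaker measure
$$\beta = \frac{a+b+c}{(2a+b+c)/2} - 1 = \frac{b+c}{2a+b+c},$$
which is 0 for identical and 1 for disjoint sets, applied to species labels
(`beta_s`), to plant–visitor interaction pairs (`beta_wn`), and to
interactions restricted to the species present in both networks (`beta_os`,
the rewiring signal). `beta_st = beta_wn - beta_os` is the part of
interaction change attributable to species turnover. All dissimilarities use
binary presence: a quantitative threshold would entangle turnover with
abundance fluctuation, and the set semantics of the Jaccard family require
it. When two sub-networks share no species, `beta_os` is undefined and
recorded as `NA` (never imputed, and dropped from regressions).

Season-wide beta diversity uses the Jaccard partition
$$\beta_{CC} = \frac{b+c}{a+b+c},\qquad
  \beta_{3M} = \frac{2\min(b,c)}{a+b+c},\qquad
  \beta_{RICH} = \frac{|b-c|}{a+b+c},$$
extended to the whole series of daily assemblages by pooling the counts over
all unordered pairs (sums of pair-wise `a`, `b`, `c` in numerator and
denominator). The pooled-pairs form was chosen over averaging per-pair ratios
because it preserves the additivity $\beta_{CC} = \beta_{3M} + \beta_{RICH}$
exactly — a property the test suite asserts to $10^{-12}$ — and reduces to
the pairwise partition when only two units are compared. $\beta_{3M}$
measures replacement (species substituting one another between days);
$\beta_{RICH}$ measures nestedness-like richness difference.

Flowering overlap between two plants is $S_{ij} = a_{ij}/b_{ij}$ with
$a_{ij}$ the days both are in flower and $b_{ij}$ the days at least one is.
Because censuses are weekly but overlap is defined in days, each species'
flowering days are filled daily between its first and last active day. This
is a Jaccard similarity on day sets, so $1 - S_{ij}$ is a proper distance.

## Regressions

Dissimilarity–lag relationships are fitted by ordinary least squares:
species dissimilarity on the raw lag, interaction dissimilarity on the
natural log of the lag. The log-lag choice reflects the saturating rise of
`beta_wn` towards complete turnover — it climbs quickly while assemblages
still overlap and flattens once they do not; a log-response option is
exposed for users who prefer to linearise the other axis. p-values come from
the two-sided t-test of zero slope, without multiple-testing correction
across the handful of season-level regressions. `turnover_lag()` reports the
smallest lag beyond which every sub-network pair has `beta_wn = 1`, the
"phenological disconnection" horizon.

## Modularity

The modularity of a partition $g$ of all species is the weighted bipartite
(Barber-type) objective
$$Q = \sum_{ij}\left(\frac{A_{ij}}{F} - \frac{k_i d_j}{F^2}\right)
      \delta(g_i, g_j),$$
with $A$ the count matrix, $F$ its total, and $k$, $d$ the marginals. The
search is simulated annealing over single-species relabel moves from a
random initial partition with $K_0 = \min(\#\text{plants},
\#\text{visitors})$ labels, geometric cooling (default 60 sweeps, initial
temperature 0.02, factor 0.92), followed by greedy label-switching to the
nearest local optimum; the best of `n_runs` restarts (default 100) is kept,
with ties broken towards fewer modules and then the lexicographically
smallest canonical labelling so that results are a deterministic function of
the seed. The single-module partition ($Q = 0$ exactly) is always an
implicit candidate, so the returned score is never negative. The annealing
inner loop is compiled (Rcpp) and uses R's RNG, keeping `set.seed()`
semantics. On every fixture small enough to enumerate exhaustively
(≤ 4 plants + 4 visitors, thousands of partitions), the search attains the
global optimum in ≥ 99 of 100 seeded runs — the regression suite re-checks
this.

Significance is assessed against randomized networks with exactly the
observed marginal totals, generated by Patefield's sequential hypergeometric
algorithm (`stats::r2dtable`). "Same degree distribution" is read as the
quantitative marginal totals, the standard choice for count networks; a
binary-degree-preserving alternative (curveball shuffles of the presence
structure with the observed weight multiset redistributed) is exposed for
sensitivity analysis. Each null network is maximized with its own restart
budget; reducing `null_runs` below `n_runs` saves time but biases null Q
downwards and therefore inflates the Z-score — the default keeps them equal,
and reduced budgets should be reported alongside results. The test is the
normal-approximation Z with two-sided p, plus the add-one empirical rank p.

## Module phenology

Module activity is the total visits received by a module's plants per census
day; profiles conserve daily network totals exactly. Each module's profile
is tested against uniform expected visits across census days with a one-way
chi-squared statistic whose p-value is Monte-Carlo (5,000 multinomial
replicates by default; the add-one rank estimator never returns exactly 0),
Holm-corrected across modules. The uniform null asks "is this module's
activity temporally structured at all?"; an activity-weighted null
(`expected = "network"`) instead asks whether a module's schedule differs
from the community's, and is the right comparison when overall sampling
effort varied.

Module membership is related to phenology with a baseline-category
multinomial logit on the start day of activity. The fit starts from
`nnet::multinom` and is polished by Newton–Raphson with step-halving until
the log-likelihood gradient max-norm is below $10^{-10}$; this makes the
likelihood-ratio statistic invariant to the choice of reference module
(a ridge penalty would break that invariance, so the default is the exact
MLE; `decay > 0` is available when stabilised coefficient paths are wanted).
The LR test compares against the intercept-only model, whose log-likelihood
is the closed form $\sum_k n_k \ln(n_k/n)$, with $df = K - 1$ for the single
predictor. Cleanly temporal modules produce quasi-complete separation; the
iteration cap keeps estimates finite and a `separation` flag marks such
fits, whose predicted probability curves are step-like but whose LR value
remains bounded by the null deviance. The predictor is centred internally
and coefficients are returned on the day-of-year scale.

## The season simulator

`simulate_season()` generates a season with known ground truth under the two
conceptual scenarios the pipeline is designed to discriminate:
`"concentrated"` (all activity windows centred on mid-season — one
synchronous flowering peak) and `"staggered"` (window centres clustered
around evenly spaced latent temporal guilds). Activity is a hard on/off
window per species; daily visits for a co-active pair are
Poisson(`base_rate` × `preference_strength` if the pair shares a guild).
Flowering censuses are emitted weekly and are positive exactly inside plant
windows.

Defaults are calibrated once to the study conditions the package targets:
17 plants and 105 visitors over 10 census days in a 45-day season, three
guilds, and window durations drawn Normal(26, 8) truncated to guild epochs
widened by `guild_overlap = 0.9` of an epoch on each side. After truncation
this realises observed activity windows of mean ≈ 20 days (SD ≈ 6) and mean
interspecific flowering overlap ≈ 0.37 — matching the short-bloom,
partial-overlap regime of Mediterranean alpine communities. With
`guild_overlap = 0` the guilds are temporally disjoint, which forces
complete cross-epoch turnover and is the configuration used for recovery
experiments. `recovery_experiment()` runs the full pipeline on one simulated
season and scores recovery: the replacement share of beta diversity, the
modularity Z-test, the adjusted Rand index between detected modules and true
guilds, and the LR p of the membership model.

What the simulator does *not* emulate: heterogeneity of link strength within
a guild (every co-active pair shares one Poisson rate, so simulated
cumulative networks are denser — more distinct links — than field networks
of comparable visit totals, which concentrate visits on a few strong links);
detection failure on census days; within-window intensity variation
(activity is flat inside the window; a smooth-bump option would lower edge
detectability); and multi-year dynamics. Passing recovery tests therefore
demonstrates the pipeline's correctness on clean temporal structure, not its
power under field-grade sparsity.

## Numerical choices and degenerate inputs

* Ties in Q between restarts: fewest modules, then lexicographically
  smallest canonical assignment.
* A 1×1 network has a single trivial module with Q = 0; its marginal-null
  fiber contains only the observed table, so the significance Z is
  undefined there and reported as an error naming the zero-variance
  condition.
* `beta_os` with no shared species (or shared species but no interactions
  among them) is `NA`.
* Monte-Carlo p-values use the add-one estimator and can never be 0; the
  smallest attainable value is $1/(B+1)$.
* OLS on a constant response reports $R^2 = 0$ (the summary ratio is
  numerically indeterminate there).
* Records with non-positive visit counts are rejected at read time — a
  recorded interaction must represent at least one visit.

## Problem sizes used by the shipped checks

The regression suite exercises the full pipeline at the calibrated default
season size (122 species, ten daily sub-networks). Exhaustive-enumeration
cross-checks of the modularity search run on networks up to 4 + 4 species
(4,140 partitions); the pooled recovery experiment uses 50 simulated seasons
per scenario with 30 observed restarts and 25 null networks × 10 restarts
each. These sizes keep the whole suite under a few minutes while leaving
every statistical conclusion at its stated confidence.

## Known limitations

* Dissimilarity regressions treat sub-network pairs as independent points;
  pairs sharing a census day are correlated, so reported p-values are
  anti-conservative in the way the plain-linear-model convention accepts.
* The marginal-preserving null follows the central hypergeometric
  distribution on the margin-fixed fiber (Patefield sampling), not the
  uniform distribution on that fiber.
* The modularity search optimises flat partitions; hierarchical module
  structure is out of scope.
* Binary-degree nulls redistribute the weight multiset independently of the
  shuffled topology, so they preserve binary degrees and total weight but
  not weighted marginals.
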