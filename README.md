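# phenonet

Within-season temporal dynamics of quantitative plant–flower visitor
networks.

A season-long pollination network — every visit of every insect to every
plant, summed into one plants × visitors count matrix — cannot say whether
its species actually co-occurred in time. In short flowering seasons
(alpine and Mediterranean-alpine communities especially), assemblages can
turn over completely within weeks, and apparent network structure may be a
shadow of phenology. `phenonet` is a toolkit for ecologists who sample one
community repeatedly across a flowering season and want to know how much of
the network's architecture phenology explains.

## What it computes

Given long-format visitation records (date, site, plant, visitor,
functional group, visits) and optional weekly flowering censuses:

* **Temporal sub-networks** — one quantitative bipartite network per census
  day (or per 2 census days, or ISO week), plus the cumulative season
  network and a species phenology table (activity start/end in
  days-since-1-January).
* **Beta-diversity partition** — season-wide Jaccard dissimilarity of the
  daily assemblages, split exactly into replacement and richness
  components, pooled over all pairs of days:
  β\_CC = (b+c)/(a+b+c), β\_3M = 2·min(b,c)/(a+b+c),
  β\_RICH = |b−c|/(a+b+c), with β\_CC = β\_3M + β\_RICH.
* **Pairwise network dissimilarity** — Whittaker dissimilarity
  β = (a+b+c)/((2a+b+c)/2) − 1 of species (β\_S), of interactions (β\_WN)
  and of interactions among shared species (β\_OS, the rewiring signal),
  with OLS fits against time lag and the lag at which interaction turnover
  is complete.
* **Flowering overlap** — S\_ij = a\_ij/b\_ij (shared flowering days over
  union days) for all plant pairs, regressed against the Jaccard
  dissimilarity of their visitor assemblages.
* **Quantitative modularity** — the weighted bipartite (Barber-type)
  objective Q = Σ\_ij (A\_ij/F − k\_i d\_j/F²)·δ(g\_i, g\_j), maximized by
  compiled simulated annealing with restarts, tested against
  marginal-preserving (Patefield) null networks with a Z-test.
* **Module phenology** — per-module activity profiles, Monte-Carlo
  chi-squared tests with Holm correction, and a multinomial logistic
  regression of module membership on activity start date with a
  likelihood-ratio chi-squared test and predicted membership curves.
* **A season simulator** — flowering seasons with known temporal guilds
  under "concentrated" vs "staggered" phenology scenarios, plus
  `recovery_experiment()` to score how well the whole pipeline recovers
  the planted truth.

## Worked example

```r
library(phenonet)

sim  <- simulate_season(season_config(seed = 42))   # staggered, 3 guilds
nets <- build_networks(sim$records)                 # daily sub-networks
cum  <- cumulative_network(sim$records)
phen <- build_phenology(sim$records, sim$flowering)

cum
#> <bipnet> cumulative: 17 plants x 105 visitors, F = 4623 visits, 1114 interactions

dplyr::bind_rows(multisite_beta(nets, "plants"), multisite_beta(nets, "visitors"))
#> # A tibble: 2 × 5
#>   guild    beta_cc beta_3m beta_rich n_units
#>   <chr>      <dbl>   <dbl>     <dbl>   <int>
#> 1 plants     0.664   0.388     0.276      10
#> 2 visitors   0.688   0.464     0.224      10
```

Two thirds of the season-wide compositional dissimilarity, and most of it
from species replacement (β\_3M > β\_RICH): assemblages are substituted
along the season rather than thinned. Interaction turnover rises with time
lag and saturates:

```r
pairs <- network_beta_pairs(nets)
beta_lag_fit(pairs, "beta_wn")
#> OLS fit (transform: log-lag)
#>   slope = 0.2823, intercept = 0.008422, R^2 = 0.838, p = 1.42e-18, n = 45
turnover_lag(pairs)
#> # A tibble: 1 × 2
#>     lag n_pairs_beyond
#>   <dbl>          <int>
#> 1    34              6
```

so sub-networks 34 or more days apart share no interaction at all. The
cumulative network is strongly modular against marginal-preserving nulls,
the modules are temporally structured, and start date of activity predicts
membership:

```r
sig <- modularity_significance(cum, n_runs = 50, n_null = 50,
                               null_runs = 10, seed = 42)
sig
#> Q = 0.4628 (3 modules) vs 50 nulls: mean 0.0869, sd 0.0029, z = 128.67,
#> p = 0 (empirical p = 0.0196)

prof <- module_activity(sig$partition, nets)
module_activity_tests(prof, seed = 42)
#> # A tibble: 3 × 7
#>   module  chi2    df     p_mc n_reps   p_holm significant
#> 1 M1     1247.     9 0.000200   5000 0.000600 TRUE
#> 2 M2     1228.     9 0.000200   5000 0.000600 TRUE
#> 3 M3     1176.     9 0.000200   5000 0.000600 TRUE

fitdf <- dplyr::inner_join(sig$partition$assignment,
                           dplyr::select(phen, species, start_day),
                           by = "species")
fit_multinomial(fitdf)
#> Multinomial module-membership model: 3 modules, n = 122
#>   LR chi2 = 241.11, df = 2, p = 4.4e-53
```

The detected modules are the simulator's three planted temporal guilds
(visible directly via `sim$truth`); `autoplot(fit_multinomial(fitdf))`,
`plot_module_activity(prof)` and `plot_beta_lag(pairs)` draw the
corresponding figures.

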