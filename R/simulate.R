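#' Configuration for a simulated flowering season
#'
#' Defines the conditions of one simulated site-season. Defaults emulate a
#' Mediterranean alpine flowering season: ~17 plant and ~105 flower-visitor
#' species sampled on 10 census days across a 45-day season, species activity
#' windows of mean ~20 days (SD ~7), and — under the `"staggered"` scenario —
#' three latent temporal guilds spread across the season with partial
#' inter-guild overlap, yielding mean interspecific flowering overlap around
#' 0.4. Under `"concentrated"`, all activity windows centre on mid-season and
#' guilds carry no temporal signal.
#'
#' @param n_plants,n_visitors Species counts.
#' @param n_census_days Number of census days, evenly spread over the season.
#' @param season_span_days Season length in days.
#' @param scenario `"staggered"` (temporally segregated guilds) or
#'   `"concentrated"` (one synchronous flowering peak).
#' @param n_guilds Number of latent temporal guilds (staggered scenario).
#' @param guild_overlap Fraction of a guild epoch by which activity windows
#'   may spill into neighbouring epochs; `0` makes guilds temporally disjoint.
#' @param mean_window,sd_window Mean and SD (days) of the normal activity
#'   window duration (truncated at 3 days and the season span).
#' @param base_rate Expected visits per active plant-visitor pair per census
#'   day.
#' @param preference_strength Poisson rate multiplier for within-guild pairs
#'   relative to cross-guild pairs (>= 1).
#' @param site Site label stamped on all emitted records.
#' @param season_start First day of the season (`Date` or string); day-of-year
#'   arithmetic uses this calendar.
#' @param flowering_census_every Days between flowering censuses.
#' @param seed Integer RNG seed; identical configs with the same seed
#'   reproduce records exactly.
#' @return A `season_config` list.
#' @export
season_config <- function(n_plants = 17, n_visitors = 105, n_census_days = 10,
                          season_span_days = 45,
                          scenario = c("staggered", "concentrated"),
                          n_guilds = 3, guild_overlap = 0.9,
                          mean_window = 26, sd_window = 8, base_rate = 0.35,
                          preference_strength = 4, site = "SIM",
                          season_start = as.Date("2015-06-14"),
                          flowering_census_every = 7, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_plants >= 1, n_visitors >= 1, n_census_days >= 1,
            season_span_days >= 1, n_guilds >= 1, mean_window > 0,
            base_rate > 0, preference_strength >= 1, guild_overlap >= 0)
  structure(list(
    n_plants = n_plants, n_visitors = n_visitors,
    n_census_days = n_census_days, season_span_days = season_span_days,
    scenario = scenario, n_guilds = n_guilds, guild_overlap = guild_overlap,
    mean_window = mean_window, sd_window = sd_window, base_rate = base_rate,
    preference_strength = preference_strength, site = site,
    season_start = as.Date(season_start),
    flowering_census_every = flowering_census_every, seed = as.integer(seed)
  ), class = "season_config")
}

functional_group_names <- c(
  "bees", "small_bees", "bumblebees", "butterflies", "hoverflies", "flies",
  "small_flies", "bee_flies", "beetles", "wasps", "others"
)

#' Simulate one flowering season with known ground truth
#'
#' Generates dated visitation records, weekly flowering censuses and the
#' latent truth (guilds and activity windows) under the configured scenario.
#' Species are active only inside hard on/off windows; for each census day
#' and each co-active plant-visitor pair, the visit count is drawn
#' \eqn{Poisson(base\_rate \cdot m)} with `m = preference_strength` for
#' within-guild pairs and 1 otherwise; zero counts emit no record. Under
#' `"staggered"`, window centres cluster around evenly spaced guild epochs and
#' windows are clipped to the epoch widened by `guild_overlap` on each side
#' (so `guild_overlap = 0` gives temporally disjoint guilds). Under
#' `"concentrated"`, all windows centre near mid-season.
#'
#' @param config A [season_config()].
#' @return A list of class `season_sim` with tibbles `records` (canonical
#'   interaction records), `flowering` (weekly census) and `truth`
#'   (`species, guild_role, true_guild, window_start, window_end` in
#'   day-of-season coordinates), plus the `config`.
#' @export
simulate_season <- function(config) {
  stopifnot(inherits(config, "season_config"))
  withr::with_seed(config$seed, simulate_season_impl(config))
}

simulate_season_impl <- function(cfg) {
  span <- cfg$season_span_days
  draw_windows <- function(n, role) {
    guild <- rep_len(seq_len(cfg$n_guilds), n)
    dur <- pmax(3, round(stats::rnorm(n, cfg$mean_window, cfg$sd_window)))
    dur <- pmin(dur, span)
    if (cfg$scenario == "concentrated") {
      center <- stats::rnorm(n, span / 2, span / 10)
      lo <- 1; hi <- span
      start <- pmax(lo, pmin(round(center - dur / 2), hi))
      end <- pmin(hi, start + dur - 1)
    } else {
      w <- span / cfg$n_guilds
      epoch_lo <- floor((guild - 1) * w) + 1
      epoch_hi <- floor(guild * w)
      lo <- pmax(1, round(epoch_lo - cfg$guild_overlap * w))
      hi <- pmin(span, round(epoch_hi + cfg$guild_overlap * w))
      center <- stats::rnorm(n, (epoch_lo + epoch_hi) / 2, w / 6)
      start <- pmax(lo, pmin(round(center - dur / 2), hi))
      end <- pmin(hi, start + dur - 1)
    }
    tibble::tibble(guild = guild, role = role,
                   start = as.integer(start), end = as.integer(pmax(end, start)))
  }

  plants <- draw_windows(cfg$n_plants, "plant") |>
    dplyr::mutate(species = sprintf("plant_%02d", dplyr::row_number()))
  visitors <- draw_windows(cfg$n_visitors, "visitor") |>
    dplyr::mutate(species = sprintf("visitor_%03d", dplyr::row_number()),
                  functional_group = rep_len(functional_group_names,
                                             cfg$n_visitors))

  census_offsets <- unique(round(seq(0, span - 1,
                                     length.out = cfg$n_census_days)))
  census_dates <- cfg$season_start + census_offsets

  grid <- tidyr::expand_grid(pi = seq_len(nrow(plants)),
                             vi = seq_len(nrow(visitors)),
                             ti = seq_along(census_offsets))
  pday <- census_offsets + 1 # day-of-season of each census
  active <- plants$start[grid$pi] <= pday[grid$ti] &
    pday[grid$ti] <= plants$end[grid$pi] &
    visitors$start[grid$vi] <= pday[grid$ti] &
    pday[grid$ti] <= visitors$end[grid$vi]
  grid <- grid[active, ]
  rate <- cfg$base_rate *
    ifelse(plants$guild[grid$pi] == visitors$guild[grid$vi],
           cfg$preference_strength, 1)
  visits <- stats::rpois(nrow(grid), rate)
  keep <- visits > 0
  if (!any(keep)) {
    stop("simulated season produced no visitation records; ",
         "increase base_rate or widen activity windows", call. = FALSE)
  }
  grid <- grid[keep, ]
  records <- tibble::tibble(
    date = census_dates[grid$ti],
    site = cfg$site,
    plant = plants$species[grid$pi],
    visitor = visitors$species[grid$vi],
    functional_group = visitors$functional_group[grid$vi],
    visits = as.integer(visits[keep])
  ) |>
    dplyr::arrange(.data$date, .data$plant, .data$visitor) |>
    dplyr::mutate(doy = as.integer(lubridate::yday(.data$date)))

  census_days <- seq(0, span - 1, by = cfg$flowering_census_every)
  fl_grid <- tidyr::expand_grid(pi = seq_len(nrow(plants)),
                                ci = seq_along(census_days))
  fday <- census_days + 1
  in_flower <- plants$start[fl_grid$pi] <= fday[fl_grid$ci] &
    fday[fl_grid$ci] <= plants$end[fl_grid$pi]
  n_flowering <- integer(nrow(fl_grid))
  n_flowering[in_flower] <- stats::rpois(sum(in_flower), 25) + 1L
  flowering <- tibble::tibble(
    date = cfg$season_start + census_days[fl_grid$ci],
    site = cfg$site,
    plant = plants$species[fl_grid$pi],
    n_flowering = n_flowering
  ) |>
    dplyr::arrange(.data$date, .data$plant) |>
    dplyr::mutate(doy = as.integer(lubridate::yday(.data$date)))

  truth <- dplyr::bind_rows(plants, visitors) |>
    dplyr::transmute(species = .data$species, guild_role = .data$role,
                     true_guild = .data$guild,
                     window_start = .data$start, window_end = .data$end)

  structure(list(records = records, flowering = flowering, truth = truth,
                 config = cfg), class = "season_sim")
}

#' @export
print.season_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated season (%s): %d records, %d plants, %d visitors, %d census days\n",
    x$config$scenario, nrow(x$records), length(unique(x$records$plant)),
    length(unique(x$records$visitor)), length(unique(x$records$date))))
  invisible(x)
}

#' Write a simulated season to canonical text files
#'
#' Emits `interactions.csv`, `flowering.csv`, `truth.csv` and `config.csv`
#' into a directory.
#'
#' @param sim A `season_sim` from [simulate_season()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_season <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_interactions(sim$records, file.path(dir, "interactions.csv"))
  write_flowering(sim$flowering, file.path(dir, "flowering.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  cfg <- sim$config
  cfg$season_start <- as.character(cfg$season_start)
  readr::write_csv(tibble::tibble(key = names(cfg),
                                  value = vapply(cfg, as.character,
                                                 character(1))),
                   file.path(dir, "config.csv"))
  invisible(dir)
}

#' End-to-end recovery experiment on one simulated season
#'
#' Runs the full pipeline on one simulated season and reports how well the
#' analysis recovers the simulator's ground truth: the replacement share of
#' overall beta diversity, modularity and its null-model significance, the
#' chance-corrected agreement (adjusted Rand index) between detected modules
#' and true temporal guilds, and the likelihood-ratio p of the
#' module-membership phenology model.
#'
#' @param config A [season_config()] (its `seed` drives the simulation; the
#'   analysis RNG derives from it).
#' @param n_runs Modularity restarts for the observed network.
#' @param n_null,null_runs Null-model budget for significance.
#' @return A one-row tibble: `scenario, seed, n_species, beta_cc, beta_3m,
#'   beta_rich, beta_3m_share, q, n_modules, z, modularity_p, guild_ari,
#'   lr_chi2, lr_p`.
#' @export
recovery_experiment <- function(config, n_runs = 30, n_null = 25,
                                null_runs = 10) {
  sim <- simulate_season(config)
  nets <- build_networks(sim$records, window = "day")
  cum <- cumulative_network(sim$records)
  phen <- build_phenology(sim$records, sim$flowering)

  beta <- multisite_beta(nets, guild = "both")
  sig <- modularity_significance(cum, n_runs = n_runs, n_null = n_null,
                                 null_runs = null_runs,
                                 seed = config$seed + 10000L)
  part <- sig$partition

  joined <- dplyr::inner_join(part$assignment, sim$truth,
                              by = "species")
  ari <- mclust::adjustedRandIndex(joined$module, joined$true_guild)

  fit_df <- dplyr::inner_join(part$assignment,
                              dplyr::select(phen, "species", "start_day"),
                              by = "species")
  mfit <- fit_multinomial(fit_df)

  tibble::tibble(
    scenario = config$scenario, seed = config$seed,
    n_species = nrow(part$assignment),
    beta_cc = beta$beta_cc, beta_3m = beta$beta_3m,
    beta_rich = beta$beta_rich,
    beta_3m_share = beta$beta_3m / beta$beta_cc,
    q = sig$q_obs, n_modules = part$n_modules, z = sig$z,
    modularity_p = sig$p_value,
    guild_ari = ari,
    lr_chi2 = mfit$lr_chi2, lr_p = mfit$p_value
  )
}
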