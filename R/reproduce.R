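#' Re-run the full within-season analysis on a deposited dataset
#'
#' Drives the whole pipeline on a directory holding one site's data in the
#' canonical file formats (`interactions.csv`, optionally `flowering.csv`):
#' daily sub-networks, the season-wide replacement/richness beta-diversity
#' partition for plants and visitors, pairwise dissimilarity-lag regressions,
#' modularity with null-model significance, and the module-membership
#' phenology model. Intended for reproducing published site analyses from an
#' archived deposit (use [read_dryad_records()] to map foreign column names
#' first).
#'
#' @param dir Directory containing `interactions.csv` and optionally
#'   `flowering.csv`.
#' @param site Site to filter on (default: all rows; must be a single site).
#' @param n_runs,n_null,null_runs,seed Modularity and null-model budget.
#' @return A list: `cumulative` (bipnet), `networks` (tibble),
#'   `beta_partition` (tibble with plant and visitor rows), `pairs` (pairwise
#'   beta table), `lag_fits` (list of `pheno_ols`), `turnover` (tibble),
#'   `significance` (`modularity_significance`), `multinomial`
#'   (`module_multinom`), `summary` (one-row tibble of headline numbers).
#' @export
reproduce_deposited_analysis <- function(dir, site = NULL, n_runs = 100,
                                         n_null = 100, null_runs = 20,
                                         seed = 1L) {
  ipath <- file.path(dir, "interactions.csv")
  records <- read_interactions(ipath)
  if (!is.null(site)) records <- dplyr::filter(records, .data$site == !!site)
  if (nrow(records) == 0) stop("no records for site", call. = FALSE)
  fpath <- file.path(dir, "flowering.csv")
  flowering <- if (file.exists(fpath)) {
    fl <- read_flowering(fpath)
    if (!is.null(site)) fl <- dplyr::filter(fl, .data$site == !!site)
    fl
  } else NULL

  nets <- build_networks(records, window = "day")
  cum <- cumulative_network(records)
  phen <- build_phenology(records, flowering)

  beta_partition <- dplyr::bind_rows(
    multisite_beta(nets, "plants"),
    multisite_beta(nets, "visitors")
  )
  pairs <- network_beta_pairs(nets)
  lag_fits <- list(
    beta_s = beta_lag_fit(pairs, "beta_s", transform = "none"),
    beta_wn = beta_lag_fit(pairs, "beta_wn", transform = "log-lag")
  )
  turnover <- turnover_lag(pairs)

  sig <- modularity_significance(cum, n_runs = n_runs, n_null = n_null,
                                 null_runs = null_runs, seed = seed)
  part <- maximize_modularity(cum, n_runs = n_runs, seed = seed,
                              phenology = phen)
  fit_df <- dplyr::inner_join(part$assignment,
                              dplyr::select(phen, "species", "start_day"),
                              by = "species")
  mfit <- fit_multinomial(fit_df)

  summary <- tibble::tibble(
    n_plants = nrow(cum), n_visitors = ncol(cum),
    n_visits = sum(cum), n_interactions = sum(cum > 0),
    n_subnetworks = nrow(nets),
    q = part$q, n_modules = part$n_modules,
    z = sig$z, modularity_p = sig$p_value,
    lr_chi2 = mfit$lr_chi2, lr_df = mfit$df, lr_p = mfit$p_value,
    turnover_lag = turnover$lag
  )
  list(cumulative = cum, networks = nets, beta_partition = beta_partition,
       pairs = pairs, lag_fits = lag_fits, turnover = turnover,
       significance = sig, multinomial = mfit, summary = summary)
}
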