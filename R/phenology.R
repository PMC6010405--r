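#' Build the species phenology table
#'
#' Derives, for every plant and flower-visitor species of one site, the start
#' and end of its activity period as day-of-year integers (days since
#' 1 January, with 1 Jan = day 1):
#' \itemize{
#'   \item plants: the union of flowering-census evidence (census dates with
#'     `n_flowering > 0`) and interaction evidence (dates on which the plant
#'     received visits). The earliest of either defines the start of activity.
#'   \item visitors: interaction evidence only — activity starts on the day the
#'     first individual was observed on a flower.
#' }
#'
#' When interaction evidence extends a plant's activity beyond what the
#' (weekly, hence coarser) flowering census recorded, the row is flagged in
#' `source`. Use `plant_evidence = "census"` to restrict plant phenology to the
#' flowering census alone.
#'
#' @param records Interaction records tibble (single site).
#' @param flowering Optional flowering-census tibble for the same site.
#' @param plant_evidence `"union"` (default) or `"census"`.
#' @return A tibble with one row per species: `species`, `guild`
#'   (`"plant"`/`"visitor"`), `start_day`, `end_day`, `duration`
#'   (`end - start + 1`), `active_days` (list of day-of-year integers) and
#'   `source` (`"interaction"`, `"census"`, `"both"`, or
#'   `"both_interaction_extends"` when visits fall outside the censused
#'   flowering period). Species named in the flowering census but never seen
#'   active anywhere are dropped with a warning.
#' @export
build_phenology <- function(records, flowering = NULL,
                            plant_evidence = c("union", "census")) {
  plant_evidence <- match.arg(plant_evidence)
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  check_single_site(records)
  if (!is.null(flowering) && nrow(flowering) > 0) {
    check_single_site(flowering)
    if (unique(flowering$site) != unique(records$site)) {
      stop("records and flowering censuses come from different sites", call. = FALSE)
    }
  }

  visitor_days <- records |>
    dplyr::group_by(species = .data$visitor) |>
    dplyr::summarise(active_days = list(sort(unique(.data$doy))), .groups = "drop") |>
    dplyr::mutate(guild = "visitor", source = "interaction")

  plant_visit_days <- records |>
    dplyr::group_by(species = .data$plant) |>
    dplyr::summarise(visit_days = list(sort(unique(.data$doy))), .groups = "drop")

  if (!is.null(flowering) && nrow(flowering) > 0) {
    census_days <- flowering |>
      dplyr::filter(.data$n_flowering > 0) |>
      dplyr::group_by(species = .data$plant) |>
      dplyr::summarise(census_days = list(sort(unique(.data$doy))), .groups = "drop")
    never_active <- setdiff(unique(flowering$plant),
                            c(census_days$species, plant_visit_days$species))
    if (length(never_active) > 0) {
      warning("species with no recorded activity dropped from phenology: ",
              paste(never_active, collapse = ", "), call. = FALSE)
    }
  } else {
    census_days <- tibble::tibble(species = character(), census_days = list())
  }

  plants <- dplyr::full_join(plant_visit_days, census_days, by = "species")
  fill_null <- function(x) purrr::map(x, ~ if (is.null(.x)) integer() else .x)
  plants$visit_days <- fill_null(plants$visit_days)
  plants$census_days <- fill_null(plants$census_days)
  if (plant_evidence == "census") {
    plants <- dplyr::filter(plants, purrr::map_int(.data$census_days, length) > 0)
  }
  plants <- plants |>
    dplyr::mutate(
      active_days = if (plant_evidence == "census") .data$census_days else
        purrr::map2(.data$visit_days, .data$census_days, ~ sort(union(.x, .y))),
      source = purrr::map2_chr(.data$visit_days, .data$census_days, function(v, cns) {
        if (length(cns) == 0) return("interaction")
        if (length(v) == 0) return("census")
        if (min(v) < min(cns) || max(v) > max(cns)) "both_interaction_extends"
        else "both"
      }),
      guild = "plant"
    ) |>
    dplyr::select("species", "active_days", "guild", "source")

  out <- dplyr::bind_rows(plants, visitor_days) |>
    dplyr::mutate(
      start_day = purrr::map_int(.data$active_days, ~ as.integer(min(.x))),
      end_day = purrr::map_int(.data$active_days, ~ as.integer(max(.x))),
      duration = .data$end_day - .data$start_day + 1L
    ) |>
    dplyr::select("species", "guild", "start_day", "end_day", "duration",
                  "active_days", "source") |>
    dplyr::arrange(.data$guild, .data$species)
  out
}
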