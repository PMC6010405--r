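#' Read dated visitation records
#'
#' Reads a delimited text file of plant-flower visitor visitation records into
#' the canonical long format used throughout the package: one row per dated,
#' weighted visitation batch. Comma and tab delimiters are auto-detected.
#'
#' The required header is `date,site,plant,visitor,functional_group,visits`
#' with ISO-8601 (`YYYY-MM-DD`) dates. Rows with a missing, zero or negative
#' visit count are rejected with an error naming the offending row, because a
#' recorded interaction must represent at least one visit.
#'
#' @param path Path to a delimited text file (UTF-8).
#' @return A tibble with columns `date` (Date), `site`, `plant`, `visitor`,
#'   `functional_group` (character) and `visits` (integer), plus `doy`, the
#'   day-of-year (days since 1 January, 1 Jan = day 1) used for all
#'   phenological arithmetic.
#' @seealso [read_flowering()], [write_interactions()], [simulate_season()]
#' @export
read_interactions <- function(path) {
  df <- read_delim_auto(path)
  required <- c("date", "site", "plant", "visitor", "functional_group", "visits")
  df <- check_columns(df, required, path)
  df <- parse_record_dates(df, path)
  bad <- which(is.na(df$visits) | df$visits < 1)
  if (length(bad) > 0) {
    stop("interaction file '", path, "': rows with missing or non-positive ",
         "visit counts (first offending data row: ", bad[1], ")", call. = FALSE)
  }
  check_labels(df, c("site", "plant", "visitor"))
  tibble::tibble(
    date = df$date,
    site = as.character(df$site),
    plant = as.character(df$plant),
    visitor = as.character(df$visitor),
    functional_group = as.character(df$functional_group),
    visits = as.integer(df$visits),
    doy = as.integer(lubridate::yday(df$date))
  )
}

#' Read weekly flowering-census records
#'
#' Reads a delimited text file of flowering censuses (one row per census date,
#' site and plant species, with the number of flowering individuals counted).
#' Header: `date,site,plant,n_flowering`; zero counts are legitimate (a species
#' censused but not in flower).
#'
#' @inheritParams read_interactions
#' @return A tibble with columns `date`, `site`, `plant`, `n_flowering`, `doy`.
#' @export
read_flowering <- function(path) {
  df <- read_delim_auto(path)
  df <- check_columns(df, c("date", "site", "plant", "n_flowering"), path)
  df <- parse_record_dates(df, path)
  if (any(is.na(df$n_flowering) | df$n_flowering < 0)) {
    stop("flowering file '", path, "': n_flowering must be a non-negative count",
         call. = FALSE)
  }
  check_labels(df, c("site", "plant"))
  tibble::tibble(
    date = df$date,
    site = as.character(df$site),
    plant = as.character(df$plant),
    n_flowering = as.integer(df$n_flowering),
    doy = as.integer(lubridate::yday(df$date))
  )
}

#' Write visitation records to delimited text
#'
#' Inverse of [read_interactions()]: writing then reading reproduces the
#' records exactly.
#'
#' @param records A tibble of interaction records.
#' @param path Output file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(records, path, delim = ",") {
  out <- dplyr::select(records, "date", "site", "plant", "visitor",
                       "functional_group", "visits")
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Write flowering-census records to delimited text
#' @inheritParams write_interactions
#' @param flowering A tibble of flowering-census records.
#' @export
write_flowering <- function(flowering, path, delim = ",") {
  out <- dplyr::select(flowering, "date", "site", "plant", "n_flowering")
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Load records deposited in a foreign column layout
#'
#' A thin shim for archived datasets (e.g. a Dryad deposit) whose files carry
#' the same information under different column names. The mapping file is a
#' two-column delimited text file with header `from,to`, where `to` names the
#' canonical columns (`date`, `site`, `plant`, `visitor`, `functional_group`,
#' `visits` for interaction files; `date`, `site`, `plant`, `n_flowering` for
#' flowering files).
#'
#' @param path Path to the deposited data file.
#' @param mapping Path to the `from,to` column-mapping file.
#' @param schema `"interactions"` or `"flowering"`.
#' @return A canonical records tibble, as from [read_interactions()] or
#'   [read_flowering()].
#' @export
read_dryad_records <- function(path, mapping,
                               schema = c("interactions", "flowering")) {
  schema <- match.arg(schema)
  map <- read_delim_auto(mapping)
  map <- check_columns(map, c("from", "to"), mapping)
  df <- read_delim_auto(path)
  missing_from <- setdiff(map$from, names(df))
  if (length(missing_from) > 0) {
    stop("mapped column(s) absent from '", path, "': ",
         paste(missing_from, collapse = ", "), call. = FALSE)
  }
  names(df)[match(map$from, names(df))] <- map$to
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  readr::write_csv(df, tmp)
  switch(schema,
         interactions = read_interactions(tmp),
         flowering = read_flowering(tmp))
}

# --- internal helpers ---------------------------------------------------------

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0) stop("empty file: ", path, call. = FALSE)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, col_types = readr::cols(.default = "c"))
  if (nrow(df) == 0) stop("file has a header but no data rows: ", path, call. = FALSE)
  df
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (cl in intersect(c("visits", "n_flowering"), required)) {
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  }
  df
}

parse_record_dates <- function(df, path) {
  parsed <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(parsed))
  if (length(bad) > 0) {
    stop("file '", path, "': unparseable date '", df$date[bad[1]],
         "' at data row ", bad[1], " (expected YYYY-MM-DD)", call. = FALSE)
  }
  df$date <- parsed
  df
}

check_labels <- function(df, cols) {
  for (cl in cols) {
    if (any(is.na(df[[cl]]) | !nzchar(df[[cl]]))) {
      stop("column '", cl, "' contains empty labels", call. = FALSE)
    }
  }
  invisible(df)
}

check_single_site <- function(records) {
  sites <- unique(records$site)
  if (length(sites) > 1) {
    stop("records span multiple sites (", paste(sites, collapse = ", "),
         "); analyses are strictly per-site — filter first", call. = FALSE)
  }
  invisible(records)
}
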