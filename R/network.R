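#' Weighted bipartite network
#'
#' The canonical container for a quantitative plant-flower visitor network:
#' a plants x visitors matrix of non-negative integer visit counts, with the
#' plants on rows and visitors on columns. Every row and every column has at
#' least one positive entry — species appear in a network only if they were
#' active in the window it covers.
#'
#' @param weights Numeric matrix of visit counts with rownames (plants) and
#'   colnames (visitors).
#' @param label Free-text label (a census date, `"cumulative"`, ...).
#' @param date Representative date of the window (used for time lags), or `NA`.
#' @return An object of class `bipnet`: the weight matrix plus attributes
#'   `label`, `date`. Total weight `F`, row marginals `k` and column marginals
#'   `d` are available via [net_totals()].
#' @export
bipnet <- function(weights, label = "", date = as.Date(NA)) {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights)) || is.null(colnames(weights))) {
    stop("bipnet weights need plant rownames and visitor colnames", call. = FALSE)
  }
  if (any(weights < 0) || any(is.na(weights))) {
    stop("bipnet weights must be non-negative counts", call. = FALSE)
  }
  if (sum(weights) < 1) stop("bipnet must contain at least one visit", call. = FALSE)
  if (any(rowSums(weights) == 0) || any(colSums(weights) == 0)) {
    stop("every plant (row) and visitor (column) must have at least one visit",
         call. = FALSE)
  }
  structure(weights, label = label, date = date, class = c("bipnet", "matrix"))
}

#' @export
print.bipnet <- function(x, ...) {
  cat("<bipnet> ", attr(x, "label"), ": ", nrow(x), " plants x ", ncol(x),
      " visitors, F = ", sum(x), " visits, ",
      sum(x > 0), " interactions\n", sep = "")
  invisible(x)
}

#' Marginal totals of a bipartite network
#'
#' @param net A [bipnet()].
#' @return A list with `F` (total visits), `k` (per-plant totals) and `d`
#'   (per-visitor totals).
#' @export
net_totals <- function(net) {
  list(F = sum(net), k = rowSums(net), d = colSums(net))
}

#' Interactions of a network as plant-visitor pairs
#'
#' @param net A [bipnet()].
#' @return Character vector of `"plant||visitor"` keys for the cells with a
#'   positive count; used as the interaction identity in dissimilarity
#'   calculations (no weight threshold is applied).
#' @export
interaction_set <- function(net) {
  idx <- which(net > 0, arr.ind = TRUE)
  paste(rownames(net)[idx[, 1]], colnames(net)[idx[, 2]], sep = "||")
}

#' Species labels of a network
#' @param net A [bipnet()].
#' @param guild `"both"` (default), `"plants"` or `"visitors"`.
#' @return Character vector of labels. Plants and visitors occupy disjoint
#'   namespaces in this package, so the pooled union is well-defined.
#' @export
species_set <- function(net, guild = c("both", "plants", "visitors")) {
  guild <- match.arg(guild)
  switch(guild,
         both = c(rownames(net), colnames(net)),
         plants = rownames(net),
         visitors = colnames(net))
}

records_to_matrix <- function(records) {
  agg <- dplyr::summarise(
    dplyr::group_by(records, .data$plant, .data$visitor),
    visits = sum(.data$visits), .groups = "drop"
  )
  plants <- sort(unique(agg$plant))
  visitors <- sort(unique(agg$visitor))
  w <- matrix(0L, length(plants), length(visitors),
              dimnames = list(plants, visitors))
  w[cbind(match(agg$plant, plants), match(agg$visitor, visitors))] <-
    as.integer(agg$visits)
  w
}

#' Cumulative season network
#'
#' Sums all visitation records of one site over the whole flowering season
#' into a single quantitative bipartite network.
#'
#' @param records Interaction records tibble (single site).
#' @return A [bipnet()] labelled `"cumulative"`.
#' @export
cumulative_network <- function(records) {
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  check_single_site(records)
  bipnet(records_to_matrix(records), label = "cumulative",
         date = min(records$date))
}

#' Break records into time-aggregated sub-networks
#'
#' Partitions one site's visitation records into temporal windows and builds
#' one quantitative sub-network per non-empty window, in chronological order.
#' Windows:
#' \describe{
#'   \item{`"day"`}{one sub-network per census day (the default; the unit of
#'     all within-season dissimilarity analyses).}
#'   \item{`"2day"`}{consecutive census days paired chronologically
#'     ((1,2), (3,4), ...; a trailing odd day forms its own window).}
#'   \item{`"week"`}{ISO calendar weeks of the census dates.}
#' }
#'
#' @param records Interaction records tibble (single site).
#' @param window `"day"`, `"2day"` or `"week"`.
#' @return A tibble with one row per window: `window_id`, `date` (first census
#'   date in the window), `n_days` (census days covered) and `network`
#'   (list-column of [bipnet()] objects).
#' @export
build_networks <- function(records, window = c("day", "2day", "week")) {
  window <- match.arg(window)
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  check_single_site(records)
  days <- sort(unique(records$date))
  grp <- switch(window,
    day = stats::setNames(seq_along(days), as.character(days)),
    `2day` = stats::setNames(ceiling(seq_along(days) / 2), as.character(days)),
    week = {
      wk <- paste0(lubridate::isoyear(days), "-W",
                   sprintf("%02d", lubridate::isoweek(days)))
      stats::setNames(match(wk, unique(wk)), as.character(days))
    })
  records$.win <- grp[as.character(records$date)]
  split_recs <- split(records, records$.win)
  nets <- purrr::map(split_recs, function(r) {
    bipnet(records_to_matrix(r), label = as.character(min(r$date)),
           date = min(r$date))
  })
  tibble::tibble(
    window_id = seq_along(nets),
    date = as.Date(unname(purrr::map_vec(split_recs, ~ min(.x$date)))),
    n_days = unname(purrr::map_int(split_recs, ~ length(unique(.x$date)))),
    network = unname(nets)
  )
}

#' Export a network as a rectangular matrix file
#'
#' Tab-separated text: first row visitor labels, first column plant labels.
#'
#' @param net A [bipnet()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  df <- tibble::as_tibble(as.data.frame.matrix(unclass(net)), rownames = "plant")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a rectangular matrix file written by [write_network()]
#' @param path Input path.
#' @param label,date Passed to [bipnet()].
#' @return A [bipnet()].
#' @export
read_network <- function(path, label = "", date = as.Date(NA)) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  bipnet(m, label = label, date = date)
}

#' Export a network as an edge list
#'
#' Writes `plant,visitor,weight` rows for the positive cells.
#'
#' @inheritParams write_network
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  idx <- which(net > 0, arr.ind = TRUE)
  df <- tibble::tibble(
    plant = rownames(net)[idx[, 1]],
    visitor = colnames(net)[idx[, 2]],
    weight = net[idx]
  )
  readr::write_csv(dplyr::arrange(df, .data$plant, .data$visitor), path)
  invisible(path)
}
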