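#' Shared/unique decomposition of two sets
#'
#' Counts the elements shared between two assemblages (`a`), unique to the
#' first (`b`) and unique to the second (`c`). Elements may be species labels
#' or plant-visitor interaction keys.
#'
#' @param set_a,set_b Vectors of elements (duplicates ignored).
#' @return A named list `list(a, b, c)`.
#' @export
shared_unique <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) == 0 && length(set_b) == 0) {
    stop("both sets are empty: dissimilarity is undefined", call. = FALSE)
  }
  a <- length(intersect(set_a, set_b))
  list(a = a, b = length(set_a) - a, c = length(set_b) - a)
}

#' Whittaker dissimilarity of two assemblages
#'
#' The measure used for all pairwise network comparisons:
#' \deqn{\beta = \frac{a+b+c}{(2a+b+c)/2} - 1 = \frac{b+c}{2a+b+c}}
#' where `a` elements are shared and `b`, `c` are unique to either assemblage.
#' It is 0 for identical sets and 1 for perfectly non-overlapping sets.
#'
#' @param counts A list with components `a`, `b`, `c`, as from
#'   [shared_unique()].
#' @return Dissimilarity in \[0, 1\].
#' @export
whittaker_beta <- function(counts) {
  with(counts, {
    if (a + b + c == 0) stop("a = b = c = 0: dissimilarity undefined", call. = FALSE)
    (a + b + c) / ((2 * a + b + c) / 2) - 1
  })
}

#' Pairwise Jaccard dissimilarity with replacement/richness partition
#'
#' Partitions overall Jaccard dissimilarity into the component due to species
#' replacement (substitution of some species by others between the two units)
#' and the component due to richness difference (one unit holding a nested
#' subset of the other):
#' \deqn{\beta_{CC} = \frac{b+c}{a+b+c},\quad
#'       \beta_{3M} = \frac{2\min(b,c)}{a+b+c},\quad
#'       \beta_{RICH} = \frac{|b-c|}{a+b+c}}
#' with \eqn{\beta_{CC} = \beta_{3M} + \beta_{RICH}} exactly.
#'
#' @inheritParams whittaker_beta
#' @return A named list `list(beta_cc, beta_3m, beta_rich)`.
#' @export
jaccard_partition_pairwise <- function(counts) {
  with(counts, {
    tot <- a + b + c
    if (tot == 0) stop("a = b = c = 0: dissimilarity undefined", call. = FALSE)
    list(beta_cc = (b + c) / tot,
         beta_3m = 2 * min(b, c) / tot,
         beta_rich = abs(b - c) / tot)
  })
}

#' Multiple-site Jaccard partition over a season of assemblages
#'
#' Extends the pairwise replacement/richness partition to a series of
#' assemblages (here: the species active in each daily sub-network) by pooling
#' the shared/unique counts over all unordered pairs:
#' \deqn{\beta_{CC} = \frac{\sum_{i<j}(b_{ij}+c_{ij})}{\sum_{i<j}(a_{ij}+b_{ij}+c_{ij})}}
#' and analogously for \eqn{\beta_{3M}} (with \eqn{2\min(b_{ij},c_{ij})}) and
#' \eqn{\beta_{RICH}} (with \eqn{|b_{ij}-c_{ij}|}). Additivity
#' \eqn{\beta_{CC}=\beta_{3M}+\beta_{RICH}} holds exactly, and with two
#' assemblages the result equals [jaccard_partition_pairwise()].
#'
#' @param assemblages List (length >= 2) of element vectors, in temporal order.
#' @return A one-row tibble: `beta_cc`, `beta_3m`, `beta_rich`, `n_units`.
#' @export
multisite_jaccard_partition <- function(assemblages) {
  if (length(assemblages) < 2) {
    stop("need at least 2 assemblages", call. = FALSE)
  }
  if (any(lengths(lapply(assemblages, unique)) == 0)) {
    stop("assemblages must be non-empty", call. = FALSE)
  }
  pairs <- utils::combn(length(assemblages), 2)
  num_cc <- num_3m <- num_rich <- den <- 0
  for (p in seq_len(ncol(pairs))) {
    cts <- shared_unique(assemblages[[pairs[1, p]]], assemblages[[pairs[2, p]]])
    num_cc <- num_cc + cts$b + cts$c
    num_3m <- num_3m + 2 * min(cts$b, cts$c)
    num_rich <- num_rich + abs(cts$b - cts$c)
    den <- den + cts$a + cts$b + cts$c
  }
  tibble::tibble(beta_cc = num_cc / den, beta_3m = num_3m / den,
                 beta_rich = num_rich / den, n_units = length(assemblages))
}

#' Season-wide beta-diversity partition from sub-networks
#'
#' Convenience wrapper applying [multisite_jaccard_partition()] to the plant
#' assemblages, the flower-visitor assemblages, or the pooled species sets of
#' a series of time-aggregated sub-networks.
#'
#' @param networks A networks tibble from [build_networks()] (or a list of
#'   [bipnet()] objects).
#' @param guild `"plants"`, `"visitors"` or `"both"`.
#' @return A one-row tibble: `guild`, `beta_cc`, `beta_3m`, `beta_rich`,
#'   `n_units`.
#' @export
multisite_beta <- function(networks, guild = c("plants", "visitors", "both")) {
  guild <- match.arg(guild)
  nets <- as_net_list(networks)
  sets <- purrr::map(nets, species_set, guild = guild)
  dplyr::bind_cols(tibble::tibble(guild = guild),
                   multisite_jaccard_partition(sets))
}

#' Pairwise network dissimilarity decomposition
#'
#' For one pair of time-aggregated networks, computes the Whittaker
#' dissimilarity of species composition (`beta_s`, over the pooled plant and
#' visitor labels), of interactions (`beta_wn`, over plant-visitor pairs), and
#' of interactions among the species shared by both networks (`beta_os`, the
#' rewiring signal). `beta_st = beta_wn - beta_os` is the part of interaction
#' dissimilarity attributable to species turnover. All dissimilarities use
#' binary presence; weights are ignored.
#'
#' `beta_os` is `NA` when the two networks share no species (it is then
#' undefined); such pairs are excluded from any regression on `beta_os`.
#'
#' @param net_a,net_b [bipnet()] objects.
#' @return A one-row tibble: `time_lag` (days, `NA` if either date is unknown),
#'   `beta_s`, `beta_wn`, `beta_os`, `beta_st`.
#' @export
network_beta <- function(net_a, net_b) {
  s <- whittaker_beta(shared_unique(species_set(net_a), species_set(net_b)))
  wn <- whittaker_beta(shared_unique(interaction_set(net_a), interaction_set(net_b)))
  shared_p <- intersect(rownames(net_a), rownames(net_b))
  shared_v <- intersect(colnames(net_a), colnames(net_b))
  restrict <- function(net) {
    idx <- which(net > 0, arr.ind = TRUE)
    keep <- rownames(net)[idx[, 1]] %in% shared_p &
      colnames(net)[idx[, 2]] %in% shared_v
    paste(rownames(net)[idx[keep, 1]], colnames(net)[idx[keep, 2]], sep = "||")
  }
  ia <- restrict(net_a)
  ib <- restrict(net_b)
  os <- if ((length(shared_p) + length(shared_v)) == 0 ||
            (length(ia) + length(ib)) == 0) NA_real_ else {
    whittaker_beta(shared_unique(ia, ib))
  }
  lag <- as.numeric(abs(difftime(attr(net_a, "date"), attr(net_b, "date"),
                                 units = "days")))
  tibble::tibble(time_lag = lag, beta_s = s, beta_wn = wn,
                 beta_os = os, beta_st = wn - os)
}

#' All pairwise network dissimilarities of a season
#'
#' Applies [network_beta()] to every unordered pair of sub-networks.
#'
#' @param networks A networks tibble from [build_networks()].
#' @return A tibble with one row per pair: `unit_a`, `unit_b` (labels),
#'   `time_lag`, `beta_s`, `beta_wn`, `beta_os`, `beta_st`.
#' @export
network_beta_pairs <- function(networks) {
  nets <- as_net_list(networks)
  if (length(nets) < 2) stop("need at least 2 sub-networks", call. = FALSE)
  pairs <- utils::combn(length(nets), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    dplyr::bind_cols(
      tibble::tibble(unit_a = attr(nets[[i]], "label"),
                     unit_b = attr(nets[[j]], "label")),
      network_beta(nets[[i]], nets[[j]])
    )
  })
}

#' Flowering overlap between two plant species
#'
#' The overlap index \eqn{S_{ij} = a_{ij}/b_{ij}}, where \eqn{a_{ij}} is the
#' number of days both species are in flower and \eqn{b_{ij}} the number of
#' days at least one is. Because weekly censuses undersample daily activity,
#' each species' flowering days are taken as the full interval from its first
#' to its last active day, filled daily.
#'
#' @param phenology Phenology tibble from [build_phenology()].
#' @param species_i,species_j Plant labels present in `phenology`.
#' @return A one-row tibble: `species_i`, `species_j`, `a_ij`, `b_ij`, `s_ij`.
#' @export
flowering_overlap <- function(phenology, species_i, species_j) {
  row_of <- function(sp) {
    r <- phenology[phenology$species == sp & phenology$guild == "plant", ]
    if (nrow(r) == 0) stop("unknown plant species: ", sp, call. = FALSE)
    r
  }
  di <- with(row_of(species_i), seq(start_day, end_day))
  dj <- with(row_of(species_j), seq(start_day, end_day))
  a <- length(intersect(di, dj))
  b <- length(union(di, dj))
  tibble::tibble(species_i = species_i, species_j = species_j,
                 a_ij = a, b_ij = b, s_ij = a / b)
}

#' Flowering overlap for all plant pairs
#'
#' @param phenology Phenology tibble from [build_phenology()].
#' @return A tibble with one row per unordered plant pair, as in
#'   [flowering_overlap()].
#' @export
flowering_overlap_pairs <- function(phenology) {
  plants <- phenology$species[phenology$guild == "plant"]
  if (length(plants) < 2) stop("need at least 2 plants", call. = FALSE)
  pairs <- utils::combn(plants, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    flowering_overlap(phenology, pairs[1, p], pairs[2, p])
  })
}

#' Dissimilarity of flower-visitor assemblages between two plants
#'
#' Jaccard dissimilarity \eqn{1 - |V_i \cap V_j| / |V_i \cup V_j|} of the sets
#' of visitor species recorded on each plant in the cumulative network.
#'
#' @param cumulative Cumulative [bipnet()] of the site.
#' @param plant_i,plant_j Plant labels.
#' @return Dissimilarity in \[0, 1\].
#' @export
visitor_assemblage_dissimilarity <- function(cumulative, plant_i, plant_j) {
  for (p in c(plant_i, plant_j)) {
    if (!p %in% rownames(cumulative)) stop("unknown plant: ", p, call. = FALSE)
  }
  vi <- colnames(cumulative)[cumulative[plant_i, ] > 0]
  vj <- colnames(cumulative)[cumulative[plant_j, ] > 0]
  1 - length(intersect(vi, vj)) / length(union(vi, vj))
}

#' Visitor-assemblage dissimilarity for all plant pairs
#'
#' @param cumulative Cumulative [bipnet()].
#' @return A tibble: `species_i`, `species_j`, `dissimilarity`.
#' @export
visitor_dissimilarity_pairs <- function(cumulative) {
  plants <- rownames(cumulative)
  if (length(plants) < 2) stop("need at least 2 plants", call. = FALSE)
  pairs <- utils::combn(plants, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    tibble::tibble(
      species_i = pairs[1, p], species_j = pairs[2, p],
      dissimilarity = visitor_assemblage_dissimilarity(cumulative,
                                                       pairs[1, p], pairs[2, p])
    )
  })
}

as_net_list <- function(networks) {
  if (inherits(networks, "bipnet")) return(list(networks))
  if (is.data.frame(networks)) return(networks$network)
  networks
}
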