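#' Weighted bipartite (Barber-type) modularity of a partition
#'
#' For a quantitative bipartite network with count matrix \eqn{A}, total
#' weight \eqn{F}, plant totals \eqn{k_i} and visitor totals \eqn{d_j},
#' the modularity of a partition \eqn{g} of all species into modules is
#' \deqn{Q = \sum_{ij}\left(\frac{A_{ij}}{F} -
#'       \frac{k_i d_j}{F^2}\right)\,\delta(g_i, g_j).}
#' Interactions concentrated within modules beyond the marginal expectation
#' give \eqn{Q > 0}; the single-module partition gives \eqn{Q = 0} exactly.
#'
#' @param net A [bipnet()].
#' @param assignment Named vector (or list) mapping every plant and visitor
#'   label of `net` to a module identifier.
#' @return The modularity score, a scalar \eqn{\le 1}.
#' @export
modularity_q <- function(net, assignment) {
  assignment <- unlist(assignment)
  labs <- c(rownames(net), colnames(net))
  missing <- setdiff(labs, names(assignment))
  if (length(missing) > 0) {
    stop("species missing from assignment: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  B <- modularity_matrix(net)
  gp <- assignment[rownames(net)]
  gv <- assignment[colnames(net)]
  sum(B * outer(gp, gv, "=="))
}

modularity_matrix <- function(net) {
  tot <- net_totals(net)
  unclass(net) / tot$F - outer(tot$k, tot$d) / tot$F^2
}

#' Maximize quantitative bipartite modularity
#'
#' Stochastic search for the partition of plants and flower visitors that
#' maximizes the weighted Barber modularity [modularity_q()]. Each restart
#' anneals single-species relabel moves from a random initial partition
#' (geometric cooling), then greedily polishes to a local optimum; the
#' best-scoring partition over all restarts is kept. Because any one run may
#' stall in a local optimum, use on the order of 100 restarts for final
#' results. Ties in Q are broken towards fewer modules, then towards the
#' lexicographically smallest canonical assignment, so results are
#' deterministic given `seed`.
#'
#' Modules are relabelled `M1, M2, ...`: by increasing earliest member start
#' day when a `phenology` table is supplied, otherwise by first member in
#' row/column order.
#'
#' @param net A [bipnet()].
#' @param n_runs Number of random restarts (default 100).
#' @param seed Integer RNG seed (optional but recommended).
#' @param phenology Optional phenology tibble from [build_phenology()], used
#'   only to order module labels by activity.
#' @param n_sweeps,t0,cooling Annealing schedule: sweeps per restart, initial
#'   temperature and geometric cooling factor.
#' @return An object of class `modular_partition`: a list with `assignment`
#'   (tibble `species`, `guild`, `module`), `q`, `n_modules`, `n_runs`,
#'   `seed` and `run_scores`.
#' @export
maximize_modularity <- function(net, n_runs = 100, seed = NULL,
                                phenology = NULL, n_sweeps = 60,
                                t0 = 0.02, cooling = 0.92) {
  stopifnot(n_runs >= 1)
  B <- modularity_matrix(net)
  search <- function() sa_search(B, n_runs, n_sweeps, t0, cooling, 200L)
  res <- if (is.null(seed)) search() else withr::with_seed(seed, search())

  labs <- c(rownames(net), colnames(net))
  canon <- function(a) match(a, unique(a)) # canonical restricted-growth form
  best <- 1L
  best_a <- canon(res$assignments[1L, ])
  for (r in seq_len(n_runs)[-1]) {
    a <- canon(res$assignments[r, ])
    dq <- res$run_scores[r] - res$run_scores[best]
    better <- if (abs(dq) > 1e-12) dq > 0 else {
      # equal Q: fewest modules wins, then lexicographically smallest
      if (max(a) != max(best_a)) max(a) < max(best_a) else order_first(a, best_a)
    }
    if (better) { best <- r; best_a <- a }
  }
  a <- best_a
  q_best <- res$run_scores[best]
  # the single-module partition (Q = 0 exactly) is always a candidate
  if (q_best < 0) {
    a <- rep(1L, length(labs))
    q_best <- 0
  }
  names(a) <- labs

  # relabel modules in activity (or appearance) order
  mods <- unique(a)
  if (!is.null(phenology)) {
    starts <- vapply(mods, function(m) {
      sp <- names(a)[a == m]
      s <- phenology$start_day[phenology$species %in% sp]
      if (length(s) == 0) Inf else min(s)
    }, numeric(1))
    mods <- mods[order(starts)]
  }
  module <- paste0("M", match(a, mods))
  structure(list(
    assignment = tibble::tibble(
      species = labs,
      guild = rep(c("plant", "visitor"), c(nrow(net), ncol(net))),
      module = module
    ),
    q = q_best,
    n_modules = length(unique(module)),
    n_runs = n_runs,
    seed = seed,
    run_scores = res$run_scores
  ), class = "modular_partition")
}

# TRUE when a sorts lexicographically before b
order_first <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' @export
print.modular_partition <- function(x, ...) {
  cat(sprintf("Modular partition: Q = %.4f, %d modules, %d species, %d runs\n",
              x$q, x$n_modules, nrow(x$assignment), x$n_runs))
  print(dplyr::count(x$assignment, .data$module, .data$guild))
  invisible(x)
}

#' @export
tidy.modular_partition <- function(x, ...) x$assignment

#' @export
glance.modular_partition <- function(x, ...) {
  tibble::tibble(q = x$q, n_modules = x$n_modules, n_runs = x$n_runs,
                 n_species = nrow(x$assignment))
}

#' Marginal-preserving null networks
#'
#' Generates random count matrices with exactly the same plant and visitor
#' visit totals as the observed network. The default `"marginal"` model fills
#' the table by Patefield's sequential hypergeometric algorithm
#' ([stats::r2dtable()]), the standard contingency-table null for
#' quantitative networks. The `"binary-degree"` alternative instead preserves
#' each species' binary degree (number of partners): the presence structure is
#' shuffled by curveball swaps (via \pkg{vegan}) and the observed multiset of
#' positive weights is then placed on the shuffled links at random (total
#' weight `F` preserved; marginal totals are not).
#'
#' @param net A [bipnet()].
#' @param n Number of null networks.
#' @param seed Integer RNG seed (optional).
#' @param method `"marginal"` (default) or `"binary-degree"`.
#' @return A list of `n` weight matrices with the dimnames of `net`. Null
#'   matrices may contain empty rows/columns by chance under
#'   `"binary-degree"`; they are returned as plain matrices.
#' @export
null_networks <- function(net, n = 100, seed = NULL,
                          method = c("marginal", "binary-degree")) {
  method <- match.arg(method)
  stopifnot(n >= 1)
  tot <- net_totals(net)
  gen <- function() {
    if (method == "marginal") {
      # a single row or column fixes the whole table through its margins
      if (nrow(net) == 1 || ncol(net) == 1) {
        m0 <- matrix(as.integer(unclass(net)), nrow(net), ncol(net),
                     dimnames = dimnames(net))
        return(rep(list(m0), n))
      }
      ms <- stats::r2dtable(n, as.integer(tot$k), as.integer(tot$d))
      lapply(ms, function(m) {
        dimnames(m) <- dimnames(net)
        m
      })
    } else {
      pres <- (unclass(net) > 0) * 1L
      sims <- stats::simulate(vegan::nullmodel(pres, "curveball"), nsim = n)
      w <- sort(net[net > 0])
      lapply(seq_len(n), function(i) {
        m <- matrix(0L, nrow(net), ncol(net), dimnames = dimnames(net))
        links <- which(sims[, , i] > 0)
        m[links] <- sample(w)
        m
      })
    }
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Significance of modularity against a null ensemble
#'
#' Maximizes Q on the observed network, then on each of `n_null` randomized
#' networks with the observed marginal totals, and reports the Z-score
#' \eqn{z = (Q_{obs} - \bar Q_{null}) / sd(Q_{null})} with its two-sided
#' normal p-value, plus the empirical add-one rank p-value.
#'
#' Null networks can be maximized with a reduced restart budget
#' (`null_runs`) for speed; note that an undersized budget biases the null Q
#' distribution downwards and so anti-conservatively inflates z.
#'
#' @param net A [bipnet()].
#' @param n_runs Restarts for the observed network (default 100).
#' @param n_null Number of null networks (default 100).
#' @param null_runs Restarts per null network (default: `n_runs`).
#' @param seed Integer RNG seed.
#' @param method Null model, see [null_networks()].
#' @param ... Passed to [maximize_modularity()] (annealing schedule).
#' @return An object of class `modularity_significance`: list with
#'   `partition` (the observed `modular_partition`), `q_obs`, `null_qs`, `z`,
#'   `p_value`, `p_empirical`, `n_null`.
#' @export
modularity_significance <- function(net, n_runs = 100, n_null = 100,
                                    null_runs = n_runs, seed = NULL,
                                    method = c("marginal", "binary-degree"),
                                    ...) {
  method <- match.arg(method)
  stopifnot(n_null >= 2)
  run <- function() {
    part <- maximize_modularity(net, n_runs = n_runs, ...)
    nulls <- null_networks(net, n = n_null, method = method)
    null_qs <- vapply(nulls, function(m) {
      ok <- rowSums(m) > 0
      okc <- colSums(m) > 0
      nb <- bipnet(m[ok, okc, drop = FALSE], label = "null")
      maximize_modularity(nb, n_runs = null_runs, ...)$q
    }, numeric(1))
    list(part = part, null_qs = null_qs)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  s <- stats::sd(res$null_qs)
  if (!is.finite(s) || s == 0) {
    stop("null Q distribution has zero variance; z-score undefined",
         call. = FALSE)
  }
  z <- (res$part$q - mean(res$null_qs)) / s
  structure(list(
    partition = res$part,
    q_obs = res$part$q,
    null_qs = res$null_qs,
    z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    p_empirical = (1 + sum(res$null_qs >= res$part$q)) / (n_null + 1),
    n_null = n_null
  ), class = "modularity_significance")
}

#' @export
print.modularity_significance <- function(x, ...) {
  cat(sprintf(
    "Q = %.4f (%d modules) vs %d nulls: mean %.4f, sd %.4f, z = %.2f, p = %.3g (empirical p = %.3g)\n",
    x$q_obs, x$partition$n_modules, x$n_null, mean(x$null_qs),
    stats::sd(x$null_qs), x$z, x$p_value, x$p_empirical))
  invisible(x)
}

#' @export
glance.modularity_significance <- function(x, ...) {
  tibble::tibble(q_obs = x$q_obs, n_modules = x$partition$n_modules,
                 null_mean = mean(x$null_qs), null_sd = stats::sd(x$null_qs),
                 z = x$z, p_value = x$p_value, p_empirical = x$p_empirical,
                 n_null = x$n_null)
}

#' Export a modular partition as delimited text
#'
#' Writes `species,guild,module,module_rank` rows.
#'
#' @param partition A `modular_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- partition$assignment
  df$module_rank <- as.integer(sub("^M", "", df$module))
  readr::write_csv(df, path)
  invisible(path)
}
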