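#' Within-season activity profiles of modules
#'
#' The activity of a module on a census day is the total number of visits
#' received by the module's plants in that day's sub-network. Profiles over
#' modules conserve the daily network totals exactly.
#'
#' @param partition A `modular_partition` from [maximize_modularity()].
#' @param networks Networks tibble from [build_networks()].
#' @return A tibble `module, date, visits` with one row per module and census
#'   day (days with zero visits included); an unassigned plant in any
#'   sub-network is an error.
#' @export
module_activity <- function(partition, networks) {
  nets <- as_net_list(networks)
  dates <- purrr::map_vec(nets, ~ attr(.x, "date"))
  plant_mod <- with(dplyr::filter(partition$assignment, .data$guild == "plant"),
                    stats::setNames(module, species))
  mods <- sort(unique(partition$assignment$module))
  rows <- purrr::map2_dfr(nets, dates, function(net, d) {
    missing <- setdiff(rownames(net), names(plant_mod))
    if (length(missing) > 0) {
      stop("plants without module assignment: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    tibble::tibble(
      module = unname(plant_mod[rownames(net)]),
      date = d,
      visits = rowSums(unclass(net))
    )
  })
  tidyr::complete(
    dplyr::summarise(dplyr::group_by(rows, .data$module, .data$date),
                     visits = sum(.data$visits), .groups = "drop"),
    module = mods, date = unique(dates), fill = list(visits = 0)
  ) |>
    dplyr::arrange(.data$module, .data$date)
}

#' Monte-Carlo chi-squared test of one module's temporal activity
#'
#' One-way goodness-of-fit test of the module's per-census-day visit counts
#' against a null expectation (uniform across census days by default, or
#' proportional to whole-network daily activity with `expected`). The p-value
#' is Monte-Carlo: counts are redrawn multinomially under the null `n_reps`
#' times and \eqn{p = (1 + \#\{\chi^2_{rep} \ge \chi^2_{obs}\})/(n_{reps}+1)},
#' so p is never exactly 0.
#'
#' @param visits Per-census-day visit counts of one module (length >= 2,
#'   positive total).
#' @param n_reps Monte-Carlo replicates (default 5000).
#' @param seed Integer RNG seed.
#' @param expected Optional vector of expected proportions (defaults to
#'   uniform); rescaled to sum to 1.
#' @return A one-row tibble: `chi2`, `df`, `p_mc`, `n_reps`.
#' @export
chi2_mc_test <- function(visits, n_reps = 5000, seed = NULL, expected = NULL) {
  visits <- as.numeric(visits)
  if (length(visits) < 2) stop("need at least 2 census days", call. = FALSE)
  if (sum(visits) <= 0) stop("module has no visits", call. = FALSE)
  p <- if (is.null(expected)) rep(1 / length(visits), length(visits))
       else expected / sum(expected)
  run <- function() {
    suppressWarnings(stats::chisq.test(visits, p = p,
                                       simulate.p.value = TRUE, B = n_reps))
  }
  ht <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(chi2 = unname(ht$statistic),
                 df = length(visits) - 1L,
                 p_mc = ht$p.value, n_reps = as.integer(n_reps))
}

#' Temporal-activity tests for all modules, Holm-corrected
#'
#' Applies [chi2_mc_test()] to every module's activity profile and corrects
#' the Monte-Carlo p-values for multiple testing across modules with Holm's
#' step-down (sequential Bonferroni) procedure.
#'
#' @param profiles Activity tibble from [module_activity()].
#' @param n_reps,seed,expected Passed to [chi2_mc_test()]; with the default
#'   `expected = NULL` the null is uniform over census days, with
#'   `expected = "network"` it is proportional to whole-network daily totals.
#' @param alpha Significance level for the `significant` decision column.
#' @return A tibble `module, chi2, df, p_mc, p_holm, significant`.
#' @export
module_activity_tests <- function(profiles, n_reps = 5000, seed = NULL,
                                  expected = NULL, alpha = 0.05) {
  mods <- sort(unique(profiles$module))
  daily <- dplyr::summarise(dplyr::group_by(profiles, .data$date),
                            total = sum(.data$visits), .groups = "drop") |>
    dplyr::arrange(.data$date)
  seeds <- if (is.null(seed)) rep(list(NULL), length(mods))
           else as.list(seed + seq_along(mods))
  out <- purrr::map2_dfr(mods, seeds, function(m, s) {
    v <- profiles |>
      dplyr::filter(.data$module == m) |>
      dplyr::arrange(.data$date)
    exp_p <- if (identical(expected, "network")) daily$total else expected
    dplyr::bind_cols(tibble::tibble(module = m),
                     chi2_mc_test(v$visits, n_reps = n_reps, seed = s,
                                  expected = exp_p))
  })
  out$p_holm <- stats::p.adjust(out$p_mc, method = "holm")
  out$significant <- out$p_holm < alpha
  out
}

#' Multinomial logistic regression of module membership on start date
#'
#' Fits the baseline-category logit model relating each species' module
#' identity to the day-of-year on which its activity starts, by maximum
#' likelihood (via \pkg{nnet}; the predictor is centred internally for
#' numerical stability and coefficients are returned on the original
#' day-of-year scale). Goodness of fit is the likelihood-ratio chi-squared
#' test against the intercept-only model, whose log-likelihood has the closed
#' form \eqn{\sum_k n_k \ln(n_k/n)}; `df = (K - 1)` for the single predictor.
#'
#' The optimizer starts from a \pkg{nnet} fit and Newton-polishes it until the
#' log-likelihood gradient max-norm falls below 1e-10, so the LR statistic is
#' invariant to the choice of reference module. Phenologically clean modules
#' make complete or quasi-complete separation likely (a module's members all
#' start before every other module's); the iteration cap keeps estimates
#' finite, `separation` flags fits where every species is classified into its
#' own module with probability > 0.99, and an optional ridge penalty
#' (`decay > 0`) can stabilise coefficient paths (at the cost of exact
#' reference-invariance). `converged` is `TRUE` when the gradient max-norm is
#' below `1e-6`.
#'
#' @param data A tibble with one row per species holding the predictor and
#'   response columns (e.g. a join of [build_phenology()] and a partition's
#'   assignment).
#' @param module,start_day Column names (strings) of the module label and the
#'   start day.
#' @param decay Optional ridge penalty (default `0`, the exact MLE).
#' @param maxit Maximum optimizer iterations.
#' @return An object of class `module_multinom`: list with `coefficients`
#'   ((K-1) x 2 matrix, original scale), `modules` (level order; first =
#'   reference), `ll_full`, `ll_null`, `lr_chi2`, `df`, `p_value`,
#'   `converged`, `separation`, `gradient_norm`, `n`, `center`, and the
#'   underlying `fit`.
#' @export
fit_multinomial <- function(data, module = "module", start_day = "start_day",
                            decay = 0, maxit = 500) {
  y <- data[[module]]
  y <- if (is.factor(y)) y else factor(y)
  x <- as.numeric(data[[start_day]])
  if (anyNA(x) || anyNA(y)) stop("missing values in predictor or response",
                                 call. = FALSE)
  counts <- table(y)
  if (any(counts == 0)) stop("module with zero members: ",
                             paste(names(counts)[counts == 0], collapse = ", "),
                             call. = FALSE)
  if (nlevels(y) < 2) stop("need at least 2 modules", call. = FALSE)
  ctr <- mean(x)
  xc <- x - ctr
  n <- length(y)
  K <- nlevels(y)
  fit <- nnet::multinom(y ~ xc, data = data.frame(y = y, xc = xc),
                        trace = FALSE, decay = decay, maxit = maxit,
                        reltol = 1e-14)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(levels(y)[2],
                                                     c("(Intercept)", "xc")))

  # Newton polish of the ridge-penalized likelihood: nnet's BFGS stops on a
  # relative-value criterion, leaving the gradient around 1e-3; a handful of
  # Newton steps drives it below 1e-8 so LR values are reference-invariant.
  X <- cbind(1, xc)
  ymat <- stats::model.matrix(~ y - 1)
  probs_of <- function(theta) {
    eta <- cbind(0, X %*% theta) # theta: 2 x (K-1)
    pr <- exp(eta - apply(eta, 1, max))
    pr / rowSums(pr)
  }
  grad_of <- function(theta, pr) {
    resid <- (ymat - pr)[, -1, drop = FALSE]
    crossprod(X, resid) - 2 * decay * theta # 2 x (K-1)
  }
  theta <- t(cf) # 2 x (K-1): rows (intercept, slope)
  pr <- probs_of(theta)
  g <- grad_of(theta, pr)
  iter <- 0
  while (max(abs(g)) > 1e-10 && iter < 100) {
    # observed-information Hessian of the penalized log-likelihood
    p2 <- 2 * (K - 1)
    H <- matrix(0, p2, p2)
    for (k in seq_len(K - 1)) {
      for (l in seq_len(K - 1)) {
        wkl <- pr[, k + 1] * ((k == l) - pr[, l + 1])
        blk <- -crossprod(X, X * wkl)
        H[(2 * k - 1):(2 * k), (2 * l - 1):(2 * l)] <- blk
      }
    }
    diag(H) <- diag(H) - 2 * decay - 1e-10 # tiny stabiliser: H stays invertible
    step <- try(solve(H, as.numeric(g)), silent = TRUE)
    if (inherits(step, "try-error")) break
    improved <- FALSE
    scale <- 1
    for (half in 1:30) { # backtrack: full Newton steps overshoot near separation
      theta_new <- theta - scale * matrix(step, 2, K - 1)
      pr_new <- probs_of(theta_new)
      g_new <- grad_of(theta_new, pr_new)
      if (all(is.finite(g_new)) && max(abs(g_new)) < max(abs(g))) {
        theta <- theta_new; pr <- pr_new; g <- g_new
        improved <- TRUE
        break
      }
      scale <- scale / 2
    }
    if (!improved) break
    iter <- iter + 1
  }
  cf <- t(theta)
  dimnames(cf) <- list(levels(y)[-1], c("(Intercept)", "xc"))

  ll_full <- sum(log(pr[cbind(seq_len(n), as.integer(y))]))
  ll_null <- sum(counts * log(counts / n))
  lr <- 2 * (ll_full - ll_null)
  df <- K - 1L
  gnorm <- max(abs(g))
  separation <- all(pr[cbind(seq_len(n), as.integer(y))] > 0.99)
  colnames(pr) <- levels(y)

  # uncenter: intercept' = intercept - slope * ctr
  cf_orig <- cf
  cf_orig[, "(Intercept)"] <- cf[, "(Intercept)"] - cf[, "xc"] * ctr
  colnames(cf_orig) <- c("(Intercept)", "start_day")

  structure(list(
    coefficients = cf_orig,
    modules = levels(y),
    ll_full = ll_full,
    ll_null = ll_null,
    lr_chi2 = lr,
    df = df,
    p_value = stats::pchisq(lr, df, lower.tail = FALSE),
    converged = gnorm < 1e-6,
    separation = separation,
    gradient_norm = gnorm,
    n = n,
    center = ctr,
    fit = fit
  ), class = "module_multinom")
}

#' @export
print.module_multinom <- function(x, ...) {
  cat(sprintf(
    "Multinomial module-membership model: %d modules, n = %d\n  LR chi2 = %.2f, df = %d, p = %.3g%s%s\n",
    length(x$modules), x$n, x$lr_chi2, x$df, x$p_value,
    if (!x$converged) " [not converged]" else "",
    if (x$separation) " [quasi-separation]" else ""))
  invisible(x)
}

#' @export
tidy.module_multinom <- function(x, ...) {
  tibble::tibble(
    module = rep(rownames(x$coefficients), 2),
    term = rep(colnames(x$coefficients), each = nrow(x$coefficients)),
    estimate = c(x$coefficients[, 1], x$coefficients[, 2])
  )
}

#' @export
glance.module_multinom <- function(x, ...) {
  tibble::tibble(lr_chi2 = x$lr_chi2, df = x$df, p_value = x$p_value,
                 ll_full = x$ll_full, ll_null = x$ll_null, nobs = x$n,
                 converged = x$converged, separation = x$separation)
}

#' Predicted module-membership probabilities along the season
#'
#' Evaluates the fitted baseline-category logits on a grid of start days and
#' returns the softmax probabilities; each day's probabilities sum to 1.
#'
#' @param fit A `module_multinom`.
#' @param day_grid Numeric vector of day-of-year values.
#' @return A tibble `start_day, module, probability` in long format.
#' @export
predict_membership <- function(fit, day_grid) {
  cf <- fit$coefficients
  eta <- vapply(seq_len(nrow(cf)), function(r) {
    cf[r, "(Intercept)"] + cf[r, "start_day"] * day_grid
  }, numeric(length(day_grid)))
  eta <- cbind(0, matrix(eta, nrow = length(day_grid)))
  pr <- exp(eta - apply(eta, 1, max))
  pr <- pr / rowSums(pr)
  colnames(pr) <- fit$modules
  tibble::as_tibble(pr) |>
    dplyr::mutate(start_day = day_grid) |>
    tidyr::pivot_longer(-"start_day", names_to = "module",
                        values_to = "probability")
}
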