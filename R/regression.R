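#' Ordinary least-squares fit for dissimilarity-lag analyses
#'
#' Fits `y ~ x` (or `y ~ ln x` with `transform = "log-lag"`, the saturating
#' form used for interaction dissimilarity against time lag) and reports the
#' slope, intercept, coefficient of determination and the two-sided t-test of
#' zero slope. A `"log-response"` option (ln y on x) is also provided.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param transform `"none"`, `"log-lag"` or `"log-response"`.
#' @return An object of class `pheno_ols`: a list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, `transform` and the underlying `lm` fit.
#'   [generics::tidy()] and [generics::glance()] methods are available.
#' @export
ols_fit <- function(x, y, transform = c("none", "log-lag", "log-response")) {
  transform <- match.arg(transform)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points for inference", call. = FALSE)
  if (transform == "log-lag") {
    if (any(x <= 0)) stop("log-lag transform requires all x > 0", call. = FALSE)
    x <- log(x)
  }
  if (transform == "log-response") {
    if (any(y <= 0)) stop("log-response transform requires all y > 0", call. = FALSE)
    y <- log(y)
  }
  if (stats::var(x) == 0) stop("zero variance in the predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  p <- if (nrow(sm$coefficients) < 2 || is.na(sm$coefficients["x", 4])) NA_real_
       else sm$coefficients["x", 4]
  r2 <- if (stats::var(y) == 0) 0 else sm$r.squared # constant response
  structure(list(
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = r2,
    p_value = p,
    n = length(x),
    transform = transform,
    fit = fit,
    summary = sm
  ), class = "pheno_ols")
}

#' @export
print.pheno_ols <- function(x, ...) {
  cat("OLS fit (transform: ", x$transform, ")\n", sep = "")
  cat(sprintf("  slope = %.4g, intercept = %.4g, R^2 = %.3f, p = %.3g, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pheno_ols <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "slope"),
                 estimate = c(x$intercept, x$slope)) |>
    dplyr::bind_cols(tibble::as_tibble(
      x$summary$coefficients[, c("Std. Error", "t value", "Pr(>|t|)")]
    ) |> stats::setNames(c("std.error", "statistic", "p.value")))
}

#' @export
glance.pheno_ols <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_value, nobs = x$n,
                 transform = x$transform)
}

#' Regress network dissimilarity on time lag
#'
#' Relates a pairwise dissimilarity component to the temporal distance between
#' sub-networks. Species dissimilarity (`beta_s`) is conventionally fitted on
#' the raw lag; whole-network interaction dissimilarity (`beta_wn`) on the
#' log-transformed lag, matching its saturating rise towards complete
#' turnover. Pairs with a missing response (e.g. undefined `beta_os`) are
#' dropped, never imputed.
#'
#' @param pairs Pairwise table from [network_beta_pairs()].
#' @param response One of `"beta_s"`, `"beta_wn"`, `"beta_os"`, `"beta_st"`.
#' @param transform Passed to [ols_fit()]; defaults to `"none"` for `beta_s`
#'   and `"log-lag"` otherwise.
#' @return A `pheno_ols` object.
#' @export
beta_lag_fit <- function(pairs,
                         response = c("beta_s", "beta_wn", "beta_os", "beta_st"),
                         transform = NULL) {
  response <- match.arg(response)
  if (is.null(transform)) {
    transform <- if (response == "beta_s") "none" else "log-lag"
  }
  ols_fit(pairs$time_lag, pairs[[response]], transform = transform)
}

#' Flowering overlap vs visitor-assemblage dissimilarity
#'
#' Regresses the Jaccard dissimilarity of flower-visitor assemblages on the
#' interspecific flowering-overlap index over all unordered plant pairs. A
#' negative slope indicates that plants flowering in synchrony share more of
#' their visitors.
#'
#' @param phenology Phenology tibble from [build_phenology()].
#' @param cumulative Cumulative [bipnet()] of the same site.
#' @return A `pheno_ols` object; the paired data are attached as `$data`.
#' @export
overlap_vs_dissimilarity <- function(phenology, cumulative) {
  plants <- intersect(phenology$species[phenology$guild == "plant"],
                      rownames(cumulative))
  if (length(plants) < 3) stop("need at least 3 plants (>= 3 pairs)", call. = FALSE)
  keep <- phenology$guild != "plant" | phenology$species %in% plants
  ov <- flowering_overlap_pairs(phenology[keep, ])
  dis <- visitor_dissimilarity_pairs(cumulative[plants, , drop = FALSE])
  df <- dplyr::inner_join(ov, dis, by = c("species_i", "species_j"))
  if (nrow(df) < 3) stop("need at least 3 plant pairs", call. = FALSE)
  fit <- ols_fit(df$s_ij, df$dissimilarity)
  fit$data <- df
  fit
}

#' Lag at which interaction turnover is complete
#'
#' The smallest observed time lag `L` such that every sub-network pair
#' separated by at least `L` days has `beta_wn = 1` (no shared interactions).
#' Returns `NA` when even the most distant pairs still share interactions.
#'
#' @param pairs Pairwise table from [network_beta_pairs()].
#' @param tol Numerical tolerance for `beta_wn == 1`.
#' @return A one-row tibble: `lag` (days or `NA`) and `n_pairs_beyond`, the
#'   number of pairs at or beyond the threshold.
#' @export
turnover_lag <- function(pairs, tol = 1e-12) {
  if (nrow(pairs) == 0) stop("empty pair table", call. = FALSE)
  incomplete <- pairs$time_lag[pairs$beta_wn < 1 - tol]
  if (length(incomplete) == 0) {
    lag <- min(pairs$time_lag)
  } else {
    beyond <- pairs$time_lag[pairs$time_lag > max(incomplete)]
    lag <- if (length(beyond) == 0) NA_real_ else min(beyond)
  }
  tibble::tibble(lag = lag,
                 n_pairs_beyond = if (is.na(lag)) 0L
                                  else sum(pairs$time_lag >= lag))
}
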