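make_two_module_setup <- function() {
  d0 <- as.Date("2015-06-14")
  rec <- dplyr::bind_rows(
    make_records(d0, c("p1", "p1", "p2"), c("v1", "v2", "v1"), c(3, 2, 1)),
    make_records(d0 + 10, c("p3", "p4"), c("v3", "v3"), c(4, 5))
  )
  nets <- build_networks(rec, "day")
  part <- structure(list(
    assignment = tibble::tibble(
      species = c("p1", "p2", "p3", "p4", "v1", "v2", "v3"),
      guild = c(rep("plant", 4), rep("visitor", 3)),
      module = c("M1", "M1", "M2", "M2", "M1", "M1", "M2")),
    q = NA_real_, n_modules = 2L, n_runs = 0L, seed = NULL,
    run_scores = numeric()), class = "modular_partition")
  list(rec = rec, nets = nets, part = part)
}

test_that("module activity profiles conserve daily network totals", {
  s <- make_two_module_setup()
  prof <- module_activity(s$part, s$nets)
  daily <- prof |>
    dplyr::group_by(date) |>
    dplyr::summarise(v = sum(visits))
  expect_equal(daily$v, purrr::map_dbl(s$nets$network, sum))
  expect_equal(prof$visits[prof$module == "M1" & prof$date == min(prof$date)], 6)
  expect_equal(prof$visits[prof$module == "M2" & prof$date == min(prof$date)], 0)
  expect_equal(prof$visits[prof$module == "M2" & prof$date == max(prof$date)], 9)
})

test_that("a single-module partition reproduces per-day totals", {
  s <- make_two_module_setup()
  part1 <- s$part
  part1$assignment$module <- "M1"
  prof <- module_activity(part1, s$nets)
  expect_equal(prof$visits, purrr::map_dbl(s$nets$network, sum))
})

test_that("an unassigned plant is an error", {
  s <- make_two_module_setup()
  bad <- s$part
  bad$assignment <- bad$assignment[bad$assignment$species != "p3", ]
  expect_error(module_activity(bad, s$nets), "p3")
})

test_that("uniform counts give chi2 = 0 and p = 1", {
  res <- chi2_mc_test(c(10, 10, 10, 10), n_reps = 500, seed = 1)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_mc, 1)
})

test_that("fully concentrated counts are extreme under the uniform null", {
  res <- chi2_mc_test(c(40, 0, 0, 0), n_reps = 5000, seed = 2)
  expect_equal(res$chi2, 120)
  expect_lte(res$p_mc, 0.001)
  expect_gte(res$p_mc, 1 / 5001)  # add-one estimator can never reach 0
})

test_that("single census day or empty profile is an error", {
  expect_error(chi2_mc_test(10), "at least 2")
  expect_error(chi2_mc_test(c(0, 0)), "no visits")
})

test_that("Monte-Carlo p matches the exact multinomial tail on a 2-day toy", {
  counts <- c(8, 2)
  obs <- sum((counts - 5)^2 / 5)
  x <- 0:10
  exact <- sum(stats::dbinom(x, 10, 0.5)[(x - 5)^2 * 2 / 5 >= obs])
  res <- chi2_mc_test(counts, n_reps = 5000, seed = 3)
  se <- sqrt(exact * (1 - exact) / 5000)
  expect_lt(abs(res$p_mc - exact), 3 * se)
})

test_that("Holm correction reproduces the hand-stepped values", {
  expect_equal(stats::p.adjust(c(0.001, 0.04, 0.2), method = "holm"),
               c(0.003, 0.08, 0.2))
  s <- make_two_module_setup()
  prof <- module_activity(s$part, s$nets)
  tests <- module_activity_tests(prof, n_reps = 200, seed = 4)
  expect_equal(nrow(tests), 2)
  expect_true(all(tests$p_holm >= tests$p_mc))
  expect_identical(tests$p_holm, stats::p.adjust(tests$p_mc, "holm"))
})

test_that("an activity-weighted null sees no signal in a proportional module", {
  # module tracks whole-network activity exactly: uniform null rejects,
  # network-weighted null does not
  prof <- tibble::tibble(
    module = rep(c("M1", "M2"), each = 3),
    date = rep(as.Date("2015-06-14") + c(0, 7, 14), 2),
    visits = c(60, 30, 10, 120, 60, 20))
  tests_u <- module_activity_tests(prof, n_reps = 2000, seed = 5)
  tests_w <- module_activity_tests(prof, n_reps = 2000, seed = 5,
                                   expected = "network")
  expect_true(all(tests_u$p_mc < 0.01))
  expect_true(all(tests_w$p_mc == 1))
})

test_that("a constant predictor carries no likelihood-ratio signal", {
  df <- tibble::tibble(module = rep(c("M1", "M2"), each = 5), start_day = 170)
  fit <- fit_multinomial(df)
  expect_lt(abs(fit$lr_chi2), 1e-6)
  expect_gt(fit$p_value, 0.99)
})

test_that("degrees of freedom follow (K - 1) for the single predictor", {
  withr::with_seed(10, {
    df <- tibble::tibble(module = rep(paste0("M", 1:5), each = 6),
                         start_day = rnorm(30, rep(c(150, 160, 170, 180, 190),
                                                   each = 6), 8))
    fit <- fit_multinomial(df)
    expect_equal(fit$df, 4L)
    expect_equal(dim(fit$coefficients), c(4L, 2L))
  })
})

test_that("separated modules yield the enumerable null deviance as LR", {
  df <- tibble::tibble(module = rep(c("early", "late"), each = 3),
                       start_day = c(160, 162, 164, 190, 192, 194))
  fit <- fit_multinomial(df)
  expect_equal(fit$ll_null, 6 * log(0.5))
  expect_gt(fit$lr_chi2, 7.88)       # chi2_1 critical value at p = 0.005
  expect_lte(fit$lr_chi2, 2 * 6 * log(2) + 1e-6)  # bounded by null deviance
  expect_true(fit$separation)
  expect_lt(fit$p_value, 0.005)
})

test_that("the LR statistic is invariant to the reference module", {
  withr::with_seed(11, {
    df <- tibble::tibble(module = rep(c("A", "B", "C"), each = 8),
                         start_day = rnorm(24, rep(c(150, 170, 190), each = 8), 10))
    f1 <- fit_multinomial(df)
    df2 <- df
    df2$module <- factor(df2$module, levels = c("C", "A", "B"))
    f2 <- fit_multinomial(df2)
    expect_equal(f1$lr_chi2, f2$lr_chi2, tolerance = 1e-8)
    expect_true(f1$converged)
    expect_lt(f1$gradient_norm, 1e-6)
  })
})

test_that("a module with zero members is refused", {
  df <- tibble::tibble(module = factor(rep("M1", 4), levels = c("M1", "M2")),
                       start_day = 1:4)
  expect_error(fit_multinomial(df), "zero members")
})

test_that("predicted membership probabilities sum to one and track separation", {
  df <- tibble::tibble(module = rep(c("early", "late"), each = 3),
                       start_day = c(160, 162, 164, 190, 192, 194))
  fit <- fit_multinomial(df)
  pred <- predict_membership(fit, c(160, 177, 194))
  sums <- pred |>
    dplyr::group_by(start_day) |>
    dplyr::summarise(s = sum(probability))
  expect_equal(sums$s, rep(1, 3))
  expect_gt(pred$probability[pred$start_day == 160 & pred$module == "early"],
            0.95)
})

test_that("an intercept-only situation predicts module frequencies", {
  df <- tibble::tibble(module = rep(c("M1", "M2"), c(6, 2)), start_day = 170)
  fit <- fit_multinomial(df)
  pred <- predict_membership(fit, 170)
  expect_equal(pred$probability[pred$module == "M1"], 0.75, tolerance = 0.01)
  expect_equal(pred$probability[pred$module == "M2"], 0.25, tolerance = 0.01)
})
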