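test_that("shared/unique decomposition counts correctly", {
  expect_equal(shared_unique(c("x", "y"), c("y", "z")), list(a = 1, b = 1, c = 1))
  expect_equal(shared_unique(letters[1:5], letters[1:5]), list(a = 5, b = 0, c = 0))
  expect_equal(shared_unique(c("w", "x"), c("y", "z")), list(a = 0, b = 2, c = 2))
  expect_error(shared_unique(character(), character()), "undefined")
})

test_that("Whittaker dissimilarity matches its defining formula", {
  expect_equal(whittaker_beta(list(a = 0, b = 2, c = 3)), 1)
  expect_equal(whittaker_beta(list(a = 5, b = 0, c = 0)), 0)
  expect_equal(whittaker_beta(list(a = 1, b = 1, c = 0)), 1 / 3)
  expect_error(whittaker_beta(list(a = 0, b = 0, c = 0)), "undefined")
})

test_that("Whittaker is symmetric in b/c, bounded, monotone in b+c", {
  withr::with_seed(1, {
    for (i in 1:200) {
      a <- sample(0:10, 1); b <- sample(0:10, 1); c <- sample(0:10, 1)
      if (a + b + c == 0) next
      w <- whittaker_beta(list(a = a, b = b, c = c))
      expect_equal(w, whittaker_beta(list(a = a, b = c, c = b)))
      expect_gte(w, 0); expect_lte(w, 1)
      expect_gte(whittaker_beta(list(a = a, b = b + 1, c = c)), w)
    }
  })
})

test_that("pairwise Jaccard partition is additive and matches hand values", {
  p <- jaccard_partition_pairwise(list(a = 2, b = 1, c = 3))
  expect_equal(p$beta_cc, 4 / 6)
  expect_equal(p$beta_3m, 2 / 6)
  expect_equal(p$beta_rich, 2 / 6)
  expect_equal(jaccard_partition_pairwise(list(a = 0, b = 2, c = 2)),
               list(beta_cc = 1, beta_3m = 1, beta_rich = 0))
  expect_equal(jaccard_partition_pairwise(list(a = 1, b = 3, c = 0)),
               list(beta_cc = 0.75, beta_3m = 0, beta_rich = 0.75))
})

test_that("multiple-site partition pools pairs and matches brute force", {
  res <- multisite_jaccard_partition(list(c("A", "B"), c("B", "C"), c("C", "D")))
  expect_equal(res$beta_cc, 0.8)
  expect_equal(res$beta_3m, 0.8)
  expect_equal(res$beta_rich, 0)
  same <- multisite_jaccard_partition(rep(list(c("A", "B", "C")), 4))
  expect_equal(same$beta_cc, 0)
  expect_error(multisite_jaccard_partition(list(c("A"))), "at least 2")
})

test_that("multiple-site on two sets reduces to the pairwise partition", {
  withr::with_seed(2, {
    for (i in 1:50) {
      s1 <- sample(letters, sample(1:10, 1))
      s2 <- sample(letters, sample(1:10, 1))
      ms <- multisite_jaccard_partition(list(s1, s2))
      pw <- jaccard_partition_pairwise(shared_unique(s1, s2))
      expect_equal(ms$beta_cc, pw$beta_cc)
      expect_equal(ms$beta_3m, pw$beta_3m)
      expect_equal(ms$beta_rich, pw$beta_rich)
    }
  })
})

test_that("network dissimilarity components match hand set arithmetic", {
  d <- as.Date("2015-06-14")
  netA <- make_net(matrix(c(1, 1), 1, 2, dimnames = list("p1", c("v1", "v2"))),
                   date = d)
  netB <- make_net(matrix(c(1, 1, 0, 0), 2, 2,
                          dimnames = list(c("p1", "p2"), c("v1", "v2")))[, 1,
                          drop = FALSE], date = d + 3)
  b <- network_beta(netA, netB)
  expect_equal(b$beta_s, 1 / 3)   # {p1,v1,v2} vs {p1,p2,v1}: a=2,b=1,c=1
  expect_equal(b$beta_wn, 0.5)    # interactions a=1,b=1,c=1
  expect_equal(b$beta_os, 0)      # shared species p1,v1 share link p1-v1
  expect_equal(b$beta_st, 0.5)
  expect_equal(b$time_lag, 3)
})

test_that("identical and disjoint networks give the boundary values", {
  net <- make_net(matrix(1:4, 2, 2))
  same <- network_beta(net, net)
  expect_equal(same$beta_s, 0)
  expect_equal(same$beta_wn, 0)
  expect_equal(same$beta_os, 0)
  other <- bipnet(matrix(2, 1, 1, dimnames = list("q1", "w1")))
  dis <- network_beta(net, other)
  expect_equal(dis$beta_s, 1)
  expect_equal(dis$beta_wn, 1)
  expect_true(is.na(dis$beta_os))
})

test_that("beta_s = 0 implies beta_wn = beta_os", {
  withr::with_seed(3, {
    for (i in 1:20) {
      a <- random_net(4, 5)
      # same species, rewired links
      repeat {
        m <- matrix(rpois(20, 1), 4, 5, dimnames = dimnames(a))
        if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
      }
      b <- bipnet(m)
      r <- network_beta(a, b)
      expect_equal(r$beta_s, 0)
      expect_equal(r$beta_wn, r$beta_os)
      expect_equal(r$beta_st, 0)
    }
  })
})

test_that("flowering overlap is interval Jaccard with symmetric bounds", {
  phen <- tibble::tibble(
    species = c("a", "b", "c", "d"), guild = "plant",
    start_day = c(1, 6, 1, 20), end_day = c(10, 15, 10, 25),
    duration = c(10, 10, 10, 6),
    active_days = list(1:10, 6:15, 1:10, 20:25), source = "census"
  )
  ov <- flowering_overlap(phen, "a", "b")
  expect_equal(ov$a_ij, 5); expect_equal(ov$b_ij, 15)
  expect_equal(ov$s_ij, 1 / 3)
  expect_equal(flowering_overlap(phen, "b", "a")$s_ij, 1 / 3)
  expect_equal(flowering_overlap(phen, "a", "c")$s_ij, 1)
  expect_equal(flowering_overlap(phen, "a", "d")$s_ij, 0)
  expect_error(flowering_overlap(phen, "a", "nope"), "unknown")
})

test_that("1 - s_ij satisfies the triangle inequality on random intervals", {
  withr::with_seed(4, {
    for (i in 1:100) {
      st <- sample(1:40, 3, replace = TRUE)
      en <- st + sample(0:20, 3, replace = TRUE)
      phen <- tibble::tibble(species = c("x", "y", "z"), guild = "plant",
                             start_day = st, end_day = en,
                             duration = en - st + 1,
                             active_days = purrr::map2(st, en, seq),
                             source = "census")
      dxy <- 1 - flowering_overlap(phen, "x", "y")$s_ij
      dyz <- 1 - flowering_overlap(phen, "y", "z")$s_ij
      dxz <- 1 - flowering_overlap(phen, "x", "z")$s_ij
      expect_lte(dxz, dxy + dyz + 1e-12)
    }
  })
})

test_that("visitor-assemblage dissimilarity is Jaccard on visitor sets", {
  m <- matrix(0, 2, 4, dimnames = list(c("pi", "pj"), paste0("v", 1:4)))
  m["pi", 1:3] <- 1
  m["pj", 3:4] <- 1
  net <- bipnet(m)
  expect_equal(visitor_assemblage_dissimilarity(net, "pi", "pj"), 0.75)
  expect_equal(visitor_assemblage_dissimilarity(net, "pi", "pi"), 0)
  expect_error(visitor_assemblage_dissimilarity(net, "pi", "zz"), "unknown")
})
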