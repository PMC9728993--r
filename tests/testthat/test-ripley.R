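V5 <- 4 / 3 * pi * 5^3

test_that("ripley_k implements the literal estimator", {
  pts <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  expect_equal(ripley_k(pts, c(0.4, 0.6), V5), c(0, V5 * 2 / 4))
  # inclusive inequality at d == r
  expect_equal(ripley_k(pts, 0.5, V5), V5 * 2 / 4)
  # unbiased variant divides by n(n-1)
  expect_equal(ripley_k(pts, 0.6, V5, normalisation = "unbiased"), V5)

  # radius below the minimum pairwise distance -> 0
  fs <- simulate_csr_nucleus(30, seed = 2)
  pts2 <- foci_as_matrix(fs)
  rmin <- min(dist(pts2))
  expect_equal(ripley_k(pts2, rmin * 0.99, V5), 0)

  expect_error(ripley_k(pts[1, , drop = FALSE], 0.5, V5), "fewer than 2")
  pts_bad <- pts; pts_bad[1, 1] <- NA
  expect_error(ripley_k(pts_bad, 0.5, V5), "non-finite")
})

test_that("fast K equals the brute-force pair counter exactly", {
  set.seed(303)
  radii <- seq(0.1, 1, 0.1)
  for (i in 1:100) {
    n <- sample(2:300, 1)
    pts <- foci_as_matrix(simulate_csr_nucleus(n, seed = 5000 + i))
    expect_identical(ripley_k(pts, radii, V5),
                     oracle_ripley_k(pts, radii, V5))
  }
})

test_that("K is non-decreasing in r for observed and null patterns", {
  for (s in 1:10) {
    pts <- foci_as_matrix(simulate_thomas_nucleus(4, 10, 0.3, seed = s))
    if (nrow(pts) < 2) next
    expect_true(all(diff(ripley_k(pts, seq(0.05, 2, 0.05), V5)) >= 0))
  }
  nm <- sample_null(25, ripley_config(n_null = 200, seed = 1))
  expect_true(all(apply(nm, 1, function(row) all(diff(row) >= 0))))
})

test_that("null sampler is reproducible with the closed-form mean", {
  cfg <- ripley_config(n_null = 1000, seed = 99)
  nm <- sample_null(40, cfg)
  expect_equal(dim(nm), c(1000, 10))
  expect_identical(nm, sample_null(40, cfg))

  # E[K(r)] = (4/3) pi r^3 (n-1)/n under CSR, edge effects < 1% at r = 0.2
  expected <- 4 / 3 * pi * 0.2^3 * 39 / 40
  col <- nm[, 2]
  se <- sd(col) / sqrt(length(col))
  expect_lt(abs(mean(col) - expected), 3 * se + 0.01 * expected)

  cfg_small <- ripley_config(n_null = 100, seed = 1)
  expect_equal(dim(sample_null(40, cfg_small)), c(100, 10))
})

test_that("empirical p-values handle ranks, ties and the optimistic rule", {
  null <- as.numeric(1:20) / 10
  # observed above every null value -> p = 0, resolution bound 1/N kept
  p0 <- empirical_pvalue(3, null)
  expect_equal(as.numeric(p0), 0)
  expect_equal(attr(p0, "resolution"), 1 / 20)
  # observed below every null value -> p = 1
  expect_equal(as.numeric(empirical_pvalue(0.05, null)), 1)

  # 5 strictly above, 2 tied: optimistic 5/20, conservative 7/20
  null2 <- c(rep(2, 5), rep(1.5, 2), seq(0.1, 1.3, length.out = 13))
  expect_equal(as.numeric(empirical_pvalue(1.5, null2, "optimistic")),
               5 / 20)
  expect_equal(as.numeric(empirical_pvalue(1.5, null2, "conservative")),
               7 / 20)

  # the randomized rule reports one of the two boundary p-values and is
  # reproducible given its seed
  pr <- empirical_pvalue(1.5, null2, "randomized", tie_seed = 5)
  expect_true(as.numeric(pr) %in% c(5 / 20, 7 / 20))
  expect_identical(as.numeric(pr),
                   as.numeric(empirical_pvalue(1.5, null2, "randomized",
                                               tie_seed = 5)))

  expect_error(empirical_pvalue(1, numeric(0)), "empty")
})

test_that("optimistic p never exceeds conservative p", {
  set.seed(17)
  for (i in 1:50) {
    null <- sample(round(runif(200, 0, 0.01), 3), 200, replace = TRUE)
    obs <- sample(null, 1)  # force ties
    expect_lte(as.numeric(empirical_pvalue(obs, null, "optimistic")),
               as.numeric(empirical_pvalue(obs, null, "conservative")))
  }
})

test_that("BH adjustment matches the step-up procedure", {
  out <- bh_adjust(c(0.01, 0.02, 0.2), fdr = 0.05)
  expect_equal(out$reject, c(TRUE, TRUE, FALSE))
  expect_equal(out$q_values, p.adjust(c(0.01, 0.02, 0.2), "BH"))

  all_one <- bh_adjust(rep(1, 5))
  expect_false(any(all_one$reject))
  expect_equal(all_one$q_values, rep(1, 5))

  expect_true(bh_adjust(0.04, 0.05)$reject)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cluster_test excludes small nuclei and types errors correctly", {
  fs20 <- simulate_csr_nucleus(20, seed = 4)
  res <- cluster_test(fs20, "EGFR", ripley_config(n_null = 100, seed = 1))
  expect_true(res$excluded)
  expect_match(res$reason, "min_foci")

  fs21 <- simulate_csr_nucleus(21, seed = 4)
  res21 <- cluster_test(fs21, "EGFR", ripley_config(n_null = 100, seed = 1))
  expect_false(res21$excluded)
  expect_equal(nrow(res21$table), 10)
  # p and q within [0,1], q >= p, K columns internally consistent
  with(res21$table, {
    expect_true(all(p_value >= 0 & p_value <= 1))
    expect_true(all(q_value >= p_value - 1e-12))
    expect_true(all(null_min <= null_median & null_median <= null_max))
    expect_true(all(diff(observed_k) >= 0))
  })
})

test_that("clustered nuclei are detected and CSR nuclei are not", {
  th <- cluster_test(simulate_thomas_nucleus(5, 8, 0.05, seed = 31),
                     "EGFR", ripley_config(n_null = 500, seed = 32))
  expect_true(any(th$table$significant[th$table$radius_um <= 0.2]))

  csr <- cluster_test(simulate_csr_nucleus(40, seed = 33),
                      "EGFR", ripley_config(n_null = 500, seed = 34))
  expect_false(any(csr$table$significant))
})

test_that("detection power increases as clusters tighten", {
  rate <- vapply(c(0.4, 0.2, 0.05), function(sigma) {
    hits <- vapply(1:15, function(s) {
      fs <- simulate_thomas_nucleus(5, 8, sigma, seed = 40 + s)
      res <- cluster_test(fs, "EGFR",
                          ripley_config(n_null = 300, seed = 400 + s))
      if (res$excluded) FALSE else any(res$table$significant)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
})

test_that("cohort summary tabulates significance and exclusions", {
  cfg <- ripley_config(n_null = 200, seed = 3)
  results <- c(
    lapply(1:3, function(i) {
      cfg$seed <- 600 + i
      cluster_test(simulate_csr_nucleus(40, seed = 500 + i), "EGFR", cfg)
    }),
    list(cluster_test(simulate_csr_nucleus(10, seed = 1), "EGFR", cfg))
  )
  tab <- cohort_summary(results)
  expect_equal(tab$n_tested, rep(3, 10))
  expect_equal(attr(tab, "n_excluded"), 1)
  expect_equal(nrow(attr(tab, "exclusions")), 1)

  # hand-built single-nucleus case: significant at 0.4 um only
  one <- results[[1]]
  one$table$significant <- one$table$radius_um == 0.4
  tab1 <- cohort_summary(list(one))
  expect_equal(tab1$n_significant, as.numeric(tab1$radius_um == 0.4))

  excluded_only <- results[4]
  expect_error(cohort_summary(excluded_only), "excluded")
})
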