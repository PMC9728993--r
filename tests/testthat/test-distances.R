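make_foci <- function(x, y = 0, z = 0, channel = "EGFR") {
  foci_set(data.frame(channel = channel, x_um = x,
                      y_um = rep_len(y, length(x)),
                      z_um = rep_len(z, length(x))))
}

test_that("shortest distances match hand geometry and handle edge cases", {
  s <- shortest_distances(make_foci(c(0, 1, 3)), "EGFR", "EGFR")
  expect_equal(s$per_focus_shortest, c(1, 1, 2))
  expect_equal(s$mean_shortest, 4 / 3)
  expect_equal(s$min_shortest, 1)

  # coincident foci give distance 0, not an error
  s0 <- shortest_distances(make_foci(c(1, 1)), "EGFR", "EGFR")
  expect_equal(s0$per_focus_shortest, c(0, 0))

  # < 2 relevant foci -> empty flagged summary
  s1 <- shortest_distances(make_foci(0), "EGFR", "EGFR")
  expect_true(s1$empty)
  expect_equal(s1$n_source, 0)
  expect_true(is.na(s1$mean_shortest))

  expect_error(shortest_distances(make_foci(c(0, 1)), "EGFR", "CDK4"),
               "unknown channel")
})

test_that("cross-channel summaries are directional and oracle-exact", {
  df <- rbind(data.frame(channel = "A", x_um = c(0, 10), y_um = 0, z_um = 0),
              data.frame(channel = "B", x_um = c(1, 2, 11), y_um = 0,
                         z_um = 0))
  fs <- foci_set(df)
  ab <- shortest_distances(fs, "A", "B")
  ba <- shortest_distances(fs, "B", "A")
  expect_equal(ab$per_focus_shortest, c(1, 1))
  expect_equal(ba$per_focus_shortest, c(1, 2, 1))
  expect_false(isTRUE(all.equal(ab$mean_shortest, ba$mean_shortest)))
})

test_that("shortest distances equal the brute-force oracle on random data", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(2:60, 1)
    fs <- simulate_csr_nucleus(n, seed = 1000 + i)
    s <- shortest_distances(fs, "EGFR", "EGFR")
    pts <- foci_as_matrix(fs)
    expect_equal(s$per_focus_shortest,
                 oracle_nearest(pts, pts, exclude_self = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("nearest-distance multiset is invariant under rigid motion", {
  set.seed(55)
  fs <- simulate_csr_nucleus(50, seed = 77)
  base <- sort(shortest_distances(fs, "EGFR", "EGFR")$per_focus_shortest)
  for (i in 1:5) {
    Q <- random_rotation()
    shift <- rnorm(3)
    pts <- foci_as_matrix(fs) %*% Q +
      matrix(shift, 50, 3, byrow = TRUE)
    perm <- sample(50)
    fs2 <- foci_set(data.frame(channel = "EGFR", x_um = pts[perm, 1],
                               y_um = pts[perm, 2], z_um = pts[perm, 3]))
    moved <- sort(shortest_distances(fs2, "EGFR", "EGFR")$per_focus_shortest)
    expect_equal(moved, base, tolerance = 1e-10)
  }
})

test_that("proximity fractions reproduce printed proportions and monotonicity", {
  # 4 of 1011 source foci below threshold -> 0.39%; 4 of 518 -> 0.77%
  d1 <- c(rep(0.1, 4), rep(1, 1007))
  s1 <- ecdnaspatial:::new_distance_summary("n", c("CDK4", "PDGFRA"), d1)
  f1 <- proximity_fraction(s1, 0.2)
  expect_equal(f1$count, 4)
  expect_equal(f1$percent, 0.39)
  d2 <- c(rep(0.1, 4), rep(1, 514))
  s2 <- ecdnaspatial:::new_distance_summary("n", c("PDGFRA", "CDK4"), d2)
  expect_equal(proximity_fraction(s2, 0.2)$percent, 0.77)

  # strict inequality at the threshold
  s3 <- ecdnaspatial:::new_distance_summary("n", c("A", "A"), c(0.2, 0.3))
  expect_equal(proximity_fraction(s3, 0.2)$count, 0)

  # monotone non-decreasing in the threshold
  set.seed(12)
  s4 <- shortest_distances(simulate_csr_nucleus(40, seed = 8),
                           "EGFR", "EGFR")
  counts <- vapply(seq(0.1, 3, 0.1),
                   function(t) proximity_fraction(s4, t)$count, numeric(1))
  expect_true(all(diff(counts) >= 0))

  # empty summary -> undefined proportion, no error
  s5 <- ecdnaspatial:::new_distance_summary("n", c("A", "A"), numeric(0))
  f5 <- proximity_fraction(s5, 0.2)
  expect_equal(f5$total, 0)
  expect_true(is.nan(f5$proportion))
})

test_that("pooled cumulative distance distribution behaves as an ECDF", {
  one <- ecdnaspatial:::new_distance_summary("n", c("A", "A"), 0.5)
  cdf <- cumulative_distance_distribution(list(one),
                                          grid = c(0, 0.49, 0.5, 1))
  expect_equal(cdf$cum_freq, c(0, 0, 1, 1))

  # doublet fixture: all shortest distances at 0.2 -> jump to 1 there
  fs <- simulate_doublets(40, 0.2, seed = 21)
  s <- shortest_distances(fs, "EGFR", "EGFR")
  cdf2 <- cumulative_distance_distribution(list(s),
                                           grid = c(0.19, 0.2 + 1e-9, 0.3))
  expect_equal(cdf2$cum_freq[2], 1)
  expect_lt(cdf2$cum_freq[1], 1)

  # monotone, ends at 1; empty summaries counted, all-empty errors
  expect_true(all(diff(cdf2$cum_freq) >= 0))
  empty <- ecdnaspatial:::new_distance_summary("n", c("A", "A"), numeric(0))
  cdf3 <- cumulative_distance_distribution(list(one, empty))
  expect_equal(attr(cdf3, "n_excluded"), 1)
  expect_error(cumulative_distance_distribution(list(empty)), "empty")
})

test_that("CSR nearest-neighbour CDF matches the Poisson closed form", {
  # P(NN < r) ~ 1 - exp(-lambda (4/3) pi r^3) for r << R
  n <- 100; R <- 5; r <- 0.3
  lambda <- n / (4 / 3 * pi * R^3)
  expected <- 1 - exp(-lambda * 4 / 3 * pi * r^3)
  pooled <- unlist(lapply(1:100, function(s) {
    shortest_distances(simulate_csr_nucleus(n, R, seed = 3000 + s),
                       "EGFR", "EGFR")$per_focus_shortest
  }))
  observed <- mean(pooled < r)
  se <- sqrt(expected * (1 - expected) / length(pooled))
  expect_lt(abs(observed - expected), 4 * se + 0.1 * expected)
})

test_that("large-focus filter applies the inclusive 500 nm cut", {
  cand <- data.frame(x_um = 1:3, y_um = 0, z_um = 0,
                     diameter_um = c(0.3, 0.5, 0.8))
  kept <- filter_large_foci(cand)
  expect_equal(nrow(kept$foci), 2)
  expect_equal(kept$foci$diameter_um, c(0.5, 0.8))

  expect_equal(nrow(filter_large_foci(cand[0, ])$foci), 0)
  all_small <- transform(cand, diameter_um = 0.1)
  expect_equal(nrow(filter_large_foci(all_small)$foci), 0)
  expect_error(filter_large_foci(data.frame(x_um = 1, y_um = 1, z_um = 1)),
               "diameter")
  cand$diameter_um[2] <- NA
  expect_error(filter_large_foci(cand), "missing diameter")
})

test_that("focus-to-hub distances match geometry and the oracle", {
  fs <- make_foci(0)
  hubs <- filter_large_foci(data.frame(x_um = c(1, 0), y_um = c(0, 2),
                                       z_um = 0, diameter_um = 0.6))
  s <- foci_to_hub_distances(fs, hubs)
  expect_equal(s$per_focus_shortest, 1)

  # coincident focus and hub centre -> 0
  hubs0 <- filter_large_foci(data.frame(x_um = 0, y_um = 0, z_um = 0,
                                        diameter_um = 0.7))
  expect_equal(foci_to_hub_distances(fs, hubs0)$per_focus_shortest, 0)

  # no hubs -> empty flagged summary
  none <- filter_large_foci(data.frame(x_um = 1, y_um = 1, z_um = 1,
                                       diameter_um = 0.2))
  expect_true(foci_to_hub_distances(fs, none)$empty)

  # random fixture vs O(n*m) oracle
  set.seed(9)
  foci <- simulate_csr_nucleus(30, seed = 14)
  hub_df <- data.frame(x_um = runif(6, -3, 3), y_um = runif(6, -3, 3),
                       z_um = runif(6, -3, 3), diameter_um = 0.8)
  hubs2 <- filter_large_foci(hub_df)
  s2 <- foci_to_hub_distances(foci, hubs2)
  expect_equal(s2$per_focus_shortest,
               oracle_nearest(foci_as_matrix(foci),
                              as.matrix(hub_df[, 1:3])),
               tolerance = 1e-12)
})
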