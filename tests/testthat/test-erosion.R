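test_that("disc mask yields five equal-area shells at the analytic radii", {
  mask <- disc_mask(100)
  A <- sum(mask)
  shells <- equal_area_shells(mask, 5)
  areas <- as.numeric(table(shells[shells > 0]))
  expect_length(areas, 5)
  expect_true(all(abs(areas - A / 5) <= 0.01 * A / 5))
  # equivalent-area outer radii of the inner regions vs 100 * sqrt(1 - k/5)
  equiv <- sqrt((A - cumsum(areas)[1:4]) / pi)
  expect_true(all(abs(equiv - 100 * sqrt(1 - (1:4) / 5)) <= 1))
  # partition: disjoint labels covering the mask exactly
  expect_equal(sum(shells > 0), A)
  expect_true(all(shells[mask == 0] == 0))
})

test_that("shell partition is valid on irregular masks and edge cases", {
  for (s in 1:5) {
    mask <- blob_mask(seed = s)
    A <- sum(mask)
    shells <- equal_area_shells(mask, 5)
    areas <- as.numeric(table(factor(shells[shells > 0], levels = 1:5)))
    expect_equal(sum(areas), A)
    expect_true(all(abs(areas - A / 5) <= 0.01 * A / 5))
  }

  mask1 <- disc_mask(20)
  expect_identical(equal_area_shells(mask1, 1), mask1)

  two <- disc_mask(10)
  two[1:3, 1:3] <- 1L  # far-away second component
  expect_error(equal_area_shells(two, 5), "connected")
  expect_error(equal_area_shells(matrix(0L, 5, 5), 2), "empty")
  tiny <- matrix(0L, 5, 5); tiny[3, 3] <- 1L
  expect_error(equal_area_shells(tiny, 2), "too small")
})

test_that("shell profiles normalise by DAPI and conserve intensity", {
  mask <- disc_mask(60)
  shells <- equal_area_shells(mask, 5)

  # flat probe and flat DAPI: identical normalised intensity in all bins
  flat <- shell_profile(list(probe = mask * 1), mask * 1, shells)
  expect_equal(flat$table$normalized, rep(1, 5))

  # probe proportional to (r/R)^2: strictly decreasing from bin 1 to 5
  img <- simulate_radial_image(nrow(mask), 60, radial_bias = 2)
  biased <- shell_profile(list(probe = img$probe), img$dapi,
                          equal_area_shells(img$mask, 5))
  expect_true(all(diff(biased$table$normalized) < 0))

  # probe identical to DAPI: normalised intensity exactly 1
  set.seed(3)
  noisy <- mask * matrix(runif(length(mask), 0.5, 1.5),
                         nrow(mask), ncol(mask))
  same <- shell_profile(list(probe = noisy), noisy, shells)
  expect_equal(same$table$normalized, rep(1, 5))

  # conservation: shell sums add up to the whole-mask total exactly
  prof <- shell_profile(list(probe = noisy), mask * 1, shells)
  expect_equal(sum(prof$table$raw_intensity), sum(noisy))

  # zero DAPI in a shell is a named error
  bad_dapi <- mask * 1
  bad_dapi[shells == 3] <- 0
  expect_error(shell_profile(list(probe = noisy), bad_dapi, shells),
               "shell\\(s\\): 3")
})

test_that("profiles are invariant under image rotation", {
  img <- simulate_radial_image(151, 60, radial_bias = 2, noise_sd = 0.05,
                               seed = 8)
  prof <- function(probe, dapi, mask) {
    shell_profile(list(probe = probe), dapi,
                  equal_area_shells(mask, 5))$table$normalized
  }
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m)))]
  a <- prof(img$probe, img$dapi, img$mask)
  b <- prof(rot90(img$probe), rot90(img$dapi), rot90(img$mask))
  expect_equal(b, a, tolerance = 0.02)
})

test_that("channel ratio profiles divide out shared radial structure", {
  mask <- disc_mask(60)
  shells <- equal_area_shells(mask, 5)
  img <- simulate_radial_image(nrow(mask), 60, radial_bias = 2)
  prof <- shell_profile(list(egfr = img$probe, chr7 = img$probe,
                             flat = mask * 1), img$dapi, shells)

  expect_equal(ratio_profile(prof, "egfr", "chr7")$ratio, rep(1, 5))
  expect_true(all(diff(ratio_profile(prof, "egfr", "flat")$ratio) < 0))
  expect_true(all(diff(ratio_profile(prof, "flat", "egfr")$ratio) > 0))
  expect_error(ratio_profile(prof, "egfr", "nope"), "not in profile")
})

test_that("the shell trend test detects radial bias and controls type I", {
  mask <- disc_mask(40)
  shells <- equal_area_shells(mask, 5)

  # identical shells across nuclei -> H = 0, p = 1
  flat <- lapply(1:4, function(i) {
    shell_profile(list(probe = mask * 1), mask * 1, shells,
                  nucleus_id = i)
  })
  kw0 <- shell_trend_test(flat, "probe")
  expect_equal(unname(kw0$statistic), 0)
  expect_equal(kw0$p.value, 1)

  # strong peripheral bias over 50 noisy nuclei -> p < 1e-4
  biased <- lapply(1:50, function(i) {
    img <- simulate_radial_image(nrow(mask), 40, radial_bias = 2,
                                 noise_sd = 0.1, seed = i)
    shell_profile(list(probe = img$probe), img$dapi, shells, nucleus_id = i)
  })
  expect_lt(shell_trend_test(biased, "probe")$p.value, 1e-4)

  # type-I: with shell labels shuffled per nucleus the test rarely rejects
  shuffled <- vapply(1:60, function(rep) {
    profs <- lapply(1:6, function(i) {
      img <- simulate_radial_image(nrow(mask), 40, radial_bias = 2,
                                   noise_sd = 0.1, seed = 100 * rep + i)
      p <- shell_profile(list(probe = img$probe), img$dapi, shells,
                         nucleus_id = i)
      p$table$shell <- sample(p$table$shell)
      p
    })
    shell_trend_test(profs, "probe")$p.value
  }, numeric(1))
  expect_lt(mean(shuffled < 0.05), 0.15)

  expect_error(shell_trend_test(flat[1], "probe"), "at least 2")
})
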