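test_that("proportional contributions divide rates by their sum", {
  expect_equal(proportional_contribution(2, 2), list(f_no3 = 0.5, f_nh4 = 0.5))
  f <- proportional_contribution(1, 2)
  expect_equal(f$f_no3, 1 / 3, tolerance = 1e-12)
  expect_equal(f$f_nh4, 2 / 3, tolerance = 1e-12)
  expect_equal(proportional_contribution(0, 5), list(f_no3 = 0, f_nh4 = 1))
  # both zero: undefined, NA
  f0 <- proportional_contribution(0, 0)
  expect_true(is.na(f0$f_no3) && is.na(f0$f_nh4))
  expect_error(proportional_contribution(-1, 2), ">= 0")
})

test_that("preference index is use minus availability", {
  expect_equal(preference_index(0.3, 3, 10), 0)
  expect_equal(preference_index(0.8, 3, 10), 0.5, tolerance = 1e-12)
  # antisymmetry of the two forms
  expect_equal(preference_index(0.2, 7, 10), -0.5, tolerance = 1e-12)
  expect_equal(preference_index(1, 0, 10), 1)
  expect_error(preference_index(0.5, 3, 0), "DIN")
  expect_error(preference_index(1.2, 3, 10), "\\[0, 1\\]")
  expect_error(preference_index(0.5, 11, 10), "soil DIN")
})

test_that("percentage similarity is calibrated and bounded", {
  expect_equal(percentage_similarity(0.8, 0.2, 0.3, 0.7), 50, tolerance = 1e-12)
  expect_equal(percentage_similarity(1, 0, 0, 1), 0)
  # f == p gives exactly 100 for any composition
  set.seed(1)
  p <- runif(100)
  expect_true(all(percentage_similarity(p, 1 - p, p, 1 - p) == 100))
  expect_error(percentage_similarity(0.8, 0.3, 0.3, 0.7), "sum to 1")
  expect_error(percentage_similarity(1.2, -0.2, 0.3, 0.7), "\\[0, 1\\]")
})

test_that("index identities hold on every simulated pipeline run", {
  for (seed in 1:3) {
    sim <- simulate_dataset(noise = noise_model(), seed = seed)
    up <- compute_uptake(sim$plants, sim$soil, sim$quadrats)
    ind <- compute_indices(up, sim$soil)
    ok <- ind[!ind$excluded, ]
    expect_true(all(abs(ok$f_no3 + ok$f_nh4 - 1) <= 1e-12))
    expect_true(all(abs(ok$p_no3 + ok$p_nh4 - 1) <= 1e-12))
    expect_true(all(abs(ok$beta_no3 + ok$beta_nh4) <= 1e-12))
    expect_true(all(abs(ok$ps - (100 - 100 * abs(ok$beta_nh4))) <= 1e-12))
    # relabeling the forms leaves PS unchanged
    expect_equal(percentage_similarity(ok$f_no3, ok$f_nh4, ok$p_no3, ok$p_nh4),
                 ok$ps, tolerance = 1e-12)
  }
})

test_that("zero-noise indices equal closed-form truth values", {
  sim <- simulate_dataset(noise = no_noise(), seed = 5)
  up <- compute_uptake(sim$plants, sim$soil, sim$quadrats)
  ind <- compute_indices(up, sim$soil)
  ti <- truth_indices(sim$truth)
  m <- match(paste(ind$species, ind$habitat), paste(ti$species, ti$habitat))
  expect_true(all(abs(ind$f_nh4 - ti$f_nh4[m]) <= 1e-9))
  expect_true(all(abs(ind$beta_nh4 - ti$beta_nh4[m]) <= 1e-9))
  expect_true(all(abs(ind$ps - ti$ps[m]) <= 1e-9))
})

test_that("monotonicity: raising true NH4 rate raises recovered f and beta", {
  tr <- flat_truth()
  prev_f <- prev_b <- -Inf
  for (r in c(20, 40, 80)) {
    tr$rate_nh4 <- r
    sim <- simulate_dataset(truth = tr, noise = no_noise(), seed = 1)
    ind <- compute_indices(compute_uptake(sim$plants, sim$soil, sim$quadrats),
                           sim$soil)
    expect_gt(min(ind$f_nh4), prev_f)
    expect_gt(min(ind$beta_nh4), prev_b)
    prev_f <- max(ind$f_nh4)
    prev_b <- max(ind$beta_nh4)
  }
})

test_that("quadrats with clamped or missing data are excluded with a reason", {
  sim <- simulate_dataset(noise = no_noise(), seed = 2)
  plants <- sim$plants
  i <- which(plants$treatment == "nh4_label")[1]
  plants$delta15N[i] <- -5 # below natural abundance -> clamped APE
  up <- suppressWarnings(compute_uptake(plants, sim$soil, sim$quadrats))
  ind <- compute_indices(up, sim$soil)
  hit <- ind$site == plants$site[i] & ind$habitat == plants$habitat[i] &
    ind$quadrat == plants$quadrat[i] & ind$species == plants$species[i]
  expect_true(ind$excluded[hit])
  expect_identical(ind$exclude_reason[hit], "clamped APE")
  expect_true(is.na(ind$f_nh4[hit]))
  # dropping one labeled plant leaves the quadrat flagged, not erroring
  up2 <- up[-which(up$form == "NO3")[1], ]
  ind2 <- compute_indices(up2, sim$soil)
  expect_identical(sum(ind2$exclude_reason == "missing labeled plant",
                       na.rm = TRUE), 1L)
})

test_that("aggregation reproduces an independent mean/SE oracle", {
  d <- data.frame(
    species = rep(c("a", "b"), each = 6),
    habitat = rep(c("h1", "h2"), times = 6),
    ps = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
    excluded = FALSE
  )
  out <- aggregate_indices(d, vars = "ps")
  row <- out[out$species == "a" & out$habitat == "h1", ]
  x <- d$ps[d$species == "a" & d$habitat == "h1"]
  expect_equal(row$mean, mean(x))
  expect_equal(row$se, sd(x) / sqrt(length(x)))
  expect_identical(row$n, length(x))
  # identical values -> SE exactly 0
  d$ps <- 7
  out2 <- aggregate_indices(d, vars = "ps")
  expect_true(all(out2$mean == 7 & out2$se == 0 & out2$n == 3))
  # default synthetic design: n = 12 per species x habitat
  sim <- simulate_dataset(noise = no_noise(), seed = 1)
  ind <- compute_indices(compute_uptake(sim$plants, sim$soil, sim$quadrats),
                         sim$soil)
  agg <- aggregate_indices(ind)
  expect_true(all(agg$n == 12))
})
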