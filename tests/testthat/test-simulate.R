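test_that("generate_design lays out one plant per treatment per quadrat", {
  d <- generate_design(study_design())
  expect_identical(nrow(d), 4L * 3L * 3L * 2L * 3L) # 216
  # exactly one plant per treatment per quadrat per species
  expect_true(all(table(d$site, d$habitat, d$quadrat, d$species,
                        d$treatment) == 1))
  # n = 12 replicate quadrats per species x habitat cell
  q <- unique(d[c("site", "habitat", "quadrat", "species")])
  expect_true(all(table(q$species, q$habitat) == 12))

  expect_identical(nrow(generate_design(tiny_design())), 3L)
  expect_error(study_design(n_sites = 0), ">= 1")
  expect_error(study_design(habitats = character(0)), ">= 1")
  expect_error(study_design(habitats = c("a", "a")), "unique")
})

test_that("same seed reproduces the dataset byte-for-byte, new seed varies it", {
  a <- simulate_dataset(seed = 11)
  b <- simulate_dataset(seed = 11)
  c <- simulate_dataset(seed = 12)
  expect_identical(a$plants, b$plants)
  expect_identical(a$soil, b$soil)
  expect_identical(a$quadrats, b$quadrats)
  expect_false(identical(a$plants$delta15N, c$plants$delta15N))
  expect_false(identical(a$soil$nh4, c$soil$nh4))
})

test_that("zero-noise simulation inverts exactly through the whole chain", {
  sim <- simulate_dataset(noise = no_noise(), seed = 4)
  expect_lt(recovered_rate_error(sim), 1e-10)
  # per-plant, not just cell means
  up <- compute_uptake(sim$plants, sim$soil, sim$quadrats)
  tr <- sim$truth
  m <- match(paste(up$species, up$habitat), paste(tr$species, tr$habitat))
  truth_rate <- ifelse(up$form == "NH4", tr$rate_nh4[m], tr$rate_no3[m])
  expect_lt(max(abs(up$actual_uptake_rate - truth_rate) / truth_rate), 1e-10)
})

test_that("a 2:1 NH4:NO3 rate ratio with equal pools gives f_nh4 = 2/3", {
  tr <- flat_truth(rate_nh4 = 60, rate_no3 = 30, soil_nh4 = 8, soil_no3 = 8)
  sim <- simulate_dataset(truth = tr, noise = no_noise(), seed = 1)
  ind <- compute_indices(compute_uptake(sim$plants, sim$soil, sim$quadrats),
                         sim$soil)
  expect_equal(unique(round(ind$f_nh4, 12)), 2 / 3, tolerance = 1e-9)
  expect_equal(unique(round(ind$beta_nh4, 12)), 2 / 3 - 0.5, tolerance = 1e-9)
})

test_that("noise is applied in the right spaces and keeps outputs positive", {
  sim <- simulate_dataset(noise = noise_model(0.2, 0.5, 0.8), seed = 9)
  expect_true(all(sim$soil$nh4 > 0 & sim$soil$no3 > 0))
  expect_true(all(sim$plants$shoot_biomass > 0 & sim$plants$root_biomass > 0))
  expect_true(all(sim$quadrats$shoot_biomass_m2 > 0 &
                    sim$quadrats$root_biomass_m2 > 0))
  expect_equal(sim$soil$din, sim$soil$nh4 + sim$soil$no3)
  # controls scatter around natural abundance with the delta precision
  ctrl <- sim$plants$delta15N[sim$plants$treatment == "control"]
  expect_lt(abs(mean(ctrl)), 0.2) # se = 0.2/sqrt(72) ~ 0.024
  expect_equal(sd(ctrl), 0.2, tolerance = 0.35)
  # log-normal noise is mean-preserving (arithmetic mean equals truth mean)
  big <- simulate_dataset(
    study_design(n_sites = 60, habitats = "farmland", species = "invasive"),
    flat_truth(), noise_model(0, 0.4, 0), seed = 2)
  expect_equal(mean(big$plants$root_biomass), 1.5, tolerance = 0.05)
})

test_that("infeasible truth (atom% above enrichment) errors", {
  tr <- flat_truth(rate_nh4 = 4e7, rate_no3 = 40)
  expect_error(simulate_dataset(truth = tr, noise = no_noise(), seed = 1),
               "enrichment")
})

test_that("truth must cover the design and respect sign constraints", {
  tr <- default_truth()
  expect_error(simulate_dataset(study_design(habitats = c("farmland", "bog")),
                                tr, no_noise()), "cover")
  tr2 <- tr; tr2$rate_nh4[1] <- -1
  expect_error(simulate_dataset(truth = tr2, noise = no_noise()), ">= 0")
  tr3 <- tr; tr3$soil_nh4[1] <- 0; tr3$soil_no3[1] <- 0
  expect_error(simulate_dataset(truth = tr3, noise = no_noise()), "DIN")
  expect_error(noise_model(-0.1), ">= 0")
})

test_that("noisy recovery: cell-mean rates stay within 10% of truth", {
  # delta noise only, n = 12, 40 replicates here (the 200-replicate run is in
  # the acceptance suite); every species x habitat x form cell must recover
  set.seed(101)
  ok <- vapply(1:40, function(i) {
    sim <- simulate_dataset(noise = noise_model(0.2, 0, 0), seed = 1000 + i)
    recovered_rate_error(sim) < 0.10
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
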