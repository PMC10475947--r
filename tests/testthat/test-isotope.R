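test_that("delta/atom-percent conversion matches the air standard", {
  # direct evaluation: R = 0.0036765 (delta/1000 + 1), AT = 100 R / (1 + R)
  expect_equal(delta_to_atom_percent(0), 0.3663032859691345, tolerance = 1e-12)
  expect_equal(delta_to_atom_percent(10), 0.3699527673373929, tolerance = 1e-12)
  # strictly increasing, round trip is an identity
  d <- seq(-50, 500, by = 7.3)
  at <- delta_to_atom_percent(d)
  expect_true(all(diff(at) > 0))
  expect_equal(atom_percent_to_delta(at), d, tolerance = 1e-12)
  expect_error(delta_to_atom_percent(-1000), "-1000")
  expect_error(atom_percent_to_delta(0), "in \\(0, 100\\)")
})

test_that("atom percent excess is the labeled-minus-control difference", {
  expect_equal(atom_percent_excess(0.4663, 0.3663), 0.1, tolerance = 1e-12)
  expect_equal(atom_percent_excess(0.3663, 0.3663), 0)
  # negative APE is returned (clamping happens at the table level)
  expect_equal(atom_percent_excess(0.36, 0.3663), -0.0063, tolerance = 1e-12)
  expect_error(atom_percent_excess(0.1, 0.3663), "\\[0.2, 100\\)")
})

test_that("tracer uptake chain reproduces hand arithmetic", {
  # APE 0.1 %, biomass 10 g, N 2 % -> 0.001 * 10 * 0.02 * 1e6 = 200 ug
  expect_equal(n15_uptake(0.1, 10, 2), 200, tolerance = 1e-12)
  expect_equal(n15_uptake(0, 10, 2), 0)
  expect_equal(n15_uptake(0.1, 20, 2), 2 * n15_uptake(0.1, 10, 2))

  expect_equal(n15_uptake_rate(200, 2, 48), 2.0833333333333335,
               tolerance = 1e-12)
  expect_equal(n15_uptake_rate(0, 2, 48), 0)
  expect_error(n15_uptake_rate(200, 0, 48), "> 0")

  expect_equal(actual_uptake(200, 10, 0.24), 8333.333333333334,
               tolerance = 1e-12)
  expect_equal(actual_uptake(200, 0, 0.24), 0)
  expect_equal(actual_uptake(200, 30, 0.24), 3 * actual_uptake(200, 10, 0.24))
  expect_error(actual_uptake(200, 10, 0), "> 0")

  expect_equal(actual_uptake_rate(2.0833333333333335, 10, 0.24),
               86.80555555555557, tolerance = 1e-12)
  # identity with the amount-based path
  expect_equal(actual_uptake(200, 10, 0.24) / (2 * 48),
               actual_uptake_rate(n15_uptake_rate(200, 2, 48), 10, 0.24),
               tolerance = 1e-12)

  expect_equal(uptake_per_quadrat(86.80555555555557, 100, 48),
               416666.66666666674, tolerance = 1e-12)
  expect_equal(uptake_per_quadrat(0, 100, 48), 0)
  expect_equal(uptake_per_quadrat(86.8, 200, 48),
               2 * uptake_per_quadrat(86.8, 100, 48))
})

test_that("chain outputs are homogeneous of degree 1 in APE", {
  for (k in c(0.5, 2, 7)) {
    base <- n15_uptake(0.08, 6, 1.8)
    scaled <- n15_uptake(0.08 * k, 6, 1.8)
    expect_equal(scaled, k * base, tolerance = 1e-12)
    expect_equal(actual_uptake(scaled, 9, 0.24), k * actual_uptake(base, 9, 0.24),
                 tolerance = 1e-12)
  }
})

test_that("compute_uptake pairs controls, clamps negatives, flags them", {
  sim <- simulate_dataset(noise = no_noise(), seed = 3)
  up <- compute_uptake(sim$plants, sim$soil, sim$quadrats)
  expect_s3_class(up, "uptake_table")
  expect_identical(nrow(up), sum(sim$plants$treatment != "control"))
  expect_false(any(up$ape_clamped))
  expect_true(all(up$ape > 0))
  # rate x root biomass x time reproduces 15N uptake
  lab <- sim$plants[sim$plants$treatment != "control", ]
  expect_equal(up$n15_uptake_rate * lab$root_biomass * 48, up$n15_uptake,
               tolerance = 1e-9)
  # per-quadrat chain consistency
  key <- function(d) paste(d$site, d$habitat, d$quadrat, d$species)
  q <- sim$quadrats[match(key(up), key(sim$quadrats)), ]
  expect_equal(up$uptake_per_quadrat,
               up$actual_uptake * q$root_biomass_m2 / lab$root_biomass,
               tolerance = 1e-9)

  # force one negative APE: labeled signal below natural abundance
  plants <- sim$plants
  i <- which(plants$treatment == "nh4_label")[1]
  plants$delta15N[i] <- -5
  expect_warning(up2 <- compute_uptake(plants, sim$soil, sim$quadrats),
                 "clamped")
  expect_true(up2$ape_clamped[up2$form == "NH4"][1])
  expect_identical(up2$actual_uptake[up2$ape_clamped], 0)
})

test_that("compute_uptake fails loudly on broken referential integrity", {
  sim <- simulate_dataset(tiny_design(), flat_truth(), no_noise())
  plants <- sim$plants[sim$plants$treatment != "control", ]
  expect_error(compute_uptake(plants, sim$soil, sim$quadrats), "no control")
  expect_error(compute_uptake(sim$plants, sim$soil[0, ], sim$quadrats),
               "soil record")
  expect_error(compute_uptake(sim$plants, sim$soil, sim$quadrats[0, ]),
               "quadrat harvest")
})
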