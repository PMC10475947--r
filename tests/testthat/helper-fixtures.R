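# Shared fixtures: a tiny one-site design and a hand-written three-plant
# dataset small enough to check against hand arithmetic.

tiny_design <- function() {
  study_design(n_sites = 1, habitats = "farmland", n_quadrats = 1,
               species = "invasive", seed = 1)
}

flat_truth <- function(rate_nh4 = 40, rate_no3 = 40,
                       soil_nh4 = 8, soil_no3 = 8,
                       species = c("invasive", "native"),
                       habitats = c("farmland", "wasteland", "roadside")) {
  cells <- expand.grid(species = species, habitat = habitats,
                       stringsAsFactors = FALSE)
  out <- data.frame(
    cells,
    rate_nh4 = rate_nh4, rate_no3 = rate_no3,
    soil_nh4 = soil_nh4, soil_no3 = soil_no3,
    shoot_m2 = 500, root_m2 = 150,
    shoot_plant = 5, root_plant = 1.5, n_conc = 1.8
  )
  class(out) <- c("truth_table", "data.frame")
  out
}

# data with an exact SMA relationship plus controllable scatter
sma_data <- function(n, slope, r2 = 0.8, intercept = 0, xmean = 0) {
  x <- stats::rnorm(n, xmean)
  sde <- abs(slope) * sqrt((1 - r2) / r2)
  list(x = x, y = intercept + slope * x + stats::rnorm(n, 0, sde))
}

# rate recovery across all species x habitat x form cells of one simulation
recovered_rate_error <- function(sim, config = labeling_config()) {
  up <- compute_uptake(sim$plants, sim$soil, sim$quadrats, config)
  tr <- sim$truth
  m <- match(paste(up$species, up$habitat), paste(tr$species, tr$habitat))
  truth_rate <- ifelse(up$form == "NH4", tr$rate_nh4[m], tr$rate_no3[m])
  cell <- paste(up$species, up$habitat, up$form)
  rec <- tapply(up$actual_uptake_rate, cell, mean)
  tru <- tapply(truth_rate, cell, mean)
  max(abs(rec - tru) / tru)
}
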