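# Forward simulator of the hierarchical 15N field design. Every downstream
# stage (uptake chain, indices, group comparisons) can be tested by parameter
# recovery because the generator runs the tracer chain FORWARD from a known
# truth table and the analysis inverts it.

#' Field study design
#'
#' The sampling layout: sites x habitats x quadrats x species x treatments,
#' with one plant individual per treatment per quadrat per species. The
#' default reproduces a 4-site, 3-habitat (farmland/wasteland/roadside),
#' 3-quadrat, 2-species, 3-treatment layout, i.e. 12 replicate quadrats per
#' species x habitat cell and 216 plant rows.
#'
#' @param n_sites number of study sites (default 4).
#' @param habitats habitat labels (default farmland, wasteland, roadside).
#' @param n_quadrats number of quadrats per habitat per site (default 3).
#' @param species species labels (default `"invasive"`, `"native"`).
#' @param treatments treatment labels; must contain `"nh4_label"`,
#'   `"no3_label"` and `"control"`.
#' @param seed default random seed used by [simulate_dataset()] when none is
#'   given there.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_sites = 4,
                         habitats = c("farmland", "wasteland", "roadside"),
                         n_quadrats = 3,
                         species = c("invasive", "native"),
                         treatments = c("nh4_label", "no3_label", "control"),
                         seed = 1L) {
  if (n_sites < 1 || n_quadrats < 1 || length(habitats) < 1 ||
      length(species) < 1 || length(treatments) < 1) {
    stop("study_design: all counts must be >= 1", call. = FALSE)
  }
  if (n_sites != round(n_sites) || n_quadrats != round(n_quadrats)) {
    stop("study_design: counts must be whole numbers", call. = FALSE)
  }
  if (anyDuplicated(habitats) || anyDuplicated(species) ||
      anyDuplicated(treatments)) {
    stop("study_design: labels must be unique", call. = FALSE)
  }
  structure(list(
    n_sites = as.integer(n_sites),
    habitats = as.character(habitats),
    n_quadrats = as.integer(n_quadrats),
    species = as.character(species),
    treatments = as.character(treatments),
    seed = as.integer(seed)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "Field design: %d sites x %d habitats x %d quadrats x %d species x %d treatments\n",
    x$n_sites, length(x$habitats), x$n_quadrats, length(x$species),
    length(x$treatments)))
  cat(sprintf("  habitats:   %s\n", paste(x$habitats, collapse = ", ")))
  cat(sprintf("  species:    %s\n", paste(x$species, collapse = ", ")))
  cat(sprintf("  treatments: %s\n", paste(x$treatments, collapse = ", ")))
  cat(sprintf("  replicates per species x habitat cell: %d; plant rows: %d\n",
              x$n_sites * x$n_quadrats,
              x$n_sites * length(x$habitats) * x$n_quadrats *
                length(x$species) * length(x$treatments)))
  invisible(x)
}

#' Measurement / between-quadrat noise model
#'
#' @param delta15N_sd analytical precision of delta-15N, per mil (default 0.2,
#'   the precision of a typical EA-IRMS line). Applied additively in delta
#'   space to every plant isotope measurement.
#' @param relative_sd_biomass between-quadrat coefficient of variation of
#'   biomass variables (log-normal; default 0.25).
#' @param relative_sd_soilN between-quadrat coefficient of variation of soil
#'   NH4+/NO3- pools (log-normal; default 0.3).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(delta15N_sd = 0.2,
                        relative_sd_biomass = 0.25,
                        relative_sd_soilN = 0.3) {
  if (delta15N_sd < 0 || relative_sd_biomass < 0 || relative_sd_soilN < 0) {
    stop("noise_model: standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(delta15N_sd = delta15N_sd,
                 relative_sd_biomass = relative_sd_biomass,
                 relative_sd_soilN = relative_sd_soilN),
            class = "noise_model")
}

#' Zero-noise model
#'
#' Convenience constructor: all noise components zero, so simulated data invert
#' exactly to the truth table.
#' @return object of class `noise_model`.
#' @export
no_noise <- function() noise_model(0, 0, 0)

#' Validate a truth table against a design
#' @noRd
.check_truth <- function(truth, design) {
  need <- c("species", "habitat", "rate_nh4", "rate_no3", "soil_nh4",
            "soil_no3", "shoot_m2", "root_m2", "shoot_plant", "root_plant",
            "n_conc")
  miss <- setdiff(need, names(truth))
  if (length(miss)) {
    stop("truth table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cells <- expand.grid(species = design$species, habitat = design$habitats,
                       stringsAsFactors = FALSE)
  have <- paste(truth$species, truth$habitat)
  bad <- setdiff(paste(cells$species, cells$habitat), have)
  if (length(bad)) {
    stop("truth table does not cover cell(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  num <- truth[setdiff(need, c("species", "habitat"))]
  if (any(as.matrix(num) < 0) || any(truth$rate_nh4 + truth$rate_no3 <= 0)) {
    stop("truth table: rates and pools must be >= 0 with positive total rate",
         call. = FALSE)
  }
  if (any(truth$soil_nh4 + truth$soil_no3 <= 0)) {
    stop("truth table: soil DIN must be > 0", call. = FALSE)
  }
  invisible(truth)
}

#' Default ground-truth table for the simulator
#'
#' Illustrative per-cell truth values for the default two-species,
#' three-habitat design. They are NOT estimates from any field study; they are
#' chosen so that (a) soils are NH4+-dominant in farmland and wasteland and
#' NO3--dominant in roadside, (b) the invasive species has no N-form
#' preference in farmland, prefers NH4+ in wasteland and NO3- in roadside
#' while the native prefers NO3- everywhere, (c) the invader has larger
#' biomass and lower root:shoot ratio, and (d) every labeled plant's expected
#' atom-percent excess is >= 0.05 atom% under the default labeling protocol,
#' comfortably above the 0.2 per-mil analytical noise.
#'
#' Columns: `species`, `habitat`; true actual uptake rates `rate_nh4`,
#' `rate_no3` (ug N g^-1 root h^-1); mean soil pools `soil_nh4`, `soil_no3`
#' (mg N kg^-1 dw); quadrat standing stocks `shoot_m2`, `root_m2` (g m^-2);
#' per-plant biomass within the labeled cylinder `shoot_plant`, `root_plant`
#' (g); whole-plant N concentration `n_conc` (% dw).
#'
#' @return data frame of class `truth_table`.
#' @export
default_truth <- function() {
  out <- data.frame(
    species = rep(c("invasive", "native"), each = 3),
    habitat = rep(c("farmland", "wasteland", "roadside"), 2),
    rate_nh4 = c(45, 80, 15, 24, 50, 13),
    rate_no3 = c(25, 16, 95, 36, 40, 62),
    soil_nh4 = c(9, 10, 4, 6, 12, 5),
    soil_no3 = c(5, 4, 10, 4, 5, 12),
    shoot_m2 = c(950, 780, 600, 320, 280, 420),
    root_m2 = c(210, 200, 260, 110, 105, 190),
    shoot_plant = c(6.0, 5.5, 4.5, 2.8, 2.5, 3.2),
    root_plant = c(1.6, 1.5, 1.8, 0.9, 0.85, 1.3),
    n_conc = c(1.8, 1.8, 1.8, 1.5, 1.5, 1.5)
  )
  class(out) <- c("truth_table", "data.frame")
  out
}

#' Closed-form strategy indices implied by a truth table
#'
#' The f, beta, and PS values a zero-noise simulation must reproduce:
#' `f` from the true rates, `p` from the true soil pools, and the identities
#' `beta = f - p`, `PS = 100 - 100 |beta_nh4|`.
#'
#' @param truth a truth table (see [default_truth()]).
#' @return data frame with `species`, `habitat`, `f_nh4`, `f_no3`, `p_nh4`,
#'   `p_no3`, `beta_nh4`, `beta_no3`, `ps`.
#' @export
truth_indices <- function(truth) {
  f_nh4 <- truth$rate_nh4 / (truth$rate_nh4 + truth$rate_no3)
  p_nh4 <- truth$soil_nh4 / (truth$soil_nh4 + truth$soil_no3)
  data.frame(
    species = truth$species, habitat = truth$habitat,
    f_nh4 = f_nh4, f_no3 = 1 - f_nh4,
    p_nh4 = p_nh4, p_no3 = 1 - p_nh4,
    beta_nh4 = f_nh4 - p_nh4, beta_no3 = (1 - f_nh4) - (1 - p_nh4),
    ps = 100 - 100 * abs(f_nh4 - p_nh4)
  )
}

#' Sample slots of a field design
#'
#' Expands a [study_design()] into one row per plant individual: exactly one
#' plant per treatment per quadrat per species, every quadrat in every habitat
#' of every site.
#'
#' @param design a [study_design()].
#' @return data frame with columns `site`, `habitat`, `quadrat`, `species`,
#'   `treatment`; `n_sites x |habitats| x n_quadrats x |species| x
#'   |treatments|` rows.
#' @examples
#' nrow(generate_design(study_design())) # 216
#' @export
generate_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  out <- expand.grid(
    treatment = design$treatments,
    species = design$species,
    quadrat = seq_len(design$n_quadrats),
    habitat = design$habitats,
    site = paste0("site", seq_len(design$n_sites)),
    stringsAsFactors = FALSE,
    KEEP.OUT.ATTRS = FALSE
  )
  out <- out[, c("site", "habitat", "quadrat", "species", "treatment")]
  rownames(out) <- NULL
  out
}

# log-normal draw with arithmetic mean `mean` and coefficient of variation
# `cv`; degenerates to the mean when cv = 0
.rlnorm_mean <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, length.out = n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Forward-simulate a complete field dataset
#'
#' Runs the tracer chain forward for every labeled plant: the true actual
#' uptake rate of the labeled form gives the actual uptake over the
#' incubation, pool-dilution scaling by `C15N_added / C_available` converts it
#' to tracer uptake, the plant's biomass and N concentration convert that to
#' an atom-percent excess, and the natural-abundance baseline plus APE give
#' the plant's true atom%. Measurement noise is added in delta space
#' (additive, normal), while soil pools and biomass vary log-normally around
#' the truth means, so all simulated quantities stay positive. Control plants
#' carry the natural-abundance signal plus noise.
#'
#' With [no_noise()], feeding the outputs through [compute_uptake()] and
#' [compute_indices()] recovers the truth table exactly (to floating-point
#' round-off).
#'
#' @param design a [study_design()].
#' @param truth a truth table covering every species x habitat cell
#'   (default [default_truth()]).
#' @param noise a [noise_model()].
#' @param config a [labeling_config()].
#' @param seed integer seed; defaults to the design's `seed` field.
#' @return list of class `nform_simulation` with elements `plants`, `soil`,
#'   `quadrats` (data frames as consumed by [compute_uptake()]), and `truth`
#'   (the truth table echoed back).
#' @export
simulate_dataset <- function(design = study_design(),
                             truth = default_truth(),
                             noise = noise_model(),
                             config = labeling_config(),
                             seed = design$seed) {
  stopifnot(inherits(design, "study_design"), inherits(noise, "noise_model"),
            inherits(config, "labeling_config"))
  .check_truth(truth, design)
  if (!all(c("nh4_label", "no3_label", "control") %in% design$treatments)) {
    stop("simulate_dataset: treatments must include nh4_label, no3_label, control",
         call. = FALSE)
  }
  set.seed(as.integer(seed))

  plants <- generate_design(design)
  n <- nrow(plants)
  trow <- match(paste(plants$species, plants$habitat),
                paste(truth$species, truth$habitat))

  # per-plant realized biomass, N concentration, and own rhizosphere soil
  plants$shoot_biomass <- .rlnorm_mean(n, truth$shoot_plant[trow],
                                       noise$relative_sd_biomass)
  plants$root_biomass <- .rlnorm_mean(n, truth$root_plant[trow],
                                      noise$relative_sd_biomass)
  plants$n_concentration <- truth$n_conc[trow]

  soil <- plants[.plant_key]
  soil$nh4 <- .rlnorm_mean(n, truth$soil_nh4[trow], noise$relative_sd_soilN)
  soil$no3 <- .rlnorm_mean(n, truth$soil_no3[trow], noise$relative_sd_soilN)
  soil$din <- soil$nh4 + soil$no3
  soil$ratio_no3_nh4 <- ifelse(soil$nh4 > 0, soil$no3 / soil$nh4, NA_real_)

  # forward tracer chain on realized quantities
  at_base <- delta_to_atom_percent(0)  # natural abundance baseline
  added <- c15n_added(config)
  labeled <- plants$treatment %in% names(.tracer_forms)
  form <- .tracer_forms[plants$treatment[labeled]]
  rate_true <- ifelse(form == "NH4", truth$rate_nh4[trow[labeled]],
                      truth$rate_no3[trow[labeled]])
  c_av <- ifelse(form == "NH4", soil$nh4[labeled], soil$no3[labeled])
  act <- rate_true * plants$root_biomass[labeled] * config$incubation_time
  n15 <- act * added / c_av
  tot <- plants$shoot_biomass[labeled] + plants$root_biomass[labeled]
  ape <- n15 / (tot * (plants$n_concentration[labeled] / 100) * 1e6) * 100
  at_true <- at_base + ape

  enr <- ifelse(form == "NH4", config$enrichment_nh4, config$enrichment_no3)
  if (any(at_true >= enr)) {
    stop("simulate_dataset: truth implies plant atom% at or above the label ",
         "enrichment; the configured dose is too small for these uptake rates",
         call. = FALSE)
  }

  delta_true <- rep(0, n)
  delta_true[labeled] <- atom_percent_to_delta(at_true)
  plants$delta15N <- delta_true + stats::rnorm(n, 0, noise$delta15N_sd)

  # quadrat harvest: standing stocks per m2
  quadrats <- unique(plants[.quadrat_key])
  rownames(quadrats) <- NULL
  qrow <- match(paste(quadrats$species, quadrats$habitat),
                paste(truth$species, truth$habitat))
  m <- nrow(quadrats)
  quadrats$shoot_biomass_m2 <- .rlnorm_mean(m, truth$shoot_m2[qrow],
                                            noise$relative_sd_biomass)
  quadrats$root_biomass_m2 <- .rlnorm_mean(m, truth$root_m2[qrow],
                                           noise$relative_sd_biomass)
  quadrats$root_shoot_ratio <- quadrats$root_biomass_m2 /
    quadrats$shoot_biomass_m2

  structure(list(plants = plants, soil = soil, quadrats = quadrats,
                 truth = truth),
            class = "nform_simulation")
}

#' @export
print.nform_simulation <- function(x, ...) {
  cat("Simulated 15N field dataset\n")
  cat(sprintf("  plants:   %d rows (%d labeled)\n", nrow(x$plants),
              sum(x$plants$treatment != "control")))
  cat(sprintf("  soil:     %d records\n", nrow(x$soil)))
  cat(sprintf("  quadrats: %d harvest records\n", nrow(x$quadrats)))
  cat(sprintf("  truth:    %d species x habitat cells\n", nrow(x$truth)))
  invisible(x)
}
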