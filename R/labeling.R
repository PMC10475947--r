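#' Labeling configuration for an in-situ 15N tracer experiment
#'
#' Bundles the constants of the field labeling protocol: the 15N dose applied
#' to each plant, the labeling-solution volume and concentration, the isotopic
#' enrichment of the two tracer salts, the geometry of the labeled soil
#' cylinder, soil bulk density, and the incubation time. These constants drive
#' the added-tracer soil concentration ([c15n_added()]) and the uptake chain in
#' [compute_uptake()].
#'
#' @param dose_15N 15N applied per plant, in micrograms (default 360).
#' @param solution_volume labeling solution volume per plant, mL (default 48).
#' @param solution_conc labeling solution concentration, mmol 15N per litre
#'   (default 0.5). Together with `solution_volume` this implies the dose via
#'   the 15 g/mol atomic mass of 15N; see [dose_from_solution()].
#' @param enrichment_nh4,enrichment_no3 isotopic enrichment of the ammonium
#'   and nitrate tracer salts, atom% 15N (defaults 99.12 and 99.21).
#' @param cylinder_radius,cylinder_depth radius and depth of the soil cylinder
#'   in which the label is dispersed, cm (defaults 5 and 15).
#' @param bulk_density soil bulk density, g cm^-3 (default 1.273, which makes
#'   the default cylinder hold ~1500 g of soil).
#' @param incubation_time time between labeling and harvest, hours (default 48).
#' @param atm_at_percent 15N natural abundance of atmospheric N2, atom%
#'   (default 0.3663).
#'
#' @return An object of class `labeling_config` (a named list).
#' @examples
#' cfg <- labeling_config()
#' c15n_added(cfg)
#' @export
labeling_config <- function(dose_15N = 360,
                            solution_volume = 48,
                            solution_conc = 0.5,
                            enrichment_nh4 = 99.12,
                            enrichment_no3 = 99.21,
                            cylinder_radius = 5,
                            cylinder_depth = 15,
                            bulk_density = 1.273,
                            incubation_time = 48,
                            atm_at_percent = 0.3663) {
  cfg <- list(
    dose_15N = dose_15N,
    solution_volume = solution_volume,
    solution_conc = solution_conc,
    enrichment_nh4 = enrichment_nh4,
    enrichment_no3 = enrichment_no3,
    cylinder_radius = cylinder_radius,
    cylinder_depth = cylinder_depth,
    bulk_density = bulk_density,
    incubation_time = incubation_time,
    atm_at_percent = atm_at_percent
  )
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("labeling_config: '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (dose_15N <= 0 || solution_volume <= 0 || incubation_time <= 0) {
    stop("labeling_config: dose, solution volume and incubation time must be > 0",
         call. = FALSE)
  }
  for (nm in c("enrichment_nh4", "enrichment_no3")) {
    e <- cfg[[nm]]
    if (e <= atm_at_percent || e > 100) {
      stop("labeling_config: '", nm,
           "' must exceed natural abundance and be <= 100 atom%", call. = FALSE)
    }
  }
  if (cylinder_radius <= 0 || cylinder_depth <= 0 || bulk_density <= 0) {
    stop("labeling_config: cylinder geometry and bulk density must be > 0",
         call. = FALSE)
  }
  structure(cfg, class = "labeling_config")
}

#' @export
print.labeling_config <- function(x, ...) {
  cat("15N labeling configuration\n")
  cat(sprintf("  dose:        %g ug 15N per plant (%g mL at %g mmol/L)\n",
              x$dose_15N, x$solution_volume, x$solution_conc))
  cat(sprintf("  enrichment:  NH4+ %g, NO3- %g atom%%\n",
              x$enrichment_nh4, x$enrichment_no3))
  cat(sprintf("  labeled soil: cylinder r = %g cm, depth = %g cm, BD = %g g/cm3 (%.0f g)\n",
              x$cylinder_radius, x$cylinder_depth, x$bulk_density,
              labeled_soil_mass(x)))
  cat(sprintf("  incubation:  %g h\n", x$incubation_time))
  cat(sprintf("  added tracer: %.4f mg 15N per kg dw soil\n", c15n_added(x)))
  invisible(x)
}

#' Mass of soil in the labeled cylinder
#'
#' pi r^2 depth x bulk density, in grams.
#'
#' @param config a [labeling_config()].
#' @return soil mass, g.
#' @export
labeled_soil_mass <- function(config) {
  stopifnot(inherits(config, "labeling_config"))
  pi * config$cylinder_radius^2 * config$cylinder_depth * config$bulk_density
}

#' Concentration of added 15N tracer in the labeled soil
#'
#' The dose is assumed evenly dispersed in the labeled cylinder, so the added
#' tracer concentration is dose / soil mass, expressed in mg 15N per kg of dry
#' soil. This is the denominator of the pool-dilution step that converts tracer
#' uptake into uptake of pre-existing soil N.
#'
#' @param config a [labeling_config()].
#' @return added 15N concentration, mg N kg^-1 dw soil.
#' @examples
#' c15n_added(labeling_config()) # ~0.240 mg/kg
#' @export
c15n_added <- function(config) {
  stopifnot(inherits(config, "labeling_config"))
  # ug / g == mg / kg
  config$dose_15N / labeled_soil_mass(config)
}

#' Per-plant 15N dose implied by the labeling solution
#'
#' Consistency check on the protocol constants: concentration (mmol 15N/L)
#' x volume (mL) x 15 g/mol = dose in micrograms.
#'
#' @param config a [labeling_config()].
#' @return implied dose, ug 15N.
#' @examples
#' dose_from_solution(labeling_config()) # 360
#' @export
dose_from_solution <- function(config) {
  stopifnot(inherits(config, "labeling_config"))
  # mmol/L * mL = umol; * 15 ug/umol = ug
  config$solution_conc * config$solution_volume * 15
}
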