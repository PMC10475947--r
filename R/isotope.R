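# 15N tracer chain: measured isotope signatures -> uptake of pre-existing
# soil NH4+ / NO3-. All percent-valued quantities are stored as percent;
# unit conversion happens only inside the formulas.

# 15R of atmospheric N2 (the delta-15N reference standard)
R_AIR <- 0.0036765

#' Convert delta-15N to 15N atom percent
#'
#' Uses the atmospheric-N2 standard ratio 15R = 0.0036765:
#' `AT% = 100 R / (1 + R)` with `R = 0.0036765 (delta/1000 + 1)`.
#' Strictly increasing in delta; delta = 0 gives natural abundance
#' (~0.36630 atom%).
#'
#' @param delta15N delta-15N in per mil; must be > -1000.
#' @return 15N atom percent.
#' @seealso [atom_percent_to_delta()] for the inverse.
#' @examples
#' delta_to_atom_percent(0)   # 0.36630
#' delta_to_atom_percent(10)  # 0.36666
#' @export
delta_to_atom_percent <- function(delta15N) {
  if (any(delta15N <= -1000, na.rm = TRUE)) {
    stop("delta_to_atom_percent: delta-15N must be > -1000 per mil",
         call. = FALSE)
  }
  R <- R_AIR * (delta15N / 1000 + 1)
  100 * R / (1 + R)
}

#' Convert 15N atom percent to delta-15N
#'
#' Exact inverse of [delta_to_atom_percent()].
#'
#' @param at_percent 15N atom percent, in (0, 100).
#' @return delta-15N, per mil.
#' @export
atom_percent_to_delta <- function(at_percent) {
  if (any(at_percent <= 0 | at_percent >= 100, na.rm = TRUE)) {
    stop("atom_percent_to_delta: atom percent must be in (0, 100)",
         call. = FALSE)
  }
  R <- at_percent / (100 - at_percent)
  (R / R_AIR - 1) * 1000
}

#' Atom percent excess of a labeled plant over its control
#'
#' The tracer signal: `APE = AT%_labeled - AT%_control`. The atmospheric
#' baseline cancels in the subtraction. Negative values (control exceeding
#' labeled, possible under measurement noise) are returned as-is here;
#' clamping and flagging happen at the table level in [compute_uptake()].
#'
#' @param at_labeled,at_control 15N atom percent of the labeled and control
#'   plant; both in `[0.2, 100)`.
#' @return atom percent excess, %.
#' @examples
#' atom_percent_excess(0.4663, 0.3663) # 0.1
#' @export
atom_percent_excess <- function(at_labeled, at_control) {
  if (any(at_labeled < 0.2 | at_labeled >= 100, na.rm = TRUE) ||
      any(at_control < 0.2 | at_control >= 100, na.rm = TRUE)) {
    stop("atom_percent_excess: atom percent values must lie in [0.2, 100)",
         call. = FALSE)
  }
  at_labeled - at_control
}

#' 15N taken up by a labeled plant
#'
#' `(APE/100) x total biomass (g) x (N%/100) x 1e6`, in micrograms.
#' Total biomass is shoot + root dry mass of the labeled individual and N% its
#' whole-plant nitrogen concentration. This is the dimensionally consistent
#' form of the tracer-uptake equation (APE and N concentration are percentages,
#' biomass is in grams, output in ug).
#'
#' @param ape atom percent excess, %.
#' @param total_biomass whole-plant dry biomass, g.
#' @param n_content whole-plant N concentration, % of dry mass.
#' @return 15N uptake, ug.
#' @examples
#' n15_uptake(0.1, 10, 2) # 200
#' @export
n15_uptake <- function(ape, total_biomass, n_content) {
  if (any(ape < 0 | total_biomass < 0 | n_content < 0, na.rm = TRUE)) {
    stop("n15_uptake: inputs must be >= 0", call. = FALSE)
  }
  (ape / 100) * total_biomass * (n_content / 100) * 1e6
}

#' 15N uptake rate per unit root biomass
#'
#' Tracer uptake divided by root biomass within the labeled zone and
#' incubation time; uptake is assumed linear over the incubation window.
#'
#' @param uptake 15N uptake, ug.
#' @param root_biomass root dry biomass within the labeled soil cylinder, g.
#' @param time incubation time, h.
#' @return uptake rate, ug N g^-1 root h^-1.
#' @export
n15_uptake_rate <- function(uptake, root_biomass, time) {
  if (any(root_biomass <= 0, na.rm = TRUE) || any(time <= 0, na.rm = TRUE)) {
    stop("n15_uptake_rate: root biomass and time must be > 0", call. = FALSE)
  }
  uptake / (root_biomass * time)
}

#' Uptake of pre-existing soil N (pool-dilution scaling)
#'
#' Scales tracer uptake by the ratio of the native soil pool of the labeled
#' form to the added tracer concentration:
#' `actual = 15N_uptake x C_available / C15N_added`.
#'
#' @param uptake 15N uptake, ug.
#' @param c_available pre-existing NH4+ or NO3- content of the rhizosphere
#'   soil, mg N kg^-1 dw.
#' @param c15n_added added tracer concentration, mg N kg^-1 dw; must be > 0
#'   (see [c15n_added()]).
#' @return actual N uptake, ug.
#' @examples
#' actual_uptake(200, 10, 0.24) # 8333.3
#' @export
actual_uptake <- function(uptake, c_available, c15n_added) {
  if (any(c15n_added <= 0, na.rm = TRUE)) {
    stop("actual_uptake: added tracer concentration must be > 0", call. = FALSE)
  }
  if (any(c_available < 0, na.rm = TRUE)) {
    stop("actual_uptake: soil N content must be >= 0", call. = FALSE)
  }
  uptake * c_available / c15n_added
}

#' Uptake rate of pre-existing soil N
#'
#' `15N uptake rate x C_available / C15N_added`; identical (to rounding) to
#' [actual_uptake()] divided by root biomass and time.
#'
#' @param uptake_rate 15N uptake rate, ug N g^-1 root h^-1.
#' @inheritParams actual_uptake
#' @return actual N uptake rate, ug N g^-1 root h^-1.
#' @export
actual_uptake_rate <- function(uptake_rate, c_available, c15n_added) {
  actual_uptake(uptake_rate, c_available, c15n_added)
}

#' Uptake of pre-existing soil N per quadrat
#'
#' Actual uptake rate scaled to ground area using the quadrat root standing
#' stock: `rate x root biomass per m2 x time`, in ug m^-2 over the incubation.
#'
#' @param actual_rate actual N uptake rate, ug N g^-1 root h^-1.
#' @param root_biomass_m2 quadrat root biomass, g m^-2.
#' @param time incubation time, h.
#' @return uptake per quadrat, ug m^-2.
#' @export
uptake_per_quadrat <- function(actual_rate, root_biomass_m2, time) {
  if (any(actual_rate < 0 | root_biomass_m2 < 0 | time < 0, na.rm = TRUE)) {
    stop("uptake_per_quadrat: inputs must be >= 0", call. = FALSE)
  }
  actual_rate * root_biomass_m2 * time
}

# keys identifying one plant individual / one quadrat
.plant_key <- c("site", "habitat", "quadrat", "species", "treatment")
.quadrat_key <- c("site", "habitat", "quadrat", "species")

.tracer_forms <- c(nh4_label = "NH4", no3_label = "NO3")

#' Run the tracer chain on plant, soil, and quadrat tables
#'
#' Computes, for every labeled plant, the full chain from measured isotope
#' signal to per-quadrat uptake of pre-existing soil N: atom percent excess
#' against the same-quadrat control individual, 15N uptake and uptake rate,
#' actual (pool-dilution-scaled) uptake and uptake rate of the labeled form,
#' and uptake per quadrat.
#'
#' Plants may report either `delta15N` (per mil) or `at_percent` (atom%);
#' delta values are converted with [delta_to_atom_percent()]. The available
#' soil pool of the labeled form is taken from the plant's own rhizosphere
#' soil record. Negative atom-percent-excess values are clamped to zero,
#' flagged in the `ape_clamped` column, and reported via a warning: negative
#' uptake is physically meaningless, but silent clamping would hide QC
#' problems.
#'
#' @param plants data frame with columns `site, habitat, quadrat, species,
#'   treatment` (`nh4_label`, `no3_label`, or `control`), `shoot_biomass`,
#'   `root_biomass` (g; roots within the labeled cylinder),
#'   `n_concentration` (% of dry mass), and `delta15N` or `at_percent`.
#' @param soil data frame with the same id columns plus `nh4` and `no3`
#'   (mg N kg^-1 dw soil), one record per plant.
#' @param quadrats data frame keyed by `site, habitat, quadrat, species` with
#'   `shoot_biomass_m2` and `root_biomass_m2` (g m^-2). Optional: if omitted,
#'   `uptake_per_quadrat` is `NA`.
#' @param config a [labeling_config()].
#'
#' @return data frame of class `uptake_table`: one row per labeled plant with
#'   id columns, `form` (`"NH4"` or `"NO3"`), `ape`, `ape_clamped`,
#'   `n15_uptake` (ug), `n15_uptake_rate` (ug/g root/h), `c_available`
#'   (mg/kg), `actual_uptake` (ug), `actual_uptake_rate` (ug/g root/h), and
#'   `uptake_per_quadrat` (ug/m2).
#' @export
compute_uptake <- function(plants, soil, quadrats = NULL,
                           config = labeling_config()) {
  stopifnot(inherits(config, "labeling_config"))
  plants <- as.data.frame(plants)
  soil <- as.data.frame(soil)
  need <- c(.plant_key, "shoot_biomass", "root_biomass", "n_concentration")
  miss <- setdiff(need, names(plants))
  if (length(miss)) {
    stop("compute_uptake: plants table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!any(c("delta15N", "at_percent") %in% names(plants))) {
    stop("compute_uptake: plants need a 'delta15N' or 'at_percent' column",
         call. = FALSE)
  }
  if (!all(c(.plant_key, "nh4", "no3") %in% names(soil))) {
    stop("compute_uptake: soil table needs id columns plus 'nh4' and 'no3'",
         call. = FALSE)
  }

  if (!"at_percent" %in% names(plants) || anyNA(plants$at_percent)) {
    plants$at_percent <- delta_to_atom_percent(plants$delta15N)
  }

  labeled <- plants[plants$treatment %in% names(.tracer_forms), , drop = FALSE]
  controls <- plants[plants$treatment == "control", , drop = FALSE]
  if (nrow(labeled) == 0L) {
    stop("compute_uptake: no labeled plants in input", call. = FALSE)
  }

  qid <- function(d) interaction(d[.quadrat_key], drop = FALSE, lex.order = TRUE)
  ctrl_at <- controls$at_percent[match(qid(labeled), qid(controls))]
  if (anyNA(ctrl_at)) {
    bad <- unique(qid(labeled)[is.na(ctrl_at)])
    stop("compute_uptake: no control plant for quadrat(s): ",
         paste(utils::head(as.character(bad), 5), collapse = "; "),
         call. = FALSE)
  }

  # own-rhizosphere soil record per labeled plant
  pid <- function(d) interaction(d[.plant_key], drop = FALSE, lex.order = TRUE)
  srow <- match(pid(labeled), pid(soil))
  if (anyNA(srow)) {
    stop("compute_uptake: missing soil record for ", sum(is.na(srow)),
         " labeled plant(s)", call. = FALSE)
  }

  form <- .tracer_forms[labeled$treatment]
  c_av <- ifelse(form == "NH4", soil$nh4[srow], soil$no3[srow])

  ape <- atom_percent_excess(labeled$at_percent, ctrl_at)
  clamped <- ape < 0
  if (any(clamped)) {
    warning("compute_uptake: ", sum(clamped),
            " negative APE value(s) clamped to 0", call. = FALSE)
    ape[clamped] <- 0
  }

  total_biomass <- labeled$shoot_biomass + labeled$root_biomass
  n15 <- n15_uptake(ape, total_biomass, labeled$n_concentration)
  rate15 <- n15_uptake_rate(n15, labeled$root_biomass, config$incubation_time)
  added <- c15n_added(config)
  act <- actual_uptake(n15, c_av, added)
  act_rate <- actual_uptake_rate(rate15, c_av, added)

  upq <- rep(NA_real_, nrow(labeled))
  if (!is.null(quadrats)) {
    quadrats <- as.data.frame(quadrats)
    if (!all(c(.quadrat_key, "root_biomass_m2") %in% names(quadrats))) {
      stop("compute_uptake: quadrats table needs id columns plus 'root_biomass_m2'",
           call. = FALSE)
    }
    qrow <- match(qid(labeled), qid(quadrats))
    if (anyNA(qrow)) {
      stop("compute_uptake: missing quadrat harvest record for ",
           sum(is.na(qrow)), " labeled plant(s)", call. = FALSE)
    }
    upq <- uptake_per_quadrat(act_rate, quadrats$root_biomass_m2[qrow],
                              config$incubation_time)
  }

  out <- data.frame(
    labeled[.plant_key],
    form = unname(form),
    ape = ape,
    ape_clamped = clamped,
    n15_uptake = n15,
    n15_uptake_rate = rate15,
    c_available = c_av,
    actual_uptake = act,
    actual_uptake_rate = act_rate,
    uptake_per_quadrat = upq,
    row.names = NULL
  )
  class(out) <- c("uptake_table", "data.frame")
  out
}
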