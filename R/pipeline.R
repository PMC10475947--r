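# Pipeline plumbing: table validation, configuration, orchestration, and
# artifact writing. CSV with UTF-8 and "." decimal, header row mandatory;
# units live in a machine-readable JSON sidecar, not in column names.

.schema_units <- list(
  plants = c(site = "id", habitat = "id", quadrat = "id", species = "id",
             treatment = "id", shoot_biomass = "g", root_biomass = "g",
             n_concentration = "% dw", delta15N = "per mil",
             at_percent = "atom%"),
  soil = c(site = "id", habitat = "id", quadrat = "id", species = "id",
           treatment = "id", nh4 = "mg N/kg dw", no3 = "mg N/kg dw",
           din = "mg N/kg dw", ratio_no3_nh4 = "dimensionless"),
  quadrats = c(site = "id", habitat = "id", quadrat = "id", species = "id",
               shoot_biomass_m2 = "g/m2", root_biomass_m2 = "g/m2",
               root_shoot_ratio = "dimensionless"),
  uptake = c(form = "NH4|NO3", ape = "atom%", n15_uptake = "ug",
             n15_uptake_rate = "ug N/g root/h", c_available = "mg N/kg dw",
             actual_uptake = "ug", actual_uptake_rate = "ug N/g root/h",
             uptake_per_quadrat = "ug/m2"),
  indices = c(f_no3 = "fraction", f_nh4 = "fraction", p_no3 = "fraction",
              p_nh4 = "fraction", beta_no3 = "dimensionless",
              beta_nh4 = "dimensionless", ps = "%")
)

#' Validate the input tables of a pipeline run
#'
#' Schema, type, and referential-integrity checks on the plant, soil, and
#' quadrat tables: required columns present and numeric where they must be,
#' biomasses positive, N concentration in (0, 100), soil pools non-negative,
#' every labeled plant matched by a same-quadrat same-species control plant
#' and its own soil record, and a quadrat harvest record for every quadrat.
#' Fails fast with row-level messages when `stop_on_error` (default); with
#' `stop_on_error = FALSE` the full report is returned for inspection.
#'
#' @param plants,soil,quadrats input tables; see [compute_uptake()] for
#'   schemas. `quadrats` may be `NULL`.
#' @param stop_on_error raise an error when problems are found (default
#'   `TRUE`).
#' @return (invisibly when clean) list with `ok` and character vector
#'   `problems`.
#' @export
validate_tables <- function(plants, soil, quadrats = NULL,
                            stop_on_error = TRUE) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  plants <- as.data.frame(plants)
  soil <- as.data.frame(soil)
  need_p <- c(.plant_key, "shoot_biomass", "root_biomass", "n_concentration")
  miss <- setdiff(need_p, names(plants))
  if (length(miss)) note("plants: missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!any(c("delta15N", "at_percent") %in% names(plants))) {
    note("plants: need a 'delta15N' or 'at_percent' column")
  }
  miss_s <- setdiff(c(.plant_key, "nh4", "no3"), names(soil))
  if (length(miss_s)) note("soil: missing column(s): ",
                           paste(miss_s, collapse = ", "))

  if (!length(problems)) {
    bad <- which(!is.finite(plants$shoot_biomass) | plants$shoot_biomass <= 0 |
                 !is.finite(plants$root_biomass) | plants$root_biomass <= 0)
    for (i in bad) note("plants row ", i, ": biomass must be > 0")
    bad <- which(!is.finite(plants$n_concentration) |
                 plants$n_concentration <= 0 | plants$n_concentration >= 100)
    for (i in bad) note("plants row ", i, ": N concentration must be in (0, 100)")
    if ("delta15N" %in% names(plants)) {
      bad <- which(is.finite(plants$delta15N) & plants$delta15N <= -1000)
      for (i in bad) note("plants row ", i, ": delta15N must be > -1000")
    }
    bad <- which(!is.finite(soil$nh4) | soil$nh4 < 0 |
                 !is.finite(soil$no3) | soil$no3 < 0)
    for (i in bad) note("soil row ", i, ": NH4/NO3 must be >= 0")

    qid <- function(d) interaction(d[.quadrat_key], drop = FALSE,
                                   lex.order = TRUE)
    pid <- function(d) interaction(d[.plant_key], drop = FALSE,
                                   lex.order = TRUE)
    labeled <- plants[plants$treatment %in% names(.tracer_forms), ,
                      drop = FALSE]
    controls <- plants[plants$treatment == "control", , drop = FALSE]
    unmatched <- !(as.character(qid(labeled)) %in%
                     as.character(qid(controls)))
    for (q in unique(as.character(qid(labeled))[unmatched])) {
      note("missing control plant for quadrat ", q)
    }
    nosoil <- !(as.character(pid(labeled)) %in% as.character(pid(soil)))
    for (q in unique(as.character(pid(labeled))[nosoil])) {
      note("missing soil record for labeled plant ", q)
    }
    if (!is.null(quadrats)) {
      quadrats <- as.data.frame(quadrats)
      miss_q <- setdiff(c(.quadrat_key, "shoot_biomass_m2", "root_biomass_m2"),
                        names(quadrats))
      if (length(miss_q)) {
        note("quadrats: missing column(s): ", paste(miss_q, collapse = ", "))
      } else {
        bad <- which(quadrats$shoot_biomass_m2 <= 0 |
                     quadrats$root_biomass_m2 <= 0)
        for (i in bad) note("quadrats row ", i, ": biomass must be > 0")
        noq <- !(as.character(qid(labeled)) %in%
                   as.character(qid(quadrats)))
        for (q in unique(as.character(qid(labeled))[noq])) {
          note("missing quadrat harvest record for ", q)
        }
      }
    }
  }

  ok <- length(problems) == 0L
  if (!ok && stop_on_error) {
    stop("validate_tables: ", length(problems), " problem(s):\n  ",
         paste(utils::head(problems, 10), collapse = "\n  "),
         if (length(problems) > 10) "\n  ..." else "", call. = FALSE)
  }
  invisible(list(ok = ok, problems = problems))
}

#' Pipeline configuration
#'
#' Assembles everything a full run needs: the labeling constants, the
#' simulate-mode blocks (design, truth, noise), the significance level, the
#' soil-proportion scope for the indices, and the seed. Can be populated from
#' a YAML file via [read_pipeline_config()].
#'
#' @param labeling a [labeling_config()].
#' @param design a [study_design()] (simulate mode).
#' @param truth truth table (simulate mode; default [default_truth()]).
#' @param noise a [noise_model()] (simulate mode).
#' @param alpha significance level for group tests (default 0.05).
#' @param soil_scope `"pair"` or `"quadrat"`; see [compute_indices()].
#' @param seed integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(labeling = labeling_config(),
                            design = study_design(),
                            truth = default_truth(),
                            noise = noise_model(),
                            alpha = 0.05,
                            soil_scope = "pair",
                            seed = 1L) {
  stopifnot(inherits(labeling, "labeling_config"),
            inherits(design, "study_design"),
            inherits(noise, "noise_model"),
            alpha > 0, alpha < 1)
  structure(list(labeling = labeling, design = design, truth = truth,
                 noise = noise, alpha = alpha, soil_scope = soil_scope,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the constructors field-for-field under blocks `labeling`,
#' `design`, `noise`, plus scalars `alpha`, `soil_scope`, `seed`; omitted
#' fields take the package defaults. An optional `truth` block holds the
#' truth-table columns as parallel lists.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(fun, block) do.call(fun, if (is.null(block)) list() else block)
  truth <- if (is.null(raw$truth)) default_truth() else {
    tt <- as.data.frame(raw$truth, stringsAsFactors = FALSE)
    class(tt) <- c("truth_table", "data.frame")
    tt
  }
  pipeline_config(
    labeling = build(labeling_config, raw$labeling),
    design = build(study_design, raw$design),
    truth = truth,
    noise = build(noise_model, raw$noise),
    alpha = if (is.null(raw$alpha)) 0.05 else raw$alpha,
    soil_scope = if (is.null(raw$soil_scope)) "pair" else raw$soil_scope,
    seed = if (is.null(raw$seed)) 1L else raw$seed
  )
}

# stable hash of the configuration for artifact provenance
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  dump <- unclass(config)
  dump$truth <- lapply(as.list(dump$truth), as.vector)
  dump <- lapply(dump, function(x) if (is.list(x)) lapply(x, as.vector) else x)
  yaml::write_yaml(dump, tmp)
  unname(tools::md5sum(tmp))
}

.write_table <- function(d, dir, name) {
  utils::write.csv(d, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end and writes a reproducible artifact
#' directory. In `"simulate"` mode the input tables are generated from the
#' configured design/truth/noise; in `"run"` mode they are read from `inputs`
#' (paths to `plants.csv`, `soil.csv`, `quadrats.csv`). Stages: validation,
#' tracer chain ([compute_uptake()]), strategy indices ([compute_indices()]),
#' cell aggregation, and the comparison layer (one-way ANOVA letters across
#' habitats per species, between-species t tests per habitat, one-sample
#' t tests of the preference index against zero, the mixed-model screen, and
#' the SMA comparison of the preference index against soil DIN). Preference
#' indices are quantile-transformed and positive variables log-transformed
#' before group tests, per the standard workflow for these data.
#'
#' Outputs under `out_dir`: `plants.csv`, `soil.csv`, `quadrats.csv` (simulate
#' mode; plus `truth.csv`), `uptake.csv`, `indices.csv`, `cell_means.csv`,
#' `tests.csv`, `stats_report.json`, `schema.json` (column units),
#' `run_metadata.json` (seed, config hash, timestamps), and `run.log`.
#' Given the same inputs, configuration, and seed the artifacts are
#' byte-identical apart from the timestamp in the metadata.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param mode `"simulate"` or `"run"`.
#' @param inputs named list of file paths (`plants`, `soil`, `quadrats`) for
#'   `"run"` mode.
#' @return (invisibly) list with the in-memory tables and test results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         mode = c("simulate", "run"), inputs = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }

  if (mode == "simulate") {
    say("INFO stage=simulate seed=", config$seed)
    sim <- simulate_dataset(config$design, config$truth, config$noise,
                            config$labeling, seed = config$seed)
    plants <- sim$plants; soil <- sim$soil; quadrats <- sim$quadrats
    .write_table(config$truth, out_dir, "truth")
  } else {
    for (nm in c("plants", "soil", "quadrats")) {
      if (is.null(inputs[[nm]])) {
        stop("run_pipeline: 'run' mode needs inputs$", nm, call. = FALSE)
      }
      if (!file.exists(inputs[[nm]])) {
        stop("run_pipeline [stage=read]: input file not found: ",
             inputs[[nm]], call. = FALSE)
      }
    }
    say("INFO stage=read")
    plants <- utils::read.csv(inputs$plants)
    soil <- utils::read.csv(inputs$soil)
    quadrats <- utils::read.csv(inputs$quadrats)
  }
  .write_table(plants, out_dir, "plants")
  .write_table(soil, out_dir, "soil")
  .write_table(quadrats, out_dir, "quadrats")

  say("INFO stage=validate")
  validate_tables(plants, soil, quadrats)

  say("INFO stage=uptake")
  uptake <- withCallingHandlers(
    compute_uptake(plants, soil, quadrats, config$labeling),
    warning = function(w) {
      say("WARNING stage=uptake ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  .write_table(uptake, out_dir, "uptake")

  say("INFO stage=indices")
  indices <- compute_indices(uptake, soil, soil_scope = config$soil_scope)
  n_excl <- sum(indices$excluded)
  if (n_excl) say("WARNING stage=indices excluded_quadrats=", n_excl)
  .write_table(indices, out_dir, "indices")

  cells <- aggregate_indices(indices)
  .write_table(cells, out_dir, "cell_means")

  say("INFO stage=compare alpha=", config$alpha)
  ok <- indices[!indices$excluded, , drop = FALSE]
  vars <- c("f_no3", "f_nh4", "beta_no3", "beta_nh4", "ps")
  tests <- list()
  report <- list(alpha = config$alpha,
                 multiple_testing = "none applied across response variables")

  for (v in vars) {
    x <- if (startsWith(v, "beta")) quantile_transform(ok[[v]])
         else suppressWarnings(log_transform(ok[[v]]))
    for (sp in unique(ok$species)) {
      sel <- ok$species == sp
      if (length(unique(ok$habitat[sel])) >= 2) {
        aw <- oneway_anova_letters(x[sel], ok$habitat[sel], config$alpha)
        tests[[length(tests) + 1]] <- data.frame(
          variable = v, test = "oneway_anova", scope = sp,
          statistic = aw$F, df = paste(aw$df, collapse = ","), p = aw$p,
          detail = paste(names(aw$letters), aw$letters, sep = "=",
                         collapse = ";"))
      }
    }
    for (hb in unique(ok$habitat)) {
      sp <- unique(ok$species)
      if (length(sp) == 2) {
        tt <- welch_or_student_t(x[ok$habitat == hb & ok$species == sp[1]],
                                 x[ok$habitat == hb & ok$species == sp[2]])
        tests[[length(tests) + 1]] <- data.frame(
          variable = v, test = "t_between_species", scope = hb,
          statistic = tt$t, df = as.character(round(tt$df, 2)), p = tt$p,
          detail = paste0(sp[1], "-", sp[2]))
      }
    }
    if (startsWith(v, "beta")) {
      for (sp in unique(ok$species)) for (hb in unique(ok$habitat)) {
        # beta vs 0 is tested on the raw scale: zero is only meaningful there
        bb <- ok[[v]][ok$species == sp & ok$habitat == hb]
        if (length(bb) >= 2) {
          tt <- welch_or_student_t(bb, mu = 0)
          tests[[length(tests) + 1]] <- data.frame(
            variable = v, test = "t_vs_zero", scope = paste(sp, hb),
            statistic = tt$t, df = as.character(tt$df), p = tt$p,
            detail = sprintf("mean=%.4f", mean(bb)))
        }
      }
    }
    mm <- tryCatch(
      mixed_model_screen(cbind(ok, .resp = x), ".resp"),
      warning = function(w) {
        say("WARNING stage=compare var=", v, " ", conditionMessage(w))
        suppressWarnings(mixed_model_screen(cbind(ok, .resp = x), ".resp"))
      })
    for (i in seq_len(nrow(mm))) {
      tests[[length(tests) + 1]] <- data.frame(
        variable = v, test = "mixed_model", scope = mm$term[i],
        statistic = mm$F[i],
        df = paste(mm$num_df[i], mm$den_df[i], sep = ","), p = mm$p[i],
        detail = attr(mm, "fit_type"))
    }
  }

  # SMA: preference for ammonium vs soil DIN, per species
  soil_q <- stats::aggregate(cbind(nh4, no3) ~ site + habitat + quadrat +
                               species, data = soil, FUN = mean)
  key_i <- interaction(ok[.quadrat_key], drop = FALSE, lex.order = TRUE)
  key_s <- interaction(soil_q[.quadrat_key], drop = FALSE, lex.order = TRUE)
  din <- (soil_q$nh4 + soil_q$no3)[match(key_i, key_s)]
  sma_groups <- lapply(split(seq_len(nrow(ok)), ok$species), function(idx) {
    list(x = suppressWarnings(log_transform(din[idx])),
         y = quantile_transform(ok$beta_nh4[idx]))
  })
  sma_res <- tryCatch(sma_compare(sma_groups, alpha = config$alpha),
                      error = function(e) NULL)
  if (!is.null(sma_res)) {
    report$sma_beta_nh4_vs_din <- list(
      common_slope = sma_res$common_slope,
      slopes = lapply(sma_res$fits, function(f)
        list(slope = f$slope, r2 = f$r2, p = f$p, n = f$n)),
      slope_test = sma_res$slope_test,
      elevation_test = sma_res$elevation_test,
      shift_test = sma_res$shift_test
    )
  }

  tests <- do.call(rbind, tests)
  .write_table(tests, out_dir, "tests")

  meta <- list(seed = config$seed, mode = mode,
               config_hash = .config_hash(config),
               n_plants = nrow(plants), n_quadrats = nrow(quadrats),
               excluded_quadrats = n_excl,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report$seed <- config$seed
  report$config_hash <- meta$config_hash
  jsonlite::write_json(report, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(.schema_units, file.path(out_dir, "schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("INFO stage=done")

  invisible(list(plants = plants, soil = soil, quadrats = quadrats,
                 uptake = uptake, indices = indices, cells = cells,
                 tests = tests, report = report))
}
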