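# Nitrogen-form acquisition strategy indices: proportional contributions f,
# preference index beta, and percentage-similarity plasticity PS.

#' Proportional contribution of each N form to plant N acquisition
#'
#' The fraction of the total actual uptake rate contributed by nitrate and by
#' ammonium: `f_no3 = rate_no3 / (rate_no3 + rate_nh4)` and its complement.
#'
#' @param rate_no3,rate_nh4 actual uptake rates of NO3- and NH4+,
#'   ug N g^-1 root h^-1; both >= 0. When both are zero the contribution is
#'   undefined and `NA` is returned for that element (rows are flagged and
#'   excluded downstream).
#' @return list with components `f_no3` and `f_nh4`, each in `[0, 1]` and
#'   summing to 1 where defined.
#' @examples
#' proportional_contribution(1, 2) # f_no3 = 1/3, f_nh4 = 2/3
#' @export
proportional_contribution <- function(rate_no3, rate_nh4) {
  if (any(rate_no3 < 0 | rate_nh4 < 0, na.rm = TRUE)) {
    stop("proportional_contribution: rates must be >= 0", call. = FALSE)
  }
  tot <- rate_no3 + rate_nh4
  und <- !is.na(tot) & tot == 0
  tot[und] <- NA_real_
  list(f_no3 = rate_no3 / tot, f_nh4 = rate_nh4 / tot)
}

#' Preference index for an inorganic N form
#'
#' `beta_NF = f_NF - [NF]/[DIN]`: the plant's proportional use of a form minus
#' that form's proportional availability in the rhizosphere soil. Positive
#' values indicate a preference for the form, negative values a preference for
#' the other form, zero no preference. Values lie in `[-1, 1]` and the two
#' forms' indices are antisymmetric (`beta_no3 = -beta_nh4`).
#'
#' @param f_nf proportional contribution of the form to plant N, in `[0, 1]`.
#' @param soil_nf soil content of the form, mg N kg^-1 dw.
#' @param soil_din total dissolved inorganic N (NH4+ + NO3-), mg N kg^-1 dw;
#'   must be > 0.
#' @return preference index, dimensionless.
#' @examples
#' preference_index(0.8, 3, 10) # 0.5
#' @export
preference_index <- function(f_nf, soil_nf, soil_din) {
  if (any(soil_din <= 0, na.rm = TRUE)) {
    stop("preference_index: soil DIN must be > 0", call. = FALSE)
  }
  if (any(f_nf < 0 | f_nf > 1, na.rm = TRUE)) {
    stop("preference_index: f must lie in [0, 1]", call. = FALSE)
  }
  if (any(soil_nf < 0 | soil_nf > soil_din, na.rm = TRUE)) {
    stop("preference_index: soil form content must lie in [0, soil DIN]",
         call. = FALSE)
  }
  f_nf - soil_nf / soil_din
}

#' Percentage similarity between plant uptake and soil availability
#'
#' The plasticity index
#' `PS = 100 (1 - 0.5 (|f_nh4 - p_nh4| + |f_no3 - p_no3|))`,
#' where `f` are the plant's proportional contributions and `p` the soil DIN
#' proportions. PS is 100% exactly when the plant takes up the two forms in
#' strict proportion to their availability (a fully plastic strategy) and
#' decreases towards 0 as uptake departs from availability.
#'
#' @param f_nh4,f_no3 plant proportional contributions, each in `[0, 1]`,
#'   summing to 1 (tolerance 1e-9).
#' @param p_nh4,p_no3 soil DIN proportions, same constraints.
#' @return percentage similarity, % in `[0, 100]`.
#' @examples
#' percentage_similarity(0.8, 0.2, 0.3, 0.7) # 50
#' @export
percentage_similarity <- function(f_nh4, f_no3, p_nh4, p_no3) {
  chk_pair <- function(a, b, what) {
    if (any(a < 0 | a > 1 | b < 0 | b > 1, na.rm = TRUE)) {
      stop("percentage_similarity: ", what, " must lie in [0, 1]", call. = FALSE)
    }
    if (any(abs(a + b - 1) > 1e-9, na.rm = TRUE)) {
      stop("percentage_similarity: ", what, " must sum to 1", call. = FALSE)
    }
  }
  chk_pair(f_nh4, f_no3, "plant fractions")
  chk_pair(p_nh4, p_no3, "soil proportions")
  100 * (1 - 0.5 * (abs(f_nh4 - p_nh4) + abs(f_no3 - p_no3)))
}

#' Per-quadrat strategy indices from an uptake table
#'
#' Pairs the two labeled individuals of each quadrat x species (one NH4+-
#' labeled, one NO3--labeled), computes the proportional contributions from
#' their actual uptake rates, the soil DIN proportions, the preference indices,
#' and the percentage-similarity plasticity index.
#'
#' Soil proportions are computed, per quadrat, from the mean NH4+ and NO3-
#' contents of the rhizosphere soil records of the two labeled plants
#' (`soil_scope = "pair"`, the default) or of all plants in the quadrat
#' including the control (`soil_scope = "quadrat"`).
#'
#' Quadrats where either labeled plant is missing, where both actual rates are
#' zero, or where an APE value was clamped are flagged in the `excluded`
#' column (with the reason in `exclude_reason`) and carry `NA` indices.
#'
#' @param uptake an `uptake_table` from [compute_uptake()].
#' @param soil the soil table used for the uptake computation.
#' @param soil_scope `"pair"` or `"quadrat"`; see Details.
#' @return data frame of class `indices_table`, one row per quadrat x species:
#'   id columns, `f_no3`, `f_nh4`, `p_no3`, `p_nh4`, `beta_no3`, `beta_nh4`,
#'   `ps`, `preference_call` (`"NH4"`, `"NO3"`, or `"none"`; sample-level sign
#'   call -- the population-level call is a t test against zero, see
#'   [welch_or_student_t()]), `excluded`, `exclude_reason`.
#' @export
compute_indices <- function(uptake, soil, soil_scope = c("pair", "quadrat")) {
  soil_scope <- match.arg(soil_scope)
  uptake <- as.data.frame(uptake)
  soil <- as.data.frame(soil)

  qid_u <- interaction(uptake[.quadrat_key], drop = TRUE, lex.order = TRUE)
  cells <- unique(uptake[.quadrat_key])
  qid_c <- interaction(cells, drop = FALSE, lex.order = TRUE)
  soil_q <- interaction(soil[.quadrat_key], drop = FALSE, lex.order = TRUE)

  n <- nrow(cells)
  out <- data.frame(
    cells,
    f_no3 = NA_real_, f_nh4 = NA_real_,
    p_no3 = NA_real_, p_nh4 = NA_real_,
    beta_no3 = NA_real_, beta_nh4 = NA_real_,
    ps = NA_real_,
    preference_call = NA_character_,
    excluded = FALSE, exclude_reason = NA_character_,
    row.names = NULL
  )

  for (i in seq_len(n)) {
    rows <- uptake[qid_u == as.character(qid_c[i]), , drop = FALSE]
    r_nh4 <- rows$actual_uptake_rate[rows$form == "NH4"]
    r_no3 <- rows$actual_uptake_rate[rows$form == "NO3"]
    if (length(r_nh4) != 1L || length(r_no3) != 1L) {
      out$excluded[i] <- TRUE
      out$exclude_reason[i] <- "missing labeled plant"
      next
    }
    if (any(rows$ape_clamped)) {
      out$excluded[i] <- TRUE
      out$exclude_reason[i] <- "clamped APE"
      next
    }
    if (r_nh4 + r_no3 == 0) {
      out$excluded[i] <- TRUE
      out$exclude_reason[i] <- "zero total uptake"
      next
    }

    srows <- soil[soil_q == as.character(qid_c[i]), , drop = FALSE]
    if (soil_scope == "pair") {
      srows <- srows[srows$treatment %in% names(.tracer_forms), , drop = FALSE]
    }
    if (nrow(srows) == 0L) {
      out$excluded[i] <- TRUE
      out$exclude_reason[i] <- "missing soil record"
      next
    }
    nh4 <- mean(srows$nh4)
    no3 <- mean(srows$no3)
    din <- nh4 + no3
    if (din <= 0) {
      out$excluded[i] <- TRUE
      out$exclude_reason[i] <- "zero soil DIN"
      next
    }

    f <- proportional_contribution(r_no3, r_nh4)
    out$f_no3[i] <- f$f_no3
    out$f_nh4[i] <- f$f_nh4
    out$p_no3[i] <- no3 / din
    out$p_nh4[i] <- nh4 / din
    out$beta_no3[i] <- preference_index(f$f_no3, no3, din)
    out$beta_nh4[i] <- preference_index(f$f_nh4, nh4, din)
    out$ps[i] <- percentage_similarity(f$f_nh4, f$f_no3,
                                       nh4 / din, no3 / din)
    out$preference_call[i] <-
      if (out$beta_nh4[i] > 0) "NH4" else if (out$beta_nh4[i] < 0) "NO3" else "none"
  }
  class(out) <- c("indices_table", "data.frame")
  out
}

#' Cell means and standard errors of strategy indices
#'
#' Aggregates per-quadrat values to species x habitat (optionally x site)
#' cells: mean, standard error, and replicate count per cell. Rows flagged
#' `excluded` are dropped before aggregation; empty cells are reported with
#' `n = 0` and `NA` mean/SE rather than as an error.
#'
#' @param indices an `indices_table` from [compute_indices()], or any data
#'   frame with the grouping columns and the requested variables.
#' @param vars character vector of columns to aggregate.
#' @param by grouping columns (default species and habitat).
#' @return data frame with one row per group x variable: grouping columns,
#'   `variable`, `mean`, `se`, `n`.
#' @export
aggregate_indices <- function(indices,
                              vars = c("f_no3", "f_nh4", "beta_no3",
                                       "beta_nh4", "ps"),
                              by = c("species", "habitat")) {
  d <- as.data.frame(indices)
  if ("excluded" %in% names(d)) d <- d[!d$excluded, , drop = FALSE]
  miss <- setdiff(c(by, vars), names(d))
  if (length(miss)) {
    stop("aggregate_indices: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  groups <- unique(d[by])
  groups <- groups[do.call(order, groups), , drop = FALSE]
  g_all <- interaction(d[by], drop = FALSE, lex.order = TRUE)
  g_lev <- interaction(groups, drop = FALSE, lex.order = TRUE)
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    in_g <- g_all == as.character(g_lev[i])
    do.call(rbind, lapply(vars, function(v) {
      x <- d[[v]][in_g & !is.na(d[[v]])]
      n <- length(x)
      data.frame(
        groups[i, , drop = FALSE],
        variable = v,
        mean = if (n) mean(x) else NA_real_,
        se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
        n = n,
        row.names = NULL
      )
    }))
  }))
  rownames(out) <- NULL
  out
}
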