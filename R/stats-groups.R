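# Group-comparison layer: one-way ANOVA with compact letter displays among
# habitats, t tests between species (and of beta against 0), and the nested
# mixed-model screen across the whole design.

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: starting from one letter covering all groups,
#' every significant pair splits the letters containing both members, and
#' redundant (subset) letters are absorbed. Two groups share a letter if and
#' only if their pairwise test is not significant at `alpha`.
#'
#' @param pmat symmetric matrix of pairwise p values with group names as
#'   dimnames (diagonal ignored).
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter strings, one per group.
#' @export
letter_display <- function(pmat, alpha = 0.05) {
  groups <- rownames(pmat)
  stopifnot(!is.null(groups), identical(rownames(pmat), colnames(pmat)))
  cols <- list(groups)
  pairs <- which(upper.tri(pmat), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- groups[pairs[k, 1]]
    j <- groups[pairs[k, 2]]
    if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
    hit <- vapply(cols, function(s) all(c(i, j) %in% s), logical(1))
    if (!any(hit)) next
    new_cols <- list()
    for (idx in seq_along(cols)) {
      if (hit[idx]) {
        new_cols <- c(new_cols, list(setdiff(cols[[idx]], i)),
                      list(setdiff(cols[[idx]], j)))
      } else {
        new_cols <- c(new_cols, cols[idx])
      }
    }
    # absorb: drop columns contained in another column
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      for (b in seq_along(new_cols)) {
        if (a != b && keep[a] && keep[b] &&
            all(new_cols[[a]] %in% new_cols[[b]]) &&
            !(all(new_cols[[b]] %in% new_cols[[a]]) && a < b)) {
          keep[a] <- FALSE
        }
      }
    }
    cols <- new_cols[keep]
  }
  # order letters by first group appearance for a stable, readable display
  first <- vapply(cols, function(s) min(match(s, groups)), numeric(1))
  cols <- cols[order(first)]
  out <- vapply(groups, function(g) {
    paste0(letters[which(vapply(cols, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  out
}

#' One-way ANOVA with Tukey HSD letters
#'
#' Classical one-way ANOVA of a variable across habitats (or any grouping),
#' followed by Tukey honest-significant-difference pairwise comparisons that
#' feed a compact letter display: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param values numeric response.
#' @param groups grouping vector (>= 2 groups, each with n >= 2).
#' @param alpha significance level for the letters (default 0.05).
#' @return list of class `anova_letters`: `F`, `df`, `p`, `letters` (named
#'   character vector), `tukey` (pairwise table), `means` (group means).
#' @export
oneway_anova_letters <- function(values, groups, alpha = 0.05) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2) {
    stop("oneway_anova_letters: need at least 2 groups", call. = FALSE)
  }
  if (any(table(groups) < 2)) {
    stop("oneway_anova_letters: every group needs n >= 2", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  tab <- stats::anova(fit)
  lv <- levels(groups)
  pmat <- matrix(1, nlevels(groups), nlevels(groups), dimnames = list(lv, lv))
  if (stats::sd(values) == 0) {
    # all observations identical: no differences anywhere
    letters_out <- stats::setNames(rep("a", nlevels(groups)), lv)
    tk <- NULL
  } else {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
    pr <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (k in seq_along(pr)) {
      a <- pr[[k]][1]; b <- pr[[k]][2]
      pmat[a, b] <- pmat[b, a] <- tk[k, "p adj"]
    }
    letters_out <- letter_display(pmat, alpha)
  }
  structure(list(
    F = tab$`F value`[1], df = tab$Df, p = tab$`Pr(>F)`[1],
    letters = letters_out, tukey = tk,
    means = tapply(values, groups, mean), alpha = alpha
  ), class = "anova_letters")
}

#' @export
print.anova_letters <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  d <- data.frame(mean = round(as.numeric(x$means), 4),
                  letter = x$letters[names(x$means)])
  print(d)
  invisible(x)
}

#' Two-sample, paired, or one-sample t test with degenerate-case handling
#'
#' Thin wrapper over [stats::t.test()] adding the conventions needed in a
#' pipeline over field data: pooled variance by default (the convention of the
#' point-and-click packages these analyses are usually run in), a one-sample
#' mode against `mu` when `b` is `NULL` (used to test the preference index
#' against zero), and explicit handling of zero-variance inputs, which are
#' flagged instead of erroring: equal constants give `t = 0, p = 1`; a
#' constant sample away from `mu` gives `t = Inf, p = 0`.
#'
#' @param a,b numeric samples; `b = NULL` for the one-sample mode.
#' @param mu null value for the one-sample mode (default 0).
#' @param paired paired test (default `FALSE`).
#' @param var_equal pooled-variance Student test when `TRUE` (default);
#'   Welch when `FALSE`.
#' @return list: `t`, `df`, `p`, `estimate`, `method`, `degenerate`.
#' @export
welch_or_student_t <- function(a, b = NULL, mu = 0, paired = FALSE,
                               var_equal = TRUE) {
  a <- a[is.finite(a)]
  if (!is.null(b)) b <- b[is.finite(b)]
  if (length(a) < 2 || (!is.null(b) && !paired && length(b) < 2)) {
    stop("welch_or_student_t: need n >= 2 per sample", call. = FALSE)
  }
  if (paired && !is.null(b)) {
    if (length(a) != length(b)) {
      stop("welch_or_student_t: paired samples must have equal length",
           call. = FALSE)
    }
    return(welch_or_student_t(a - b, b = NULL, mu = mu))
  }

  zero_var <- function(x) stats::sd(x) == 0
  if (is.null(b)) {
    if (zero_var(a)) {
      hit <- isTRUE(all.equal(mean(a), mu))
      return(list(t = if (hit) 0 else Inf * sign(mean(a) - mu),
                  df = length(a) - 1,
                  p = if (hit) 1 else 0,
                  estimate = mean(a), method = "one-sample (degenerate)",
                  degenerate = TRUE))
    }
    tt <- stats::t.test(a, mu = mu)
  } else {
    if (zero_var(a) && zero_var(b)) {
      hit <- isTRUE(all.equal(mean(a), mean(b)))
      return(list(t = if (hit) 0 else Inf * sign(mean(a) - mean(b)),
                  df = length(a) + length(b) - 2,
                  p = if (hit) 1 else 0,
                  estimate = mean(a) - mean(b),
                  method = "two-sample (degenerate)", degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       estimate = if (is.null(b)) unname(tt$estimate)
                  else unname(tt$estimate[1] - tt$estimate[2]),
       method = tt$method, degenerate = FALSE)
}

#' Mixed-model screen of habitat and species effects
#'
#' Fits `response ~ habitat * species` with random intercepts for quadrats
#' nested within sites (REML, via [nlme::lme()]) and returns the fixed-effect
#' F table. With one observation per quadrat the quadrat level is confounded
#' with the residual and is dropped (random intercept for site only); with a
#' single site the random structure is unidentifiable and the screen
#' downgrades to a fixed-effects ANOVA with a warning. A constant response
#' yields a degenerate report rather than an error.
#'
#' @param data data frame with columns `habitat`, `species`, `site`,
#'   `quadrat`, and the response.
#' @param response name of the response column.
#' @return data frame: `term`, `num_df`, `den_df`, `F`, `p`, plus attribute
#'   `fit_type` (`"lme"`, `"lm"`, or `"degenerate"`).
#' @export
mixed_model_screen <- function(data, response) {
  need <- c("habitat", "species", "site", "quadrat", response)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("mixed_model_screen: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- data.frame(
    y = data[[response]],
    habitat = factor(data$habitat),
    species = factor(data$species),
    site = factor(data$site),
    # physical quadrat: unique within site across habitats/species
    quadrat = factor(paste(data$habitat, data$species, data$quadrat, sep = "/"))
  )
  d <- d[is.finite(d$y), , drop = FALSE]

  if (stats::sd(d$y) == 0) {
    out <- data.frame(term = c("habitat", "species", "habitat:species"),
                      num_df = NA_integer_, den_df = NA_integer_,
                      F = NA_real_, p = NA_real_)
    attr(out, "fit_type") <- "degenerate"
    warning("mixed_model_screen: constant response; no test performed",
            call. = FALSE)
    return(out)
  }

  fixed_only <- function(reason) {
    warning("mixed_model_screen: ", reason,
            "; downgrading to fixed-effects ANOVA", call. = FALSE)
    tab <- stats::anova(stats::lm(y ~ habitat * species, data = d))
    terms <- rownames(tab)[rownames(tab) != "Residuals"]
    out <- data.frame(term = terms,
                      num_df = tab$Df[seq_along(terms)],
                      den_df = tab$Df[nrow(tab)],
                      F = tab$`F value`[seq_along(terms)],
                      p = tab$`Pr(>F)`[seq_along(terms)])
    attr(out, "fit_type") <- "lm"
    out
  }

  if (nlevels(d$site) < 2) {
    return(fixed_only("fewer than 2 sites: random structure unidentifiable"))
  }

  reps_per_quadrat <- max(table(d$site, d$quadrat))
  rand <- if (reps_per_quadrat > 1) ~ 1 | site / quadrat else ~ 1 | site

  fit <- tryCatch(
    nlme::lme(y ~ habitat * species, random = rand, data = d,
              method = "REML"),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(fixed_only("mixed-model fit failed"))
  }
  tab <- stats::anova(fit)
  tab <- tab[rownames(tab) != "(Intercept)", , drop = FALSE]
  out <- data.frame(term = rownames(tab),
                    num_df = tab$numDF, den_df = tab$denDF,
                    F = tab$`F-value`, p = tab$`p-value`)
  rownames(out) <- NULL
  attr(out, "fit_type") <- "lme"
  out
}
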