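# Pre-analysis transforms and assumption checks. Preference indices are
# bounded in [-1, 1] and usually non-normal, hence the rank-based
# inverse-normal transform; strictly positive variables are log-transformed.

#' Rank-based inverse-normal (quantile) transform
#'
#' Maps values to normal scores through their ranks using the Blom offset:
#' `qnorm((r - 3/8) / (n + 1/4))`, with average ranks for ties. The result is
#' a deterministic function of the ranks only, preserves order, and is
#' approximately standard normal for untied data.
#'
#' @param values numeric vector; at least 3 finite values, not all equal.
#'   `NA`s are preserved in place.
#' @return numeric vector of normal scores, same length as `values`.
#' @examples
#' quantile_transform(c(3, 1, 2)) # symmetric about 0, middle value 0
#' @export
quantile_transform <- function(values) {
  ok <- is.finite(values)
  x <- values[ok]
  if (length(x) < 3) {
    stop("quantile_transform: need at least 3 finite values", call. = FALSE)
  }
  if (max(x) == min(x)) {
    stop("quantile_transform: all values tied; transform is degenerate",
         call. = FALSE)
  }
  r <- rank(x, ties.method = "average")
  n <- length(x)
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Log transform with exclusion of non-positive values
#'
#' Natural log by default (`base` configurable). Non-positive values cannot be
#' log-transformed; they are set to `NA`, counted, and reported via a warning
#' so the exclusion is visible rather than silent.
#'
#' @param values numeric vector.
#' @param base logarithm base (default `exp(1)`).
#' @return transformed vector with attribute `n_excluded`.
#' @export
log_transform <- function(values, base = exp(1)) {
  bad <- is.finite(values) & values <= 0
  if (any(bad)) {
    warning("log_transform: ", sum(bad),
            " non-positive value(s) excluded (set to NA)", call. = FALSE)
    values[bad] <- NA_real_
  }
  out <- log(values, base = base)
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Normality and homoscedasticity checks
#'
#' Shapiro-Wilk test per group and a Levene test on absolute deviations from
#' the group medians (the Brown-Forsythe variant). Advisory only: results are
#' returned for inspection and never block a pipeline run. Groups with fewer
#' than 3 observations are skipped with a warning; groups with zero spread are
#' flagged degenerate.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length.
#' @return list with `shapiro` (data frame: group, n, W, p, degenerate),
#'   `levene` (data frame: df1, df2, F, p, degenerate or `NULL` if fewer than
#'   2 usable groups).
#' @export
assumption_checks <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])

  shap <- do.call(rbind, lapply(levels(groups), function(g) {
    x <- values[groups == g]
    if (length(x) < 3) {
      warning("assumption_checks: group '", g,
              "' has n < 3; Shapiro-Wilk skipped", call. = FALSE)
      return(data.frame(group = g, n = length(x), W = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    }
    if (max(x) == min(x)) {
      return(data.frame(group = g, n = length(x), W = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    }
    sw <- stats::shapiro.test(x)
    data.frame(group = g, n = length(x), W = unname(sw$statistic),
               p = sw$p.value, degenerate = FALSE)
  }))

  levene <- NULL
  usable <- levels(groups)[table(groups) >= 2]
  if (length(usable) >= 2) {
    sel <- groups %in% usable
    g <- droplevels(groups[sel])
    x <- values[sel]
    adev <- abs(x - stats::ave(x, g, FUN = stats::median))
    if (max(adev) == min(adev)) {
      levene <- data.frame(df1 = nlevels(g) - 1L,
                           df2 = length(x) - nlevels(g),
                           F = NA_real_, p = NA_real_, degenerate = TRUE)
    } else {
      fit <- stats::anova(stats::lm(adev ~ g))
      levene <- data.frame(df1 = fit$Df[1], df2 = fit$Df[2],
                           F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
                           degenerate = FALSE)
    }
  } else {
    warning("assumption_checks: fewer than 2 groups with n >= 2; Levene skipped",
            call. = FALSE)
  }
  list(shapiro = shap, levene = levene)
}
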