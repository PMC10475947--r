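# Standardized major axis (SMA) line fitting and between-group inference:
# likelihood-ratio test for a common slope, Wald test for elevation
# (intercept) differences at the common slope, and a Wald test for shift of
# the groups along the common slope.

#' Fit a standardized major axis line
#'
#' The SMA slope is `sign(r) * sd(y) / sd(x)` and the line passes through the
#' joint mean, so `intercept = mean(y) - slope * mean(x)`. Unlike ordinary
#' regression the fit is symmetric in x and y: swapping the axes gives the
#' reciprocal slope. `r2` is the squared Pearson correlation and `p` the
#' correlation test p value (used for the "only significant lines" screening
#' convention, r2 > 0.1 and p < 0.05).
#'
#' @param x,y numeric vectors, n >= 3, each with positive spread.
#' @param group optional single label carried into the result.
#' @return object of class `sma_fit`: `slope`, `intercept`, `r2`, `p`, `n`,
#'   `group`, `scores` (fitted-axis scores `y + slope * x`), `data`.
#' @examples
#' f <- sma_fit(1:10, 2 * (1:10))
#' coef(f) # intercept 0, slope 2
#' @export
sma_fit <- function(x, y, group = NULL) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("sma_fit: need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("sma_fit: x and y must both have positive spread", call. = FALSE)
  }
  r <- stats::cor(x, y)
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  if (slope == 0) slope <- stats::sd(y) / stats::sd(x) # r exactly 0: sign convention
  intercept <- mean(y) - slope * mean(x)
  ct <- stats::cor.test(x, y)
  structure(list(
    slope = slope, intercept = intercept, r2 = r^2, p = ct$p.value,
    n = length(x), group = group, scores = y + slope * x,
    data = list(x = x, y = y)
  ), class = "sma_fit")
}

#' @export
coef.sma_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA fit%s: slope = %.4g, intercept = %.4g, r2 = %.3f, p = %.3g, n = %d\n",
              if (!is.null(x$group)) paste0(" [", x$group, "]") else "",
              x$slope, x$intercept, x$r2, x$p, x$n))
  invisible(x)
}

# -2 log-likelihood profile for a common SMA slope b: at a group's own SMA
# slope the residual axis (y - b x) and fitted axis (y + b x) are
# uncorrelated, so departure from b is measured by that correlation.
# Bartlett-corrected weights (n - 2.5) give the chi-square calibration at
# moderate n.
.sma_lr <- function(b, groups) {
  sum(vapply(groups, function(g) {
    r <- stats::cor(g$y - b * g$x, g$y + b * g$x)
    -(g$n - 2.5) * log(max(1 - r^2, 1e-300))
  }, numeric(1)))
}

# asymptotic variance of a group's SMA slope estimate at slope b
.sma_var_b <- function(b, g) {
  r2 <- stats::cor(g$x, g$y)^2
  b^2 * (1 - r2) / (max(r2, 1e-12) * (g$n - 2))
}

#' Compare SMA lines across groups
#'
#' Implements the standard bivariate line-fitting comparison sequence:
#' (a) a likelihood-ratio test of a common SMA slope (the common slope is the
#' minimizer of the Bartlett-corrected LR profile; the statistic is chi-square
#' with g - 1 df); and, when the common slope is not rejected at `alpha`,
#' (b) a Wald test of elevation (intercept) differences at the common slope
#' and (c) a Wald test of shift of the group means along the common slope
#' (on the fitted-axis scores `y + b x`). Elevation and shift results are
#' reported only when the slope test is non-significant, since neither is
#' meaningful without a common slope.
#'
#' @param groups named list; each element a list or data frame with numeric
#'   `x` and `y` (each group must satisfy [sma_fit()]'s preconditions).
#' @param alpha significance level gating the elevation/shift tests
#'   (default 0.05).
#' @return object of class `sma_comparison`: `fits` (per-group [sma_fit()]
#'   objects), `common_slope`, `slope_test` (`stat`, `df`, `p`),
#'   `elevation_test` and `shift_test` (same shape, or `NULL` when the slope
#'   test rejects), `elevations` (per-group intercepts at the common slope),
#'   `alpha`.
#' @export
sma_compare <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) {
    stop("sma_compare: need at least 2 groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  fits <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    sma_fit(g$x, g$y, group = nm)
  })
  names(fits) <- names(groups)

  gd <- lapply(fits, function(f) list(x = f$data$x, y = f$data$y, n = f$n))
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  if (length(unique(sign(slopes))) > 1) {
    warning("sma_compare: group slopes differ in sign; common-slope test is ",
            "questionable", call. = FALSE)
  }
  sgn <- unname(sign(slopes[which.max(abs(slopes))]))

  # minimize the LR profile over log|b| within a generous bracket of the
  # per-group slopes
  lo <- log(min(abs(slopes))) - 3
  hi <- log(max(abs(slopes))) + 3
  opt <- stats::optimize(function(t) .sma_lr(sgn * exp(t), gd),
                         interval = c(lo, hi), tol = 1e-10)
  b_com <- sgn * exp(opt$minimum)
  lr <- .sma_lr(b_com, gd)
  df <- length(gd) - 1L
  slope_test <- list(stat = lr, df = df,
                     p = stats::pchisq(lr, df, lower.tail = FALSE))

  elevation_test <- NULL
  shift_test <- NULL
  elevations <- vapply(gd, function(g) mean(g$y) - b_com * mean(g$x),
                       numeric(1))
  if (slope_test$p >= alpha) {
    var_b <- 1 / sum(vapply(gd, function(g) 1 / .sma_var_b(b_com, g),
                            numeric(1)))
    # elevation: intercepts at the common slope, inverse-variance weighted
    var_a <- vapply(gd, function(g) {
      stats::var(g$y - b_com * g$x) / g$n + mean(g$x)^2 * var_b
    }, numeric(1))
    w <- 1 / var_a
    a_hat <- sum(w * elevations) / sum(w)
    elev_stat <- sum(w * (elevations - a_hat)^2)
    elevation_test <- list(stat = elev_stat, df = df,
                           p = stats::pchisq(elev_stat, df, lower.tail = FALSE))

    # shift along the common slope: group means of fitted-axis scores
    f_means <- vapply(gd, function(g) mean(g$y + b_com * g$x), numeric(1))
    var_f <- vapply(gd, function(g) {
      stats::var(g$y + b_com * g$x) / g$n + mean(g$x)^2 * var_b
    }, numeric(1))
    wf <- 1 / var_f
    f_hat <- sum(wf * f_means) / sum(wf)
    shift_stat <- sum(wf * (f_means - f_hat)^2)
    shift_test <- list(stat = shift_stat, df = df,
                       p = stats::pchisq(shift_stat, df, lower.tail = FALSE))
  }

  structure(list(
    fits = fits, common_slope = b_com, slope_test = slope_test,
    elevation_test = elevation_test, shift_test = shift_test,
    elevations = elevations, alpha = alpha
  ), class = "sma_comparison")
}

#' @export
print.sma_comparison <- function(x, ...) {
  cat("SMA comparison across", length(x$fits), "groups\n")
  for (f in x$fits) print(f)
  cat(sprintf("Common slope: %.4g; LR test: stat = %.3f, df = %d, p = %.4g\n",
              x$common_slope, x$slope_test$stat, x$slope_test$df,
              x$slope_test$p))
  if (is.null(x$elevation_test)) {
    cat(sprintf("Slopes heterogeneous at alpha = %g; elevation/shift tests not reported\n",
                x$alpha))
  } else {
    cat(sprintf("Elevation test: stat = %.3f, p = %.4g\n",
                x$elevation_test$stat, x$elevation_test$p))
    cat(sprintf("Shift test:     stat = %.3f, p = %.4g\n",
                x$shift_test$stat, x$shift_test$p))
  }
  invisible(x)
}
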