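test_that("one-way ANOVA F matches the textbook formula on a hand table", {
  # 3 groups x 4 observations, hand-computable
  vals <- c(1, 2, 3, 4,   2, 3, 4, 5,   6, 7, 8, 9)
  grp <- rep(c("g1", "g2", "g3"), each = 4)
  means <- tapply(vals, grp, mean)           # 2.5, 3.5, 7.5
  gm <- mean(vals)
  ss_b <- 4 * sum((means - gm)^2)
  ss_w <- sum((vals - means[grp])^2)
  f_oracle <- (ss_b / 2) / (ss_w / 9)
  res <- oneway_anova_letters(vals, grp)
  expect_equal(res$F, f_oracle, tolerance = 1e-12)
  expect_identical(res$df, c(2L, 9L))
  # g3 clearly separated, g1/g2 not (Tukey at alpha = 0.05)
  expect_identical(res$letters[["g1"]], res$letters[["g2"]])
  expect_false(res$letters[["g3"]] %in% res$letters[c("g1", "g2")])
})

test_that("letters: identical groups share one letter, separated groups split", {
  # constant data: base aov warns about a perfect fit; the letters still apply
  res <- suppressWarnings(
    oneway_anova_letters(rep(5, 9), rep(c("a", "b", "c"), each = 3)))
  expect_true(all(res$letters == "a"))
  set.seed(2)
  x <- c(rnorm(10), rnorm(10, 10)) # 10 sd apart
  res2 <- oneway_anova_letters(x, rep(c("lo", "hi"), each = 10))
  expect_identical(sort(unname(res2$letters)), c("a", "b"))
  expect_error(oneway_anova_letters(1:5, rep("a", 5)), "2 groups")
  expect_error(oneway_anova_letters(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("letter display is consistent with the pairwise p matrix", {
  # property: share a letter iff pairwise p >= alpha
  set.seed(6)
  for (rep_i in 1:20) {
    g <- 4
    pmat <- matrix(1, g, g, dimnames = list(letters[1:g], letters[1:g]))
    ps <- runif(choose(g, 2))
    pmat[upper.tri(pmat)] <- ps
    pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
    ltr <- letter_display(pmat, alpha = 0.3)
    share <- function(i, j) {
      any(strsplit(ltr[i], "")[[1]] %in% strsplit(ltr[j], "")[[1]])
    }
    for (i in 1:(g - 1)) for (j in (i + 1):g) {
      expect_identical(share(i, j), pmat[i, j] >= 0.3)
    }
  }
})

test_that("t test wrapper matches closed form and handles degeneracy", {
  a <- c(5, 6, 7, 8, 9)
  b <- c(1, 2, 3, 4, 5)
  res <- welch_or_student_t(a, b)
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_identical(res$df, 8)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 8), tolerance = 1e-12)
  # identical samples -> t = 0
  expect_equal(welch_or_student_t(a, a)$t, 0)
  # one-sample: mean of a against 0
  r1 <- welch_or_student_t(a, mu = 0)
  expect_equal(r1$t, mean(a) / (sd(a) / sqrt(5)), tolerance = 1e-12)
  # constant sample vs 0: infinite t, flagged
  rc <- welch_or_student_t(rep(1, 6), mu = 0)
  expect_identical(rc$t, Inf)
  expect_identical(rc$p, 0)
  expect_true(rc$degenerate)
  # equal constants: p = 1 convention, flagged
  re <- welch_or_student_t(rep(2, 4), rep(2, 4))
  expect_identical(re$p, 1)
  expect_true(re$degenerate)
  # Welch switch changes df
  set.seed(4)
  x <- rnorm(10); y <- rnorm(25, sd = 4)
  expect_lt(welch_or_student_t(x, y, var_equal = FALSE)$df, 33)
})

test_that("mixed-model screen returns an F table and downgrades gracefully", {
  sim <- simulate_dataset(seed = 13)
  ind <- compute_indices(
    suppressWarnings(compute_uptake(sim$plants, sim$soil, sim$quadrats)),
    sim$soil)
  ok <- ind[!ind$excluded, ]
  tab <- mixed_model_screen(ok, "beta_nh4")
  expect_identical(tab$term, c("habitat", "species", "habitat:species"))
  expect_identical(attr(tab, "fit_type"), "lme")
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  # the default truth's preferences flip across habitats differently for the
  # two species: the interaction must be detected
  expect_lt(tab$p[tab$term == "habitat:species"], 0.01)
  # single site: downgrade with warning
  one <- ok[ok$site == "site1", ]
  expect_warning(tab1 <- mixed_model_screen(one, "ps"), "downgrading")
  expect_identical(attr(tab1, "fit_type"), "lm")
  # constant response: degenerate report
  ok$const <- 1
  expect_warning(tabc <- mixed_model_screen(ok, "const"), "constant")
  expect_identical(attr(tabc, "fit_type"), "degenerate")
})

test_that("mixed-model screen is calibrated under the null and powered", {
  # null: flat truth, no habitat/species effect; response = quadrat ps
  set.seed(31)
  null_p <- vapply(1:60, function(i) {
    sim <- simulate_dataset(truth = flat_truth(), seed = 5000 + i)
    ind <- compute_indices(
      suppressWarnings(compute_uptake(sim$plants, sim$soil, sim$quadrats)),
      sim$soil)
    ok <- ind[!ind$excluded, ]
    tab <- mixed_model_screen(ok, "ps")
    tab$p[tab$term == "species"]
  }, numeric(1))
  # ~ alpha rejection rate; binomial 99% band for 60 draws at 0.05
  expect_lt(mean(null_p < 0.05), 0.17)
  # power: a species effect of ~3 between-quadrat sds on beta_nh4
  tr <- flat_truth()
  tr$rate_nh4[tr$species == "native"] <- 60 # f 0.5 -> 0.6
  set.seed(32)
  pow <- vapply(1:25, function(i) {
    sim <- simulate_dataset(truth = tr, seed = 7000 + i)
    ind <- compute_indices(
      suppressWarnings(compute_uptake(sim$plants, sim$soil, sim$quadrats)),
      sim$soil)
    ok <- ind[!ind$excluded, ]
    tab <- mixed_model_screen(ok, "beta_nh4")
    tab$p[tab$term == "species"] < 0.05
  }, logical(1))
  expect_gt(mean(pow), 0.9)
})
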