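# Attribution chain: per-group PCA, additive model on the top PCs, group
# effects and per-variable sensitivities.

test_that("group PCA is orthonormal, sign-fixed and handles degeneracy", {
  set.seed(61)
  n <- 5000
  dat <- data.frame(
    a1 = rnorm(n), a2 = rnorm(n), a3 = rnorm(n),
    b1 = rnorm(n)
  )
  dat$b2 <- 2 * dat$b1 # perfectly correlated pair
  pca <- group_pca(dat, list(ga = c("a1", "a2", "a3"), gb = c("b1", "b2")))
  L <- pca$ga$loadings
  expect_lt(max(abs(t(L) %*% L - diag(3))), 1e-8)
  # independent standard variables: near-isotropic explained fractions
  expect_true(all(abs(pca$ga$explained - 1 / 3) < 0.05))
  expect_true(all(diff(pca$ga$explained) <= 1e-12))
  # rank-1 group: PC1 explains everything
  expect_equal(pca$gb$explained[1], 1, tolerance = 1e-12)
  # sign convention: the dominant loading of each component is positive
  for (j in 1:3) expect_gt(L[which.max(abs(L[, j])), j], 0)
  # zero-variance variable dropped with a warning
  dat$a3 <- 5
  expect_warning(
    group_pca(dat, list(ga = c("a1", "a2", "a3"))),
    "zero-variance"
  )
})

test_that("a constant response yields flat partial curves", {
  set.seed(62)
  dat <- data.frame(x1 = runif(300), x2 = runif(300),
                    y1 = runif(300), y2 = runif(300))
  pca <- group_pca(dat, list(ga = c("x1", "x2"), gb = c("y1", "y2")))
  att <- fit_attribution_gam(rep(7, 300), pca, pft = NULL)
  for (curve in att$partial_curves) {
    expect_lt(max(abs(curve$delta_flnr)), 0.1)
  }
})

test_that("a linear response gives linear partials and additive effects", {
  set.seed(63)
  n <- 800
  dat <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10),
                    y1 = runif(n, 0, 5), y2 = runif(n, 0, 5))
  flnr <- 5 + 1.2 * dat$x1 + 0.6 * dat$y1
  spec <- list(ga = c("x1", "x2"), gb = c("y1", "y2"))
  pca <- group_pca(dat, spec)
  att <- fit_attribution_gam(flnr, pca, pft = NULL)
  # partial curves of the signal-bearing group are straight lines
  for (v in c("ga_PC1", "ga_PC2")) {
    curve <- att$partial_curves[[v]]
    lin <- lm(delta_flnr ~ score, data = curve)
    expect_gt(summary(lin)$r.squared, 0.999)
  }
  eff <- compute_group_effects(att, c(ga = 0.5, gb = 0.3))
  # model additivity: terms + constant reproduce the fitted values
  recon <- rowSums(eff$terms) + eff$constant
  expect_lt(max(abs(recon - eff$fitted)), 1e-6)
  # and group effects + intercept-like remainder reproduce them too
  recon2 <- rowSums(as.matrix(eff$effects)) + eff$constant
  expect_lt(max(abs(recon2 - eff$fitted)), 1e-6)

  # the group OLS recovers the generating coefficients
  sens <- fit_sensitivities(att, eff, dat, spec)
  est <- setNames(sens$estimate, sens$variable)
  expect_equal(unname(est["x1"]), 1.2, tolerance = 0.02)
  expect_equal(unname(est["y1"]), 0.6, tolerance = 0.02)
  ic <- attr(sens, "intercepts")[["global"]]
  expect_equal(ic, 5, tolerance = 0.1)
})

test_that("adding a pure-noise group barely changes deviance explained", {
  set.seed(64)
  n <- 600
  dat <- data.frame(x1 = runif(n), x2 = runif(n),
                    z1 = runif(n), z2 = runif(n))
  flnr <- 2 + 3 * dat$x1 + rnorm(n, 0, 0.3)
  p1 <- group_pca(dat, list(ga = c("x1", "x2")))
  p2 <- group_pca(dat, list(ga = c("x1", "x2"), noise = c("z1", "z2")))
  d1 <- summary(fit_attribution_gam(flnr, p1, pft = NULL)$gam)$dev.expl
  d2 <- summary(fit_attribution_gam(flnr, p2, pft = NULL)$gam)$dev.expl
  expect_lt(abs(d2 - d1), 0.01)
})

test_that("dominance maps isolate the generating group", {
  set.seed(65)
  n <- 900
  dat <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10),
                    y1 = runif(n, 0, 10), y2 = runif(n, 0, 10))
  # truth depends only on the first group
  flnr <- 1 + 2 * dat$x1 - 1.5 * dat$x2
  spec <- list(ga = c("x1", "x2"), gb = c("y1", "y2"))
  pca <- group_pca(dat, spec)
  att <- fit_attribution_gam(flnr, pca, pft = NULL)
  eff <- compute_group_effects(att, c(ga = 0.5, gb = 0.3))
  expect_gt(mean(eff$shares$ga > 0.9, na.rm = TRUE), 0.95)
  expect_gt(eff$area_fractions[["ga"]], 0.95)

  # symmetric two-group truth on same-scale variables: balanced shares
  flnr_sym <- 1 + 2 * dat$x1 + 2 * dat$y1
  att2 <- fit_attribution_gam(flnr_sym, pca, pft = NULL)
  eff2 <- compute_group_effects(att2, c(ga = 0.5, gb = 0.5))
  expect_lt(abs(mean(eff2$shares$ga, na.rm = TRUE) -
                mean(eff2$shares$gb, na.rm = TRUE)), 0.1)
})

test_that("sensitivities carry OLS unit covariance and honest null CIs", {
  set.seed(66)
  n <- 500
  dat <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10))
  dat$flnr <- 4 + 1.5 * dat$x1 + rnorm(n, 0, 1)
  f1 <- fit_flnr_equation(dat, predictors = c("x1", "x2"))
  dat2 <- dat
  dat2$x1 <- dat2$x1 * 2 # a unit change, not an information change
  f2 <- fit_flnr_equation(dat2, predictors = c("x1", "x2"))
  expect_equal(unname(f2$coefficients["x1"]),
               unname(f1$coefficients["x1"]) / 2, tolerance = 1e-12)

  # a variable absent from the truth: its CI covers zero in >= 90% of reseeds
  covers <- vapply(1:20, function(s) {
    set.seed(s)
    d <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10))
    d$flnr <- 4 + 1.5 * d$x1 + rnorm(n, 0, 1)
    f <- fit_flnr_equation(d, predictors = c("x1", "x2"))
    abs(f$coefficients["x2"]) <= f$ci95_halfwidth["x2"]
  }, logical(1))
  expect_gte(sum(covers), 18)
})

test_that("per-PFT equations respect the minimum cell count", {
  set.seed(67)
  n <- 700
  dat <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10))
  pft <- factor(c(rep("CRO", 450), rep("GRA", 230), rep("WET", 20)),
                levels = c("CRO", "GRA", "WET"))
  flnr <- 2 + 1.0 * dat$x1 + ifelse(pft == "CRO", 3, 0) + rnorm(n, 0, 0.2)
  spec <- list(ga = c("x1", "x2"))
  pca <- group_pca(dat, spec)
  att <- suppressWarnings(fit_attribution_gam(flnr, pca, pft = pft))
  eff <- compute_group_effects(att, c(ga = 0.5))
  expect_warning(
    sens <- fit_sensitivities(att, eff, dat, spec, scope = "per_pft",
                              min_cells = 200),
    "skipped"
  )
  expect_setequal(unique(sens$scope), c("CRO", "GRA"))
  expect_match(sensitivity_equation(sens, "CRO"), "fLNR = ")
})
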