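# Bagged-tree upscaling: importance ranking, forward selection, OOB
# stopping, cross-validation (conventional and spatially buffered) and
# gridded prediction with per-tree spread.

test_that("an informative predictor outranks noise and constants score zero", {
  tab <- white_grid_table(seed = 31)
  set.seed(32)
  tab$vcmax25 <- 3 * as.numeric(scale(tab$chl)) + rnorm(nrow(tab), 0, 0.5)
  tab$flat <- 1
  expect_message(
    rk <- rank_importance(tab, c("chl", "pp", "ph", "sand", "flat"),
                          n_trees = 150, seed = 33),
    "constant"
  )
  expect_identical(names(rk)[1], "chl")
  expect_identical(unname(rk["flat"]), 0)
})

test_that("duplicating a predictor dilutes but roughly preserves its importance", {
  tab <- white_grid_table(seed = 34)
  set.seed(35)
  tab$vcmax25 <- 3 * as.numeric(scale(tab$chl)) + rnorm(nrow(tab), 0, 0.5)
  tab$chl_dup <- tab$chl
  single <- rank_importance(tab, c("chl", "pp", "ph", "sand"),
                            n_trees = 150, seed = 36)
  dup <- rank_importance(tab, c("chl", "chl_dup", "pp", "ph", "sand"),
                         n_trees = 150, seed = 36)
  ratio <- (dup["chl"] + dup["chl_dup"]) / single["chl"]
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 1.5)
})

test_that("pure-noise responses give no systematically large importance", {
  # paired sign test: the max importance under a noise response is
  # exchangeable with that of an independent noise response
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    x <- as.data.frame(matrix(rnorm(150 * 10), 150, 10))
    o1 <- cbind(x, vcmax25 = rnorm(150))
    o2 <- cbind(x, vcmax25 = rnorm(150))
    r1 <- rank_importance(o1, names(x), n_trees = 60, seed = s)
    r2 <- rank_importance(o2, names(x), n_trees = 60, seed = s + 1000)
    max(r1) > max(r2)
  }, logical(1))
  expect_gte(sum(wins), 4)
  expect_lte(sum(wins), 16)
})

test_that("forward selection adds a perfect signal first and stops cleanly", {
  tab <- white_grid_table(seed = 37)
  tab$vcmax25 <- tab$chl # exact copy, no noise
  rk <- rank_importance(tab, c("chl", "pp", "ph", "sand", "cn"),
                        n_trees = 80, seed = 38)
  expect_identical(names(rk)[1], "chl")
  sel <- select_predictors(tab, rk, n_trees = 80, seed = 38)
  expect_identical(sel$selected[1], "chl")
  tr <- sel$oob_trace
  # r2 non-decreasing until the stopping step (the last row tried)
  if (nrow(tr) > 2) expect_true(all(diff(tr$r2[-nrow(tr)]) > -1e-6))
  expect_error(select_predictors(tab, character(0)), "empty")
})

test_that("ensemble fits are reproducible and separate signal from null", {
  tab <- white_grid_table(seed = 39, shape = c(30, 60))
  set.seed(40)
  tab$vcmax25 <- 40 + 0.5 * tab$chl + 0.01 * tab$pp # noiseless function
  m1 <- fit_rf(tab, c("chl", "pp"), n_trees = 150, seed = 41)
  m2 <- fit_rf(tab, c("chl", "pp"), n_trees = 150, seed = 41)
  expect_identical(m1$oob_r2, m2$oob_r2)
  expect_gt(m1$oob_r2, 0.9)

  set.seed(42)
  tab$vcmax25 <- sample(tab$vcmax25) # permuted response
  m0 <- fit_rf(tab, c("chl", "pp"), n_trees = 150, seed = 43)
  expect_lte(m0$oob_r2, 0.05)
  expect_error(fit_rf(tab[1:10, ], c("chl", "pp")), "at least")
})

test_that("haversine distances and the exclusion rule behave as stated", {
  # half a degree of latitude on a 6371 km sphere is ~55.6 km
  d <- greatcircle_km(data.frame(lon = 0, lat = 0),
                      data.frame(lon = 0, lat = 0.5))
  expect_equal(d[1, 1], 6371 * pi / 360, tolerance = 1e-6)

  w <- default_world()
  # radius 0 reproduces the conventional mode exactly under shared seeds
  conv <- cross_validate(w$obs, c("chl", "pp", "ph", "pft"),
                         mode = "conventional", n_reps = 3, n_trees = 60,
                         seed = 44)
  spat0 <- cross_validate(w$obs, c("chl", "pp", "ph", "pft"),
                          mode = "spatial", exclusion_radius_km = 0,
                          n_reps = 3, n_trees = 60, seed = 44)
  expect_equal(conv$r2, spat0$r2, tolerance = 1e-12)
  expect_equal(conv$rmse, spat0$rmse, tolerance = 1e-12)

  # retained validation rows all sit beyond the radius of every training row
  spat <- suppressWarnings(cross_validate(
    w$obs, c("chl", "pp", "ph", "pft"), mode = "spatial",
    exclusion_radius_km = 60, n_reps = 4, n_trees = 60, seed = 45,
    return_splits = TRUE
  ))
  for (sp in spat$splits) {
    if (is.null(sp) || length(sp$validation) == 0) next
    d <- greatcircle_km(w$obs[sp$validation, c("lon", "lat")],
                        w$obs[sp$train, c("lon", "lat")])
    expect_gte(min(d), 60)
  }
})

test_that("spatial validation is scarcer and more variable than conventional", {
  w <- default_world()
  preds <- c("chl", "pp", "ph", "pft")
  conv <- cross_validate(w$obs, preds, mode = "conventional", n_reps = 8,
                         n_trees = 80, seed = 46)
  spat <- suppressWarnings(cross_validate(
    w$obs, preds, mode = "spatial", exclusion_radius_km = 60,
    n_reps = 8, n_trees = 80, seed = 46
  ))
  expect_lt(spat$n_validation_effective, conv$n_validation_effective)
  expect_gte(spat$r2_sd, conv$r2_sd)
})

test_that("gridded predictions honor the mask and quantify tree spread", {
  w <- default_world()
  tab <- grid_table(w$grid)
  # constant response: every tree predicts the constant, sd is zero
  obs_const <- tab
  obs_const$vcmax25 <- 55
  mc <- fit_rf(obs_const, c("chl", "pp"), n_trees = 50, seed = 47)
  pc <- predict_grid(mc, w$grid)
  expect_true(all(pc$sd[w$grid$mask] == 0))
  expect_true(all(abs(pc$mean[w$grid$mask] - 55) < 1e-9))
  # masked cells are missing in both layers
  expect_true(all(is.na(pc$mean[!w$grid$mask])))
  expect_true(all(is.na(pc$sd[!w$grid$mask])))

  # memorization on noiseless duplicated data: grid predictions track the
  # per-cell targets closely
  dup <- tab[rep(seq_len(nrow(tab)), 4), ]
  dup$vcmax25 <- 30 + 0.8 * dup$chl + 2 * dup$ph
  mm <- fit_rf(dup, c("chl", "ph"), n_trees = 100, seed = 48)
  pm <- predict_grid(mm, w$grid)
  target <- 30 + 0.8 * w$grid$layers$chl + 2 * w$grid$layers$ph
  expect_gt(cor(pm$mean[w$grid$mask], target[w$grid$mask]), 0.95)

  miss <- mm
  miss$predictors <- c("chl", "ph", "not_a_layer")
  expect_error(predict_grid(miss, w$grid), "not_a_layer")
})

test_that("the bagged mean stabilizes as trees are added", {
  g <- make_covariate_grid(c(15, 20), seed = 49, smoothness = 0)
  tb <- grid_table(g)
  set.seed(50)
  tb$vcmax25 <- 50 + 5 * as.numeric(scale(tb$chl)) + rnorm(nrow(tb), 0, 3)
  grid_mean_var <- function(nt) {
    stats::var(vapply(1:5, function(s) {
      m <- fit_rf(tb, c("chl", "pp"), n_trees = nt, seed = 100 + s)
      mean(predict_grid(m, g)$mean, na.rm = TRUE)
    }, numeric(1)))
  }
  expect_lt(grid_mean_var(400), grid_mean_var(50))
})
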