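# Synthetic globe generator: covariate grids, trait maps, ground truth and
# clustered observations.

test_that("covariate grids are reproducible, range-clamped and validated", {
  g1 <- make_covariate_grid(c(20, 40), seed = 1, smoothness = 3)
  g2 <- make_covariate_grid(c(20, 40), seed = 1, smoothness = 3)
  expect_identical(g1$layers, g2$layers)
  expect_identical(g1$pft, g2$pft)

  on <- g1$mask
  expect_true(all(g1$layers$sand[on] >= 10 & g1$layers$sand[on] <= 90))
  expect_true(all(g1$layers$vpd[on] >= 0))
  expect_true(all(g1$layers$lma[on] >= 20 & g1$layers$lma[on] <= 250))
  # masked cells carry NA everywhere
  expect_true(all(is.na(g1$layers$chl[!on])))
  expect_true(all(is.na(g1$pft[!on])))
  # every PFT class present on the mask
  expect_setequal(unique(na.omit(as.vector(g1$pft))), pft_classes())
  expect_error(make_covariate_grid(c(5, 40)), "at least 10")
  expect_error(make_covariate_grid(c(20, 40), smoothness = -1), ">= 0")
})

test_that("smoothness zero gives spatially uncorrelated layers", {
  g <- make_covariate_grid(c(20, 40), seed = 2, smoothness = 0,
                           mask_fraction = 1)
  f <- g$layers$tair
  r <- cor(as.vector(f[, -ncol(f)]), as.vector(f[, -1]))
  expect_lt(abs(r), 0.1)
})

test_that("truth generation honors the linear model, noise level and floor", {
  g <- make_covariate_grid(c(16, 20), seed = 3, smoothness = 2)
  tg <- make_trait_grid(g, seed = 4)
  # all-zero coefficients, no offsets, no noise: constant field
  tr0 <- make_truth(g, tg, coefficients = c(lma = 0), intercept = 18.2,
                    pft_offsets = c(CRO = 0), noise_sd = 0, seed = 5)
  expect_true(all(abs(tr0$flnr_true[g$mask] - 18.2) < 1e-12))

  # noise contract: residual sd approximates the requested level
  tr2 <- suppressWarnings(make_truth(g, tg, noise_sd = 2, seed = 6,
                                     flnr_floor = NULL))
  resid <- (tr2$flnr_true - tr2$flnr_expected)[g$mask]
  expect_gt(length(resid), 250)
  expect_lt(abs(sd(resid) - 2) / 2, 0.1)

  # flooring warns and counts
  expect_warning(
    trf <- make_truth(g, tg, coefficients = c(lma = 0), intercept = -5,
                      pft_offsets = c(CRO = 0), noise_sd = 0, seed = 7,
                      flnr_floor = 1),
    "floor"
  )
  expect_equal(trf$n_floored, sum(g$mask))
  expect_true(all(trf$flnr_true[g$mask] == 1))
  expect_error(make_truth(g, tg, coefficients = c(nope = 1)), "missing")
})

test_that("forward identity and inversion are exact", {
  # 47.34 * 6.25 * 1 g m-2 * 20% = 59.175 umol m-2 s-1
  expect_equal(forward_vcmax25(20, 1), 59.175, tolerance = 1e-12)
  w <- default_world()
  on <- w$grid$mask
  back <- invert_flnr(w$truth$vcmax25_true, w$truth$lnc)
  expect_lt(max(abs(back[on] - w$truth$flnr_true[on])), 1e-10)
})

test_that("observations sit on vegetated cells and honor their contracts", {
  w <- default_world()
  expect_error(
    sample_observations(w$truth, w$grid, n = 5, n_clusters = 10),
    "n_clusters"
  )
  # zero noise at the reference temperature reproduces the truth exactly
  obs0 <- sample_observations(w$truth, w$grid, n = 100, n_clusters = 10,
                              obs_noise_sd = 0, tleaf_range = c(25, 25),
                              seed = 8)
  expect_equal(obs0$vcmax_obs, obs0$vcmax25_true, tolerance = 1e-12)
  cells <- cbind(obs0$cell_row, obs0$cell_col)
  expect_true(all(w$grid$mask[cells]))
  expect_true(all(obs0$tleaf == 25))

  # one cluster of radius 0.5 degrees: pairwise spread bounded by diameter
  obs1 <- sample_observations(w$truth, w$grid, n = 40, n_clusters = 1,
                              cluster_radius = 0.5, seed = 9)
  dmax <- max(dist(cbind(obs1$lat, obs1$lon)))
  expect_lte(dmax, 1 + 1e-9)

  # determinism
  oa <- sample_observations(w$truth, w$grid, n = 60, n_clusters = 6, seed = 10)
  ob <- sample_observations(w$truth, w$grid, n = 60, n_clusters = 6, seed = 10)
  expect_identical(oa, ob)

  # standardization round-trips the projection applied inside the sampler
  obs <- standardize_observations(obs0)
  expect_equal(obs$vcmax25, obs0$vcmax25_true, tolerance = 1e-12)
})

test_that("trait grids are positive, coherent with LMA, and attach LNC", {
  w <- default_world()
  on <- w$grid$mask
  expect_true(all(w$traits$lncm_mean[on] > 0))
  expect_true(all(w$traits$sla_mean[on] > 0))
  expect_true(all(w$traits$lncm_sd[on] >= 0))
  expect_equal(w$traits$sla_mean[on], 1000 / w$grid$layers$lma[on])
  expect_equal(w$grid$layers$lnc[on],
               (w$traits$lncm_mean / w$traits$sla_mean)[on])
})

test_that("the recovery table evaluates the generating equation exactly", {
  tab1 <- simulate_recovery_table(500, seed = 11)
  tab2 <- simulate_recovery_table(500, seed = 11)
  expect_identical(tab1, tab2)
  eq <- global_flnr_equation()
  manual <- eq$intercept +
    as.matrix(tab1[names(eq$coefficients)]) %*% eq$coefficients
  expect_equal(tab1$flnr, as.vector(manual), tolerance = 1e-12)
  rg <- default_layer_ranges()
  expect_true(all(tab1$lma >= rg$lma[1] & tab1$lma <= rg$lma[2]))
})
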