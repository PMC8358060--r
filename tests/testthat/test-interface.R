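# File formats, configuration and pipeline orchestration.

test_that("covariate grids round-trip through NetCDF", {
  w <- default_world()
  path <- withr::local_tempfile(fileext = ".nc")
  write_covariate_grid_nc(w$grid, path)
  back <- read_covariate_grid_nc(path)
  expect_identical(back$mask, w$grid$mask)
  expect_identical(back$pft, w$grid$pft)
  expect_equal(back$lat, w$grid$lat)
  for (nm in names(w$grid$layers)) {
    expect_equal(back$layers[[nm]], w$grid$layers[[nm]],
                 info = nm, tolerance = 0)
  }
})

test_that("uncertain maps and trait grids round-trip through NetCDF", {
  w <- default_world()
  vmap <- uncertain_map(w$truth$vcmax25_true, 0.1 * w$truth$vcmax25_true,
                        w$grid$lat, w$grid$lon, "vcmax25", "umol m-2 s-1")
  p1 <- withr::local_tempfile(fileext = ".nc")
  write_uncertain_map_nc(vmap, p1, extra = list(extra_layer = vmap$sd))
  back <- read_uncertain_map_nc(p1, "vcmax25")
  expect_equal(back$mean, vmap$mean, tolerance = 0)
  expect_equal(back$sd, vmap$sd, tolerance = 0)
  expect_identical(back$units, "umol m-2 s-1")
  expect_error(read_uncertain_map_nc(p1, "flnr"), "flnr_mean")

  p2 <- withr::local_tempfile(fileext = ".nc")
  write_trait_grid_nc(w$traits, p2)
  tb <- read_trait_grid_nc(p2)
  expect_equal(tb$lncm_mean, w$traits$lncm_mean, tolerance = 0)
  expect_equal(tb$sla_sd, w$traits$sla_sd, tolerance = 0)
})

test_that("a variable without a units attribute warns but still reads", {
  path <- withr::local_tempfile(fileext = ".nc")
  dims <- list(ncdf4::ncdim_def("lon", "degrees_east", c(0.25, 0.75)),
               ncdf4::ncdim_def("lat", "degrees_north", c(0.25, 0.75)))
  vars <- list(ncdf4::ncvar_def("q_mean", "", dims, prec = "double"),
               ncdf4::ncvar_def("q_sd", "", dims, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  ncdf4::ncvar_put(nc, "q_mean", matrix(1, 2, 2))
  ncdf4::ncvar_put(nc, "q_sd", matrix(0, 2, 2))
  ncdf4::nc_close(nc)
  expect_warning(m <- read_uncertain_map_nc(path, "q"), "units")
  expect_equal(m$mean, matrix(1, 2, 2))
})

test_that("observation CSVs are lossless and validate their schema", {
  w <- default_world()
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations_csv(w$obs, path)
  back <- read_observations_csv(path)
  for (nm in names(w$obs)) {
    if (is.numeric(w$obs[[nm]])) {
      expect_identical(back[[nm]], as.vector(w$obs[[nm]]), info = nm)
    }
  }
  expect_identical(as.character(back$pft), as.character(w$obs$pft))
  # a missing required column is named in the error
  slim <- w$obs[, setdiff(names(w$obs), "tleaf")]
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_observations_csv(slim, p2)
  expect_error(read_observations_csv(p2), "tleaf")
})

test_that("run configurations expand seeds and round-trip through YAML", {
  s <- expand_seeds(7)
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(s, expand_seeds(7))
  expect_gt(length(unique(s)), 1)

  cfg <- default_run_config(seed = 7)
  p1 <- withr::local_tempfile(fileext = ".yaml")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, p1)
  cfg2 <- read_run_config(p1)
  write_run_config(cfg2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # user overrides merge into the defaults
  writeLines("seed: 9\nrf:\n  n_trees: 55", p2)
  cfg3 <- read_run_config(p2)
  expect_identical(cfg3$rf$n_trees, 55L)
  expect_identical(cfg3$rf$n_reps, default_run_config()$rf$n_reps)
})

# small fast configuration for orchestration tests: smaller world and
# ensembles, shorter exclusion radius matched to the smaller domain
fast_config <- function(seed, dir) {
  cfg <- default_run_config(seed = seed, output_dir = dir)
  cfg$grid$shape <- c(16L, 30L)
  cfg$observations$n <- 250L
  cfg$observations$n_clusters <- 15L
  cfg$observations$p_scatter <- 0.3
  cfg$rf$n_trees <- 60L
  cfg$rf$n_reps <- 3L
  cfg$rf$exclusion_radius_km <- 30
  cfg$bootstrap$n_boot <- 200L
  cfg
}

test_that("the pipeline gates stages and keeps the rest unchanged", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- fast_config(5, d1)
  rep_full <- suppressWarnings(run_pipeline(cfg, write_artifacts = FALSE))
  cfg_off <- fast_config(5, d2)
  cfg_off$attribution$enabled <- FALSE
  rep_off <- suppressWarnings(run_pipeline(cfg_off, write_artifacts = FALSE))
  expect_identical(rep_off$stages$attribution, "disabled")
  expect_null(rep_off$attribution)
  expect_false(is.null(rep_full$attribution))
  # every other block is unchanged
  for (blk in c("simulate", "standardize", "selection", "fit", "crossval",
                "predict", "flnr", "zoo")) {
    expect_identical(rep_off[[blk]], rep_full[[blk]], info = blk)
  }
})

test_that("pipeline artifacts land on disk and reload", {
  d <- withr::local_tempdir()
  rep <- suppressWarnings(run_pipeline(fast_config(6, d)))
  expect_true(all(file.exists(file.path(
    d, c("covariates.nc", "traits.nc", "observations.csv", "vcmax25_rf.nc",
         "flnr.nc", "sensitivities.csv", "report.json")
  ))))
  fl <- read_uncertain_map_nc(file.path(d, "flnr.nc"), "flnr")
  expect_equal(mean(fl$mean, na.rm = TRUE), rep$flnr$flnr_mean,
               tolerance = 1e-9)
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_identical(js$stages$simulate, "ok")
  expect_equal(js$flnr$flnr_mean, rep$flnr$flnr_mean, tolerance = 1e-9)
})
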