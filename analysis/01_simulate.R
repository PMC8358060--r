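#!/usr/bin/env Rscript
# Stage 1: build the synthetic globe. A 40 x 80 half-degree window with 19
# covariate layers + PFTs, leaf-trait maps with uncertainty, a ground-truth
# fLNR/Vcmax25 world generated from the published global fLNR equation
# (plus per-PFT offsets and 2% noise), and 600 clustered-plus-scattered
# site observations of Vcmax at leaf temperature.

library(flnr)

config <- default_run_config(seed = 42)
seeds <- expand_seeds(config$seed)
out <- "results/simulation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

grid <- make_covariate_grid(
  shape = config$grid$shape, seed = seeds[["grid"]],
  smoothness = config$grid$smoothness,
  mask_fraction = config$grid$mask_fraction,
  correlate_groups = config$grid$correlate_groups,
  group_rho = config$grid$group_rho
)
traits <- make_trait_grid(grid, seed = seeds[["traits"]])
grid <- attach_lnc(grid, traits)
truth <- make_truth(grid, traits, seed = seeds[["truth"]])
obs <- sample_observations(
  truth, grid, n = config$observations$n,
  n_clusters = config$observations$n_clusters,
  cluster_radius = config$observations$cluster_radius,
  obs_noise_sd = config$observations$obs_noise_sd,
  tleaf_range = config$observations$tleaf_range,
  seed = seeds[["observations"]], p_scatter = config$observations$p_scatter
)

write_covariate_grid_nc(grid, file.path(out, "covariates.nc"))
write_trait_grid_nc(traits, file.path(out, "traits.nc"))
write_uncertain_map_nc(
  uncertain_map(truth$flnr_true, 0 * truth$flnr_true, grid$lat, grid$lon,
                "flnr_true", "%"),
  file.path(out, "flnr_true.nc")
)
write_observations_csv(obs, file.path(out, "observations.csv"))

cat(sprintf("synthetic globe: %d vegetated cells, %d floored fLNR cells\n",
            sum(grid$mask), truth$n_floored))
cat(sprintf("true fLNR %.1f +/- %.1f %%, true Vcmax25 %.1f umol m-2 s-1\n",
            mean(truth$flnr_true, na.rm = TRUE),
            sd(truth$flnr_true[grid$mask]),
            mean(truth$vcmax25_true, na.rm = TRUE)))
cat(sprintf("%d observations written to %s\n", nrow(obs), out))
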