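# Shared synthetic worlds, built once per test run and cached.

.world_cache <- new.env(parent = emptyenv())

# default mid-size world with correlated covariate groups, noisy truth and
# clustered + scattered observations
default_world <- function() {
  if (!is.null(.world_cache$default)) return(.world_cache$default)
  grid <- make_covariate_grid(c(20, 40), seed = 101, smoothness = 3,
                              correlate_groups = TRUE)
  traits <- make_trait_grid(grid, seed = 102)
  grid <- attach_lnc(grid, traits)
  truth <- suppressWarnings(make_truth(grid, traits, seed = 103))
  obs <- standardize_observations(
    sample_observations(truth, grid, n = 400, n_clusters = 25,
                        cluster_radius = 1, seed = 104, p_scatter = 0.2)
  )
  .world_cache$default <- list(grid = grid, traits = traits, truth = truth,
                               obs = obs)
  .world_cache$default
}

# white-noise covariates (smoothness 0) for statistical tests that need
# independent cells
white_grid_table <- function(seed, shape = c(20, 40)) {
  grid_table(make_covariate_grid(shape, seed = seed, smoothness = 0))
}

# observation table whose response depends on chl, pp, ph and PFT only,
# among the full 20-candidate set (selection-consistency experiment)
make_selection_obs <- function(seed, n = 500) {
  tab <- white_grid_table(seed)
  set.seed(seed + 500)
  tab <- tab[sample(nrow(tab), n, replace = TRUE), ]
  z <- function(v) (v - mean(v)) / stats::sd(v)
  offs <- c(CRO = 0, DBF = 7, EBF = -7, ENF = 4, MF = -4, GRA = 10,
            SH = -10, WET = 0)
  tab$vcmax25 <- 60 + 12 * z(tab$chl) + 10 * z(tab$pp) + 9 * z(tab$ph) +
    offs[as.character(tab$pft)] + stats::rnorm(n, 0, 1.5)
  tab
}

# noiseless world generated from the published global equation with
# correlated covariate groups: input of the PCA+GAM recovery experiment
recovery_world <- function() {
  if (!is.null(.world_cache$recovery)) return(.world_cache$recovery)
  grid <- make_covariate_grid(c(60, 80), seed = 111, smoothness = 0,
                              correlate_groups = TRUE)
  traits <- make_trait_grid(grid, seed = 112)
  grid <- attach_lnc(grid, traits)
  truth <- make_truth(grid, traits, pft_offsets = c(CRO = 0), noise_sd = 0,
                      seed = 113, flnr_floor = NULL)
  .world_cache$recovery <- list(grid = grid, traits = traits, truth = truth)
  .world_cache$recovery
}

# minimal hand-built trait grid: constant means, chosen sds
constant_traits <- function(lncm = 20, sla = 10, lncm_sd = 0, sla_sd = 0,
                            shape = c(12, 12)) {
  m <- function(v) matrix(v, shape[1], shape[2])
  structure(
    list(
      lat = (seq_len(shape[1]) - (shape[1] + 1) / 2) * 0.5,
      lon = (seq_len(shape[2]) - (shape[2] + 1) / 2) * 0.5,
      mask = m(TRUE),
      lncm_mean = m(lncm), lncm_sd = m(lncm_sd),
      sla_mean = m(sla), sla_sd = m(sla_sd)
    ),
    class = "trait_grid"
  )
}
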