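# Run configuration: one global seed expands deterministically into
# per-stage seeds so stages can be rerun in isolation; every tunable of the
# pipeline lives here and round-trips through YAML.

stage_names <- function() {
  c("grid", "traits", "truth", "observations", "rank", "select", "fit",
    "crossval", "bootstrap", "attribution")
}

#' Expand a global seed into per-stage seeds
#'
#' Deterministic, collision-free for practical purposes, and kept below
#' 2^31 so the values are valid R integer seeds.
#'
#' @param seed Global integer seed.
#' @return Named integer vector over the pipeline stages.
#' @export
expand_seeds <- function(seed) {
  idx <- seq_along(stage_names())
  vals <- (abs(as.numeric(seed)) + 7919 * idx) %% 2147483647
  stats::setNames(as.integer(vals), stage_names())
}

#' Default pipeline configuration
#'
#' The defaults are the study conditions of the synthetic globe: a 40 x 80
#' half-degree window (large enough that a 150 km exclusion buffer leaves
#' isolated validation sites), 600 site observations of which a quarter are
#' scattered singletons and the rest clustered, 200 bagged trees, 80/20
#' cross-validation with a 150 km spatial buffer, 1000 bootstrap draws, and
#' the published global fLNR equation (plus per-PFT offsets) as generating
#' truth. `correlate_groups` is on so that within-group covariance
#' concentrates in the leading principal components, as it does in real
#' climate and soil products.
#'
#' @param seed Global seed; expanded per stage via [expand_seeds()].
#' @param output_dir Where [run_pipeline()] writes artifacts.
#' @return Nested named list (class `run_config`).
#' @export
default_run_config <- function(seed = 1, output_dir = "results/pipeline") {
  eq <- global_flnr_equation()
  structure(list(
    seed = as.integer(seed),
    output_dir = output_dir,
    grid = list(
      shape = c(40L, 80L), smoothness = 3, mask_fraction = 0.9,
      correlate_groups = TRUE, group_rho = 0.6, pft_noise = 0.15
    ),
    traits = list(lncm_range = c(5, 18), rel_sd = 0.1, smoothness = 3),
    truth = list(
      coefficients = as.list(eq$coefficients), intercept = eq$intercept,
      pft_offsets = as.list(default_pft_offsets()),
      noise_sd = 2, flnr_floor = 1
    ),
    observations = list(
      n = 600L, n_clusters = 30L, cluster_radius = 1, obs_noise_sd = 5,
      tleaf_range = c(10, 35), p_scatter = 0.25
    ),
    constants = list(),
    rf = list(
      n_trees = 200L, holdout_fraction = 0.2, exclusion_radius_km = 150,
      n_reps = 10L
    ),
    bootstrap = list(n_boot = 1000L),
    attribution = list(
      enabled = TRUE, n_pcs = 3L, k = 10L,
      thresholds = list(leaf_traits = 0.5, climate = 0.3, soil = 0.15),
      per_pft = FALSE, min_cells = 200L
    ),
    zoo = list(enabled = TRUE)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return A `run_config` (defaults filled in for absent fields).
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_run_config(seed = if (!is.null(user$seed)) user$seed else 1)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  out <- merge_lists(unclass(base), user)
  structure(out, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

physio_from_config <- function(config) {
  do.call(physio_constants, config$constants)
}
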