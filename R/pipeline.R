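# End-to-end pipeline: simulate -> standardize -> rank/select/fit/crossval
# -> predict -> invert + bootstrap -> attribute -> model-zoo comparison.
# Every quantitative output lands in a machine-readable JSON report;
# artifacts (NetCDF maps, CSV tables) are written under the output
# directory. Deterministic under the config seed.

num <- function(x) unname(round(as.numeric(x), 10)) # stable JSON numbers

#' Run the full fLNR derivation pipeline on a synthetic globe
#'
#' Executes every stage in order and writes the artifacts plus a
#' `report.json` holding every headline statistic. A stage failure marks
#' the stage failed in the report and skips downstream stages. Running
#' twice under the same config yields byte-identical reports.
#'
#' @param config A `run_config`, see [default_run_config()].
#' @param output_dir Overrides `config$output_dir` (`NULL` keeps it).
#' @param write_artifacts If `FALSE`, only the report is written.
#' @return The report (named list), invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), output_dir = NULL,
                         write_artifacts = TRUE) {
  if (!is.null(output_dir)) config$output_dir <- output_dir
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- expand_seeds(config$seed)
  constants <- physio_from_config(config)
  report <- list(seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed) {
      report$stages[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    res <- tryCatch(
      {
        fun()
        report$stages[[name]] <<- "ok"
      },
      error = function(e) {
        warning(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
        report$stages[[name]] <<- paste("failed:", conditionMessage(e))
        failed <<- TRUE
      }
    )
    invisible(res)
  }

  run_stage("simulate", function() {
    g <- config$grid
    grid <- make_covariate_grid(
      shape = g$shape, seed = seeds[["grid"]], smoothness = g$smoothness,
      mask_fraction = g$mask_fraction, correlate_groups = g$correlate_groups,
      group_rho = g$group_rho, pft_noise = g$pft_noise
    )
    traits <- make_trait_grid(
      grid, seed = seeds[["traits"]], lncm_range = config$traits$lncm_range,
      rel_sd = config$traits$rel_sd, smoothness = config$traits$smoothness
    )
    grid <- attach_lnc(grid, traits)
    tr <- config$truth
    truth <- withCallingHandlers(
      make_truth(
        grid, traits,
        coefficients = unlist(tr$coefficients), intercept = tr$intercept,
        pft_offsets = unlist(tr$pft_offsets), noise_sd = tr$noise_sd,
        constants = constants, seed = seeds[["truth"]],
        flnr_floor = tr$flnr_floor
      ),
      warning = function(w) invokeRestart("muffleWarning")
    )
    ob <- config$observations
    obs <- sample_observations(
      truth, grid, n = ob$n, n_clusters = ob$n_clusters,
      cluster_radius = ob$cluster_radius, obs_noise_sd = ob$obs_noise_sd,
      tleaf_range = ob$tleaf_range, constants = constants,
      seed = seeds[["observations"]],
      p_scatter = if (is.null(ob$p_scatter)) 0 else ob$p_scatter
    )
    state$grid <- grid; state$traits <- traits
    state$truth <- truth; state$obs <- obs
    report$simulate <<- list(
      n_vegetated = sum(grid$mask),
      n_floored = truth$n_floored,
      flnr_true_mean = num(mean(truth$flnr_true, na.rm = TRUE)),
      flnr_true_sd = num(stats::sd(truth$flnr_true[grid$mask])),
      vcmax25_true_mean = num(mean(truth$vcmax25_true, na.rm = TRUE)),
      n_observations = nrow(obs)
    )
    if (write_artifacts) {
      write_covariate_grid_nc(grid, file.path(config$output_dir, "covariates.nc"))
      write_trait_grid_nc(traits, file.path(config$output_dir, "traits.nc"))
      write_observations_csv(obs, file.path(config$output_dir, "observations.csv"))
    }
  })

  run_stage("standardize", function() {
    state$obs <- standardize_observations(state$obs, constants)
    report$standardize <<- list(
      tleaf_mean = num(mean(state$obs$tleaf)),
      vcmax25_obs_mean = num(mean(state$obs$vcmax25))
    )
  })

  run_stage("select", function() {
    ranking <- rank_importance(
      state$obs, n_trees = config$rf$n_trees, seed = seeds[["rank"]]
    )
    sel <- select_predictors(
      state$obs, ranking, n_trees = config$rf$n_trees,
      seed = seeds[["select"]]
    )
    state$ranking <- ranking; state$selected <- sel$selected
    report$selection <<- list(
      importance = lapply(as.list(ranking), num),
      selected = sel$selected,
      oob_trace = lapply(seq_len(nrow(sel$oob_trace)), function(i) {
        list(
          predictor = sel$oob_trace$predictor[i],
          r2 = num(sel$oob_trace$r2[i]), mse = num(sel$oob_trace$mse[i])
        )
      })
    )
  })

  run_stage("fit", function() {
    state$model <- fit_rf(
      state$obs, state$selected, n_trees = config$rf$n_trees,
      seed = seeds[["fit"]]
    )
    report$fit <<- list(
      n_trees = config$rf$n_trees,
      oob_r2 = num(state$model$oob_r2), oob_mse = num(state$model$oob_mse)
    )
  })

  run_stage("crossval", function() {
    cv_report_json <- function(cv) {
      list(
        r2_mean = num(cv$r2_mean), r2_sd = num(cv$r2_sd),
        rmse_mean = num(cv$rmse_mean), rmse_sd = num(cv$rmse_sd),
        n_reps_used = cv$n_reps_used,
        n_validation_effective = num(cv$n_validation_effective)
      )
    }
    conv <- cross_validate(
      state$obs, state$selected, mode = "conventional",
      holdout_fraction = config$rf$holdout_fraction,
      n_reps = config$rf$n_reps, n_trees = config$rf$n_trees,
      seed = seeds[["crossval"]]
    )
    spat <- cross_validate(
      state$obs, state$selected, mode = "spatial",
      holdout_fraction = config$rf$holdout_fraction,
      exclusion_radius_km = config$rf$exclusion_radius_km,
      n_reps = config$rf$n_reps, n_trees = config$rf$n_trees,
      seed = seeds[["crossval"]]
    )
    report$crossval <<- list(
      conventional = cv_report_json(conv), spatial = cv_report_json(spat)
    )
  })

  run_stage("predict", function() {
    vmap <- predict_grid(state$model, state$grid)
    state$vcmax25_map <- vmap
    report$predict <<- list(
      vcmax25_mean = num(mean(vmap$mean, na.rm = TRUE)),
      vcmax25_spatial_sd = num(stats::sd(vmap$mean[!is.na(vmap$mean)])),
      vcmax25_tree_sd_mean = num(mean(vmap$sd, na.rm = TRUE)),
      r_to_truth = num(stats::cor(
        vmap$mean[state$grid$mask], state$truth$vcmax25_true[state$grid$mask]
      ))
    )
    if (write_artifacts) {
      write_uncertain_map_nc(vmap, file.path(config$output_dir, "vcmax25_rf.nc"))
    }
  })

  run_stage("derive_flnr", function() {
    product <- bootstrap_flnr(
      state$vcmax25_map, state$traits, constants,
      n_boot = config$bootstrap$n_boot, seed = seeds[["bootstrap"]]
    )
    state$flnr_product <- product
    src <- vapply(product$source_contributions,
                  function(m) mean(m, na.rm = TRUE), numeric(1))
    report$flnr <<- list(
      flnr_mean = num(mean(product$flnr$mean, na.rm = TRUE)),
      flnr_spatial_sd = num(stats::sd(product$flnr$mean[!is.na(product$flnr$mean)])),
      flnr_total_uncertainty_mean = num(mean(product$flnr$sd, na.rm = TRUE)),
      source_sd_mean = lapply(as.list(src), num),
      n_boot = product$n_boot
    )
    if (write_artifacts) {
      write_uncertain_map_nc(
        product$flnr, file.path(config$output_dir, "flnr.nc"),
        extra = stats::setNames(
          product$source_contributions,
          paste0("flnr_sd_source_", names(product$source_contributions))
        )
      )
    }
  })

  if (!isTRUE(config$attribution$enabled) && !failed) {
    report$stages[["attribution"]] <- "disabled"
  }
  if (isTRUE(config$attribution$enabled)) run_stage("attribution", function() {
    tab <- grid_table(state$grid)
    flnr_vals <- state$flnr_product$flnr$mean[state$grid$mask]
    spec <- default_group_spec()
    pca <- group_pca(tab, spec)
    att <- fit_attribution_gam(
      flnr_vals, pca, pft = tab$pft,
      n_pcs = config$attribution$n_pcs, k = config$attribution$k
    )
    eff <- compute_group_effects(att, unlist(config$attribution$thresholds))
    sens <- fit_sensitivities(att, eff, tab, spec, scope = "global")
    state$sensitivities <- sens
    explained <- lapply(pca, function(g) {
      num(g$explained[seq_len(min(3, length(g$explained)))])
    })
    report$attribution <<- list(
      explained_variance_top3 = explained,
      area_fractions = lapply(as.list(eff$area_fractions), num),
      mean_abs_effects = stats::setNames(
        lapply(seq_len(nrow(eff$mean_abs_effects)), function(i) {
          list(mean = num(eff$mean_abs_effects$mean_abs[i]),
               sd = num(eff$mean_abs_effects$sd_abs[i]))
        }),
        eff$mean_abs_effects$group
      ),
      sensitivities = stats::setNames(
        lapply(seq_len(nrow(sens)), function(i) {
          list(estimate = num(sens$estimate[i]),
               ci95_halfwidth = num(sens$ci95_halfwidth[i]))
        }),
        sens$variable
      ),
      intercept = num(attr(sens, "intercepts")[["global"]]),
      equation = sensitivity_equation(sens, "global")
    )
    if (write_artifacts) {
      utils::write.csv(sens, file.path(config$output_dir, "sensitivities.csv"),
                       row.names = FALSE)
    }
  })

  if (!isTRUE(config$zoo$enabled) && !failed) {
    report$stages[["zoo"]] <- "disabled"
  }
  if (isTRUE(config$zoo$enabled)) run_stage("zoo", function() {
    flnr_map <- state$flnr_product$flnr
    lnc <- state$grid$layers$lnc
    zoo_entry <- function(id) {
      v <- evaluate_model(em_model(id), state$grid)
      fl <- implied_flnr(v, lnc, constants)
      cmp <- compare_maps(flnr_map$mean, fl, state$grid$pft)
      list(
        vcmax25_mean = num(mean(v, na.rm = TRUE)),
        implied_flnr_mean = num(mean(fl, na.rm = TRUE)),
        implied_flnr_sd = num(stats::sd(fl[!is.na(fl)])),
        spatial_r_to_derived = num(cmp$spatial_r)
      )
    }
    derived_cmp <- compare_maps(flnr_map$mean, flnr_map$mean, state$grid$pft)
    report$zoo <<- list(
      EM3 = zoo_entry("EM3"), EM4 = zoo_entry("EM4"),
      derived_forest_vs_nonforest = list(
        t = num(derived_cmp$group_test$t), p = num(derived_cmp$group_test$p),
        forest_mean = num(derived_cmp$group_test$forest_mean),
        nonforest_mean = num(derived_cmp$group_test$nonforest_mean)
      )
    )
  })

  write_report_json(report, file.path(config$output_dir, "report.json"))
  invisible(report)
}
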