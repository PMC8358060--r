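# Bagged-tree upscaling of site Vcmax25: permutation-importance ranking,
# forward predictor selection with an out-of-bag stopping rule, conventional
# and spatially buffered cross-validation, and gridded prediction with
# per-tree uncertainty. randomForest supplies the bagged ensemble; factors
# (PFT, Koeppen) are single predictors in ranking and selection.

EARTH_RADIUS_M <- 6371000 # haversine radius, 6371 km

#' Default candidate predictor set
#'
#' The 19 gridded covariate layers plus the PFT class: 20 candidates.
#'
#' @return Character vector of column names.
#' @export
default_candidate_predictors <- function() {
  c(names(default_layer_ranges()), "koeppen", "pft")
}

obs_xy <- function(obs, predictors, response) {
  missing_cols <- setdiff(c(predictors, response), names(obs))
  if (length(missing_cols) > 0L) {
    stop("columns missing from observation table: ",
         paste(missing_cols, collapse = ", "))
  }
  x <- obs[, predictors, drop = FALSE]
  for (nm in names(x)) if (is.character(x[[nm]])) x[[nm]] <- factor(x[[nm]])
  list(x = x, y = obs[[response]])
}

is_constant_col <- function(v) {
  v <- v[!is.na(v)]
  length(unique(v)) <= 1L
}

#' Rank candidate predictors by permutation importance
#'
#' Fits one bagged ensemble on all candidates and returns the unscaled
#' permutation importance (mean OOB MSE increase when the predictor is
#' permuted), in descending order. Constant-valued candidates get
#' importance 0 and are reported.
#'
#' @param obs Observation table (>= 50 rows).
#' @param candidates Predictor column names; factors count as single
#'   predictors.
#' @param response Response column (default `"vcmax25"`).
#' @param n_trees Number of bagged trees (default 200).
#' @param seed Integer seed; the ranking is deterministic under it.
#' @return Named numeric vector, descending.
#' @export
rank_importance <- function(obs, candidates = default_candidate_predictors(),
                            response = "vcmax25", n_trees = 200, seed = 1) {
  if (nrow(obs) < 50) stop("need at least 50 observations to rank predictors")
  xy <- obs_xy(obs, candidates, response)
  const <- vapply(xy$x, is_constant_col, logical(1))
  if (any(const)) {
    message("constant predictors assigned importance 0: ",
            paste(candidates[const], collapse = ", "))
  }
  live <- candidates[!const]
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = xy$x[, live, drop = FALSE], y = xy$y,
    ntree = n_trees, importance = TRUE
  )
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  out <- stats::setNames(numeric(length(candidates)), candidates)
  out[names(imp)] <- imp
  sort(out, decreasing = TRUE)
}

oob_metrics <- function(rf, y) {
  mse <- rf$mse[length(rf$mse)]
  list(r2 = 1 - mse / mean((y - mean(y))^2), mse = mse)
}

#' Forward predictor selection with an out-of-bag stopping rule
#'
#' Feeds predictors one by one in ranking order, refitting the full
#' ensemble at each step, and stops at the first step at which the OOB r2
#' no longer increases AND the OOB mean squared error no longer decreases
#' (ties, within `epsilon`, stop). Returns the predictor set before the
#' failed step.
#'
#' @param obs Observation table.
#' @param ranking Named importance vector from [rank_importance()] (or any
#'   ordered character vector of predictor names).
#' @param response Response column.
#' @param n_trees Trees per step.
#' @param seed Integer seed.
#' @param epsilon Tolerance absorbing float jitter in the stopping
#'   comparisons.
#' @return List with `selected` (character) and `oob_trace` (data.frame
#'   with one row per step tried: predictor added, OOB r2, OOB mse).
#' @export
select_predictors <- function(obs, ranking, response = "vcmax25",
                              n_trees = 200, seed = 1, epsilon = 1e-6) {
  nms <- if (is.character(ranking)) ranking else names(ranking)
  if (length(nms) == 0L) stop("ranking is empty")
  xy <- obs_xy(obs, nms, response)
  trace <- data.frame(
    step = integer(), predictor = character(), r2 = numeric(), mse = numeric()
  )
  selected <- character(0)
  prev <- NULL
  for (k in seq_along(nms)) {
    set.seed((seed + k) %% 2147483647)
    rf <- randomForest::randomForest(
      x = xy$x[, nms[seq_len(k)], drop = FALSE], y = xy$y, ntree = n_trees
    )
    m <- oob_metrics(rf, xy$y)
    trace <- rbind(trace, data.frame(
      step = k, predictor = nms[k], r2 = m$r2, mse = m$mse
    ))
    if (!is.null(prev) &&
        m$r2 <= prev$r2 + epsilon && m$mse >= prev$mse - epsilon) {
      if (k == 2L) {
        message("first predictor alone already at the stopping condition; ",
                "returning the singleton set")
      }
      break
    }
    selected <- nms[seq_len(k)]
    prev <- m
  }
  list(selected = selected, oob_trace = trace)
}

#' Fit the bagged-tree Vcmax25 model
#'
#' Fits the ensemble on all rows (no species/genus abundance weighting);
#' tree hyperparameters beyond the count are library defaults, recorded in
#' the returned bundle.
#'
#' @param obs Observation table.
#' @param predictors Selected predictor names.
#' @param response Response column.
#' @param n_trees Number of trees (default 200).
#' @param seed Integer seed.
#' @param min_rows Minimum admissible number of rows (default 30).
#' @return An object of class `flnr_rf` wrapping the ensemble with its OOB
#'   r2/mse and the factor levels seen in training.
#' @export
fit_rf <- function(obs, predictors, response = "vcmax25", n_trees = 200,
                   seed = 1, min_rows = 30) {
  if (nrow(obs) < min_rows) {
    stop(sprintf("need at least %d rows to fit the ensemble", min_rows))
  }
  xy <- obs_xy(obs, predictors, response)
  set.seed(seed)
  rf <- randomForest::randomForest(x = xy$x, y = xy$y, ntree = n_trees)
  m <- oob_metrics(rf, xy$y)
  structure(
    list(
      rf = rf, predictors = predictors, response = response,
      n_trees = n_trees, seed = seed, oob_r2 = m$r2, oob_mse = m$mse,
      xlevels = lapply(Filter(is.factor, xy$x), levels),
      hyperparameters = list(mtry = rf$mtry, nodesize = 5)
    ),
    class = "flnr_rf"
  )
}

#' @export
print.flnr_rf <- function(x, ...) {
  cat(sprintf(
    "flnr_rf: %d trees on {%s}; OOB r2 = %.3f, OOB mse = %.2f\n",
    x$n_trees, paste(x$predictors, collapse = ", "), x$oob_r2, x$oob_mse
  ))
  invisible(x)
}

#' Pairwise great-circle distances between two coordinate sets
#'
#' Haversine distance on a 6371 km sphere. Exposed so tests can verify the
#' spatial exclusion post hoc.
#'
#' @param a,b Data frames (or matrices) with `lon` and `lat` columns /
#'   two columns in lon, lat order.
#' @return Matrix of distances in km, `nrow(a)` x `nrow(b)`.
#' @export
greatcircle_km <- function(a, b) {
  pts <- function(z) {
    if (is.data.frame(z)) cbind(z$lon, z$lat) else z
  }
  geosphere::distm(pts(a), pts(b), fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M)
  }) / 1000
}

#' Conventional and spatially buffered cross-validation
#'
#' Per repetition, a random holdout split (default 80/20). In spatial mode
#' the holdout rows lying within `exclusion_radius_km` great-circle
#' distance of ANY training row are removed before scoring, breaking
#' spatial autocorrelation between splits; the exclusion is applied per
#' repetition. r2 is 1 - SSE/SST on the surviving holdout; RMSE in response
#' units. With `exclusion_radius_km = 0` the spatial mode reproduces the
#' conventional mode exactly (splits share seeds).
#'
#' @param obs Observation table with `lat`/`lon` columns.
#' @param predictors Predictor names.
#' @param response Response column.
#' @param mode `"conventional"` or `"spatial"`.
#' @param holdout_fraction Fraction held out per rep (default 0.2).
#' @param exclusion_radius_km Buffer radius (spatial mode; default 150).
#' @param n_reps Number of repetitions (>= 1).
#' @param n_trees Trees per fit.
#' @param seed Integer seed.
#' @param return_splits If `TRUE`, the report carries a `splits` list with
#'   the training and retained-validation row indices of every repetition,
#'   so the exclusion can be verified post hoc.
#' @return An object of class `cv_report`.
#' @export
cross_validate <- function(obs, predictors, response = "vcmax25",
                           mode = c("conventional", "spatial"),
                           holdout_fraction = 0.2, exclusion_radius_km = 150,
                           n_reps = 20, n_trees = 200, seed = 1,
                           return_splits = FALSE) {
  mode <- match.arg(mode)
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must be in (0, 1)")
  }
  n <- nrow(obs)
  r2 <- rmse <- nval <- rep(NA_real_, n_reps)
  splits <- if (return_splits) vector("list", n_reps) else NULL
  for (rep_i in seq_len(n_reps)) {
    rep_seed <- (seed %% 1000000L) * 1000L + rep_i # keep below 2^31
    set.seed(rep_seed)
    hold <- sample.int(n, max(1L, round(holdout_fraction * n)))
    train <- setdiff(seq_len(n), hold)
    if (mode == "spatial" && exclusion_radius_km > 0) {
      d <- greatcircle_km(obs[hold, c("lon", "lat")],
                          obs[train, c("lon", "lat")])
      hold <- hold[apply(d, 1L, min) >= exclusion_radius_km]
    }
    if (return_splits) splits[[rep_i]] <- list(train = train, validation = hold)
    if (length(hold) == 0L) {
      warning(sprintf("rep %d: no validation rows survive the exclusion; skipped",
                      rep_i))
      next
    }
    model <- fit_rf(obs[train, , drop = FALSE], predictors, response,
                    n_trees = n_trees, seed = rep_seed, min_rows = 10)
    xy <- obs_xy(obs[hold, , drop = FALSE], predictors, response)
    pred <- stats::predict(model$rf, newdata = xy$x)
    err <- xy$y - pred
    sst <- sum((xy$y - mean(xy$y))^2)
    r2[rep_i] <- if (sst > 0) 1 - sum(err^2) / sst else NA_real_
    rmse[rep_i] <- sqrt(mean(err^2))
    nval[rep_i] <- length(hold)
  }
  ok <- !is.na(rmse)
  if (!any(ok)) stop("all cross-validation repetitions were skipped")
  structure(
    list(
      mode = mode,
      r2_mean = mean(r2[ok]), r2_sd = stats::sd(r2[ok]),
      rmse_mean = mean(rmse[ok]), rmse_sd = stats::sd(rmse[ok]),
      n_reps = n_reps, n_reps_used = sum(ok),
      holdout_fraction = holdout_fraction,
      exclusion_radius_km = if (mode == "spatial") exclusion_radius_km else NA_real_,
      n_validation_effective = mean(nval[ok]),
      r2 = r2, rmse = rmse, splits = splits
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "%s cross-validation (%d/%d reps): r2 = %.3f +/- %.3f, rmse = %.2f +/- %.2f (n_val ~ %.0f)\n",
    x$mode, x$n_reps_used, x$n_reps, x$r2_mean, x$r2_sd,
    x$rmse_mean, x$rmse_sd, x$n_validation_effective
  ))
  invisible(x)
}

#' Predict a gridded Vcmax25 map with per-tree uncertainty
#'
#' Per vegetated cell: mean over the ensemble's trees and the standard
#' deviation of the per-tree estimates (the map's uncertainty layer).
#' Masked cells are missing in both fields.
#'
#' @param model A `flnr_rf` bundle.
#' @param grid A `covariate_grid` carrying every selected predictor.
#' @return An `uncertain_map` of Vcmax25 (umol m-2 s-1).
#' @export
predict_grid <- function(model, grid) {
  tab <- grid_table(grid)
  missing_layers <- setdiff(model$predictors, names(tab))
  if (length(missing_layers) > 0L) {
    stop("predictor layers missing from grid: ",
         paste(missing_layers, collapse = ", "))
  }
  newx <- tab[, model$predictors, drop = FALSE]
  for (nm in names(model$xlevels)) {
    newx[[nm]] <- factor(as.character(newx[[nm]]), levels = model$xlevels[[nm]])
  }
  pr <- stats::predict(model$rf, newdata = newx, predict.all = TRUE)
  mu <- rowMeans(pr$individual)
  sdev <- apply(pr$individual, 1L, stats::sd)
  dm <- dim(grid$mask)
  mean_f <- array(NA_real_, dm)
  sd_f <- array(NA_real_, dm)
  ij <- cbind(tab$row, tab$col)
  mean_f[ij] <- mu
  sd_f[ij] <- sdev
  uncertain_map(mean_f, sd_f, grid$lat, grid$lon,
                quantity = "vcmax25", units = "umol m-2 s-1")
}
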