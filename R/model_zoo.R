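# Empirical Vcmax25 model zoo (EM1-EM5), the fLNR each model implies, and
# map-comparison statistics (spatial correlation, per-PFT distributions,
# forest vs non-forest test). EM3/EM4 carry printed constants; EM1/EM2/EM5
# take per-PFT coefficients from a config file (their canonical values live
# in the source publications and are not printed here — the shipped example
# file is synthetic and labelled non-canonical).

em_forms <- c(
  EM1 = "linear_lnc", EM2 = "linear_lnc",
  EM3 = "power_lnc", EM4 = "power_lnc_lpc", EM5 = "linear_climate"
)

#' Specify an empirical Vcmax25 model
#'
#' * `EM1`/`EM2` (`linear_lnc`): `Vcmax25 = n1 * LNC + n2` with PFT-specific
#'   `n1`, `n2` — a fixed fLNR per PFT.
#' * `EM3` (`power_lnc`): `Vcmax25 = e^3.712 * LNC^0.65` (fixed constants,
#'   no overrides accepted).
#' * `EM4` (`power_lnc_lpc`): `Vcmax25 = e^3.946 * LNC^(0.921 + 0.282
#'   ln(LPC)) * LPC^0.121` (fixed constants).
#' * `EM5` (`linear_climate`): per-PFT linear model in precipitation, air
#'   temperature, radiation and a scalar CO2 term.
#'
#' @param model_id One of `"EM1"`..`"EM5"`.
#' @param coefficients For EM1/EM2: data frame with columns `pft`, `n1`,
#'   `n2`. For EM5: data frame with columns `pft`, `b_pp`, `b_tair`,
#'   `b_par`, `b_co2`, `b0`, plus attribute-free scalar `co2` passed
#'   separately. Must be `NULL` for EM3/EM4.
#' @param co2 Atmospheric CO2 (ppm) used by EM5 (default 400).
#' @return An object of class `em_model`.
#' @export
em_model <- function(model_id, coefficients = NULL, co2 = 400) {
  model_id <- match.arg(model_id, names(em_forms))
  form <- em_forms[[model_id]]
  if (form %in% c("power_lnc", "power_lnc_lpc")) {
    if (!is.null(coefficients)) {
      stop(model_id, " carries printed constants and accepts no overrides")
    }
  } else {
    if (is.null(coefficients)) {
      stop(model_id, " requires a per-PFT coefficient table ",
           "(see read_em_coefficients())")
    }
    need <- if (form == "linear_lnc") c("pft", "n1", "n2") else
      c("pft", "b_pp", "b_tair", "b_par", "b_co2", "b0")
    missing_cols <- setdiff(need, names(coefficients))
    if (length(missing_cols) > 0L) {
      stop("coefficient table misses columns: ",
           paste(missing_cols, collapse = ", "))
    }
  }
  structure(
    list(model_id = model_id, form = form, coefficients = coefficients,
         co2 = co2),
    class = "em_model"
  )
}

pft_coef_field <- function(grid, coefficients, column) {
  f <- array(NA_real_, dim = dim(grid$mask))
  idx <- match(grid$pft[grid$mask], coefficients$pft)
  vals <- coefficients[[column]][idx]
  f[grid$mask] <- vals
  f
}

#' Evaluate an empirical Vcmax25 model on a grid
#'
#' Cell-wise evaluation of the model's closed form. EM4 cells with
#' non-positive LPC are masked (log undefined); cells of a PFT without
#' coefficients are masked with a warning.
#'
#' @param spec An `em_model`.
#' @param grid A `covariate_grid` carrying the required layers (`lnc`;
#'   `lpc` for EM4; `pp`, `tair`, `par` for EM5; `pft` for PFT-specific
#'   forms).
#' @return Vcmax25 field (matrix, umol m-2 s-1).
#' @examples
#' # EM3 at LNC = 1 g m-2 is e^3.712 ~ 40.9 umol m-2 s-1
#' @export
evaluate_model <- function(spec, grid) {
  lnc <- grid$layers$lnc
  out <- switch(spec$form,
    power_lnc = exp(3.712) * lnc^0.65,
    power_lnc_lpc = {
      lpc <- grid$layers$lpc
      bad <- !is.na(lpc) & lpc <= 0
      if (any(bad)) {
        warning(sprintf("EM4: %d cells with non-positive LPC masked", sum(bad)))
        lpc[bad] <- NA
      }
      exp(3.946) * lnc^(0.921 + 0.282 * log(lpc)) * lpc^0.121
    },
    linear_lnc = {
      n1 <- pft_coef_field(grid, spec$coefficients, "n1")
      n2 <- pft_coef_field(grid, spec$coefficients, "n2")
      n1 * lnc + n2
    },
    linear_climate = {
      cf <- spec$coefficients
      b <- lapply(c("b_pp", "b_tair", "b_par", "b_co2", "b0"), function(cl) {
        pft_coef_field(grid, cf, cl)
      })
      b[[1]] * grid$layers$pp + b[[2]] * grid$layers$tair +
        b[[3]] * grid$layers$par + b[[4]] * spec$co2 + b[[5]]
    }
  )
  if (spec$form %in% c("linear_lnc", "linear_climate")) {
    uncovered <- grid$mask & !(grid$pft %in% spec$coefficients$pft)
    if (any(uncovered)) {
      warning(sprintf(
        "%s: %d cells of PFTs without coefficients masked (%s)",
        spec$model_id, sum(uncovered),
        paste(unique(grid$pft[uncovered]), collapse = ", ")
      ))
    }
  }
  out[!grid$mask] <- NA
  out
}

#' fLNR implied by a Vcmax25 field
#'
#' Inverts the nitrogen-allocation identity for the candidate model's
#' Vcmax25 map, exposing the nitrogen-use assumption the model encodes.
#'
#' @param vcmax25 Vcmax25 field (matrix or `uncertain_map`).
#' @param lnc LNC field (g m-2).
#' @param constants A [physio_constants()] object.
#' @return fLNR field (percent).
#' @export
implied_flnr <- function(vcmax25, lnc, constants = physio_constants()) {
  invert_flnr(vcmax25, lnc, constants)
}

#' Read EM coefficient tables from a YAML config
#'
#' Per-model blocks with per-PFT rows. See
#' `system.file("extdata", "em_coefficients_example.yaml", package = "flnr")`
#' for the documented (synthetic, non-canonical) example format.
#'
#' @param path YAML file path.
#' @return Named list of data frames (one per model id present).
#' @export
read_em_coefficients <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(block) {
    do.call(rbind, lapply(block, function(row) as.data.frame(row)))
  })
}

#' Compare two co-registered maps
#'
#' Pearson correlation over co-valid vegetated cells, per-PFT distribution
#' summaries (mean, sd, quartiles, 10th/90th percentiles) for both maps,
#' and a Welch two-sample t-test of forest vs non-forest means of the
#' candidate map.
#'
#' @param reference,candidate Fields (matrices or `uncertain_map`s) on the
#'   same grid.
#' @param pft PFT label matrix (from a `covariate_grid`).
#' @param forest Character vector of forest PFT classes.
#' @param min_cells Minimum co-valid cells (default 30); fewer refuses the
#'   statistics.
#' @return An object of class `map_comparison`: `spatial_r`,
#'   `per_pft_stats` (long data frame), `group_test` (t statistic, p value,
#'   group means), `n_covalid`.
#' @export
compare_maps <- function(reference, candidate, pft,
                         forest = forest_classes(), min_cells = 30) {
  ref <- field_of(reference)
  cand <- field_of(candidate)
  stopifnot(identical(dim(ref), dim(cand)))
  ok <- !is.na(ref) & !is.na(cand)
  if (sum(ok) < min_cells) {
    stop(sprintf("only %d co-valid cells (< %d); statistics refused",
                 sum(ok), min_cells))
  }
  r <- stats::cor(ref[ok], cand[ok])

  qstats <- function(v) {
    q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
    data.frame(
      n = length(v), mean = mean(v), sd = stats::sd(v),
      p10 = q[1], q25 = q[2], median = q[3], q75 = q[4], p90 = q[5]
    )
  }
  per_pft <- NULL
  for (map_name in c("reference", "candidate")) {
    f <- if (map_name == "reference") ref else cand
    for (cl in sort(unique(stats::na.omit(pft[ok])))) {
      sel <- ok & !is.na(pft) & pft == cl
      if (sum(sel) == 0L) next
      per_pft <- rbind(per_pft, cbind(
        data.frame(map = map_name, pft = cl), qstats(f[sel])
      ))
    }
  }

  is_forest <- ok & !is.na(pft) & pft %in% forest
  is_nonforest <- ok & !is.na(pft) & !(pft %in% forest)
  group_test <- NULL
  if (sum(is_forest) >= 2 && sum(is_nonforest) >= 2) {
    tt <- stats::t.test(cand[is_forest], cand[is_nonforest])
    group_test <- list(
      t = unname(tt$statistic), p = tt$p.value,
      forest_mean = unname(tt$estimate[1]),
      nonforest_mean = unname(tt$estimate[2])
    )
  }
  structure(
    list(spatial_r = r, per_pft_stats = per_pft, group_test = group_test,
         n_covalid = sum(ok)),
    class = "map_comparison"
  )
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("map_comparison: r = %.3f over %d co-valid cells\n",
              x$spatial_r, x$n_covalid))
  if (!is.null(x$group_test)) {
    cat(sprintf(
      "  forest %.2f vs non-forest %.2f (Welch t = %.2f, p = %.3g)\n",
      x$group_test$forest_mean, x$group_test$nonforest_mean,
      x$group_test$t, x$group_test$p
    ))
  }
  invisible(x)
}
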