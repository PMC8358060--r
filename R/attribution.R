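# Attribution of fLNR variation to leaf-trait, climate and soil drivers:
# z-score normalization, per-group PCA, a generalized additive model of
# fLNR on the top-3 PCs of each group plus PFT dummies, per-cell group
# total effects and dominance, and multivariate linear sensitivities of the
# group effects to the raw variables, assembled into one empirical fLNR
# equation per scope.

#' Default variable grouping for the attribution
#'
#' Leaf traits (LNC excluded, since it enters the fLNR denominator),
#' climate and soil. Groups are disjoint.
#'
#' @return Named list of character vectors.
#' @export
default_group_spec <- function() {
  list(
    leaf_traits = c("lpc", "lma"),
    climate = c("tair", "pp", "par", "vpd", "swc"),
    soil = c("soilC", "soilN", "cn", "ph", "sand", "silt", "bulkD", "cec")
  )
}

units_of <- function(vars) {
  u <- layer_units()
  ifelse(vars %in% names(u), u[vars], "")
}

#' Per-group principal component analysis on normalized variables
#'
#' Each group's variables are z-scored (zero-variance variables dropped
#' with a warning) and eigendecomposed. Loadings follow a deterministic
#' sign convention: the largest-|loading| entry of each component is
#' positive.
#'
#' @param data Data frame of cells/sites containing every group variable.
#' @param spec Named list of variable groups, see [default_group_spec()].
#' @return An object of class `group_pca`: per group, `loadings`
#'   (variables x components, orthonormal), `explained` (variance
#'   fractions, non-increasing), `scores` (rows x components), `center`,
#'   `scale`, `vars`.
#' @export
group_pca <- function(data, spec = default_group_spec()) {
  out <- list()
  for (g in names(spec)) {
    vars <- spec[[g]]
    missing_vars <- setdiff(vars, names(data))
    if (length(missing_vars) > 0L) {
      stop(sprintf("group '%s': variables missing from data: %s",
                   g, paste(missing_vars, collapse = ", ")))
    }
    x <- as.matrix(data[, vars, drop = FALSE])
    sds <- apply(x, 2L, stats::sd)
    drop <- sds == 0 | is.na(sds)
    if (any(drop)) {
      warning(sprintf("group '%s': zero-variance variables dropped: %s",
                      g, paste(vars[drop], collapse = ", ")))
      vars <- vars[!drop]
      x <- x[, vars, drop = FALSE]
      sds <- sds[!drop]
    }
    if (nrow(x) < 10 * length(vars)) {
      warning(sprintf(
        "group '%s': fewer than 10 rows per variable (%d rows, %d variables)",
        g, nrow(x), length(vars)
      ))
    }
    ctr <- colMeans(x)
    z <- scale(x, center = ctr, scale = sds)
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    load <- pc$rotation
    scores <- pc$x
    for (j in seq_len(ncol(load))) { # sign convention
      if (load[which.max(abs(load[, j])), j] < 0) {
        load[, j] <- -load[, j]
        scores[, j] <- -scores[, j]
      }
    }
    out[[g]] <- list(
      loadings = load,
      explained = pc$sdev^2 / sum(pc$sdev^2),
      scores = scores,
      center = ctr, scale = sds, vars = vars
    )
  }
  structure(out, class = "group_pca")
}

score_frame <- function(pca, n_pcs) {
  dfs <- lapply(names(pca), function(g) {
    k <- min(n_pcs, ncol(pca[[g]]$scores))
    s <- pca[[g]]$scores[, seq_len(k), drop = FALSE]
    colnames(s) <- paste0(g, "_PC", seq_len(k))
    as.data.frame(s)
  })
  do.call(cbind, dfs)
}

#' Fit the additive attribution model of fLNR on group PCs
#'
#' `fLNR ~ PFT + sum over groups and components of s(PC_k)`, with penalized
#' cubic regression splines (basis dimension `k`) and smoothness chosen by
#' generalized cross-validation. PFT levels with fewer than
#' `min_pft_cells` cells are merged into the most frequent level. Partial
#' response curves are tabulated on a 100-point lattice spanning each
#' score's observed range, with pointwise standard errors.
#'
#' @param flnr fLNR values (percent), one per row of the PCA scores.
#' @param pca A `group_pca` whose scores are co-registered with `flnr`.
#' @param pft Factor (or character) of PFT labels per row; `NULL` drops the
#'   PFT term.
#' @param n_pcs Components per group entering the model (default 3).
#' @param k Spline basis dimension per smooth (default 10).
#' @param min_pft_cells Minimum cells per PFT level (default 20).
#' @return An object of class `flnr_attribution`: the fitted `gam`, the
#'   model frame, `partial_curves` (named list of data frames with `score`,
#'   `delta_flnr`, `se`), `pca`, `n_pcs`.
#' @export
fit_attribution_gam <- function(flnr, pca, pft = NULL, n_pcs = 3, k = 10,
                                min_pft_cells = 20) {
  scores <- score_frame(pca, n_pcs)
  if (length(flnr) != nrow(scores)) {
    stop("flnr and PCA scores are not co-registered")
  }
  df <- cbind(data.frame(flnr = flnr), scores)
  has_pft <- !is.null(pft)
  if (has_pft) {
    pft <- factor(as.character(pft))
    tab <- table(pft)
    small <- names(tab)[tab < min_pft_cells & tab > 0]
    if (length(small) > 0L) {
      biggest <- names(tab)[which.max(tab)]
      warning(sprintf("PFT levels with < %d cells merged into '%s': %s",
                      min_pft_cells, biggest, paste(small, collapse = ", ")))
      pft[pft %in% small] <- biggest
      pft <- droplevels(pft)
    }
    df$pft <- pft
    if (nlevels(df$pft) < 2L) has_pft <- FALSE
  }
  sm <- sprintf("s(%s, bs = \"cr\", k = %d)", names(scores), k)
  rhs <- paste(c(if (has_pft) "pft", sm), collapse = " + ")
  form <- stats::as.formula(paste("flnr ~", rhs))
  gm <- mgcv::gam(form, data = df, method = "GCV.Cp")

  curves <- list()
  for (v in names(scores)) {
    lattice <- seq(min(scores[[v]]), max(scores[[v]]), length.out = 100)
    nd <- as.data.frame(lapply(scores, function(z) rep(0, 100)))
    nd[[v]] <- lattice
    if (has_pft) nd$pft <- factor(levels(df$pft)[1], levels = levels(df$pft))
    pr <- stats::predict(gm, newdata = nd, type = "terms", se.fit = TRUE)
    col <- grep(sprintf("s(%s)", v), colnames(pr$fit), fixed = TRUE)
    curves[[v]] <- data.frame(
      score = lattice,
      delta_flnr = pr$fit[, col],
      se = pr$se.fit[, col]
    )
  }

  structure(
    list(gam = gm, data = df, partial_curves = curves, pca = pca,
         n_pcs = n_pcs, has_pft = has_pft),
    class = "flnr_attribution"
  )
}

#' Per-cell group effects, dominance and area fractions
#'
#' Per cell, a group's total effect is the sum of its smooth terms
#' (partial ΔfLNR of its top PCs); the relative share is
#' |effect_g| / Σ_g |effect_g|; the dominance label is the argmax share.
#' Area fractions report the share of vegetated cells on which each group's
#' share meets its threshold (cells unweighted).
#'
#' @param att A `flnr_attribution`.
#' @param thresholds Named share thresholds per group.
#' @return List with `effects` (data frame, one column per group),
#'   `shares`, `dominance` (factor), `area_fractions`, `mean_abs_effects`
#'   (mean and sd of |effect| per group), `n_excluded` (cells with all-zero
#'   effects), and `fitted` (GAM fitted values, for additivity checks).
#' @export
compute_group_effects <- function(att, thresholds = c(
                                    leaf_traits = 0.50, climate = 0.30,
                                    soil = 0.15
                                  )) {
  tm <- stats::predict(att$gam, type = "terms")
  groups <- names(att$pca)
  eff <- sapply(groups, function(g) {
    cols <- grep(sprintf("s(%s_PC", g), colnames(tm), fixed = TRUE)
    rowSums(tm[, cols, drop = FALSE])
  })
  eff <- as.data.frame(eff)
  tot <- rowSums(abs(eff))
  zero <- tot == 0
  shares <- sweep(abs(eff), 1L, tot, "/")
  shares[zero, ] <- NA
  absm <- as.matrix(abs(eff))
  dominance <- rep(NA_character_, nrow(absm))
  if (any(!zero)) {
    dominance[!zero] <- groups[max.col(absm[!zero, , drop = FALSE], "first")]
  }
  dominance <- factor(dominance, levels = groups)
  area_fractions <- vapply(groups, function(g) {
    thr <- if (g %in% names(thresholds)) thresholds[[g]] else 0.5
    mean(shares[[g]][!zero] >= thr)
  }, numeric(1))
  mean_abs_effects <- data.frame(
    group = groups,
    mean_abs = vapply(groups, function(g) mean(abs(eff[[g]])), numeric(1)),
    sd_abs = vapply(groups, function(g) stats::sd(abs(eff[[g]])), numeric(1))
  )
  list(
    effects = eff, shares = shares, dominance = dominance,
    area_fractions = area_fractions, mean_abs_effects = mean_abs_effects,
    n_excluded = sum(zero), fitted = stats::fitted(att$gam),
    terms = tm, constant = attr(tm, "constant")
  )
}

sensitivity_rows <- function(fit, vars, scope) {
  est <- stats::coef(fit)[vars]
  ci <- stats::confint(fit)[vars, , drop = FALSE]
  data.frame(
    scope = scope, variable = vars, estimate = unname(est),
    ci95_halfwidth = unname((ci[, 2] - ci[, 1]) / 2),
    units = sprintf("%% per %s", units_of(vars)),
    row.names = NULL
  )
}

#' Per-variable fLNR sensitivities from the group effects
#'
#' Per group, an ordinary least squares fit of the group's total effect on
#' that group's raw (unnormalized) variables; the coefficients of all
#' groups are merged into one empirical fLNR equation per scope, with the
#' intercept assembled so that the equation is centered on the model:
#' intercept = mean(GAM fitted) - sum over variables of coef x mean(x).
#' Per-PFT scope refits the group OLS on that PFT's cells only (minimum
#' `min_cells`, else skipped with a warning).
#'
#' @param att A `flnr_attribution`.
#' @param effects Output of [compute_group_effects()].
#' @param data Data frame with the raw group variables, co-registered with
#'   the attribution rows.
#' @param spec The variable grouping used.
#' @param scope `"global"` or `"per_pft"`.
#' @param min_cells Minimum cells per PFT for a per-PFT equation.
#' @return An object of class `sensitivity_table`: data frame with columns
#'   scope, variable, estimate, ci95_halfwidth, units; the per-scope
#'   intercepts are in `attr(, "intercepts")`, condition numbers of the
#'   group design matrices in `attr(, "condition_numbers")`.
#' @export
fit_sensitivities <- function(att, effects, data,
                              spec = default_group_spec(),
                              scope = c("global", "per_pft"),
                              min_cells = 200) {
  scope <- match.arg(scope)
  groups <- names(spec)

  fit_scope <- function(rows, label) {
    out <- NULL
    condn <- numeric(0)
    coef_all <- numeric(0)
    for (g in groups) {
      vars <- intersect(spec[[g]], names(data))
      d <- data[rows, vars, drop = FALSE]
      d$effect <- effects$effects[[g]][rows]
      fit <- stats::lm(effect ~ ., data = d)
      kappa_g <- kappa(stats::model.matrix(fit), exact = FALSE)
      if (kappa_g > 1e8) {
        message(sprintf("scope %s, group %s: condition number %.3g",
                        label, g, kappa_g))
      }
      condn[g] <- kappa_g
      out <- rbind(out, sensitivity_rows(fit, vars, label))
      coef_all[vars] <- stats::coef(fit)[vars]
    }
    xbar <- colMeans(data[rows, names(coef_all), drop = FALSE])
    intercept <- mean(effects$fitted[rows]) - sum(coef_all * xbar)
    list(rows = out, intercept = intercept, condn = condn)
  }

  tables <- NULL
  intercepts <- numeric(0)
  condition_numbers <- list()
  if (scope == "global") {
    fs <- fit_scope(seq_len(nrow(data)), "global")
    tables <- fs$rows
    intercepts["global"] <- fs$intercept
    condition_numbers[["global"]] <- fs$condn
  } else {
    if (!att$has_pft) stop("per-PFT scope requires a PFT term in the GAM")
    for (lv in levels(att$data$pft)) {
      rows <- which(att$data$pft == lv)
      if (length(rows) < min_cells) {
        warning(sprintf("PFT %s: only %d cells (< %d); skipped",
                        lv, length(rows), min_cells))
        next
      }
      fs <- fit_scope(rows, lv)
      tables <- rbind(tables, fs$rows)
      intercepts[lv] <- fs$intercept
      condition_numbers[[lv]] <- fs$condn
    }
    if (is.null(tables)) stop("no PFT reached the minimum cell count")
  }
  structure(tables,
    intercepts = intercepts, condition_numbers = condition_numbers,
    class = c("sensitivity_table", "data.frame")
  )
}

#' Direct multivariate linear fit of the empirical fLNR equation
#'
#' One ordinary least squares fit of fLNR on the raw variables — the
#' composition the assembled per-group equation represents. This is the
#' reference path for coefficient recovery, free of the smoothing bias of
#' the PCA+GAM route.
#'
#' @param data Data frame with `response` and the predictor columns.
#' @param predictors Variable names (default: those of
#'   [global_flnr_equation()]).
#' @param response Response column (default `"flnr"`).
#' @return List with `coefficients` (named), `intercept`,
#'   `ci95_halfwidth` (named, intercept included as `"(Intercept)"`),
#'   `equation` (printable string) and the `lm` fit.
#' @export
fit_flnr_equation <- function(data,
                              predictors = names(global_flnr_equation()$coefficients),
                              response = "flnr") {
  missing_cols <- setdiff(c(predictors, response), names(data))
  if (length(missing_cols) > 0L) {
    stop("columns missing: ", paste(missing_cols, collapse = ", "))
  }
  form <- stats::reformulate(predictors, response)
  fit <- stats::lm(form, data = data)
  cf <- stats::coef(fit)
  ci <- stats::confint(fit)
  halfwidth <- (ci[, 2] - ci[, 1]) / 2
  eq <- paste0(
    response, " = ",
    paste(sprintf("%+.4g %s", cf[predictors], predictors), collapse = " "),
    sprintf(" %+.4g", cf["(Intercept)"])
  )
  list(
    coefficients = cf[predictors],
    intercept = unname(cf["(Intercept)"]),
    ci95_halfwidth = halfwidth,
    equation = eq,
    fit = fit
  )
}

#' Render a sensitivity table scope as an equation string
#'
#' @param st A `sensitivity_table`.
#' @param scope Scope label present in the table.
#' @return A single string.
#' @export
sensitivity_equation <- function(st, scope = "global") {
  rows <- st[st$scope == scope, ]
  if (nrow(rows) == 0L) stop("scope not present in the table")
  ic <- attr(st, "intercepts")[scope]
  paste0(
    "fLNR = ",
    paste(sprintf("%+.4g %s", rows$estimate, rows$variable), collapse = " "),
    sprintf(" %+.4g", ic)
  )
}
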