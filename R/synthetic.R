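# Synthetic-globe generator. Produces masked half-degree covariate stacks,
# trait maps with uncertainty, a ground-truth fLNR/Vcmax25 world and
# spatially clustered site observations, so every downstream stage is
# testable without external downloads. Random fields are Gaussian white
# noise convolved with a (separable) Gaussian kernel and affinely rescaled
# into documented realistic ranges.

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian smoothing with reflective padding; sigma in cells
smooth_field <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  conv1 <- function(v) {
    n <- length(v)
    p <- c(rev(v[seq_len(r)]), v, rev(v[n - seq_len(r) + 1L]))
    as.numeric(stats::filter(p, k, sides = 2))[(r + 1L):(r + n)]
  }
  x <- apply(x, 2L, conv1)
  t(apply(x, 1L, conv1))
}

#' Default realistic ranges for the synthetic covariate layers
#'
#' Each continuous layer of [make_covariate_grid()] is rescaled into these
#' closed ranges. Units as in [layer_units()].
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
default_layer_ranges <- function() {
  list(
    chl = c(5, 80), lnc = c(0.5, 3.5), lpc = c(0.05, 0.25),
    lma = c(20, 250), tair = c(-10, 30), pp = c(100, 3000),
    par = c(200, 1200), vpd = c(0.2, 3), swc = c(0.05, 0.45),
    alpha_et = c(0.05, 1), soilC = c(1000, 50000), soilN = c(50, 3000),
    cn = c(5, 40), ph = c(4, 8.5), sand = c(10, 90), silt = c(5, 70),
    bulkD = c(0.8, 1.8), cec = c(2, 40)
  )
}

rescale_range <- function(x, lo, hi) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(array(mean(c(lo, hi)), dim = dim(x)))
  lo + (hi - lo) * (x - rng[1]) / (rng[2] - rng[1])
}

#' Generate a synthetic masked covariate grid
#'
#' Builds a half-degree grid (cell centers at -0.25/+0.25-style offsets,
#' latitude index south to north) carrying the 19 gridded candidate
#' predictors plus a PFT field. Continuous layers are smoothed Gaussian
#' random fields rescaled into `ranges`; PFTs (and Koeppen classes) are
#' contiguous latitudinal bands with categorical noise so that every class
#' has cells.
#'
#' @param shape `c(nlat, nlon)`, each at least 10.
#' @param seed Integer seed; output is bitwise reproducible.
#' @param smoothness Gaussian correlation length in cells (>= 0; 0 gives
#'   spatially white layers).
#' @param ranges Per-layer target ranges, see [default_layer_ranges()].
#' @param mask_fraction Fraction of cells flagged vegetated.
#' @param correlate_groups If `TRUE`, the climate variables other than VPD
#'   and PAR (tair, pp, swc) and the soil variables other than pH and sand
#'   (soilC, soilN, cn, silt, bulkD, cec) are generated from a common latent
#'   field per group, emulating the strong within-group correlation of real
#'   climate and soil products in which the leading principal component
#'   carries most of the group variance. Default `FALSE` (independent
#'   layers).
#' @param group_rho Variance share of the latent field when
#'   `correlate_groups` is `TRUE`.
#' @param pft_noise Fraction of cells whose banded PFT label is reassigned
#'   uniformly at random.
#' @return A `covariate_grid`.
#' @examples
#' g <- make_covariate_grid(c(20, 40), seed = 1)
#' range(g$layers$sand, na.rm = TRUE) # within [10, 90] by construction
#' @export
make_covariate_grid <- function(shape = c(20, 40), seed = 1, smoothness = 3,
                                ranges = default_layer_ranges(),
                                mask_fraction = 0.9,
                                correlate_groups = FALSE, group_rho = 0.6,
                                pft_noise = 0.15) {
  if (length(shape) != 2L || any(shape < 10)) {
    stop("grid shape must be two dimensions, each at least 10")
  }
  if (smoothness < 0) stop("smoothness must be >= 0")
  nlat <- as.integer(shape[1]); nlon <- as.integer(shape[2])
  set.seed(seed)
  lat <- (seq_len(nlat) - (nlat + 1) / 2) * 0.5
  lon <- (seq_len(nlon) - (nlon + 1) / 2) * 0.5

  zfield <- function() {
    f <- smooth_field(matrix(stats::rnorm(nlat * nlon), nlat, nlon), smoothness)
    (f - mean(f)) / stats::sd(f)
  }

  mf <- zfield()
  mask <- mf >= stats::quantile(mf, 1 - mask_fraction)

  band_field <- function(classes) {
    nb <- length(classes)
    band <- ceiling(seq_len(nlat) / nlat * nb)
    lab <- matrix(classes[band], nlat, nlon)
    flip <- stats::runif(nlat * nlon) < pft_noise
    lab[flip] <- sample(classes, sum(flip), replace = TRUE)
    lab
  }
  pft <- band_field(pft_classes())
  # guarantee every PFT class on the mask (per-PFT fits need all classes)
  for (cl in pft_classes()) {
    on <- which(mask & pft == cl)
    if (length(on) == 0L) {
      pft[sample(which(mask), max(3L, sum(mask) %/% 50L))] <- cl
    }
  }
  koeppen <- band_field(koeppen_classes())

  latent_climate <- zfield()
  latent_soil <- zfield()
  latent_for <- function(nm) {
    if (!correlate_groups) return(NULL)
    if (nm %in% c("tair", "pp", "swc")) return(latent_climate)
    if (nm %in% c("soilC", "soilN", "cn", "silt", "bulkD", "cec")) {
      return(latent_soil)
    }
    NULL
  }

  layers <- list()
  for (nm in names(default_layer_ranges())) {
    z <- zfield()
    lt <- latent_for(nm)
    if (!is.null(lt)) z <- sqrt(group_rho) * lt + sqrt(1 - group_rho) * z
    rg <- ranges[[nm]]
    layers[[nm]] <- rescale_range(z, rg[1], rg[2])
  }
  layers$koeppen <- koeppen

  for (nm in names(layers)) layers[[nm]][!mask] <- NA
  pft[!mask] <- NA

  new_covariate_grid(lat, lon, mask, pft, layers, seed, smoothness, ranges)
}

#' Generate a leaf-trait grid with per-cell uncertainty
#'
#' Specific leaf area is derived from the grid's LMA layer (SLA = 1000/LMA,
#' m2 kg-1) so the trait maps are physically coherent with the covariate
#' stack. Mass-based leaf nitrogen (LNCm, mg g-1) is a smoothed random
#' field anticorrelated with LMA (`lma_rho`), reflecting the leaf economic
#' spectrum: thick, persistent leaves carry less nitrogen per unit mass,
#' which keeps area-based LNC = LNCm/SLA in its realistic range. Per-cell
#' standard deviations are a fixed relative fraction of the means,
#' mimicking the uncertainty layers that accompany upscaled trait products.
#'
#' @param grid A `covariate_grid` (its `lma` layer is used).
#' @param seed Integer seed.
#' @param lncm_range Range of mass-based leaf nitrogen (mg g-1).
#' @param rel_sd Relative uncertainty of both traits (sd/mean).
#' @param smoothness Correlation length of the LNCm field, in cells.
#' @param lma_rho Variance share of the (negated, standardized) LMA field
#'   in the LNCm field.
#' @return An object of class `trait_grid` with fields `lncm_mean`,
#'   `lncm_sd`, `sla_mean`, `sla_sd` (matrices) plus coordinates and mask.
#' @export
make_trait_grid <- function(grid, seed = 1, lncm_range = c(5, 18),
                            rel_sd = 0.1, smoothness = 3, lma_rho = 0.5) {
  set.seed(seed)
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  z <- smooth_field(matrix(stats::rnorm(nlat * nlon), nlat, nlon), smoothness)
  lma <- grid$layers$lma
  zl <- -(lma - mean(lma, na.rm = TRUE)) / stats::sd(lma, na.rm = TRUE)
  zl[is.na(zl)] <- 0
  z <- sqrt(lma_rho) * zl + sqrt(1 - lma_rho) * z
  lncm <- rescale_range(z, lncm_range[1], lncm_range[2])
  sla <- 1000 / grid$layers$lma
  lncm[!grid$mask] <- NA
  tg <- structure(
    list(
      lat = grid$lat, lon = grid$lon, mask = grid$mask,
      lncm_mean = lncm, lncm_sd = rel_sd * lncm,
      sla_mean = sla, sla_sd = rel_sd * sla,
      rel_sd = rel_sd, seed = seed
    ),
    class = "trait_grid"
  )
  stopifnot(all(tg$lncm_mean[grid$mask] > 0), all(tg$sla_mean[grid$mask] > 0))
  tg
}

#' Attach the area-based leaf nitrogen layer implied by a trait grid
#'
#' Sets the grid's `lnc` layer to `lncm_mean / sla_mean` (g m-2), the same
#' identity used when deriving fLNR, so the covariate stack and the trait
#' maps agree.
#'
#' @param grid A `covariate_grid`.
#' @param traits A `trait_grid` on the same grid.
#' @return The modified `covariate_grid`.
#' @export
attach_lnc <- function(grid, traits) {
  stopifnot(identical(dim(grid$mask), dim(traits$lncm_mean)))
  grid$layers$lnc <- traits$lncm_mean / traits$sla_mean
  grid$layers$lnc[!grid$mask] <- NA
  grid
}

#' The published global empirical fLNR equation
#'
#' Coefficients (percent fLNR per unit of each variable) and intercept of
#' the global multivariate sensitivity equation
#' `fLNR = -0.19 LMA + 42.2 LPC + 4.76 VPD + 0.25 pH + 0.0026 PAR +
#' 0.032 sand + 2.4`. Used as the default generating truth of the synthetic
#' globe and as the reference for coefficient-recovery experiments.
#'
#' @return List with elements `coefficients` (named numeric) and
#'   `intercept` (percent).
#' @export
global_flnr_equation <- function() {
  list(
    coefficients = c(
      lma = -0.19, lpc = 42.2, vpd = 4.76,
      ph = 0.25, par = 0.0026, sand = 0.032
    ),
    intercept = 2.4
  )
}

#' Default per-PFT fLNR offsets of the synthetic truth
#'
#' Additive percent offsets applied on top of the global linear equation.
#' Chosen once so that, over the default covariate ranges, the synthetic
#' globe has a global mean fLNR near the observed ~18% and forests sit
#' below non-forests (~15% vs ~21%); the printed global intercept alone
#' does not place uniform mid-range covariates in the physical range
#' because on real data it absorbs the covariance between predictors.
#'
#' @return Named numeric vector over [pft_classes()].
#' @export
default_pft_offsets <- function() {
  c(CRO = 25.5, DBF = 19, EBF = 18.5, ENF = 19.5,
    MF = 19.5, GRA = 25.5, SH = 25, WET = 25)
}

#' Build the ground-truth fLNR and Vcmax25 world
#'
#' fLNR (percent) is a linear combination of covariate layers plus per-PFT
#' offsets and optional Gaussian noise; Vcmax25 follows from the forward
#' nitrogen-allocation identity using LNC = LNCm/SLA from the trait grid.
#'
#' @param grid A `covariate_grid`.
#' @param traits A `trait_grid` on the same grid.
#' @param coefficients Named vector: percent fLNR per unit of each named
#'   layer. All names must exist as layers.
#' @param intercept Intercept (percent).
#' @param pft_offsets Named vector of additive offsets (percent) over the
#'   PFT classes; missing classes get 0.
#' @param noise_sd Cell-wise Gaussian noise sd (percent).
#' @param constants A [physio_constants()] object.
#' @param seed Integer seed for the noise.
#' @param flnr_floor Minimum admissible fLNR (percent). Cells falling below
#'   it are floored with a warning and counted (`n_floored`); `NULL`
#'   disables flooring (used in coefficient-recovery experiments, where
#'   flooring would censor the linear target).
#' @return An object of class `truth_bundle`: `flnr_true`, `flnr_expected`
#'   (linear part + offsets, before noise and flooring), `vcmax25_true`,
#'   `lnc`, the generating coefficients, `noise_sd`, `seed`, `n_floored`.
#' @export
make_truth <- function(grid, traits,
                       coefficients = global_flnr_equation()$coefficients,
                       intercept = global_flnr_equation()$intercept,
                       pft_offsets = default_pft_offsets(),
                       noise_sd = 2,
                       constants = physio_constants(),
                       seed = 1,
                       flnr_floor = 1) {
  missing_layers <- setdiff(names(coefficients), names(grid$layers))
  if (length(missing_layers) > 0L) {
    stop(
      "coefficient variables missing from grid layers: ",
      paste(missing_layers, collapse = ", ")
    )
  }
  dm <- dim(grid$mask)
  lin <- matrix(intercept, dm[1], dm[2])
  for (nm in names(coefficients)) {
    lin <- lin + coefficients[[nm]] * grid$layers[[nm]]
  }
  off <- matrix(0, dm[1], dm[2])
  on <- grid$mask & !is.na(grid$pft)
  off[on] <- ifelse(
    grid$pft[on] %in% names(pft_offsets), pft_offsets[grid$pft[on]], 0
  )
  expected <- lin + off
  expected[!grid$mask] <- NA

  set.seed(seed)
  noise <- matrix(stats::rnorm(prod(dm), sd = noise_sd), dm[1], dm[2])
  flnr <- expected + noise
  flnr[!grid$mask] <- NA

  n_floored <- 0L
  if (!is.null(flnr_floor)) {
    low <- which(!is.na(flnr) & flnr < flnr_floor)
    n_floored <- length(low)
    if (n_floored > 0L) {
      warning(sprintf(
        "%d cells below the fLNR floor of %g%%; floored", n_floored, flnr_floor
      ))
      flnr[low] <- flnr_floor
    }
  }

  lnc <- traits$lncm_mean / traits$sla_mean
  vcmax25 <- forward_vcmax25(flnr, lnc, constants)

  structure(
    list(
      flnr_true = flnr, flnr_expected = expected, vcmax25_true = vcmax25,
      lnc = lnc, coefficients = coefficients, intercept = intercept,
      pft_offsets = pft_offsets, noise_sd = noise_sd, seed = seed,
      n_floored = n_floored, flnr_floor = flnr_floor
    ),
    class = "truth_bundle"
  )
}

#' Sample clustered site observations of Vcmax at leaf temperature
#'
#' Sites are drawn uniformly within discs around randomly placed cluster
#' centres (emulating the spatial clustering of real trait campaigns, which
#' is what spatially buffered cross-validation exercises). Each site takes
#' its covariates from its grid cell; the observed Vcmax is the true
#' Vcmax25 projected to a random leaf temperature plus measurement noise.
#'
#' @param truth A `truth_bundle`.
#' @param grid The `covariate_grid` the truth was generated on.
#' @param n Number of sites (>= 1).
#' @param n_clusters Number of cluster centres (<= n).
#' @param cluster_radius Disc radius in degrees.
#' @param obs_noise_sd Measurement noise sd (umol m-2 s-1); non-positive
#'   draws of Vcmax are redrawn.
#' @param p_scatter Fraction of sites placed uniformly over the vegetated
#'   mask instead of around cluster centres (isolated sites, as in real
#'   trait compilations; such sites are the ones that survive a spatial
#'   exclusion buffer). Default 0: fully clustered.
#' @param tleaf_range Leaf-temperature interval (degrees C) sampled
#'   uniformly; a degenerate interval (e.g. `c(25, 25)`) gives a fixed
#'   temperature.
#' @param constants A [physio_constants()] object.
#' @param seed Integer seed.
#' @return A `data.frame` with one row per site: coordinates, grid indices,
#'   `vcmax_obs` (at `tleaf`), `tleaf`, `vcmax25_true` (diagnostic),
#'   `species_group`, `pft`, `koeppen` and every covariate layer.
#' @export
sample_observations <- function(truth, grid, n = 800, n_clusters = 40,
                                cluster_radius = 2, obs_noise_sd = 5,
                                tleaf_range = c(10, 35),
                                constants = physio_constants(), seed = 1,
                                p_scatter = 0) {
  if (n < 1) stop("n must be >= 1")
  if (n_clusters > n) stop("n_clusters must not exceed n")
  set.seed(seed)
  veg <- which(grid$mask, arr.ind = TRUE)
  centers <- veg[sample.int(nrow(veg), n_clusters, replace = n_clusters > nrow(veg)), , drop = FALSE]
  clat <- grid$lat[centers[, 1]]
  clon <- grid$lon[centers[, 2]]

  snap <- function(latv, lonv) {
    r <- which.min(abs(grid$lat - latv))
    c <- which.min(abs(grid$lon - lonv))
    c(r, c)
  }

  rows <- integer(n); cols <- integer(n)
  slat <- numeric(n); slon <- numeric(n)
  scattered <- stats::runif(n) < p_scatter
  for (i in seq_len(n)) {
    if (scattered[i]) {
      j <- sample.int(nrow(veg), 1L)
      rows[i] <- veg[j, 1]; cols[i] <- veg[j, 2]
      slat[i] <- grid$lat[rows[i]] + stats::runif(1, -0.25, 0.25)
      slon[i] <- grid$lon[cols[i]] + stats::runif(1, -0.25, 0.25)
      next
    }
    ok <- FALSE
    for (try in 1:50) {
      j <- sample.int(n_clusters, 1L)
      a <- stats::runif(1, 0, 2 * pi)
      r <- cluster_radius * sqrt(stats::runif(1))
      la <- clat[j] + r * sin(a)
      lo <- clon[j] + r * cos(a)
      rc <- snap(la, lo)
      if (grid$mask[rc[1], rc[2]]) {
        rows[i] <- rc[1]; cols[i] <- rc[2]; slat[i] <- la; slon[i] <- lo
        ok <- TRUE
        break
      }
    }
    if (!ok) { # fall back to the cluster centre cell
      rows[i] <- centers[j, 1]; cols[i] <- centers[j, 2]
      slat[i] <- clat[j]; slon[i] <- clon[j]
    }
  }

  cell <- cbind(rows, cols)
  tleaf <- stats::runif(n, tleaf_range[1], tleaf_range[2])
  v_true <- truth$vcmax25_true[cell]
  v_at_t <- project_from_25(v_true, tleaf, constants)
  vobs <- v_at_t + stats::rnorm(n, 0, obs_noise_sd)
  bad <- which(vobs <= 0)
  while (length(bad) > 0L) {
    vobs[bad] <- v_at_t[bad] + stats::rnorm(length(bad), 0, obs_noise_sd)
    bad <- which(vobs <= 0)
  }

  pft <- grid$pft[cell]
  species_group <- ifelse(
    pft %in% c("DBF", "MF"), "deciduous tree",
    ifelse(pft %in% c("EBF", "ENF"), "evergreen tree", "herbaceous")
  )

  obs <- data.frame(
    site = seq_len(n), lat = slat, lon = slon,
    cell_row = rows, cell_col = cols,
    vcmax_obs = vobs, tleaf = tleaf, vcmax25_true = v_true,
    species_group = species_group,
    pft = factor(pft, levels = pft_classes())
  )
  for (nm in names(grid$layers)) {
    v <- grid$layers[[nm]][cell]
    obs[[nm]] <- if (nm == "koeppen") factor(v, levels = koeppen_classes()) else v
  }
  obs
}

#' Add a Vcmax25 column to an observation table
#'
#' Applies the peaked Arrhenius standardization to `vcmax_obs` at `tleaf`.
#'
#' @param obs Observation table from [sample_observations()] (or a CSV
#'   read back with [read_observations_csv()]).
#' @param constants A [physio_constants()] object.
#' @return `obs` with a `vcmax25` column.
#' @export
standardize_observations <- function(obs, constants = physio_constants()) {
  obs$vcmax25 <- standardize_to_25(obs$vcmax_obs, obs$tleaf, constants)
  obs
}

#' Simulate the coefficient-recovery table
#'
#' Draws covariates independently and uniformly over the documented ranges
#' and evaluates the global empirical fLNR equation (optionally plus noise).
#' This is the input of the sensitivity-recovery experiment: a fit of the
#' equation's own functional form to a noiseless draw must return the
#' generating coefficients.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param coefficients,intercept Generating equation; defaults to
#'   [global_flnr_equation()].
#' @param ranges Per-variable uniform ranges (defaults to the matching
#'   entries of [default_layer_ranges()]).
#' @param noise_sd Gaussian noise sd (percent), default 0.
#' @return A `data.frame` with the covariates and an `flnr` column.
#' @export
simulate_recovery_table <- function(n = 2000, seed = 1,
                                    coefficients = global_flnr_equation()$coefficients,
                                    intercept = global_flnr_equation()$intercept,
                                    ranges = default_layer_ranges()[names(coefficients)],
                                    noise_sd = 0) {
  set.seed(seed)
  out <- data.frame(row.names = seq_len(n))
  for (nm in names(coefficients)) {
    rg <- ranges[[nm]]
    out[[nm]] <- stats::runif(n, rg[1], rg[2])
  }
  flnr <- rep(intercept, n)
  for (nm in names(coefficients)) flnr <- flnr + coefficients[[nm]] * out[[nm]]
  if (noise_sd > 0) flnr <- flnr + stats::rnorm(n, 0, noise_sd)
  out$flnr <- flnr
  out
}
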