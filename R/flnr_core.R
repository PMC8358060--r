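# Core of the fLNR derivation: the nitrogen-allocation identity
# Vcmax25 = alpha25 * LNC * fNR * fLNR, its inversion, LNC from trait maps,
# and bootstrap propagation of the four uncertainty sources (Vcmax25 map,
# LNC map, alpha25, fNR).

#' Forward nitrogen-allocation identity
#'
#' Vcmax25 implied by an fLNR field: `alpha25 * fNR * LNC * fLNR/100`.
#'
#' @param flnr_pct fLNR in percent (numeric scalar, vector or matrix).
#' @param lnc Area-based leaf nitrogen (g m-2), same shape.
#' @param constants A [physio_constants()] object.
#' @return Vcmax25 (umol m-2 s-1), same shape as `flnr_pct`.
#' @export
forward_vcmax25 <- function(flnr_pct, lnc, constants = physio_constants()) {
  constants$alpha25 * constants$fNR * lnc * flnr_pct / 100
}

#' Invert the nitrogen-allocation identity to fLNR
#'
#' `fLNR(%) = 100 * Vcmax25 / (alpha25 * fNR * LNC)`. Cells with
#' non-positive LNC are masked (NA) with a warning.
#'
#' @param vcmax25 Vcmax25 (umol m-2 s-1): numeric, matrix or
#'   `uncertain_map` (its mean field is used).
#' @param lnc Area-based leaf nitrogen (g m-2): numeric, matrix or
#'   `uncertain_map`.
#' @param constants A [physio_constants()] object.
#' @return fLNR in percent, same shape as the inputs.
#' @examples
#' invert_flnr(59.175, 1) # 20 percent
#' @export
invert_flnr <- function(vcmax25, lnc, constants = physio_constants()) {
  v <- field_of(vcmax25)
  l <- field_of(lnc)
  bad <- !is.na(l) & l <= 0
  if (any(bad)) {
    warning(sprintf("%d cells with non-positive LNC masked", sum(bad)))
    l[bad] <- NA
  }
  100 * v / (constants$alpha25 * constants$fNR * l)
}

# positive-truncated Gaussian draws by redrawing; returns list(x, n_redrawn)
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  n_redrawn <- 0L
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    n_redrawn <- n_redrawn + length(bad)
    x[bad] <- stats::rnorm(length(bad), mean[(bad - 1L) %% length(mean) + 1L],
                           sd[(bad - 1L) %% length(sd) + 1L])
    bad <- which(x <= 0)
    guard <- guard + 1L
  }
  if (length(bad) > 0L) x[bad] <- .Machine$double.eps
  list(x = x, n_redrawn = n_redrawn)
}

#' Area-based leaf nitrogen with bootstrapped uncertainty
#'
#' LNC = LNCm / SLA (mass-based nitrogen over specific leaf area; the unit
#' algebra (g/kg)/(m2/kg) gives g m-2). The per-cell sd comes from paired
#' positive-truncated Gaussian draws of (LNCm, SLA).
#'
#' @param traits A `trait_grid`.
#' @param n_boot Number of bootstrap draws (>= 2).
#' @param seed Integer seed.
#' @return An `uncertain_map` of LNC (g m-2); the attribute `n_redrawn`
#'   counts truncation redraws.
#' @export
compute_lnc <- function(traits, n_boot = 1000, seed = 1) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (any(traits$sla_mean[traits$mask] <= 0)) {
    stop("SLA must be positive on vegetated cells")
  }
  set.seed(seed)
  cells <- which(traits$mask)
  m <- length(cells)
  lncm_m <- traits$lncm_mean[cells]; lncm_s <- traits$lncm_sd[cells]
  sla_m <- traits$sla_mean[cells]; sla_s <- traits$sla_sd[cells]

  mean_field <- traits$lncm_mean / traits$sla_mean

  d1 <- rnorm_pos(m * n_boot, rep(lncm_m, n_boot), rep(lncm_s, n_boot))
  d2 <- rnorm_pos(m * n_boot, rep(sla_m, n_boot), rep(sla_s, n_boot))
  n_redrawn <- d1$n_redrawn + d2$n_redrawn
  if (n_redrawn > 0L) {
    message(sprintf("compute_lnc: %d non-positive trait draws redrawn", n_redrawn))
  }
  draws <- matrix(d1$x / d2$x, m, n_boot)
  sd_cells <- apply(draws, 1L, stats::sd)

  sd_field <- array(NA_real_, dim = dim(traits$lncm_mean))
  sd_field[cells] <- sd_cells
  out <- uncertain_map(mean_field, sd_field, traits$lat, traits$lon,
                       quantity = "lnc", units = "g m-2")
  attr(out, "n_redrawn") <- n_redrawn
  out
}

#' Bootstrap the fLNR map over its four uncertainty sources
#'
#' Per bootstrap iteration: alpha25 ~ Uniform over its literature range,
#' fNR ~ Uniform over its range (one draw per iteration, shared across
#' cells, since each constant is a single physical quantity), per-cell
#' Gaussian draws of the Vcmax25 map, and per-cell LNC draws via the trait
#' uncertainties. The total per-cell sd over draws is reported alongside
#' single-source sds in which three sources are held at their
#' defaults/means and one varies.
#'
#' @param vcmax25 An `uncertain_map` of Vcmax25.
#' @param traits A `trait_grid` (LNC uncertainty source).
#' @param constants A [physio_constants()] object carrying the ranges.
#' @param n_boot Number of bootstrap iterations (>= 2; 1000 in production).
#' @param seed Integer seed.
#' @param per_source If `TRUE` (default) also compute the four
#'   single-source sd fields.
#' @return An object of class `flnr_product`: `flnr` (an `uncertain_map`
#'   whose mean is the deterministic inversion at default constants and
#'   whose sd is the total bootstrap sd), `source_contributions` (named
#'   list of sd matrices for alpha25, fnr, lnc, vcmax25), `n_boot`, `seed`,
#'   `n_redrawn`.
#' @export
bootstrap_flnr <- function(vcmax25, traits, constants = physio_constants(),
                           n_boot = 1000, seed = 1, per_source = TRUE) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  set.seed(seed)
  cells <- which(!is.na(vcmax25$mean) & traits$mask)
  m <- length(cells)
  v_m <- vcmax25$mean[cells]; v_s <- vcmax25$sd[cells]
  lncm_m <- traits$lncm_mean[cells]; lncm_s <- traits$lncm_sd[cells]
  sla_m <- traits$sla_mean[cells]; sla_s <- traits$sla_sd[cells]
  lnc_m <- lncm_m / sla_m
  a_rng <- constants$alpha25_range
  f_rng <- constants$fNR_range
  n_redrawn <- 0L

  draw_v <- function() {
    d <- rnorm_pos(m * n_boot, rep(v_m, n_boot), rep(v_s, n_boot))
    n_redrawn <<- n_redrawn + d$n_redrawn
    matrix(d$x, m, n_boot)
  }
  draw_lnc <- function() {
    d1 <- rnorm_pos(m * n_boot, rep(lncm_m, n_boot), rep(lncm_s, n_boot))
    d2 <- rnorm_pos(m * n_boot, rep(sla_m, n_boot), rep(sla_s, n_boot))
    n_redrawn <<- n_redrawn + d1$n_redrawn + d2$n_redrawn
    matrix(d1$x / d2$x, m, n_boot)
  }
  sd_rows <- function(x) apply(x, 1L, stats::sd)
  to_field <- function(vals) {
    f <- array(NA_real_, dim = dim(vcmax25$mean))
    f[cells] <- vals
    f
  }

  # total: all four sources vary
  a <- stats::runif(n_boot, a_rng[1], a_rng[2])
  f <- stats::runif(n_boot, f_rng[1], f_rng[2])
  flnr_draws <- 100 * draw_v() / (draw_lnc() * rep(a * f, each = m))
  total_sd <- sd_rows(flnr_draws)

  sources <- NULL
  if (per_source) {
    # the held-fixed sources sit at their means (range midpoints for the
    # constants), so the single-source variances decompose the total
    a_mid <- mean(a_rng)
    f_mid <- mean(f_rng)
    a2 <- stats::runif(n_boot, a_rng[1], a_rng[2])
    f2 <- stats::runif(n_boot, f_rng[1], f_rng[2])
    sources <- list(
      alpha25 = to_field(sd_rows(
        outer(100 * v_m / (f_mid * lnc_m), 1 / a2)
      )),
      fnr = to_field(sd_rows(
        outer(100 * v_m / (a_mid * lnc_m), 1 / f2)
      )),
      lnc = to_field(sd_rows(
        100 * rep(v_m, n_boot) / (draw_lnc() * a_mid * f_mid)
      )),
      vcmax25 = to_field(sd_rows(draw_v() * (100 / (a_mid * f_mid * lnc_m))))
    )
  }

  mean_field <- invert_flnr(vcmax25$mean, traits$lncm_mean / traits$sla_mean,
                            constants)
  flnr_map <- uncertain_map(mean_field, to_field(total_sd),
                            vcmax25$lat, vcmax25$lon,
                            quantity = "flnr", units = "%")
  structure(
    list(flnr = flnr_map, source_contributions = sources,
         n_boot = n_boot, seed = seed, n_redrawn = n_redrawn),
    class = "flnr_product"
  )
}

#' @export
print.flnr_product <- function(x, ...) {
  cat(sprintf(
    "flnr_product: %d bootstrap draws; global mean %.2f%%, mean total sd %.2f%%\n",
    x$n_boot, mean(x$flnr$mean, na.rm = TRUE), mean(x$flnr$sd, na.rm = TRUE)
  ))
  if (!is.null(x$source_contributions)) {
    s <- vapply(x$source_contributions, function(m) mean(m, na.rm = TRUE),
                numeric(1))
    cat("  mean single-source sd (%):",
        paste(sprintf("%s=%.2f", names(s), s), collapse = ", "), "\n")
  }
  invisible(x)
}
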