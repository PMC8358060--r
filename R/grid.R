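# Gridded containers. Fields are stored as [lat, lon] matrices with the
# latitude index running south -> north and cell centers at half-degree
# offsets; masked-out (non-vegetated) cells carry NA in every layer.

#' Plant functional type classes
#' @return Character vector of the eight PFT codes.
#' @export
pft_classes <- function() {
  c("CRO", "DBF", "EBF", "ENF", "MF", "GRA", "SH", "WET")
}

#' Forest PFT classes
#' @return Character vector of the four forest PFT codes.
#' @export
forest_classes <- function() c("DBF", "EBF", "ENF", "MF")

koeppen_classes <- function() c("A", "B", "C", "D", "E")

# units for every gridded layer, used as NetCDF attributes and in tables
layer_units <- function() {
  c(
    chl = "ug cm-2", lnc = "g m-2", lpc = "g m-2", lma = "g m-2",
    tair = "degC", pp = "mm yr-1", par = "umol m-2 s-1", vpd = "kPa",
    swc = "m3 m-3", alpha_et = "1", koeppen = "class",
    soilC = "g m-3", soilN = "g m-3", cn = "1", ph = "1",
    sand = "%", silt = "%", bulkD = "g cm-3", cec = "cmol kg-1"
  )
}

new_covariate_grid <- function(lat, lon, mask, pft, layers, seed, smoothness,
                               ranges) {
  g <- structure(
    list(
      lat = lat, lon = lon, mask = mask, pft = pft, layers = layers,
      seed = seed, smoothness = smoothness, ranges = ranges
    ),
    class = "covariate_grid"
  )
  validate_covariate_grid(g)
  g
}

validate_covariate_grid <- function(g) {
  dm <- dim(g$mask)
  stopifnot(
    length(g$lat) == dm[1], length(g$lon) == dm[2],
    identical(dim(g$pft), dm)
  )
  for (nm in names(g$layers)) {
    if (!identical(dim(g$layers[[nm]]), dm)) {
      stop(sprintf("layer '%s' does not share the grid shape", nm))
    }
    if (any(!is.na(g$layers[[nm]][!g$mask]))) {
      stop(sprintf("layer '%s' has values on masked-out cells", nm))
    }
  }
  invisible(g)
}

#' @export
print.covariate_grid <- function(x, ...) {
  cat(sprintf(
    "covariate_grid: %d x %d cells (%d vegetated), %d layers + pft\n",
    nrow(x$mask), ncol(x$mask), sum(x$mask), length(x$layers)
  ))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Flatten the vegetated cells of a grid into a data frame
#'
#' One row per vegetated cell, with coordinates, grid indices, the PFT and
#' Koeppen factors (full level sets) and every numeric layer.
#'
#' @param grid A `covariate_grid`.
#' @return A `data.frame` with `sum(grid$mask)` rows.
#' @export
grid_table <- function(grid) {
  idx <- which(grid$mask, arr.ind = TRUE)
  out <- data.frame(
    cell = which(grid$mask),
    row = idx[, 1], col = idx[, 2],
    lat = grid$lat[idx[, 1]], lon = grid$lon[idx[, 2]]
  )
  out$pft <- factor(grid$pft[grid$mask], levels = pft_classes())
  for (nm in names(grid$layers)) {
    v <- grid$layers[[nm]][grid$mask]
    out[[nm]] <- if (nm == "koeppen") factor(v, levels = koeppen_classes()) else v
  }
  out
}

#' Gridded quantity with per-cell mean and standard deviation
#'
#' @param mean,sd Numeric `[lat, lon]` matrices; `sd` must be non-negative
#'   wherever `mean` is present.
#' @param lat,lon Cell-center coordinates (decimal degrees).
#' @param quantity Short name of the quantity (e.g. `"vcmax25"`).
#' @param units Units string.
#' @return An object of class `uncertain_map`.
#' @export
uncertain_map <- function(mean, sd, lat, lon, quantity, units) {
  stopifnot(identical(dim(mean), dim(sd)))
  has <- !is.na(mean)
  if (any(is.na(sd[has]))) stop("sd missing where mean is present")
  if (any(sd[has] < 0)) stop("negative sd in uncertain_map")
  structure(
    list(mean = mean, sd = sd, lat = lat, lon = lon,
         quantity = quantity, units = units),
    class = "uncertain_map"
  )
}

#' @export
print.uncertain_map <- function(x, ...) {
  cat(sprintf(
    "uncertain_map '%s' (%s): %d x %d, %d cells; mean %.3g +/- sd %.3g\n",
    x$quantity, x$units, nrow(x$mean), ncol(x$mean), sum(!is.na(x$mean)),
    mean(x$mean, na.rm = TRUE), mean(x$sd, na.rm = TRUE)
  ))
  invisible(x)
}

# pull the mean field out of an uncertain_map, or pass a matrix through
field_of <- function(x) {
  if (inherits(x, "uncertain_map")) x$mean else x
}
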