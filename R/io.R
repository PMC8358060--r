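# File formats: NetCDF for grids and maps (CF-style lat/lon coordinate
# variables, units attributes, one variable per layer), CSV for tables
# (numeric columns at full double precision), JSON for reports. The
# latitude convention (index south -> north, half-degree cell centers) is
# recorded as a global attribute.

nc_dims <- function(lat, lon) {
  list(
    lon = ncdf4::ncdim_def("lon", "degrees_east", lon),
    lat = ncdf4::ncdim_def("lat", "degrees_north", lat)
  )
}

# matrices are [lat, lon]; NetCDF vars are written [lon, lat]
nc_put <- function(nc, var, mat) ncdf4::ncvar_put(nc, var, t(mat))
nc_get <- function(nc, name) t(ncdf4::ncvar_get(nc, name))

grid_convention_note <-
  "cell centers at half-degree offsets; latitude index south to north"

check_units_attr <- function(nc, name) {
  a <- ncdf4::ncatt_get(nc, name, "units")
  if (!a$hasatt) {
    warning(sprintf("variable '%s' has no units attribute", name))
    ""
  } else {
    a$value
  }
}

#' Write a covariate grid to NetCDF
#'
#' One variable per layer with a units attribute; categorical layers (PFT,
#' Koeppen) stored as integer codes with `flag_values`/`flag_meanings`
#' attributes; the mask as an integer field.
#'
#' @param grid A `covariate_grid`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_covariate_grid_nc <- function(grid, path) {
  dims <- nc_dims(grid$lat, grid$lon)
  u <- layer_units()
  vars <- list(
    ncdf4::ncvar_def("mask", "1", dims, prec = "integer"),
    ncdf4::ncvar_def("pft", "class", dims, missval = -1L, prec = "integer")
  )
  for (nm in setdiff(names(grid$layers), "koeppen")) {
    vars[[length(vars) + 1L]] <-
      ncdf4::ncvar_def(nm, unname(u[nm]), dims, missval = NA_real_,
                       prec = "double")
  }
  vars[[length(vars) + 1L]] <-
    ncdf4::ncvar_def("koeppen", "class", dims, missval = -1L,
                     prec = "integer")
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  nc_put(nc, "mask", grid$mask * 1L)
  pcode <- matrix(match(grid$pft, pft_classes()), nrow(grid$pft))
  pcode[is.na(pcode)] <- -1L
  nc_put(nc, "pft", pcode)
  ncdf4::ncatt_put(nc, "pft", "flag_values",
                   paste(seq_along(pft_classes()), collapse = " "))
  ncdf4::ncatt_put(nc, "pft", "flag_meanings",
                   paste(pft_classes(), collapse = " "))
  kcode <- matrix(match(grid$layers$koeppen, koeppen_classes()),
                  nrow(grid$mask))
  kcode[is.na(kcode)] <- -1L
  nc_put(nc, "koeppen", kcode)
  ncdf4::ncatt_put(nc, "koeppen", "flag_meanings",
                   paste(koeppen_classes(), collapse = " "))
  for (nm in setdiff(names(grid$layers), "koeppen")) {
    nc_put(nc, nm, grid$layers[[nm]])
  }
  ncdf4::ncatt_put(nc, 0, "grid_convention", grid_convention_note)
  ncdf4::ncatt_put(nc, 0, "seed", grid$seed)
  ncdf4::ncatt_put(nc, 0, "smoothness", grid$smoothness)
  invisible(path)
}

#' Read a covariate grid from NetCDF
#'
#' @param path File written by [write_covariate_grid_nc()].
#' @return A `covariate_grid`.
#' @export
read_covariate_grid_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lat <- as.numeric(nc$dim$lat$vals)
  lon <- as.numeric(nc$dim$lon$vals)
  mask <- nc_get(nc, "mask") == 1
  pcode <- nc_get(nc, "pft")
  pft <- matrix(pft_classes()[ifelse(pcode %in% seq_along(pft_classes()),
                                     pcode, NA)], nrow(mask))
  layer_names <- setdiff(names(nc$var), c("mask", "pft", "koeppen"))
  layers <- list()
  for (nm in layer_names) {
    check_units_attr(nc, nm)
    f <- nc_get(nc, nm)
    f[!mask] <- NA
    layers[[nm]] <- f
  }
  kcode <- nc_get(nc, "koeppen")
  koe <- matrix(koeppen_classes()[ifelse(kcode %in% seq_along(koeppen_classes()),
                                         kcode, NA)], nrow(mask))
  layers$koeppen <- koe
  seed <- ncdf4::ncatt_get(nc, 0, "seed")
  smoothness <- ncdf4::ncatt_get(nc, 0, "smoothness")
  new_covariate_grid(
    lat, lon, mask, pft, layers,
    seed = if (seed$hasatt) seed$value else NA,
    smoothness = if (smoothness$hasatt) smoothness$value else NA,
    ranges = NULL
  )
}

#' Write an uncertain map to NetCDF
#'
#' Variables `<quantity>_mean` and `<quantity>_sd`, each with a units
#' attribute.
#'
#' @param map An `uncertain_map`.
#' @param path Output file.
#' @param extra Optional named list of additional fields (matrices) to
#'   write alongside (e.g. single-source sd layers).
#' @return `path`, invisibly.
#' @export
write_uncertain_map_nc <- function(map, path, extra = NULL) {
  dims <- nc_dims(map$lat, map$lon)
  nm_mean <- paste0(map$quantity, "_mean")
  nm_sd <- paste0(map$quantity, "_sd")
  vars <- list(
    ncdf4::ncvar_def(nm_mean, map$units, dims, missval = NA_real_,
                     prec = "double"),
    ncdf4::ncvar_def(nm_sd, map$units, dims, missval = NA_real_,
                     prec = "double")
  )
  for (nm in names(extra)) {
    vars[[length(vars) + 1L]] <-
      ncdf4::ncvar_def(nm, map$units, dims, missval = NA_real_,
                       prec = "double")
  }
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  nc_put(nc, nm_mean, map$mean)
  nc_put(nc, nm_sd, map$sd)
  for (nm in names(extra)) nc_put(nc, nm, extra[[nm]])
  ncdf4::ncatt_put(nc, 0, "grid_convention", grid_convention_note)
  invisible(path)
}

#' Read an uncertain map from NetCDF
#'
#' @param path File written by [write_uncertain_map_nc()].
#' @param quantity Quantity name (variable prefix).
#' @return An `uncertain_map`.
#' @export
read_uncertain_map_nc <- function(path, quantity) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  nm_mean <- paste0(quantity, "_mean")
  nm_sd <- paste0(quantity, "_sd")
  if (!nm_mean %in% names(nc$var)) {
    stop(sprintf("variable '%s' not found in %s", nm_mean, path))
  }
  units <- check_units_attr(nc, nm_mean)
  uncertain_map(
    nc_get(nc, nm_mean), nc_get(nc, nm_sd),
    as.numeric(nc$dim$lat$vals), as.numeric(nc$dim$lon$vals),
    quantity = quantity, units = units
  )
}

#' Write a trait grid to NetCDF
#' @param traits A `trait_grid`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trait_grid_nc <- function(traits, path) {
  dims <- nc_dims(traits$lat, traits$lon)
  defs <- list(
    lncm_mean = "mg g-1", lncm_sd = "mg g-1",
    sla_mean = "m2 kg-1", sla_sd = "m2 kg-1"
  )
  vars <- c(
    list(ncdf4::ncvar_def("mask", "1", dims, prec = "integer")),
    lapply(names(defs), function(nm) {
      ncdf4::ncvar_def(nm, defs[[nm]], dims, missval = NA_real_,
                       prec = "double")
    })
  )
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  nc_put(nc, "mask", traits$mask * 1L)
  for (nm in names(defs)) nc_put(nc, nm, traits[[nm]])
  ncdf4::ncatt_put(nc, 0, "grid_convention", grid_convention_note)
  invisible(path)
}

#' Read a trait grid from NetCDF
#' @param path File written by [write_trait_grid_nc()].
#' @return A `trait_grid`.
#' @export
read_trait_grid_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  mask <- nc_get(nc, "mask") == 1
  out <- list(
    lat = as.numeric(nc$dim$lat$vals), lon = as.numeric(nc$dim$lon$vals),
    mask = mask
  )
  for (nm in c("lncm_mean", "lncm_sd", "sla_mean", "sla_sd")) {
    check_units_attr(nc, nm)
    f <- nc_get(nc, nm)
    f[!mask] <- NA
    out[[nm]] <- f
  }
  structure(out, class = "trait_grid")
}

#' Write an observation table to CSV at full double precision
#'
#' Numeric columns are serialized with 17 significant digits so the
#' round-trip through [read_observations_csv()] is lossless.
#'
#' @param obs Observation data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_observations_csv <- function(obs, path) {
  out <- obs
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- sprintf("%.17g", out[[nm]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an observation table from CSV
#'
#' @param path CSV file.
#' @param required Columns that must be present; a missing one raises an
#'   error naming it.
#' @return Data frame with `pft`, `koeppen`, `species_group` as factors.
#' @export
read_observations_csv <- function(path,
                                  required = c("lat", "lon", "vcmax_obs",
                                               "tleaf")) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols) > 0L) {
    stop("required columns missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  if ("pft" %in% names(obs)) obs$pft <- factor(obs$pft, levels = pft_classes())
  if ("koeppen" %in% names(obs)) {
    obs$koeppen <- factor(obs$koeppen, levels = koeppen_classes())
  }
  if ("species_group" %in% names(obs)) {
    obs$species_group <- factor(obs$species_group)
  }
  obs
}

#' Write a run report (or any list of results) as JSON
#'
#' Deterministic, human-readable JSON: identical input yields byte-identical
#' files.
#'
#' @param report Named list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
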