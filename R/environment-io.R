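## netCDF reader/writer for EnvironmentStack.  CF-style rectilinear axes
## (lat / lon / month), variables d13c_pom, sst, biomass, depth,
## land_mask.  A small naming map accepts common axis aliases.

.NC_AXIS_ALIASES <- list(lat = c("lat", "latitude", "y"),
                         lon = c("lon", "longitude", "x"),
                         month = c("month", "time", "t"))
.NC_VARS <- c("d13c_pom", "sst", "biomass", "depth", "land_mask")

#' Write an EnvironmentStack to netCDF
#'
#' @param env an \code{\linkS4class{EnvironmentStack}}.
#' @param path output file path (.nc).
#' @return \code{path}, invisibly.
#' @export
saveEnvironment <- function(env, path) {
  stopifnot(is(env, "EnvironmentStack"))
  dimLon <- ncdf4::ncdim_def("lon", "degrees_east", env@lon)
  dimLat <- ncdf4::ncdim_def("lat", "degrees_north", env@lat)
  dimMon <- ncdf4::ncdim_def("month", "month_of_year", 1:12)
  mv <- -9.99e33
  v3 <- function(nm, units) ncdf4::ncvar_def(nm, units, list(dimLon, dimLat, dimMon), mv, prec = "double")
  v2 <- function(nm, units) ncdf4::ncvar_def(nm, units, list(dimLon, dimLat), mv, prec = "double")
  vars <- list(d13c_pom = v3("d13c_pom", "permil_VPDB"),
               sst = v3("sst", "degC"),
               biomass = v3("biomass", "mmol N m-3"),
               depth = v2("depth", "m"),
               land_mask = v2("land_mask", "1"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  ## internal [lat, lon, month] -> file [lon, lat, month]
  put3 <- function(nm, a) ncdf4::ncvar_put(nc, vars[[nm]], aperm(a, c(2, 1, 3)))
  put3("d13c_pom", env@d13cPom); put3("sst", env@sst); put3("biomass", env@biomass)
  ncdf4::ncvar_put(nc, vars$depth, t(env@depth))
  ncdf4::ncvar_put(nc, vars$land_mask, t(env@landMask * 1))
  invisible(path)
}

.ncFindDim <- function(nc, key) {
  nms <- names(nc$dim)
  hit <- nms[tolower(nms) %in% .NC_AXIS_ALIASES[[key]]]
  if (!length(hit)) stop(sprintf("format error: file lacks a '%s' axis", key))
  nc$dim[[hit[1]]]
}

#' Read an EnvironmentStack from netCDF
#'
#' Expects a rectilinear grid with 12 monthly climatology slices and the
#' variables \code{d13c_pom}, \code{sst}, \code{biomass}, \code{depth}
#' and \code{land_mask}.  Axes named \code{latitude}/\code{longitude}/
#' \code{time} are also accepted; latitude stored north-to-south is
#' flipped on read.
#'
#' @param path a netCDF file written by \code{\link{saveEnvironment}} or
#'   following the same layout.
#' @return an \code{\linkS4class{EnvironmentStack}}.
#' @export
loadEnvironment <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  missing <- setdiff(.NC_VARS, names(nc$var))
  if (length(missing))
    stop("format error: missing variable(s): ", paste(missing, collapse = ", "))
  dLat <- .ncFindDim(nc, "lat"); dLon <- .ncFindDim(nc, "lon")
  dMon <- .ncFindDim(nc, "month")
  if (dMon$len != 12)
    stop(sprintf("format error: expected 12 monthly slices, found %d", dMon$len))
  lat <- as.numeric(dLat$vals); lon <- as.numeric(dLon$vals)
  flip <- FALSE
  if (all(diff(lat) < 0)) { lat <- rev(lat); flip <- TRUE }
  if (any(diff(lat) <= 0) || any(diff(lon) <= 0))
    stop("format error: non-rectilinear or non-monotone axes")

  get3 <- function(nm) {
    a <- aperm(ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE), c(2, 1, 3))
    if (flip) a <- a[rev(seq_along(lat)), , , drop = FALSE]
    a
  }
  get2 <- function(nm) {
    m <- t(ncdf4::ncvar_get(nc, nm, collapse_degen = TRUE))
    if (flip) m <- m[rev(seq_along(lat)), , drop = FALSE]
    m
  }
  land <- get2("land_mask")
  land[is.na(land)] <- 1
  environmentStack(lat, lon, get3("d13c_pom"), get3("sst"), get3("biomass"),
                   get2("depth"), landMask = land > 0.5,
                   resolutionDeg = diff(lat)[1],
                   config = list(source = path))
}
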