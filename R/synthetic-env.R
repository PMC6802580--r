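#' Construct an EnvironmentStack from field arrays
#'
#' Low-level constructor; most users will call
#' \code{\link{generateSyntheticEnvironment}} or \code{\link{loadEnvironment}}.
#' Cells flagged in \code{landMask} are set to \code{NA} in every field.
#'
#' @param lat,lon cell-centre coordinates, strictly increasing, degrees.
#' @param d13cPom,sst,biomass arrays \code{[lat, lon, 12]}.
#' @param depth matrix \code{[lat, lon]}, metres positive downward.
#' @param landMask logical matrix \code{[lat, lon]}; defaults to all water.
#' @param resolutionDeg grid spacing; defaults to the latitude step.
#' @param config provenance list.
#' @return an \code{\linkS4class{EnvironmentStack}}.
#' @export
environmentStack <- function(lat, lon, d13cPom, sst, biomass, depth,
                             landMask = NULL, resolutionDeg = NULL,
                             config = list()) {
  if (is.null(landMask))
    landMask <- matrix(FALSE, length(lat), length(lon))
  if (is.null(resolutionDeg)) resolutionDeg <- diff(lat)[1]
  na3 <- function(a) { for (m in 1:12) { s <- a[, , m]; s[landMask] <- NA; a[, , m] <- s }; a }
  depth[landMask] <- NA
  new("EnvironmentStack", lat = as.numeric(lat), lon = as.numeric(lon),
      resolutionDeg = resolutionDeg, d13cPom = na3(d13cPom), sst = na3(sst),
      biomass = na3(biomass), depth = depth, landMask = landMask,
      config = config)
}

#' Configuration for the synthetic North Atlantic environment
#'
#' Parametric emulation of the large-scale structure of a monthly
#' isotope-enabled ocean climatology: the annual-mean POM d13C baseline
#' declines from subtropical to subpolar latitudes, the seasonal d13C
#' cycle is bloom-skewed (a steep 2-3 month rise to a peak followed by a
#' slow decline to a late-winter minimum) and grows in amplitude with
#' latitude, biomass co-peaks with the bloom, SST declines poleward and
#' cycles seasonally, and bathymetry is a deep basin with shallow shelf
#' bands along the two meridional coasts.  The bloom peak shifts from
#' late winter in the subtropics (weak deep-mixing bloom) to early
#' summer at high latitudes, the classic poleward bloom progression.
#'
#' All defaults are synthetic choices, not values taken from any ocean
#' model output; every constant is exposed here so the emulated
#' structure can be tuned.
#'
#' @param latRange,lonRange domain bounds, degrees (default North
#'   Atlantic basin, 0-80 N, 80 W-20 E).
#' @param resolutionDeg grid spacing (default 1 degree).
#' @param cBase subtropical annual-mean d13C, per mil (default -20.5).
#' @param cGrad total equator-to-pole decrease in annual-mean d13C,
#'   per mil (default 3.5).
#' @param aMax seasonal half-amplitude of d13C at the northern edge of
#'   the latitude ramp, per mil (default 1.5).
#' @param aSub seasonal half-amplitude in the subtropics, per mil
#'   (default 0.2; set to 0 for a perfectly flat subtropical band).
#' @param phiS,phiN latitudes bounding the gradient ramp, degrees
#'   (defaults 20 and 70): the ramp function is
#'   \code{L(phi) = clamp((phi - phiS) / (phiN - phiS), 0, 1)}.
#' @param bloomPeakMonth month of the bloom d13C maximum at high
#'   latitude (default 6, June).
#' @param subPeakMonth month of the weak subtropical maximum
#'   (default 2, February).
#' @param sstEquator,sstGradient,sstAmp,sstPeakMonth SST surface:
#'   \code{sstEquator - sstGradient * lat + sstAmp * cos(...)} peaking
#'   in \code{sstPeakMonth} (defaults 27 C, 0.28 C/deg, 2.5 C, August).
#' @param bioBase,bioBloom biomass floor and high-latitude bloom
#'   amplitude, mmol N m-3 (defaults 0.4 and 3).
#' @param basinDepth,shelfDepth,shelfWidthDeg,landWidthDeg bathymetry:
#'   open-basin depth, shallowest shelf depth, width of the shelf ramp
#'   and of the land strip along each meridional coast, m / degrees.
#' @param noiseSd standard deviation of optional Gaussian noise added
#'   to the d13C field (default 0, deterministic).
#' @param seed RNG seed used only when \code{noiseSd > 0}.
#' @return a validated configuration list of class
#'   \code{"SyntheticEnvConfig"}.
#' @export
syntheticEnvConfig <- function(latRange = c(0, 80), lonRange = c(-80, 20),
                               resolutionDeg = 1, cBase = -20.5, cGrad = 3.5,
                               aMax = 1.5, aSub = 0.2, phiS = 20, phiN = 70,
                               bloomPeakMonth = 6L, subPeakMonth = 2L,
                               sstEquator = 27, sstGradient = 0.28,
                               sstAmp = 2.5, sstPeakMonth = 8L,
                               bioBase = 0.4, bioBloom = 3,
                               basinDepth = 4000, shelfDepth = 80,
                               shelfWidthDeg = 3, landWidthDeg = 2,
                               noiseSd = 0, seed = NULL) {
  if (diff(latRange) <= 0 || diff(lonRange) <= 0)
    stop("configuration error: degenerate lat/lon range")
  if (phiS >= phiN) stop("configuration error: phiS must be < phiN")
  if (aMax < 0 || aSub < 0 || cGrad < 0 || sstAmp < 0)
    stop("configuration error: amplitudes and gradients must be non-negative")
  if (bioBase < 0 || bioBloom < 0) stop("configuration error: negative biomass")
  if (!bloomPeakMonth %in% 1:12 || !subPeakMonth %in% 1:12 || !sstPeakMonth %in% 1:12)
    stop("configuration error: peak months must be in 1..12")
  cfg <- as.list(environment())
  class(cfg) <- "SyntheticEnvConfig"
  cfg
}

## Zero-mean bloom-skewed annual cycle with unit half-amplitude:
## slow linear decline over the 9 months after the peak down to the
## late-winter minimum, then a steep 3-month rise back to the peak.
## Exactly zero mean and exact +1/-1 extrema at integer peak months.
.annualCycle <- function(peakMonth) {
  d <- (seq_len(12) - peakMonth) %% 12
  ifelse(d <= 9, 1 - 2 * d / 9, ifelse(d == 10, -0.35, 0.35))
}

.latRamp <- function(phi, phiS, phiN) pmin(pmax((phi - phiS) / (phiN - phiS), 0), 1)

#' Generate the synthetic monthly environment
#'
#' Builds an \code{\linkS4class{EnvironmentStack}} from a
#' \code{\link{syntheticEnvConfig}}.  With the latitude ramp
#' \code{L(phi)}, the carbon baseline is
#' \deqn{\delta^{13}C(\phi, m) = cBase - cGrad \cdot L(\phi) +
#'   a(\phi)\, B_{p(\phi)}(m)}
#' where \code{a(phi) = aSub + (aMax - aSub) L(phi)} is the seasonal
#' half-amplitude and \code{B_p} the zero-mean bloom cycle peaking in
#' month \code{p(phi)}, shifting from \code{subPeakMonth} to
#' \code{bloomPeakMonth} along the ramp.  Biomass co-peaks with the
#' local bloom at high latitude; SST declines poleward with a seasonal
#' cycle warmest in late summer; depth is a deep basin with shelf bands
#' along the two coasts.
#'
#' @param config a \code{\link{syntheticEnvConfig}}.
#' @return an \code{\linkS4class{EnvironmentStack}}.
#' @examples
#' env <- generateSyntheticEnvironment()
#' sampleField(env, 65, -20, month = 6)
#' @export
generateSyntheticEnvironment <- function(config = syntheticEnvConfig()) {
  stopifnot(inherits(config, "SyntheticEnvConfig"))
  c2 <- config
  res <- c2$resolutionDeg
  lat <- seq(c2$latRange[1], c2$latRange[2], by = res)
  lon <- seq(c2$lonRange[1], c2$lonRange[2], by = res)
  nlat <- length(lat); nlon <- length(lon)
  if (nlat < 2 || nlon < 2) stop("configuration error: degenerate grid")

  L <- .latRamp(lat, c2$phiS, c2$phiN)
  amp <- c2$aSub + (c2$aMax - c2$aSub) * L
  peak <- round(c2$subPeakMonth + (c2$bloomPeakMonth - c2$subPeakMonth) * L)
  cycles <- vapply(1:12, .annualCycle, numeric(12))   # [month, peak]

  d13c <- array(NA_real_, c(nlat, nlon, 12))
  sst <- array(NA_real_, c(nlat, nlon, 12))
  bio <- array(NA_real_, c(nlat, nlon, 12))
  for (m in 1:12) {
    B <- cycles[m, peak]                              # per-latitude cycle value
    d13c[, , m] <- (c2$cBase - c2$cGrad * L + amp * B)
    sst[, , m] <- (c2$sstEquator - c2$sstGradient * lat +
                   c2$sstAmp * cos(2 * pi * (m - c2$sstPeakMonth) / 12))
    bio[, , m] <- (c2$bioBase + c2$bioBloom * L * (B + 1) / 2)
  }
  if (c2$noiseSd > 0) {
    if (!is.null(c2$seed)) set.seed(c2$seed)
    d13c <- d13c + rnorm(length(d13c), 0, c2$noiseSd)
  }

  ## meridional coasts: land strip + shelf ramp at each longitude edge
  distEdge <- pmin(lon - (c2$lonRange[1] + c2$landWidthDeg),
                   (c2$lonRange[2] - c2$landWidthDeg) - lon)
  landRow <- distEdge < 0
  depthRow <- ifelse(landRow, NA,
                     c2$shelfDepth + (c2$basinDepth - c2$shelfDepth) *
                       pmin(distEdge / c2$shelfWidthDeg, 1))
  depth <- matrix(rep(depthRow, each = nlat), nlat, nlon)
  landMask <- matrix(rep(landRow, each = nlat), nlat, nlon)
  if (all(landMask)) stop("configuration error: domain is all land")

  environmentStack(lat, lon, d13c, sst, bio, depth, landMask, res,
                   config = unclass(c2))
}

## Nearest-cell index helpers (vectorised); NA when outside the grid
## (cells extend half a resolution beyond the outermost centres).
.gridIndex <- function(x, centres, res) {
  i <- round((x - centres[1]) / res) + 1
  i[x < centres[1] - res / 2 | x > centres[length(centres)] + res / 2] <- NA
  as.integer(i)
}

#' Sample an environmental field at a point
#'
#' Nearest-cell (piecewise constant) lookup by default, matching
#' extraction of values from one-degree cells; bilinear interpolation is
#' available behind \code{method = "bilinear"}.  Points on land return
#' \code{NA}; points outside the grid raise an error.
#'
#' @param env an \code{\linkS4class{EnvironmentStack}}.
#' @param lat,lon point coordinates, degrees.
#' @param month month 1-12 (ignored for \code{depth}).
#' @param field field name (default \code{"d13c_pom"}).
#' @param method \code{"nearest"} or \code{"bilinear"}.
#' @return the field value, or \code{NA} on a land cell.
#' @export
sampleField <- function(env, lat, lon, month = 1L,
                        field = c("d13c_pom", "sst", "biomass", "depth"),
                        method = c("nearest", "bilinear")) {
  stopifnot(is(env, "EnvironmentStack"))
  field <- match.arg(field)
  method <- match.arg(method)
  if (!month %in% 1:12) stop("month must be in 1..12")
  i <- .gridIndex(lat, env@lat, env@resolutionDeg)
  j <- .gridIndex(lon, env@lon, env@resolutionDeg)
  if (is.na(i) || is.na(j))
    stop(sprintf("coordinates (%.2f, %.2f) outside grid bounds", lat, lon))
  a <- envField(env, field)
  if (method == "nearest") {
    if (env@landMask[i, j]) return(NA_real_)
    return(if (field == "depth") a[i, j] else a[i, j, month])
  }
  ## bilinear over the 2x2 cell-centre neighbourhood
  i0 <- max(1, min(length(env@lat) - 1, findInterval(lat, env@lat)))
  j0 <- max(1, min(length(env@lon) - 1, findInterval(lon, env@lon)))
  fx <- (lat - env@lat[i0]) / (env@lat[i0 + 1] - env@lat[i0])
  fy <- (lon - env@lon[j0]) / (env@lon[j0 + 1] - env@lon[j0])
  fx <- min(max(fx, 0), 1); fy <- min(max(fy, 0), 1)
  g <- function(ii, jj) if (field == "depth") a[ii, jj] else a[ii, jj, month]
  v <- c(g(i0, j0), g(i0 + 1, j0), g(i0, j0 + 1), g(i0 + 1, j0 + 1))
  w <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  if (any(is.na(v))) return(NA_real_)
  sum(v * w)
}
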