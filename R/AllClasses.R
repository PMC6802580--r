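#' @import methods
#' @importFrom stats lm coef cor cov var sd median quantile rnorm runif qnorm pnorm plogis fft resid approx
#' @importFrom utils read.csv write.csv head packageVersion
#' @importFrom tools md5sum
NULL

setOldClass("Date")

## Behavioural states recognised by the movement model
.STATES <- c("MIGRATE_NORTH", "MIGRATE_SOUTH", "FORAGE")

#' EnvironmentStack: gridded monthly climatological ocean environment
#'
#' Holds the four environmental fields a simulated whale moves through:
#' phytoplankton (POM) carbon isotope baseline, sea-surface temperature,
#' plankton biomass and water depth, on one shared regular
#' latitude/longitude lattice with a 12-month climatological time axis
#' (no interannual variation).  Monthly fields are arrays indexed
#' \code{[lat, lon, month]}; depth and the land mask are time-invariant
#' matrices \code{[lat, lon]}.  Cells on land carry \code{NA} in every
#' field and \code{TRUE} in \code{landMask}.
#'
#' @slot lat,lon numeric vectors of cell-centre coordinates, strictly
#'   increasing, degrees north / east.
#' @slot resolutionDeg grid spacing in degrees.
#' @slot d13cPom array, per-mil VPDB.
#' @slot sst array, degrees Celsius.
#' @slot biomass array, mmol N m-3 (combined diatom + non-diatom).
#' @slot depth matrix, metres, positive downward.
#' @slot landMask logical matrix.
#' @slot config list; provenance (generator configuration or source file).
#' @export
setClass("EnvironmentStack",
  representation(lat = "numeric", lon = "numeric", resolutionDeg = "numeric",
                 d13cPom = "array", sst = "array", biomass = "array",
                 depth = "matrix", landMask = "matrix", config = "list"))

setValidity("EnvironmentStack", function(object) {
  msg <- character()
  nlat <- length(object@lat); nlon <- length(object@lon)
  if (nlat < 2 || nlon < 2) msg <- c(msg, "grid must have at least 2 cells per axis")
  if (any(diff(object@lat) <= 0)) msg <- c(msg, "latitude must be strictly increasing")
  if (any(diff(object@lon) <= 0)) msg <- c(msg, "longitude must be strictly increasing")
  want <- c(nlat, nlon, 12L)
  for (f in c("d13cPom", "sst", "biomass")) {
    d <- dim(slot(object, f))
    if (length(d) != 3 || any(d != want))
      msg <- c(msg, sprintf("field '%s' must have dim [lat, lon, 12]", f))
  }
  if (!all(dim(object@depth) == want[1:2])) msg <- c(msg, "depth must be [lat, lon]")
  if (!all(dim(object@landMask) == want[1:2])) msg <- c(msg, "landMask must be [lat, lon]")
  if (!is.logical(object@landMask)) msg <- c(msg, "landMask must be logical")
  water <- !object@landMask
  if (any(water)) {
    for (f in c("d13cPom", "sst", "biomass")) {
      v <- slot(object, f)
      ok <- vapply(1:12, function(m) all(is.finite(v[, , m][water])), logical(1))
      if (!all(ok)) msg <- c(msg, sprintf("non-finite '%s' values on water cells", f))
    }
    if (any(object@depth[water] < 0, na.rm = TRUE)) msg <- c(msg, "negative depth on water")
    bio <- object@biomass
    if (any(vapply(1:12, function(m) any(bio[, , m][water] < 0), logical(1))))
      msg <- c(msg, "negative biomass on water")
  }
  if (length(msg)) msg else TRUE
})

#' Track: daily positions and behavioural states of one simulated whale
#'
#' @slot data data.frame with columns \code{date} (Date), \code{lat},
#'   \code{lon} (degrees) and \code{state} (behavioural state string),
#'   one row per day including the start day.
#' @slot status \code{"COMPLETE"} or \code{"FAILED_TRAPPED"}.
#' @slot failedDay day index at which the whale was declared trapped
#'   (\code{NA} for complete tracks).
#' @slot seed integer seed used (\code{NA} if simulated from an ambient
#'   RNG stream).
#' @slot config list; schedule and movement configuration used.
#' @export
setClass("Track",
  representation(data = "data.frame", status = "character",
                 failedDay = "integer", seed = "integer", config = "list"))

setValidity("Track", function(object) {
  msg <- character()
  if (!object@status %in% c("COMPLETE", "FAILED_TRAPPED"))
    msg <- c(msg, "status must be COMPLETE or FAILED_TRAPPED")
  d <- object@data
  if (!all(c("date", "lat", "lon", "state") %in% names(d)))
    msg <- c(msg, "track data needs columns date, lat, lon, state")
  else {
    if (nrow(d) > 1 && !all(diff(as.integer(d$date)) == 1L))
      msg <- c(msg, "dates must be strictly consecutive days")
    if (!all(d$state %in% .STATES)) msg <- c(msg, "unknown behavioural state")
  }
  if (object@status == "FAILED_TRAPPED" && is.na(object@failedDay))
    msg <- c(msg, "failed track must record failedDay")
  if (length(msg)) msg else TRUE
})

#' BaleenProfile: ordered isotope samples along a baleen plate
#'
#' Samples are ordered from the gingival (gum, most recent) end towards
#' the distal (oldest) end, at uniform spacing.  Nitrogen isotope values
#' and elemental composition are optional; calendar dates are attached
#' by \code{\link{assignDates}} after time calibration.
#'
#' @slot distanceCm distance of each sample from the gingival end, cm,
#'   strictly increasing and uniformly spaced.
#' @slot d13c per-mil VPDB.
#' @slot d15n per-mil AIR (optional: length 0 or n).
#' @slot pctC,pctN weight percent carbon / nitrogen (optional).
#' @slot dates per-sample calendar dates (optional; strictly decreasing
#'   with distance: deeper into the plate is older).
#' @slot spacingCm sample spacing, cm.
#' @export
setClass("BaleenProfile",
  representation(distanceCm = "numeric", d13c = "numeric", d15n = "numeric",
                 pctC = "numeric", pctN = "numeric", dates = "Date",
                 spacingCm = "numeric"))

setValidity("BaleenProfile", function(object) {
  msg <- character()
  n <- length(object@distanceCm)
  if (n < 2) msg <- c(msg, "a profile needs at least 2 samples")
  dd <- diff(object@distanceCm)
  if (any(dd <= 0)) msg <- c(msg, "distances must be strictly increasing")
  if (n >= 2 && max(abs(dd - object@spacingCm)) > 1e-6 * max(1, object@spacingCm))
    msg <- c(msg, "samples must be uniformly spaced")
  if (length(object@d13c) != n) msg <- c(msg, "d13c length must match distances")
  for (f in c("d15n", "pctC", "pctN", "dates")) {
    len <- length(slot(object, f))
    if (!len %in% c(0L, n)) msg <- c(msg, sprintf("'%s' must have length 0 or n", f))
  }
  if (length(object@dates) == n && any(diff(as.integer(object@dates)) >= 0))
    msg <- c(msg, "dates must be strictly decreasing with distance")
  if (length(msg)) msg else TRUE
})

#' DietSignal: daily diet-integrated carbon isotope values along a track
#'
#' The trailing biomass-weighted average of the POM baseline sampled at
#' the whale's daily positions, shifted by a constant trophic offset.
#'
#' @slot date daily dates.
#' @slot d13c per-mil values after diet integration.
#' @slot windowMonths number of monthly climatology values averaged.
#' @slot offset constant trophic offset, per mil.
#' @export
setClass("DietSignal",
  representation(date = "Date", d13c = "numeric",
                 windowMonths = "integer", offset = "numeric"))

#' CalibrationResult: time calibration of a baleen profile
#'
#' @slot periodCm dominant periodicity from the periodogram, cm.
#' @slot periodResolutionCm frequency-grid resolution at the peak, cm.
#' @slot pValue Fisher g-test p-value for the periodogram peak.
#' @slot peakSpacingCm mean distance between successive detected peaks.
#' @slot growthRate baleen growth rate, cm per year (one cycle = one year).
#' @slot anchorDate assumed date of the gingival-most sample.
#' @slot sampleDates per-sample calendar dates.
#' @slot spacingCm sample spacing of the calibrated profile.
#' @export
setClass("CalibrationResult",
  representation(periodCm = "numeric", periodResolutionCm = "numeric",
                 pValue = "numeric", peakSpacingCm = "numeric",
                 growthRate = "numeric", anchorDate = "Date",
                 sampleDates = "Date", spacingCm = "numeric"))

setValidity("CalibrationResult", function(object) {
  msg <- character()
  if (object@growthRate <= 0) msg <- c(msg, "growth rate must be positive")
  if (object@periodCm <= 2 * object@spacingCm)
    msg <- c(msg, "period must exceed twice the sample spacing (Nyquist)")
  if (length(object@sampleDates) > 1 && any(diff(as.integer(object@sampleDates)) >= 0))
    msg <- c(msg, "sample dates must be strictly decreasing with distance")
  if (length(msg)) msg else TRUE
})

#' PhaseSegmentation: behavioural phases along a baleen profile
#'
#' Contiguous, non-overlapping intervals \code{[startCm, endCm)} covering
#' the profile, each with summary statistics of the d13C record.
#'
#' @slot phases data.frame with columns startCm, endCm, label, n,
#'   meanD13c, sdD13c, amplitude.
#' @export
setClass("PhaseSegmentation", representation(phases = "data.frame"))

#' Hypothesis: a movement scenario to simulate and score
#'
#' @slot name scenario name.
#' @slot kind \code{"MIGRATORY"} or \code{"RESIDENT"}.
#' @slot schedule behaviour schedule (see \code{\link{behaviourSchedule}}).
#' @slot movement movement configuration (see \code{\link{movementConfig}}).
#' @slot startRegion numeric \code{c(latMin, latMax, lonMin, lonMax)} box
#'   from which start positions are drawn.
#' @slot nYears simulated duration in years.
#' @slot region optional confinement box for resident scenarios
#'   (length 0 for unconstrained movement).
#' @export
setClass("Hypothesis",
  representation(name = "character", kind = "character", schedule = "list",
                 movement = "list", startRegion = "numeric",
                 nYears = "numeric", region = "numeric"))

setValidity("Hypothesis", function(object) {
  msg <- character()
  if (!object@kind %in% c("MIGRATORY", "RESIDENT")) msg <- c(msg, "unknown kind")
  if (length(object@startRegion) != 4) msg <- c(msg, "startRegion must be c(latMin, latMax, lonMin, lonMax)")
  if (!length(object@region) %in% c(0L, 4L)) msg <- c(msg, "region must be empty or a 4-element box")
  if (object@nYears <= 0) msg <- c(msg, "nYears must be positive")
  if (object@kind == "RESIDENT") {
    if (!all(object@schedule$states == "FORAGE"))
      msg <- c(msg, "resident hypotheses must forage in all 12 months")
    if (length(object@region) != 4)
      msg <- c(msg, "resident hypotheses need a named region")
  }
  if (length(msg)) msg else TRUE
})

#' EnsembleSummary: scored ensemble of simulated movement runs
#'
#' @slot hypothesisName,kind identity of the scenario run.
#' @slot nRequested,nCompleted,nFailed run counts; failed runs are
#'   whales trapped in coastal features before the end of the record.
#' @slot runs data.frame with one row per requested run: runId, seed,
#'   status, r2, slope, intercept, degenerate.
#' @slot topFraction fraction of completed runs retained as best fits.
#' @slot top ranked subset of \code{runs} (r-squared descending).
#' @slot topTracks list of daily-track data.frames for the top subset.
#' @slot occupancy per-month daily locations of the top subset
#'   (month, lat, lon).
#' @export
setClass("EnsembleSummary",
  representation(hypothesisName = "character", kind = "character",
                 nRequested = "integer", nCompleted = "integer",
                 nFailed = "integer", runs = "data.frame",
                 topFraction = "numeric", top = "data.frame",
                 topTracks = "list", occupancy = "data.frame"))

setValidity("EnsembleSummary", function(object) {
  msg <- character()
  if (object@nCompleted + object@nFailed != object@nRequested)
    msg <- c(msg, "completed + failed must equal requested")
  if (any(!is.na(object@runs$r2) & (object@runs$r2 < 0 | object@runs$r2 > 1)))
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (any(object@runs$status == "FAILED_TRAPPED" & !is.na(object@runs$r2)))
    msg <- c(msg, "failed runs must not carry an r2")
  if (length(msg)) msg else TRUE
})
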