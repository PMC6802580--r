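## Accessors and show methods.  Slot access from user code should go
## through these rather than @.

#' @rdname EnvironmentStack-class
#' @param object,x an object.
#' @export
setGeneric("envLat", function(x) standardGeneric("envLat"))
#' @rdname EnvironmentStack-class
#' @export
setGeneric("envLon", function(x) standardGeneric("envLon"))
#' @rdname EnvironmentStack-class
#' @param name one of \code{"d13c_pom"}, \code{"sst"}, \code{"biomass"},
#'   \code{"depth"}, \code{"land_mask"}.
#' @export
setGeneric("envField", function(x, name) standardGeneric("envField"))

#' @rdname EnvironmentStack-class
#' @export
setMethod("envLat", "EnvironmentStack", function(x) x@lat)
#' @rdname EnvironmentStack-class
#' @export
setMethod("envLon", "EnvironmentStack", function(x) x@lon)
#' @rdname EnvironmentStack-class
#' @export
setMethod("envField", "EnvironmentStack", function(x, name) {
  switch(match.arg(name, c("d13c_pom", "sst", "biomass", "depth", "land_mask")),
         d13c_pom = x@d13cPom, sst = x@sst, biomass = x@biomass,
         depth = x@depth, land_mask = x@landMask)
})

setMethod("show", "EnvironmentStack", function(object) {
  cat(sprintf("EnvironmentStack: %d x %d cells at %.3g deg, 12-month climatology\n",
              length(object@lat), length(object@lon), object@resolutionDeg))
  cat(sprintf("  lat %.1f..%.1f  lon %.1f..%.1f  water fraction %.2f\n",
              min(object@lat), max(object@lat), min(object@lon), max(object@lon),
              mean(!object@landMask)))
  r <- range(object@d13cPom, na.rm = TRUE)
  cat(sprintf("  d13C-POM %.2f..%.2f permil\n", r[1], r[2]))
})

#' @rdname Track-class
#' @param x a Track.
#' @export
setGeneric("trackData", function(x) standardGeneric("trackData"))
#' @rdname Track-class
#' @export
setGeneric("trackStatus", function(x) standardGeneric("trackStatus"))
#' @rdname Track-class
#' @export
setMethod("trackData", "Track", function(x) x@data)
#' @rdname Track-class
#' @export
setMethod("trackStatus", "Track", function(x) x@status)

setMethod("show", "Track", function(object) {
  d <- object@data
  cat(sprintf("Track: %d daily positions, %s", nrow(d), object@status))
  if (object@status == "FAILED_TRAPPED") cat(sprintf(" at day %d", object@failedDay))
  cat(sprintf("\n  %s .. %s  lat %.1f..%.1f\n",
              format(min(d$date)), format(max(d$date)), min(d$lat), max(d$lat)))
})

#' @rdname BaleenProfile-class
#' @param x a BaleenProfile.
#' @export
setGeneric("profileData", function(x) standardGeneric("profileData"))
#' @rdname BaleenProfile-class
#' @export
setGeneric("sampleDates", function(x) standardGeneric("sampleDates"))

#' @rdname BaleenProfile-class
#' @export
setMethod("profileData", "BaleenProfile", function(x) {
  d <- data.frame(distance_cm = x@distanceCm, d13c = x@d13c)
  if (length(x@d15n)) d$d15n <- x@d15n
  if (length(x@pctC)) d$pct_c <- x@pctC
  if (length(x@pctN)) d$pct_n <- x@pctN
  if (length(x@dates)) d$date <- x@dates
  d
})
#' @rdname BaleenProfile-class
#' @export
setMethod("sampleDates", "BaleenProfile", function(x) x@dates)

setMethod("show", "BaleenProfile", function(object) {
  cat(sprintf("BaleenProfile: %d samples at %.3g cm spacing, %.1f..%.1f cm from gingival end\n",
              length(object@distanceCm), object@spacingCm,
              min(object@distanceCm), max(object@distanceCm)))
  cat(sprintf("  d13C %.2f..%.2f permil%s%s\n",
              min(object@d13c), max(object@d13c),
              if (length(object@d15n)) sprintf("  d15N %.2f..%.2f", min(object@d15n), max(object@d15n)) else "",
              if (length(object@dates)) sprintf("  dated %s..%s", format(min(object@dates)), format(max(object@dates))) else ""))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: period %.2f cm (+/- %.2f, Fisher g p = %.3g)\n",
              object@periodCm, object@periodResolutionCm, object@pValue))
  cat(sprintf("  mean peak spacing %.2f cm; growth rate %.2f cm/yr; anchor %s\n",
              object@peakSpacingCm, object@growthRate, format(object@anchorDate)))
})

setMethod("show", "PhaseSegmentation", function(object) {
  cat(sprintf("PhaseSegmentation: %d phases\n", nrow(object@phases)))
  print(object@phases, row.names = FALSE)
})

setMethod("show", "Hypothesis", function(object) {
  cat(sprintf("Hypothesis '%s' (%s), %.3g years, start box [%g..%g N, %g..%g E]\n",
              object@name, object@kind, object@nYears,
              object@startRegion[1], object@startRegion[2],
              object@startRegion[3], object@startRegion[4]))
})

setMethod("show", "EnsembleSummary", function(object) {
  r2 <- object@runs$r2
  cat(sprintf("EnsembleSummary '%s' (%s): %d runs, %d completed, %d failed\n",
              object@hypothesisName, object@kind, object@nRequested,
              object@nCompleted, object@nFailed))
  if (any(!is.na(r2)))
    cat(sprintf("  r2 median %.3f  max %.3f  (top %d runs retained)\n",
                median(r2, na.rm = TRUE), max(r2, na.rm = TRUE), nrow(object@top)))
})

#' Median and maximum regression fit of an ensemble
#'
#' @param x an EnsembleSummary.
#' @return named numeric vector with elements \code{median} and \code{max}
#'   of r-squared over completed runs.
#' @export
ensembleR2 <- function(x) {
  stopifnot(is(x, "EnsembleSummary"))
  r2 <- x@runs$r2[!is.na(x@runs$r2)]
  c(median = median(r2), max = max(r2))
}
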