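#' Named residency hotspot regions
#'
#' Approximate bounding boxes for the known North Atlantic blue-whale
#' sighting hotspots and historic hunting grounds used as residency
#' scenarios: the Norwegian/Barents Sea, waters west of Ireland, the
#' Canaries/Azores and Mid-Atlantic Ridge region, and the Cape
#' Verde/Mauritanian upwelling.  The regions are named in the
#' literature without formal coordinates; these boxes are the package's
#' documented approximations.
#'
#' @return named list of \code{c(latMin, latMax, lonMin, lonMax)} boxes.
#' @export
hotspotRegions <- function() {
  list(norwegian_barents = c(62, 74, -5, 15),
       west_ireland = c(50, 56, -16, -11),
       canaries_azores_mar = c(27, 40, -45, -15),
       cape_verde_mauritania = c(12, 22, -26, -16))
}

#' Movement hypotheses
#'
#' \code{migratoryHypothesis()} codes seasonal latitudinal migration:
#' northerly migration in spring, southerly in autumn, foraging
#' otherwise, starting from a subtropical winter box, with a wide
#' between-individual spread of daily movement capacity.
#' \code{residencyHypothesis()} codes year-round foraging confined to a
#' named hotspot, with a narrower individual spread.
#'
#' @param name scenario name.
#' @param startRegion start box \code{c(latMin, latMax, lonMin, lonMax)}.
#' @param nYears simulated duration, years.
#' @param schedule a \code{\link{behaviourSchedule}}.
#' @param movement a \code{\link{movementConfig}}.
#' @return a \code{\linkS4class{Hypothesis}}.
#' @export
migratoryHypothesis <- function(name = "migratory",
                                startRegion = c(15, 25, -35, -15),
                                nYears = 7,
                                schedule = behaviourSchedule(),
                                movement = movementConfig(stepBetweenSd = 15)) {
  new("Hypothesis", name = name, kind = "MIGRATORY", schedule = schedule,
      movement = movement, startRegion = startRegion, nYears = nYears,
      region = numeric())
}

#' @rdname migratoryHypothesis
#' @param hotspot a name from \code{\link{hotspotRegions}}, or a custom
#'   4-element box.
#' @export
residencyHypothesis <- function(hotspot, nYears = 2,
                                movement = movementConfig(stepBetweenSd = 5)) {
  if (is.character(hotspot)) {
    box <- hotspotRegions()[[match.arg(hotspot, names(hotspotRegions()))]]
    name <- hotspot
  } else {
    box <- hotspot; name <- "residency"
  }
  new("Hypothesis", name = paste0("resident_", name), kind = "RESIDENT",
      schedule = residencySchedule(), movement = movement,
      startRegion = box, nYears = nYears, region = box)
}

#' Align a simulated profile with a measured profile
#'
#' Profiles are aligned at their gingival endpoints (the most recent
#' tissue of simulation and specimen coincide in time), the simulated
#' record is interpolated onto the measured distance grid, and only the
#' overlapping span is retained.
#'
#' @param simulated,measured \code{\linkS4class{BaleenProfile}}s.
#' @return data.frame with columns \code{distance_cm},
#'   \code{simulated}, \code{measured}.
#' @export
alignProfiles <- function(simulated, measured) {
  stopifnot(is(simulated, "BaleenProfile"), is(measured, "BaleenProfile"))
  lo <- max(min(simulated@distanceCm), min(measured@distanceCm))
  hi <- min(max(simulated@distanceCm), max(measured@distanceCm))
  keep <- measured@distanceCm >= lo & measured@distanceCm <= hi
  if (!any(keep)) stop("profiles do not overlap in time")
  d <- measured@distanceCm[keep]
  simVals <- approx(simulated@distanceCm, simulated@d13c, xout = d)$y
  data.frame(distance_cm = d, simulated = simVals,
             measured = measured@d13c[keep])
}

#' Score a simulated profile against a measured profile
#'
#' Simple linear regression of the measured values on the simulated
#' values; the reported r-squared is the squared Pearson correlation
#' (invariant under affine transformation of either series, so absolute
#' d13C levels and trophic offsets do not affect ranking).
#'
#' @param simulated,measured paired value vectors (at least 3 pairs;
#'   measured must not be constant).
#' @return list with \code{r2}, \code{slope}, \code{intercept},
#'   \code{n} and \code{degenerate} (TRUE when the simulated values are
#'   constant, in which case r2 is 0 by convention, with a warning).
#' @export
fitR2 <- function(simulated, measured) {
  ok <- is.finite(simulated) & is.finite(measured)
  simulated <- simulated[ok]; measured <- measured[ok]
  if (length(simulated) < 3) stop("need at least 3 paired values")
  if (sd(measured) == 0) stop("measured values are constant")
  if (sd(simulated) == 0) {
    warning("constant simulated values: r2 set to 0")
    return(list(r2 = 0, slope = NA_real_, intercept = NA_real_,
                n = length(simulated), degenerate = TRUE))
  }
  slope <- cov(simulated, measured) / var(simulated)
  list(r2 = cor(simulated, measured)^2, slope = slope,
       intercept = mean(measured) - slope * mean(simulated),
       n = length(simulated), degenerate = FALSE)
}

## draw a legal start position uniformly within a box (rejection)
.sampleStart <- function(e, box, month, cfg, maxTries = 500) {
  for (k in seq_len(maxTries)) {
    lat <- runif(1, box[1], box[2]); lon <- runif(1, box[3], box[4])
    i <- .cellI(e, lat); j <- .cellJ(e, lon)
    if (is.na(i) || is.na(j) || e$land[i, j]) next
    sst <- e$sst[i, j, month]
    if (sst >= cfg$tMin && sst <= cfg$tMax) return(c(lat, lon))
  }
  stop("could not find a legal start position in the start region")
}

#' Run and score an ensemble of simulated whales under one hypothesis
#'
#' Simulates \code{nRuns} whales under the hypothesis, each ending at
#' the measured record's anchor date; converts each complete track to a
#' simulated baleen profile (diet integration at the given growth rate
#' and the measured sample spacing); scores it against the measured
#' profile with \code{\link{fitR2}}; and ranks the best fits.  Whales
#' trapped in coastal features before completing the record are counted
#' as failures and excluded from scoring.  Run r is seeded with
#' \code{baseSeed + r}, so the whole ensemble is reproducible from
#' \code{baseSeed} and failure exclusion cannot alter the completed
#' runs' scores.
#'
#' @param hypothesis a \code{\linkS4class{Hypothesis}}.
#' @param env an \code{\linkS4class{EnvironmentStack}}.
#' @param measured the measured \code{\linkS4class{BaleenProfile}}
#'   (dated, or supply \code{endDate}).
#' @param nRuns ensemble size.
#' @param baseSeed integer; run r uses seed \code{baseSeed + r}.
#' @param growthRate baleen growth rate used to build simulated
#'   profiles, cm per year.
#' @param endDate date of the gingival end of the record; defaults to
#'   the measured profile's gingival date.
#' @param topFraction fraction of completed runs retained as the
#'   best-fitting subset (default 0.10).
#' @param windowMonths diet-integration window (default 2).
#' @return an \code{\linkS4class{EnsembleSummary}}.
#' @export
runEnsemble <- function(hypothesis, env, measured, nRuns, baseSeed,
                        growthRate, endDate = NULL, topFraction = 0.10,
                        windowMonths = 2L) {
  stopifnot(is(hypothesis, "Hypothesis"), is(env, "EnvironmentStack"),
            is(measured, "BaleenProfile"), nRuns >= 1)
  if (is.null(endDate)) {
    if (!length(measured@dates))
      stop("measured profile is undated: supply endDate")
    endDate <- measured@dates[1]
  }
  endDate <- as.Date(endDate)
  nDays <- round(hypothesis@nYears * 365.25)
  startDate <- endDate - nDays
  startMonth <- as.POSIXlt(startDate)$mon + 1L
  e <- .envData(env)
  region <- if (length(hypothesis@region)) hypothesis@region else NULL

  runs <- vector("list", nRuns)
  tracks <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    seed <- baseSeed + r
    set.seed(seed)
    pos <- .sampleStart(e, hypothesis@startRegion, startMonth,
                        hypothesis@movement)
    tr <- simulateTrack(whaleState(pos[1], pos[2], startDate), env,
                        hypothesis@schedule, hypothesis@movement, nDays,
                        seed = NULL, region = region)
    row <- data.frame(runId = r, seed = seed, status = tr@status,
                      r2 = NA_real_, slope = NA_real_,
                      intercept = NA_real_, degenerate = FALSE)
    if (tr@status == "COMPLETE") {
      tracks[[r]] <- tr@data
      prof <- dietToProfile(trackToDiet(tr, env, windowMonths),
                            growthRate, measured@spacingCm, endDate)
      pairs <- alignProfiles(prof, measured)
      fit <- withCallingHandlers(fitR2(pairs$simulated, pairs$measured),
                                 warning = function(w) invokeRestart("muffleWarning"))
      row$r2 <- fit$r2; row$slope <- fit$slope
      row$intercept <- fit$intercept; row$degenerate <- fit$degenerate
    }
    runs[[r]] <- row
  }
  runs <- do.call(rbind, runs)
  completed <- runs[runs$status == "COMPLETE", , drop = FALSE]
  if (!nrow(completed)) {
    fd <- table(runs$status)
    stop("all ", nRuns, " runs failed (whales trapped); status counts: ",
         paste(names(fd), fd, sep = "=", collapse = ", "))
  }
  top <- selectTop(completed, topFraction)
  topTracks <- tracks[top$runId]
  occ <- occupancyByMonth(topTracks)$locations
  new("EnsembleSummary", hypothesisName = hypothesis@name,
      kind = hypothesis@kind, nRequested = as.integer(nRuns),
      nCompleted = as.integer(nrow(completed)),
      nFailed = as.integer(nRuns - nrow(completed)), runs = runs,
      topFraction = topFraction, top = top, topTracks = topTracks,
      occupancy = occ)
}

#' Select the best-fitting fraction of scored runs
#'
#' Runs are ranked by r-squared descending; the first
#' \code{ceiling(topFraction * n)} are returned, with ties broken by
#' run id (deterministic, reproducible ranking).
#'
#' @param results data.frame of scored runs (columns \code{runId},
#'   \code{r2}) or an \code{\linkS4class{EnsembleSummary}}.
#' @param topFraction fraction to retain (default 0.10).
#' @return the ranked subset of \code{results}.
#' @export
selectTop <- function(results, topFraction = 0.10) {
  if (is(results, "EnsembleSummary"))
    results <- results@runs[!is.na(results@runs$r2), , drop = FALSE]
  if (!nrow(results)) stop("no scored results to rank")
  ord <- order(-results$r2, results$runId)
  results[head(ord, ceiling(topFraction * nrow(results))), , drop = FALSE]
}

#' Daily locations of an ensemble subset, by calendar month
#'
#' Pools the daily positions of the given complete tracks by calendar
#' month, the basis for mapping where the best-fitting simulated whales
#' were in each month of the year.
#'
#' @param tracks list of \code{\linkS4class{Track}}s or of track
#'   data.frames (non-empty, COMPLETE).
#' @return list with \code{locations} (data.frame month, lat, lon) and
#'   \code{latSummary} (per-month latitude quartiles and counts).
#' @export
occupancyByMonth <- function(tracks) {
  if (!length(tracks)) stop("empty track subset")
  dfs <- lapply(tracks, function(t) {
    if (is(t, "Track")) {
      if (t@status != "COMPLETE") stop("occupancy requires COMPLETE tracks")
      t <- t@data
    }
    t
  })
  all <- do.call(rbind, dfs)
  loc <- data.frame(month = as.POSIXlt(all$date)$mon + 1L,
                    lat = all$lat, lon = all$lon)
  qs <- do.call(rbind, lapply(split(loc$lat, loc$month), quantile,
                              probs = c(0.25, 0.5, 0.75)))
  latSummary <- data.frame(month = as.integer(rownames(qs)),
                           q25 = qs[, 1], median = qs[, 2], q75 = qs[, 3],
                           n = as.integer(table(loc$month)[rownames(qs)]),
                           row.names = NULL)
  list(locations = loc, latSummary = latSummary)
}
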