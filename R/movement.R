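## Daily probabilistic movement rules.  Each day the whale decides
## whether to move (binomial), in which of 8 compass directions
## (multinomial over candidate-cell utilities) and how far (zero-
## truncated Gaussian), all conditioned on behavioural state, SST,
## depth and plankton biomass.  Draw order is fixed (move? -> heading
## -> distance) so a seed reproduces a track exactly.

#' Month-by-month behaviour schedule
#'
#' Behavioural state is fixed per calendar month by the operator;
#' foraging overrides the scheduled state in any month when the whale
#' encounters plankton biomass at or above the trigger threshold.
#'
#' @param states character vector of 12 monthly states from
#'   \code{c("MIGRATE_NORTH", "MIGRATE_SOUTH", "FORAGE")}.
#' @param forageTriggerBiomass biomass threshold, mmol N m-3, at which
#'   foraging is triggered regardless of the scheduled state.
#' @return a schedule list.
#' @export
behaviourSchedule <- function(states = defaultMigratoryStates(),
                              forageTriggerBiomass = 2) {
  states <- as.character(states)
  if (length(states) != 12 || !all(states %in% .STATES))
    stop("schedule must map all 12 months to a valid behavioural state")
  if (forageTriggerBiomass < 0) stop("forage trigger must be non-negative")
  list(states = states, forageTriggerBiomass = forageTriggerBiomass)
}

#' @rdname behaviourSchedule
#' @details \code{defaultMigratoryStates()} codes northerly migration in
#'   spring (March-May), southerly migration in autumn
#'   (September-November) and foraging otherwise.
#' @export
defaultMigratoryStates <- function() {
  s <- rep("FORAGE", 12)
  s[3:5] <- "MIGRATE_NORTH"
  s[9:11] <- "MIGRATE_SOUTH"
  s
}

#' @rdname behaviourSchedule
#' @details \code{residencySchedule()} forages in all 12 months.
#' @export
residencySchedule <- function(forageTriggerBiomass = 2)
  behaviourSchedule(rep("FORAGE", 12), forageTriggerBiomass)

#' Movement model configuration
#'
#' @param tMin,tMax thermal envelope, degrees C: candidate cells outside
#'   \code{[tMin, tMax]} are never entered (defaults 3 and 25).
#' @param depthSoft depth below which cells become increasingly
#'   unattractive, m (default 400); the penalty scales linearly with
#'   depth down to near-zero weight at zero depth.
#' @param moveProbBase per-state daily probability of attempting a move.
#' @param stepMean,stepSd per-state daily step length distribution, km:
#'   a Gaussian truncated at zero.
#' @param wSst steepness of the temperature preference (per degree C):
#'   northward migrants prefer colder candidate cells, southward
#'   migrants warmer ones, through a logistic in the SST difference.
#' @param wBiomass weight of the biomass attraction term.
#' @param forageBiomassGain multiplier on \code{wBiomass} while foraging.
#' @param forageStayGain strength of the tendency to remain within
#'   high-biomass patches while foraging (reduces move probability by
#'   this fraction at the domain biomass maximum).
#' @param stepBetweenSd between-individual SD of the per-track mean step
#'   length, km: each simulated whale draws its own mean once at the
#'   start of its track (larger for migratory scenarios).
#' @param trappedDays number of consecutive days with no legal candidate
#'   cell after which a whale is declared trapped.
#' @return a validated configuration list.
#' @export
movementConfig <- function(tMin = 3, tMax = 25, depthSoft = 400,
                           moveProbBase = c(MIGRATE_NORTH = 0.95,
                                            MIGRATE_SOUTH = 0.95,
                                            FORAGE = 0.5),
                           stepMean = c(MIGRATE_NORTH = 120,
                                        MIGRATE_SOUTH = 120, FORAGE = 25),
                           stepSd = c(MIGRATE_NORTH = 30,
                                      MIGRATE_SOUTH = 30, FORAGE = 10),
                           wSst = 6, wBiomass = 1, forageBiomassGain = 3,
                           forageStayGain = 0.8, stepBetweenSd = 0,
                           trappedDays = 10L) {
  if (!(tMin > 0 && tMin < tMax)) stop("need 0 < tMin < tMax")
  if (depthSoft <= 0) stop("depthSoft must be positive")
  fill <- function(x) { x <- x[.STATES]; names(x) <- .STATES; x }
  moveProbBase <- fill(moveProbBase); stepMean <- fill(stepMean); stepSd <- fill(stepSd)
  if (any(is.na(moveProbBase)) || any(moveProbBase < 0) || any(moveProbBase > 1))
    stop("moveProbBase must be in [0, 1] for every state")
  if (any(is.na(stepMean)) || any(stepMean <= 0) || any(is.na(stepSd)) || any(stepSd < 0))
    stop("stepMean must be positive and stepSd non-negative")
  if (forageStayGain < 0 || forageStayGain > 1) stop("forageStayGain must be in [0, 1]")
  list(tMin = tMin, tMax = tMax, depthSoft = depthSoft,
       moveProbBase = moveProbBase, stepMean = stepMean, stepSd = stepSd,
       wSst = wSst, wBiomass = wBiomass, forageBiomassGain = forageBiomassGain,
       forageStayGain = forageStayGain, stepBetweenSd = stepBetweenSd,
       trappedDays = as.integer(trappedDays))
}

#' A whale's instantaneous state
#'
#' @param lat,lon position, degrees.
#' @param date calendar date.
#' @param state behavioural state string.
#' @return a list with elements lat, lon, date, state.
#' @export
whaleState <- function(lat, lon, date, state = "FORAGE") {
  state <- match.arg(state, .STATES)
  list(lat = lat, lon = lon, date = as.Date(date), state = state)
}

#' Behavioural state for a date
#'
#' The scheduled state for the calendar month, overridden to foraging
#' when the locally encountered biomass reaches the schedule's trigger.
#'
#' @param date calendar date.
#' @param schedule a \code{\link{behaviourSchedule}}.
#' @param localBiomass biomass at the whale's position, mmol N m-3.
#' @return one of \code{"MIGRATE_NORTH"}, \code{"MIGRATE_SOUTH"},
#'   \code{"FORAGE"}.
#' @export
behaviourState <- function(date, schedule, localBiomass = 0) {
  m <- as.POSIXlt(as.Date(date))$mon + 1L
  if (!is.na(localBiomass) && localBiomass >= schedule$forageTriggerBiomass)
    return("FORAGE")
  schedule$states[m]
}

## ---- fast internal representation -----------------------------------

.envData <- function(env) {
  bio <- env@biomass
  bioMax <- suppressWarnings(max(bio, na.rm = TRUE))
  if (!is.finite(bioMax) || bioMax <= 0) bioMax <- 1
  list(lat = env@lat, lon = env@lon, lat0 = env@lat[1], lon0 = env@lon[1],
       res = env@resolutionDeg, nlat = length(env@lat), nlon = length(env@lon),
       sst = env@sst, bio = bio, d13c = env@d13cPom, depth = env@depth,
       land = env@landMask, bioMax = bioMax)
}

## compass order: N, NE, E, SE, S, SW, W, NW
.DLAT <- c(1, 1, 0, -1, -1, -1, 0, 1)
.DLON <- c(0, 1, 1, 1, 0, -1, -1, -1)
.HEADINGS <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

.cellI <- function(e, lat) {
  i <- as.integer(round((lat - e$lat0) / e$res)) + 1L
  if (i < 1L || i > e$nlat || lat < e$lat0 - e$res / 2 ||
      lat > e$lat[e$nlat] + e$res / 2) NA_integer_ else i
}
.cellJ <- function(e, lon) {
  j <- as.integer(round((lon - e$lon0) / e$res)) + 1L
  if (j < 1L || j > e$nlon || lon < e$lon0 - e$res / 2 ||
      lon > e$lon[e$nlon] + e$res / 2) NA_integer_ else j
}

.inRegion <- function(lat, lon, region)
  lat >= region[1] && lat <= region[2] && lon >= region[3] && lon <= region[4]

## candidate-cell utilities for the 8 headings; returns 8 normalised
## weights, or all zeros when no candidate is admissible (NoLegalMove)
.candWeights <- function(e, i, j, month, state, cfg, region = NULL) {
  w <- numeric(8)
  sstCur <- e$sst[i, j, month]
  forage <- state == "FORAGE"
  wBio <- cfg$wBiomass * if (forage) cfg$forageBiomassGain else 1
  for (h in 1:8) {
    ci <- i + .DLAT[h]; cj <- j + .DLON[h]
    if (ci < 1L || ci > e$nlat || cj < 1L || cj > e$nlon) next
    if (e$land[ci, cj]) next
    sstC <- e$sst[ci, cj, month]
    if (sstC < cfg$tMin || sstC > cfg$tMax) next
    if (!is.null(region) && !.inRegion(e$lat[ci], e$lon[cj], region)) next
    u <- 1
    d <- e$depth[ci, cj]
    if (d < cfg$depthSoft) u <- u * max(d / cfg$depthSoft, 1e-3)
    if (state == "MIGRATE_NORTH") u <- u * plogis(cfg$wSst * (sstCur - sstC))
    else if (state == "MIGRATE_SOUTH") u <- u * plogis(cfg$wSst * (sstC - sstCur))
    u <- u * (1 + wBio * e$bio[ci, cj, month] / e$bioMax)
    w[h] <- u
  }
  s <- sum(w)
  if (s > 0) w / s else w
}

#' Daily move probability
#'
#' The per-state base probability, reduced while foraging in proportion
#' to local biomass so that whales tend to remain within rich patches.
#' A whale whose current cell has drifted outside the thermal envelope
#' (the climatology changed under it) always attempts to move.
#'
#' @param state a \code{\link{whaleState}}.
#' @param env an \code{\linkS4class{EnvironmentStack}}.
#' @param config a \code{\link{movementConfig}}.
#' @return a probability in [0, 1].
#' @export
moveProbability <- function(state, env, config) {
  e <- .envData(env)
  m <- as.POSIXlt(state$date)$mon + 1L
  i <- .cellI(e, state$lat); j <- .cellJ(e, state$lon)
  if (is.na(i) || is.na(j)) stop("position outside grid")
  .moveProb(e, i, j, m, state$state, config)
}

.moveProb <- function(e, i, j, month, state, cfg) {
  sstCur <- e$sst[i, j, month]
  if (is.na(sstCur) || sstCur < cfg$tMin || sstCur > cfg$tMax) return(1)
  p <- cfg$moveProbBase[[state]]
  if (state == "FORAGE")
    p <- p * (1 - cfg$forageStayGain * e$bio[i, j, month] / e$bioMax)
  min(max(p, 0), 1)
}

#' Direction weights over the 8 compass headings
#'
#' Evaluates a multiplicative utility at each cell one grid step away:
#' zero for candidates on land, outside the grid, outside the thermal
#' envelope or outside a confinement region; a depth penalty shrinking
#' linearly below \code{depthSoft}; a logistic SST preference (colder
#' when migrating north, warmer when migrating south); and a biomass
#' attraction amplified while foraging.  Weights are normalised to sum
#' to one; an all-zero vector signals that no legal move exists.
#'
#' @inheritParams moveProbability
#' @param region optional confinement box
#'   \code{c(latMin, latMax, lonMin, lonMax)}.
#' @return named numeric vector of 8 weights (N, NE, E, SE, S, SW, W,
#'   NW) summing to 1, or to 0 when no candidate is admissible.
#' @export
directionWeights <- function(state, env, config, region = NULL) {
  e <- .envData(env)
  m <- as.POSIXlt(state$date)$mon + 1L
  i <- .cellI(e, state$lat); j <- .cellJ(e, state$lon)
  if (is.na(i) || is.na(j)) stop("position outside grid")
  w <- .candWeights(e, i, j, m, state$state, config, region)
  names(w) <- .HEADINGS
  w
}

## inverse-CDF draw from a Gaussian truncated at zero (one uniform)
.truncNormDraw <- function(mu, sd) {
  if (sd <= 0) return(max(mu, 0))
  a <- pnorm(0, mu, sd)
  qnorm(a + runif(1) * (1 - a), mu, sd)
}

#' Sample a daily movement distance
#'
#' A draw from the state's Gaussian step-length distribution truncated
#' at zero (negative draws are impossible, not clipped: the draw uses
#' the inverse CDF of the truncated distribution).
#'
#' @param state behavioural state string.
#' @param config a \code{\link{movementConfig}}.
#' @param n number of draws.
#' @return non-negative distance(s), km.
#' @export
sampleDistance <- function(state, config, n = 1) {
  state <- match.arg(state, .STATES)
  vapply(seq_len(n), function(k)
    .truncNormDraw(config$stepMean[[state]], config$stepSd[[state]]), numeric(1))
}

.KM_PER_DEG <- 111.32

## one daily step; returns list(lat, lon, moved, noLegal)
.stepCore <- function(e, i, j, lat, lon, month, state, cfg, region = NULL) {
  p <- .moveProb(e, i, j, month, state, cfg)
  if (runif(1) >= p) return(list(lat = lat, lon = lon, moved = FALSE, noLegal = FALSE))
  w <- .candWeights(e, i, j, month, state, cfg, region)
  if (sum(w) == 0) return(list(lat = lat, lon = lon, moved = FALSE, noLegal = TRUE))
  h <- sample.int(8L, 1L, prob = w)
  s <- .truncNormDraw(cfg$stepMean[[state]], cfg$stepSd[[state]])
  norm <- if (.DLAT[h] != 0 && .DLON[h] != 0) sqrt(2) else 1
  nlat <- lat + s * .DLAT[h] / norm / .KM_PER_DEG
  nlon <- lon + s * .DLON[h] / norm / (.KM_PER_DEG * cos(lat * pi / 180))
  ni <- .cellI(e, nlat); nj <- .cellJ(e, nlon)
  ok <- !is.na(ni) && !is.na(nj) && !e$land[ni, nj]
  if (ok) {
    sstN <- e$sst[ni, nj, month]
    ok <- sstN >= cfg$tMin && sstN <= cfg$tMax
  }
  if (ok && !is.null(region)) ok <- .inRegion(nlat, nlon, region)
  if (!ok) return(list(lat = lat, lon = lon, moved = FALSE, noLegal = FALSE))
  list(lat = nlat, lon = nlon, moved = TRUE, noLegal = FALSE)
}

#' Advance a whale by one day
#'
#' Applies the daily movement rules once: behavioural state from the
#' schedule (with the biomass foraging override), a move/stay draw, a
#' heading draw from \code{\link{directionWeights}} and a distance draw
#' from \code{\link{sampleDistance}}, in that fixed order.  Moves whose
#' sampled displacement would land on an illegal cell are aborted (the
#' whale stays), so a realised displacement never exceeds the drawn
#' distance.  Displacement geometry is equirectangular with per-latitude
#' longitude scaling.
#'
#' @inheritParams moveProbability
#' @param schedule a \code{\link{behaviourSchedule}}.
#' @param region optional confinement box.
#' @return a \code{\link{whaleState}} for the next day, with attribute
#'   \code{"noLegalMove"} set to TRUE when all 8 candidates were
#'   inadmissible.
#' @export
stepWhale <- function(state, env, schedule, config, region = NULL) {
  e <- .envData(env)
  m <- as.POSIXlt(state$date)$mon + 1L
  i <- .cellI(e, state$lat); j <- .cellJ(e, state$lon)
  if (is.na(i) || is.na(j)) stop("position outside grid")
  bs <- behaviourState(state$date, schedule, e$bio[i, j, m])
  res <- .stepCore(e, i, j, state$lat, state$lon, m, bs, config, region)
  out <- whaleState(res$lat, res$lon, state$date + 1, bs)
  attr(out, "noLegalMove") <- res$noLegal
  out
}
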