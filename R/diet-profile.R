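#' Biomass-weighted trailing mean
#'
#' The diet-integration primitive: the weighted average of baseline
#' carbon isotope values over a trailing window, weighted by the
#' proportional plankton biomass of each contributing month.
#'
#' @param values d13C values, per mil.
#' @param weights non-negative biomass weights, same length.
#' @return \code{sum(w * v) / sum(w)}; with all-zero weights the
#'   unweighted mean is returned with a warning.
#' @export
weightedTrailingMean <- function(values, weights) {
  if (length(values) != length(weights) || length(values) < 1)
    stop("values and weights must have equal length >= 1")
  if (any(weights < 0)) stop("weights must be non-negative")
  s <- sum(weights)
  if (s == 0) {
    warning("all-zero weights: falling back to unweighted mean")
    return(mean(values))
  }
  sum(weights * values) / s
}

#' Convert a movement track to a daily diet carbon isotope signal
#'
#' For each day of a complete track, the POM d13C baseline is sampled at
#' that day's cell for the \code{windowMonths} most recent mid-month
#' climatology values at or before the date, averaged with the cell's
#' monthly biomass as weights, and shifted by a constant trophic offset.
#' This emulates the damping of phytoplankton isotopic variability
#' through assimilation into the krill the whale eats: keratin reflects
#' prey grown over the preceding weeks to months, not same-day
#' phytoplankton.  Monthly climatology values are attributed to the
#' 15th of each month; the climatology has no year axis, so the window
#' wraps across calendar years.
#'
#' @param track a COMPLETE \code{\linkS4class{Track}}.
#' @param env the \code{\linkS4class{EnvironmentStack}} the track was
#'   simulated on.
#' @param windowMonths trailing window length in months (default 2).
#' @param offset constant trophic offset, per mil (default 0: inference
#'   rests on relative, not absolute, d13C values).
#' @return a \code{\linkS4class{DietSignal}}.
#' @export
trackToDiet <- function(track, env, windowMonths = 2L, offset = 0) {
  stopifnot(is(track, "Track"), is(env, "EnvironmentStack"))
  if (track@status != "COMPLETE")
    stop("diet integration requires a COMPLETE track")
  windowMonths <- as.integer(windowMonths)
  if (windowMonths < 1) stop("windowMonths must be >= 1")
  d <- track@data
  e <- .envData(env)
  i <- as.integer(round((d$lat - e$lat0) / e$res)) + 1L
  j <- as.integer(round((d$lon - e$lon0) / e$res)) + 1L
  bad <- which(is.na(i) | is.na(j) | i < 1 | i > e$nlat | j < 1 | j > e$nlon)
  if (length(bad)) stop("track leaves the grid at day index ", bad[1])
  onLand <- which(e$land[cbind(i, j)])
  if (length(onLand)) stop("track position on land at day index ", onLand[1])

  lt <- as.POSIXlt(d$date)
  mon <- lt$mon + 1L
  lastMid <- ifelse(lt$mday >= 15L, mon, mon - 1L)      # most recent mid-month
  n <- nrow(d)
  num <- numeric(n); den <- numeric(n)
  vmin <- rep(Inf, n); vmax <- rep(-Inf, n)
  for (k in seq_len(windowMonths) - 1L) {
    mk <- ((lastMid - k - 1L) %% 12L) + 1L
    idx <- cbind(i, j, mk)
    v <- e$d13c[idx]; w <- e$bio[idx]
    num <- num + w * v; den <- den + w
    vmin <- pmin(vmin, v); vmax <- pmax(vmax, v)
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  zero <- is.na(out)
  if (any(zero)) {
    warning(sum(zero), " day(s) with all-zero biomass weights: unweighted mean used")
    ## recompute unweighted for those days
    acc <- numeric(n)
    for (k in seq_len(windowMonths) - 1L) {
      mk <- ((lastMid - k - 1L) %% 12L) + 1L
      acc <- acc + e$d13c[cbind(i, j, mk)]
    }
    out[zero] <- acc[zero] / windowMonths
  }
  new("DietSignal", date = d$date, d13c = out + offset,
      windowMonths = windowMonths, offset = offset)
}

#' Map a daily diet signal onto a baleen distance axis
#'
#' Baleen grows at a constant rate, so time maps linearly to distance
#' from the gingival end.  The sample at distance d carries the mean of
#' diet values in the time bin
#' \code{[endDate - (d + spacing)/g, endDate - d/g)} years, i.e. each
#' centimetre of baleen integrates roughly a month of growth at typical
#' blue-whale growth rates.  The profile has
#' \code{floor(span_years * g / spacing)} samples.
#'
#' @param diet a \code{\linkS4class{DietSignal}}.
#' @param growthRate baleen growth rate g, cm per year.
#' @param spacingCm sample spacing, cm (default 1).
#' @param endDate date of the gingival end of the record (default: the
#'   last diet day).
#' @return a \code{\linkS4class{BaleenProfile}} with per-sample dates
#'   assigned from \code{endDate} and \code{growthRate}.
#' @export
dietToProfile <- function(diet, growthRate, spacingCm = 1, endDate = NULL) {
  stopifnot(is(diet, "DietSignal"))
  if (growthRate <= 0) stop("growth rate must be positive")
  if (is.null(endDate)) endDate <- max(diet@date)
  endDate <- as.Date(endDate)
  spanDays <- as.numeric(endDate - min(diet@date)) + 1
  nSamples <- floor((spanDays / 365.25) * growthRate / spacingCm)
  if (nSamples < 1) stop("diet signal shorter than one baleen sample bin")
  binDays <- 365.25 * spacingCm / growthRate
  t <- as.numeric(diet@date - endDate)          # <= 0 within record
  keep <- t < 0 & t >= -nSamples * binDays
  bin <- floor(-t[keep] / binDays)              # 0 = gingival-most bin
  means <- tapply(diet@d13c[keep], factor(bin, levels = 0:(nSamples - 1)), mean)
  if (anyNA(means)) stop("diet signal does not cover every baleen sample bin")
  dist <- (seq_len(nSamples) - 1) * spacingCm
  prof <- new("BaleenProfile", distanceCm = dist, d13c = as.numeric(means),
              d15n = numeric(), pctC = numeric(), pctN = numeric(),
              dates = as.Date(character()), spacingCm = spacingCm)
  assignDates(prof, growthRate, endDate)
}
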