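#' Simulate a multi-year daily movement track
#'
#' Runs the daily movement rules for \code{nDays} steps from a legal
#' start position.  A whale with no admissible candidate cell on
#' \code{trappedDays} consecutive days is declared trapped in coastal
#' features and the track is marked \code{FAILED_TRAPPED} at that day;
#' otherwise the track is \code{COMPLETE} with \code{nDays + 1} daily
#' positions (including the start).  Identical inputs and seed yield a
#' byte-identical track.
#'
#' @param start a \code{\link{whaleState}} (its state element is
#'   ignored; the behaviour schedule governs).
#' @param env an \code{\linkS4class{EnvironmentStack}}.
#' @param schedule a \code{\link{behaviourSchedule}}.
#' @param config a \code{\link{movementConfig}}.
#' @param nDays number of daily steps to simulate.
#' @param seed integer seed, or \code{NULL} to draw from the ambient RNG
#'   stream (used by \code{\link{runEnsemble}}, which seeds per run).
#' @param region optional confinement box
#'   \code{c(latMin, latMax, lonMin, lonMax)} applied to every move
#'   (used for residency scenarios).
#' @return a \code{\linkS4class{Track}}.
#' @examples
#' env <- generateSyntheticEnvironment(syntheticEnvConfig(latRange = c(20, 50),
#'                                                        lonRange = c(-40, -10)))
#' tr <- simulateTrack(whaleState(30, -25, "1890-01-01"), env,
#'                     behaviourSchedule(), movementConfig(), 60, seed = 1)
#' trackStatus(tr)
#' @export
simulateTrack <- function(start, env, schedule, config, nDays,
                          seed = NULL, region = NULL) {
  stopifnot(is(env, "EnvironmentStack"), nDays >= 0)
  e <- .envData(env)
  if (!is.null(seed)) set.seed(seed)

  cfg <- config
  if (cfg$stepBetweenSd > 0) {
    ## per-individual variation in maximum daily movement
    cfg$stepMean <- pmax(cfg$stepMean + rnorm(1, 0, cfg$stepBetweenSd), 1)
  }

  dates <- as.Date(start$date) + 0:nDays
  months <- as.POSIXlt(dates)$mon + 1L

  i <- .cellI(e, start$lat); j <- .cellJ(e, start$lon)
  if (is.na(i) || is.na(j) || e$land[i, j])
    stop("illegal start position: outside grid or on land")
  sst0 <- e$sst[i, j, months[1]]
  if (sst0 < cfg$tMin || sst0 > cfg$tMax)
    stop("illegal start position: SST outside thermal envelope")

  n <- nDays + 1L
  lat <- numeric(n); lon <- numeric(n); st <- character(n)
  lat[1] <- start$lat; lon[1] <- start$lon
  st[1] <- behaviourState(dates[1], schedule, e$bio[i, j, months[1]])

  status <- "COMPLETE"; failedDay <- NA_integer_
  trapped <- 0L
  for (d in seq_len(nDays)) {
    m <- months[d]
    res <- .stepCore(e, i, j, lat[d], lon[d], m, st[d], cfg, region)
    if (res$noLegal) {
      trapped <- trapped + 1L
      if (trapped >= cfg$trappedDays) {
        status <- "FAILED_TRAPPED"; failedDay <- d
        lat <- lat[1:d]; lon <- lon[1:d]; st <- st[1:d]; dates <- dates[1:d]
        break
      }
    } else trapped <- 0L
    lat[d + 1] <- res$lat; lon[d + 1] <- res$lon
    i <- .cellI(e, res$lat); j <- .cellJ(e, res$lon)
    st[d + 1] <- behaviourState(dates[d + 1], schedule,
                                e$bio[i, j, months[d + 1]])
  }

  new("Track",
      data = data.frame(date = dates, lat = lat, lon = lon, state = st,
                        stringsAsFactors = FALSE),
      status = status, failedDay = failedDay,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      config = list(schedule = schedule, movement = cfg, region = region))
}

#' Write a track to CSV or GeoJSON
#'
#' @param track a \code{\linkS4class{Track}}.
#' @param path output path.
#' @param format \code{"csv"} (date, lat, lon, state) or
#'   \code{"geojson"} (LineString with status/seed properties).
#' @return \code{path}, invisibly.
#' @export
writeTrack <- function(track, path, format = c("csv", "geojson")) {
  stopifnot(is(track, "Track"))
  format <- match.arg(format)
  d <- track@data
  if (format == "csv") {
    out <- data.frame(date = format(d$date), lat = d$lat, lon = d$lon,
                      state = d$state)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    gj <- list(type = "Feature",
               properties = list(status = track@status,
                                 seed = if (is.na(track@seed)) NULL else track@seed,
                                 start = format(d$date[1]),
                                 end = format(d$date[nrow(d)])),
               geometry = list(type = "LineString",
                               coordinates = Map(function(x, y) c(x, y),
                                                 d$lon, d$lat)))
    writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 10), path)
  }
  invisible(path)
}

#' Read a track written by \code{\link{writeTrack}}
#'
#' @param path CSV track file.
#' @return a \code{\linkS4class{Track}} (status COMPLETE; the file does
#'   not carry failure metadata).
#' @export
readTrack <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "lat", "lon", "state")
  if (!all(need %in% names(d)))
    stop("format error: track file needs columns ", paste(need, collapse = ", "))
  d$date <- as.Date(d$date)
  new("Track", data = d[need], status = "COMPLETE", failedDay = NA_integer_,
      seed = NA_integer_, config = list())
}
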