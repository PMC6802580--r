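#' Deterministic synthetic fixtures
#'
#' Builds small, fully synthetic stand-in datasets by running the
#' forward model under a known (recorded) truth: a small environment
#' grid, a 97-sample synthetic "measured" baleen profile for a
#' migratory whale (about seven years at 13.5 cm/yr), and a two-year
#' one for a subtropical-resident whale.  The migratory profile
#' doubles as a stand-in for a real multi-year baleen record: d13C from
#' the forward model plus measurement noise, a d15N column carrying an
#' annual cycle consistent with the generating growth rate, and
#' keratin-range elemental composition.  Every file is deterministic in
#' \code{seed}; the generating truth is written to a manifest next to
#' the data.
#'
#' @param kind \code{"env_small"}, \code{"migratory_profile"} or
#'   \code{"resident_profile"}.
#' @param seed integer seed.
#' @param dir output directory.
#' @param noiseSd analytical measurement noise added to profile
#'   isotope values, per mil (default 0.1, typical EA-IRMS precision).
#' @return invisible list of the file paths written, with the generated
#'   object attached as attribute \code{"object"}.
#' @export
makeFixture <- function(kind = c("env_small", "migratory_profile",
                                 "resident_profile"),
                        seed = 1, dir = tempdir(), noiseSd = 0.1) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  growthRate <- 13.5
  anchor <- as.Date("1891-03-01")

  if (kind == "env_small") {
    env <- generateSyntheticEnvironment(
      syntheticEnvConfig(latRange = c(45, 65), lonRange = c(-40, -20)))
    path <- file.path(dir, "fixture_env_small.nc")
    saveEnvironment(env, path)
    return(invisible(structure(list(env = path), object = env)))
  }

  env <- generateSyntheticEnvironment()
  if (kind == "migratory_profile") {
    hyp <- migratoryHypothesis()
    hyp@movement$stepBetweenSd <- 0          # representative individual
    nDays <- 2625L                       # ~7.19 yr -> 97 one-cm samples
    d15nMean <- 13; d15nAmp <- 0.8
  } else {
    hyp <- residencyHypothesis("cape_verde_mauritania")
    hyp@movement$stepBetweenSd <- 0          # representative individual
    nDays <- round(hyp@nYears * 365.25)
    d15nMean <- 11; d15nAmp <- 0.2       # weak cycle in subtropical residency
  }

  set.seed(seed)
  e <- .envData(env)
  startDate <- anchor - nDays
  pos <- .sampleStart(e, hyp@startRegion, as.POSIXlt(startDate)$mon + 1L,
                      hyp@movement)
  track <- NULL
  for (try in 1:25) {                    # retry trapped truths deterministically
    track <- simulateTrack(whaleState(pos[1], pos[2], startDate), env,
                           hyp@schedule, hyp@movement, nDays, seed = NULL,
                           region = if (length(hyp@region)) hyp@region else NULL)
    if (track@status == "COMPLETE") break
    pos <- .sampleStart(e, hyp@startRegion, as.POSIXlt(startDate)$mon + 1L,
                        hyp@movement)
  }
  if (track@status != "COMPLETE") stop("could not simulate a complete truth track")

  prof <- dietToProfile(trackToDiet(track, env), growthRate, 1, anchor)
  n <- length(prof@distanceCm)
  ## annual d15N cycle tied to the same growth rate (feeding/excretion
  ## seasonality), plus analytical noise; keratin-range C:N
  yearFrac <- as.numeric(format(prof@dates, "%j")) / 365.25
  d15n <- d15nMean + d15nAmp * cos(2 * pi * (yearFrac - 0.55)) +
    rnorm(n, 0, noiseSd)
  pctC <- rnorm(n, 45, 1)
  cn <- runif(n, 3.30, 3.70)
  prof@d13c <- prof@d13c + rnorm(n, 0, noiseSd)
  prof@d15n <- d15n
  prof@pctC <- pctC
  prof@pctN <- pctC / cn

  stem <- file.path(dir, paste0("synthetic_", kind))
  csv <- paste0(stem, ".csv")
  writeProfile(prof, csv)
  manifest <- list(kind = kind, synthetic = TRUE, seed = seed,
                   truth = list(hypothesis = hyp@name, kind = hyp@kind,
                                nDays = nDays, growthRate = growthRate,
                                anchorDate = format(anchor),
                                noiseSd = noiseSd,
                                start = list(lat = pos[1], lon = pos[2])),
                   version = as.character(packageVersion("baleenIso")))
  man <- paste0(stem, "_manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = 10), man)
  invisible(structure(list(profile = csv, manifest = man), object = prof))
}
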