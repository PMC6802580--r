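test_that("biomass weighting of the diet average is exact on hand cases", {
  expect_equal(weightedTrailingMean(c(-20, -24), c(1, 1)), -22)
  expect_equal(weightedTrailingMean(c(-20, -24), c(1, 3)), -23)
  expect_equal(weightedTrailingMean(-21, 5), -21)
  expect_warning(out <- weightedTrailingMean(c(-20, -24), c(0, 0)), "all-zero")
  expect_equal(out, -22)
  expect_error(weightedTrailingMean(c(-20, -24), 1), "equal length")
  expect_error(weightedTrailingMean(c(-20), c(-1)), "non-negative")
})

stationaryTrack <- function(env, nDays, start = "1888-01-01") {
  cfg <- movementConfig(moveProbBase = c(MIGRATE_NORTH = 0, MIGRATE_SOUTH = 0,
                                         FORAGE = 0))
  simulateTrack(whaleState(20, 20, start), env, residencySchedule(), cfg,
                nDays, seed = 1)
}

test_that("diet integration averages the trailing monthly baseline", {
  ## constant field: the diet is the field value, offset is additive
  env <- uniformOcean(bio = 1)
  tr <- stationaryTrack(env, 400)
  diet <- trackToDiet(tr, env)
  expect_true(all(diet@d13c == -21))
  dietOff <- trackToDiet(tr, env, offset = 1)
  expect_equal(dietOff@d13c, diet@d13c + 1)

  ## alternating monthly field with equal biomass: two-month window
  ## always averages one -20 month and one -22 month
  alt <- alternatingOcean()
  dietAlt <- trackToDiet(stationaryTrack(alt, 400), alt, windowMonths = 2)
  expect_true(all(dietAlt@d13c == -21))

  ## diet values stay within the envelope of contributing baseline values
  env2 <- defaultEnv()
  hyp <- migratoryHypothesis()
  tr2 <- simulateTrack(whaleState(20, -25, "1886-03-01"), env2, hyp@schedule,
                       hyp@movement, 800, seed = 12)
  diet2 <- trackToDiet(tr2, env2)
  d13 <- envField(env2, "d13c_pom")
  expect_true(all(diet2@d13c >= min(d13, na.rm = TRUE) &
                  diet2@d13c <= max(d13, na.rm = TRUE)))
})

test_that("the distance axis maps time at the growth rate", {
  env <- uniformOcean(bio = 1)
  tr <- stationaryTrack(env, 800)
  diet <- trackToDiet(tr, env)
  prof <- dietToProfile(diet, 13.5, 1)
  expect_true(all(profileData(prof)$d13c == -21))

  ## one year of growth separates samples 13.5 cm apart
  dts <- sampleDates(prof)
  i0 <- which(prof@distanceCm == 0)
  i1 <- which(prof@distanceCm == 13)
  expect_lt(abs(as.numeric(dts[i0] - dts[i1]) - 365.25 * 13 / 13.5), 1.5)

  ## a 365-day diet at 13.5 cm/yr yields floor(13.49) = 13 samples
  tr365 <- stationaryTrack(env, 364)
  expect_length(dietToProfile(trackToDiet(tr365, env), 13.5, 1)@d13c, 13L)

  ## binning commutes with constant offsets
  profOff <- dietToProfile(trackToDiet(tr, env, offset = 2), 13.5, 1)
  expect_equal(profOff@d13c, prof@d13c + 2)
})

test_that("profiles round-trip through CSV with composition columns", {
  prof <- baleenProfile(0:96, rnorm(97, -16, 0.5), d15n = rnorm(97, 13, 0.5),
                        pctC = rep(45, 97), pctN = rep(13, 97))
  path <- tempfile(fileext = ".csv")
  writeProfile(prof, path)
  back <- readProfile(path)
  expect_equal(back@d13c, prof@d13c, tolerance = 1e-10)
  expect_equal(back@d15n, prof@d15n, tolerance = 1e-10)
  expect_equal(cnRatio(back)[1], 45 / 13, tolerance = 1e-10)

  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(distance_cm = 0:9, d15n = 1:10), bad, row.names = FALSE)
  expect_error(readProfile(bad), "missing required column.*d13c")

  uneven <- tempfile(fileext = ".csv")
  write.csv(data.frame(distance_cm = c(0, 1, 2.5, 3.5), d13c = 1:4), uneven,
            row.names = FALSE)
  expect_warning(try(readProfile(uneven), silent = TRUE), "non-uniform")
  unlink(c(path, bad, uneven))
})

test_that("subtropical residents record far flatter profiles than migrants", {
  ## noisy stand-in records: the resident stays well under a third of
  ## the migrant's variability
  migratory <- truthFixture("migratory_profile")
  resident <- truthFixture("resident_profile")
  expect_lt(sd(resident@d13c), 0.3 * sd(migratory@d13c))

  ## noiseless forward profiles, resident confined to the flat
  ## subtropical band: seasonal amplitude under a fifth of a migrant's
  env <- defaultEnv()
  hypM <- migratoryHypothesis(); hypM@movement$stepBetweenSd <- 0
  trM <- simulateTrack(whaleState(20, -25, "1884-03-01"), env, hypM@schedule,
                       hypM@movement, 2557, seed = 301)
  flat <- residencyHypothesis(c(12, 19, -32, -22), nYears = 2)
  flat@movement$stepBetweenSd <- 0
  trR <- NULL
  for (s in 301:320) {
    trR <- simulateTrack(whaleState(16, -27, "1889-03-01"), env,
                         flat@schedule, flat@movement, 730, seed = s,
                         region = flat@region)
    if (trackStatus(trR) == "COMPLETE") break
  }
  expect_equal(trackStatus(trM), "COMPLETE")
  expect_equal(trackStatus(trR), "COMPLETE")
  amp <- function(tr) diff(range(dietToProfile(trackToDiet(tr, env),
                                               13.5, 1)@d13c))
  expect_lt(amp(trR), 0.2 * amp(trM))
})
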