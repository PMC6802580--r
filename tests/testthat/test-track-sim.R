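test_that("zero-day simulation returns just the start state", {
  tr <- simulateTrack(whaleState(20, 20, "1888-01-01"), uniformOcean(),
                      residencySchedule(), movementConfig(), 0, seed = 1)
  expect_equal(trackStatus(tr), "COMPLETE")
  expect_equal(nrow(trackData(tr)), 1L)
})

test_that("a whale in a one-cell pond is declared trapped immediately", {
  cfg <- movementConfig(moveProbBase = c(MIGRATE_NORTH = 1, MIGRATE_SOUTH = 1,
                                         FORAGE = 1),
                        trappedDays = 1L)
  tr <- simulateTrack(whaleState(11, 11, "1888-01-01"), pondEnv(),
                      residencySchedule(), cfg, 30, seed = 1)
  expect_equal(trackStatus(tr), "FAILED_TRAPPED")
  expect_equal(tr@failedDay, 1L)
})

test_that("illegal start positions are rejected", {
  env <- defaultEnv()
  expect_error(simulateTrack(whaleState(40, 19.5, "1888-01-01"), env,
                             residencySchedule(), movementConfig(), 5),
               "land")
  ## equatorial summer water is above the 25 C ceiling
  expect_error(simulateTrack(whaleState(1, -30, "1888-08-01"), env,
                             residencySchedule(), movementConfig(), 5),
               "thermal envelope")
})

test_that("a seven-year migratory track completes with all invariants holding", {
  env <- defaultEnv()
  hyp <- migratoryHypothesis()
  tr <- simulateTrack(whaleState(20, -25, "1884-03-01"), env,
                      hyp@schedule, hyp@movement, 2557, seed = 99)
  expect_equal(trackStatus(tr), "COMPLETE")
  d <- trackData(tr)
  expect_equal(nrow(d), 2558L)
  expect_true(all(diff(as.integer(d$date)) == 1L))

  e <- baleenIso:::.envData(env)
  i <- as.integer(round((d$lat - e$lat0) / e$res)) + 1L
  j <- as.integer(round((d$lon - e$lon0) / e$res)) + 1L
  expect_false(any(e$land[cbind(i, j)]))
  m <- as.POSIXlt(d$date)$mon + 1L
  sst <- e$sst[cbind(i, j, m)]
  expect_true(all(sst >= 3 & sst <= 25))
})

test_that("identical seeds reproduce a track byte for byte", {
  env <- defaultEnv()
  hyp <- migratoryHypothesis()
  a <- simulateTrack(whaleState(20, -25, "1884-03-01"), env, hyp@schedule,
                     hyp@movement, 400, seed = 5)
  b <- simulateTrack(whaleState(20, -25, "1884-03-01"), env, hyp@schedule,
                     hyp@movement, 400, seed = 5)
  expect_identical(serialize(trackData(a), NULL), serialize(trackData(b), NULL))
})

test_that("heading frequencies are uniform in a spatially uniform ocean", {
  env <- uniformOcean(latRange = c(0, 40), lonRange = c(0, 40))
  cfg <- movementConfig(moveProbBase = c(MIGRATE_NORTH = 1, MIGRATE_SOUTH = 1,
                                         FORAGE = 1),
                        stepMean = c(MIGRATE_NORTH = 60, MIGRATE_SOUTH = 60,
                                     FORAGE = 60),
                        stepSd = c(MIGRATE_NORTH = 0, MIGRATE_SOUTH = 0,
                                   FORAGE = 0))
  sch <- residencySchedule()
  ws <- whaleState(20, 20, "1888-07-01")
  set.seed(101)
  heads <- integer(8)
  for (k in 1:10000) {
    out <- stepWhale(ws, env, sch, cfg)
    dlat <- sign(round(out$lat - ws$lat, 6))
    dlon <- sign(round(out$lon - ws$lon, 6))
    h <- which(baleenIso:::.DLAT == dlat & baleenIso:::.DLON == dlon)
    heads[h] <- heads[h] + 1L
  }
  expect_gt(chisq.test(heads)$p.value, 0.001)
})

test_that("north-only schedules end further north than south-only schedules", {
  env <- defaultEnv()
  cfg <- movementConfig()
  north <- behaviourSchedule(rep("MIGRATE_NORTH", 12), forageTriggerBiomass = Inf)
  south <- behaviourSchedule(rep("MIGRATE_SOUTH", 12), forageTriggerBiomass = Inf)
  finals <- sapply(list(north, south), function(sch)
    mean(sapply(1:25, function(s) {
      tr <- simulateTrack(whaleState(30, -30, "1888-04-01"), env, sch, cfg,
                          120, seed = s)
      d <- trackData(tr)
      d$lat[nrow(d)]
    })))
  expect_gt(finals[1], finals[2])
})

test_that("tracks round-trip through CSV and export to GeoJSON", {
  tr <- simulateTrack(whaleState(20, 20, "1888-01-01"), uniformOcean(),
                      residencySchedule(), movementConfig(), 10, seed = 2)
  csv <- tempfile(fileext = ".csv")
  writeTrack(tr, csv)
  back <- readTrack(csv)
  expect_equal(trackData(back)$lat, trackData(tr)$lat, tolerance = 1e-10)

  gj <- tempfile(fileext = ".geojson")
  writeTrack(tr, gj, format = "geojson")
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$geometry$type, "LineString")
  expect_length(parsed$geometry$coordinates, 11)
  unlink(c(csv, gj))
})
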