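test_that("behaviour follows the monthly schedule with a biomass forage override", {
  sch <- behaviourSchedule()
  expect_equal(behaviourState(as.Date("1888-04-10"), sch, 0), "MIGRATE_NORTH")
  expect_equal(behaviourState(as.Date("1888-10-10"), sch, 0), "MIGRATE_SOUTH")
  expect_equal(behaviourState(as.Date("1888-07-10"), sch, 0), "FORAGE")
  ## rich plankton patch triggers foraging even in a migration month
  expect_equal(behaviourState(as.Date("1888-04-10"), sch, 5), "FORAGE")
})

test_that("move probability equals the state base rate and drops in rich patches", {
  cfg <- movementConfig()
  lowBio <- uniformOcean(bio = 0)
  ws <- whaleState(20, 20, "1888-07-01", "FORAGE")
  expect_equal(moveProbability(ws, lowBio, cfg), cfg$moveProbBase[["FORAGE"]])

  richBio <- uniformOcean(bio = 4)
  pRich <- moveProbability(ws, richBio, cfg)
  expect_lt(pRich, cfg$moveProbBase[["FORAGE"]])
  expect_gte(pRich, 0)
  for (st in c("MIGRATE_NORTH", "MIGRATE_SOUTH", "FORAGE")) {
    p <- moveProbability(whaleState(20, 20, "1888-07-01", st), richBio, cfg)
    expect_true(p >= 0 && p <= 1)
  }
})

test_that("direction weights respect symmetry, thermal limits and depth penalty", {
  cfg <- movementConfig()
  ## uniform unbounded ocean: all 8 headings equally likely
  w <- directionWeights(whaleState(20, 20, "1888-07-01", "FORAGE"),
                        uniformOcean(), cfg)
  expect_equal(unname(w), rep(1 / 8, 8))

  ## cells below the 3 C minimum are never entered
  env <- uniformOcean(sst = 5)
  sst <- env@sst
  iN <- which(envLat(env) == 21)                 # cells due north of (20, 20)
  for (m in 1:12) sst[iN, , m] <- 2
  cold <- initialize(env, sst = sst)
  w <- directionWeights(whaleState(20, 20, "1888-07-01", "MIGRATE_NORTH"), cold, cfg)
  expect_equal(unname(w[c("N", "NE", "NW")]), c(0, 0, 0))
  expect_equal(sum(w), 1)

  ## shallow candidates are penalised relative to deep ones
  env <- uniformOcean()
  depth <- env@depth
  depth[, which(envLon(env) == 21)] <- 200       # shallow strip to the east
  depth[, which(envLon(env) == 19)] <- 1000
  shelf <- initialize(env, depth = depth)
  w <- directionWeights(whaleState(20, 20, "1888-07-01", "FORAGE"), shelf, cfg)
  expect_lt(w[["E"]], w[["W"]])
  expect_gt(w[["E"]], 0)

  ## migrating north prefers the colder candidate, south the warmer
  grad <- gradientOcean()
  wN <- directionWeights(whaleState(20, 20, "1888-04-01", "MIGRATE_NORTH"), grad, cfg)
  wS <- directionWeights(whaleState(20, 20, "1888-10-01", "MIGRATE_SOUTH"), grad, cfg)
  expect_gt(wN[["N"]], wN[["S"]])
  expect_gt(wS[["S"]], wS[["N"]])
})

test_that("distance draws follow a zero-truncated Gaussian", {
  cfg <- movementConfig(stepMean = c(MIGRATE_NORTH = 50, MIGRATE_SOUTH = 50,
                                     FORAGE = 50),
                        stepSd = c(MIGRATE_NORTH = 0, MIGRATE_SOUTH = 0,
                                   FORAGE = 0))
  expect_equal(sampleDistance("FORAGE", cfg), 50)

  set.seed(42)
  cfg2 <- movementConfig(stepMean = c(MIGRATE_NORTH = 40, MIGRATE_SOUTH = 40,
                                      FORAGE = 40),
                         stepSd = c(MIGRATE_NORTH = 10, MIGRATE_SOUTH = 10,
                                    FORAGE = 10))
  x <- sampleDistance("FORAGE", cfg2, n = 1e5)
  expect_true(all(x >= 0))
  ## closed-form mean of a Gaussian truncated at zero
  mu <- 40; s <- 10
  alpha <- -mu / s
  truthMean <- mu + s * dnorm(alpha) / (1 - pnorm(alpha))
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - truthMean), 3 * se)
})

test_that("a single step is seed-deterministic, stays put at p = 0, and moves the drawn distance", {
  env <- uniformOcean()
  sch <- residencySchedule()
  never <- movementConfig(moveProbBase = c(MIGRATE_NORTH = 0, MIGRATE_SOUTH = 0,
                                           FORAGE = 0))
  ws <- whaleState(20, 20, "1888-07-01")
  set.seed(1)
  out <- stepWhale(ws, env, sch, never)
  expect_equal(out$lat, 20)
  expect_equal(out$lon, 20)
  expect_equal(out$date, as.Date("1888-07-02"))

  mover <- movementConfig(moveProbBase = c(MIGRATE_NORTH = 1, MIGRATE_SOUTH = 1,
                                           FORAGE = 1))
  set.seed(7); a <- stepWhale(ws, env, sch, mover)
  set.seed(7); b <- stepWhale(ws, env, sch, mover)
  expect_identical(a, b)

  ## with a degenerate distance distribution the realised great-circle
  ## displacement equals the drawn step length
  fixed <- movementConfig(moveProbBase = c(MIGRATE_NORTH = 1, MIGRATE_SOUTH = 1,
                                           FORAGE = 1),
                          stepMean = c(MIGRATE_NORTH = 60, MIGRATE_SOUTH = 60,
                                       FORAGE = 60),
                          stepSd = c(MIGRATE_NORTH = 0, MIGRATE_SOUTH = 0,
                                     FORAGE = 0))
  set.seed(3)
  for (k in 1:20) {
    out <- stepWhale(ws, env, sch, fixed)
    d <- geosphere::distHaversine(c(ws$lon, ws$lat), c(out$lon, out$lat)) / 1000
    expect_lt(abs(d - 60), 1)
  }
})

test_that("northward migrants drift north against an SST gradient", {
  env <- gradientOcean()
  cfg <- movementConfig(moveProbBase = c(MIGRATE_NORTH = 1, MIGRATE_SOUTH = 1,
                                         FORAGE = 1))
  sch <- behaviourSchedule(rep("MIGRATE_NORTH", 12))
  ws <- whaleState(20, 20, "1888-04-01")
  set.seed(11)
  north <- south <- 0
  for (k in 1:2000) {
    out <- stepWhale(ws, env, sch, cfg)
    if (out$lat > ws$lat) north <- north + 1
    if (out$lat < ws$lat) south <- south + 1
  }
  expect_gt(north, south)
})
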