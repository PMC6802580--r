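## Small environments built in code for the unit tests.

## spatially uniform open ocean (no land, constant fields)
uniformOcean <- function(latRange = c(0, 40), lonRange = c(0, 40),
                         sst = 15, bio = 0, d13c = -21, depth = 4000,
                         res = 1) {
  lat <- seq(latRange[1], latRange[2], by = res)
  lon <- seq(lonRange[1], lonRange[2], by = res)
  n <- c(length(lat), length(lon), 12L)
  environmentStack(lat, lon,
                   d13cPom = array(d13c, n), sst = array(sst, n),
                   biomass = array(bio, n),
                   depth = matrix(depth, n[1], n[2]))
}

## ocean with a linear north-south SST gradient
gradientOcean <- function(latRange = c(0, 40), lonRange = c(0, 40),
                          sstSouth = 22, slope = 0.3, bio = 0, res = 1) {
  env <- uniformOcean(latRange, lonRange, bio = bio, res = res)
  sst <- env@sst
  for (m in 1:12) sst[, , m] <- sstSouth - slope * (env@lat - latRange[1])
  initialize(env, sst = sst)
}

## one water cell surrounded by land
pondEnv <- function() {
  land <- matrix(TRUE, 3, 3); land[2, 2] <- FALSE
  n <- c(3L, 3L, 12L)
  environmentStack(10:12, 10:12,
                   d13cPom = array(-21, n), sst = array(15, n),
                   biomass = array(0, n), depth = matrix(4000, 3, 3),
                   landMask = land)
}

## uniform ocean whose d13C alternates -20 / -22 by calendar month,
## with constant biomass
alternatingOcean <- function() {
  env <- uniformOcean(bio = 1)
  d <- env@d13cPom
  for (m in 1:12) d[, , m] <- if (m %% 2 == 1) -20 else -22
  initialize(env, d13cPom = d)
}

## memoised default synthetic environment and truth fixtures, shared
## across test files (building them once keeps the suite fast)
.cache <- new.env(parent = emptyenv())
defaultEnv <- function() {
  if (is.null(.cache$env)) .cache$env <- generateSyntheticEnvironment()
  .cache$env
}
truthFixture <- function(kind) {
  key <- paste0("fx_", kind)
  if (is.null(.cache[[key]])) {
    fx <- makeFixture(kind, seed = 20 + nchar(kind), dir = tempfile("fx"))
    prof <- readProfile(fx$profile)
    .cache[[key]] <- assignDates(prof, 13.5, as.Date("1891-03-01"))
  }
  .cache[[key]]
}
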