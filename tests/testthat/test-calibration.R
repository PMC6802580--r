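test_that("the periodogram recovers a pure sinusoid's period to grid resolution", {
  x <- sin(2 * pi * (0:96) / 13.5)
  p <- estimatePeriod(x, 1)
  expect_lt(abs(as.numeric(p) - 13.5), 0.2)
  expect_lt(attr(p, "resolutionCm"), 0.2)
  expect_lt(attr(p, "pValue"), 1e-6)

  ## independent oracle: direct DFT of the detrended series on a dense
  ## frequency grid
  xd <- resid(lm(x ~ seq_along(x)))
  freqs <- seq(1 / 48, 0.5, length.out = 20000)
  power <- vapply(freqs, function(f) {
    t <- seq_along(xd) - 1
    sum(xd * cos(2 * pi * f * t))^2 + sum(xd * sin(2 * pi * f * t))^2
  }, numeric(1))
  expect_lt(abs(as.numeric(p) - 1 / freqs[which.max(power)]), 0.2)

  expect_error(estimatePeriod(rep(1, 97)), "constant")
  expect_error(estimatePeriod(sin(1:10)), "too short")
})

test_that("white noise is almost never flagged as periodic", {
  set.seed(77)
  pvals <- replicate(1000, attr(estimatePeriod(rnorm(97)), "pValue"))
  ## at the documented alpha = 0.001 detection threshold, at least 99%
  ## of pure-noise series yield no claimed period
  expect_gte(mean(pvals >= 0.001), 0.99)
})

test_that("period is recoverable under heavy noise", {
  set.seed(31)
  errs <- replicate(200, {
    x <- sin(2 * pi * (0:96) / 13.5) + rnorm(97, 0, 0.5)
    abs(as.numeric(estimatePeriod(x)) - 13.5) / 13.5
  })
  expect_lt(median(errs), 0.05)
})

test_that("peak spacing matches the generating period and rejects flat ramps", {
  x <- sin(2 * pi * (0:96) / 13.5)
  expect_lt(abs(as.numeric(peakSpacing(x, 1)) - 13.5), 1)
  expect_error(peakSpacing(seq(0, 1, length.out = 97)), "insufficient")

  ## the two growth-rate estimators agree on noiseless sinusoids
  for (per in seq(8, 30, by = 2)) {
    x <- sin(2 * pi * (0:96) / per)
    expect_lt(abs(as.numeric(estimatePeriod(x)) - as.numeric(peakSpacing(x))),
              0.1 * per)
  }
})

test_that("one cycle converts to one year of growth", {
  expect_equal(growthRateFromPeriod(13.5), 13.5)
  expect_equal(growthRateFromPeriod(20), 20)
  expect_equal(growthRateFromPeriod(1), 1)
  expect_error(growthRateFromPeriod(-2), "positive")
})

test_that("date assignment anchors the gingival sample and steps back one year per period", {
  prof <- baleenProfile(0:96, rnorm(97))
  dated <- assignDates(prof, 13.5, "1891-03-01")
  dts <- sampleDates(dated)
  expect_equal(dts[1], as.Date("1891-03-01"))
  ## 24 days before the 1891-03-25 stranding
  expect_equal(as.numeric(as.Date("1891-03-25") - dts[1]), 24)
  ## 13.5 cm is one year
  i <- which(dated@distanceCm == 13.5)
  expect_length(i, 0L)                       # integer grid: check 13 + 14 bracket
  expect_lt(abs(as.numeric(dts[1] - dts[which(dated@distanceCm == 27)]) - 2 * 365.25), 2)
  ## monotone: deeper is strictly older
  expect_true(all(diff(as.integer(dts)) < 0))
})

test_that("cross-correlation matches a brute-force oracle and locates shifts", {
  x <- sin(2 * pi * (0:60) / 12)
  expect_equal(crossCorrelation(x, x, 5)$r[6], 1)
  expect_equal(crossCorrelation(x, -x, 5)$r[6], -1)

  ## y delayed by k samples peaks at lag k
  k <- 4
  y <- c(rep(0, k), x)[seq_along(x)]
  cc <- crossCorrelation(x, y, 8)
  expect_equal(cc$lag[which.max(cc$r)], k)

  ## brute-force oracle on random short series
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(20:64, 1)
    a <- rnorm(n); b <- rnorm(n)
    L <- 6
    cc <- crossCorrelation(a, b, L)
    for (lag in -L:L) {
      idx <- if (lag >= 0) cbind(1:(n - lag), (1 + lag):n)
             else cbind((1 - lag):n, 1:(n + lag))
      u <- a[idx[, 1]]; v <- b[idx[, 2]]
      oracle <- sum((u - mean(u)) * (v - mean(v))) /
        sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
      expect_lt(abs(cc$r[cc$lag == lag] - oracle), 1e-10)
    }
  }
  expect_error(crossCorrelation(rep(1, 30), rnorm(30), 3), "constant")
})

test_that("phase segmentation covers the profile contiguously", {
  prof <- baleenProfile(0:96, rnorm(97))
  seg <- segmentPhases(prof, c(26, 76))
  ph <- seg@phases
  expect_equal(nrow(ph), 3L)
  expect_equal(ph$startCm, c(0, 26, 76))
  expect_equal(ph$endCm, c(26, 76, 97))
  expect_equal(sum(ph$n), 97L)

  single <- segmentPhases(prof)
  expect_equal(nrow(single@phases), 1L)
  expect_error(segmentPhases(prof, 200), "outside")
  expect_error(segmentPhases(prof, c(40, 30)), "increasing")
})

test_that("full calibration of the synthetic baleen stand-in recovers its growth rate", {
  prof <- truthFixture("migratory_profile")
  cal <- calibrateProfile(prof, "1891-03-01")
  expect_lt(abs(cal@periodCm - 13.5) / 13.5, 0.1)
  expect_lt(abs(cal@growthRate - 13.5) / 13.5, 0.1)
  expect_lt(cal@pValue, 0.001)
  ## the d15N record is ~7 annual cycles: peak spacing agrees roughly
  expect_lt(abs(cal@peakSpacingCm - 13.5), 3)
  expect_equal(cal@sampleDates[1], as.Date("1891-03-01"))
})
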