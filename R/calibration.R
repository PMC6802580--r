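## Time calibration: baleen grows at an approximately constant rate and
## seasonal behaviour imprints an annual cycle on d15N, so the dominant
## periodicity of the d15N profile (in cm) estimates the annual growth
## rate (in cm per year), which converts distance along the plate to
## calendar time.

#' Dominant periodicity of a uniformly sampled series
#'
#' Periodogram estimate: the series is linearly detrended (raw trends
#' leak power into low frequencies) and its periodogram evaluated on an
#' 8x zero-padded FFT grid (rounded up to a power of two), which is what
#' limits the attainable period resolution; for a 97-sample series at
#' 1 cm this is about 0.18 cm near a 13.5 cm period.  The reported
#' period is the reciprocal of the frequency maximising the periodogram,
#' restricted to periods no longer than half the record; at exactly tied
#' maxima the lowest frequency wins.  A Fisher g-test p-value computed
#' on the unpadded periodogram is attached: peaks with
#' \code{p >= alpha} should not be claimed as periodicity (the default
#' alpha of 0.001 demands strong evidence, as befits an argmax search).
#'
#' @param x series values at uniform spacing (at least 16, not constant).
#' @param spacingCm sample spacing, cm.
#' @param padFactor zero-padding factor for the frequency grid.
#' @return the period in cm, with attributes \code{resolutionCm} (grid
#'   resolution at the peak), \code{pValue} (Fisher g-test) and
#'   \code{frequency} (cycles per cm).
#' @export
estimatePeriod <- function(x, spacingCm = 1, padFactor = 8) {
  n <- length(x)
  if (n < 16) stop("series too short for period estimation (need >= 16 samples)")
  if (sd(x) == 0) stop("no periodic signal: series is constant")
  xd <- resid(lm(x ~ seq_len(n)))
  nfft <- 2^ceiling(log2(padFactor * n))
  P <- Mod(fft(c(xd, rep(0, nfft - n))))^2
  k <- seq_len(nfft %/% 2)                    # positive frequencies
  freq <- k / (nfft * spacingCm)
  ok <- freq >= 2 / (n * spacingCm)           # period <= half the record
  kk <- k[ok]
  kmax <- kk[which.max(P[kk + 1])]            # first max = lowest frequency
  fstar <- kmax / (nfft * spacingCm)
  period <- 1 / fstar

  ## Fisher g on the raw (unpadded) periodogram
  P0 <- Mod(fft(xd))^2
  m <- floor((n - 1) / 2)
  I0 <- P0[2:(m + 1)]
  g <- max(I0) / sum(I0)
  jmax <- min(floor(1 / g), m)
  terms <- vapply(seq_len(jmax), function(j)
    (-1)^(j - 1) * exp(lchoose(m, j) + (m - 1) * log1p(-j * g)), numeric(1))
  pval <- min(max(sum(terms), 0), 1)

  structure(period,
            resolutionCm = period^2 / (nfft * spacingCm),
            pValue = pval, frequency = fstar)
}

## prominence of a local maximum: height above the higher of the two
## saddle minima separating it from taller terrain (or the record edge)
.peakProminence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    leftMin <- h; i <- p
    while (i > 1) { i <- i - 1; leftMin <- min(leftMin, x[i]); if (x[i] > h) break }
    rightMin <- h; i <- p
    while (i < length(x)) { i <- i + 1; rightMin <- min(rightMin, x[i]); if (x[i] > h) break }
    h - max(leftMin, rightMin)
  }, numeric(1))
}

#' Mean spacing between successive isotopic peaks
#'
#' The distance between successive peaks (local maxima exceeding a
#' prominence threshold) is an independent estimate of the annual growth
#' increment, complementary to the periodogram.
#'
#' @param x series values at uniform spacing.
#' @param spacingCm sample spacing, cm.
#' @param minProminence minimum peak prominence; defaults to half the
#'   series standard deviation.
#' @return mean peak-to-peak distance, cm, with attribute
#'   \code{peaksCm} (peak positions).
#' @export
peakSpacing <- function(x, spacingCm = 1, minProminence = 0.5 * sd(x)) {
  n <- length(x)
  if (n < 3) stop("insufficient signal: series too short")
  cand <- which(diff(sign(diff(x))) < 0) + 1L   # local maxima
  if (length(cand) > 1) {
    ## a flat-topped peak sampled as two equal values yields adjacent
    ## candidates; collapse each adjacent run to its centre
    grp <- cumsum(c(1L, diff(cand) > 1L))
    cand <- as.integer(round(tapply(cand, grp, mean)))
  }
  if (length(cand)) cand <- cand[.peakProminence(x, cand) >= minProminence]
  if (length(cand) < 2)
    stop("insufficient signal: fewer than 2 peaks above the prominence threshold")
  structure(mean(diff(cand)) * spacingCm,
            peaksCm = (cand - 1) * spacingCm)
}

#' Growth rate from an annual periodicity
#'
#' Under the assumption that one isotopic cycle represents one year of
#' growth, the growth rate in cm per year is numerically equal to the
#' periodicity in cm.
#'
#' @param periodCm dominant periodicity, cm.
#' @return growth rate, cm per year.
#' @export
growthRateFromPeriod <- function(periodCm) {
  if (any(periodCm <= 0)) stop("period must be positive")
  periodCm
}

#' Assign calendar dates to profile samples
#'
#' Constant-growth date model: the sample at distance d from the
#' gingival end is dated \code{anchorDate - round(365.25 * d / g)} days,
#' so the gingival-most sample carries the anchor date and dates
#' decrease strictly with distance.
#'
#' @param profile a \code{\linkS4class{BaleenProfile}}.
#' @param growthRate growth rate g, cm per year.
#' @param anchorDate date of the gingival-most sample.
#' @return the profile with dates filled in.
#' @export
assignDates <- function(profile, growthRate, anchorDate) {
  stopifnot(is(profile, "BaleenProfile"))
  if (growthRate <= 0) stop("growth rate must be positive")
  profile@dates <- as.Date(anchorDate) -
    round(365.25 * profile@distanceCm / growthRate)
  validObject(profile)
  profile
}

#' Normalised cross-correlation between two series
#'
#' Pearson correlation of the overlapping segments at each lag:
#' \code{r(k) = cor(x[t], y[t + k])}, guaranteed to lie in [-1, 1].
#' Positive lags mean y is shifted later (a y that equals x delayed by k
#' samples peaks at lag k).
#'
#' @param x,y equal-length non-constant series.
#' @param maxLag largest lag, samples (must leave at least 3
#'   overlapping pairs).
#' @return data.frame with columns \code{lag} and \code{r}.
#' @export
crossCorrelation <- function(x, y, maxLag) {
  n <- length(x)
  if (length(y) != n) stop("series must have equal length")
  if (n <= maxLag + 2) stop("series too short for the requested maximum lag")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant input series")
  lags <- -maxLag:maxLag
  r <- vapply(lags, function(k) {
    if (k >= 0) cor(x[1:(n - k)], y[(1 + k):n])
    else cor(x[(1 - k):n], y[1:(n + k)])
  }, numeric(1))
  data.frame(lag = lags, r = r)
}

#' Segment a profile into behavioural phases
#'
#' Phase boundaries are operator-supplied (the record is divided into
#' behavioural phases by inspection of the d13C and d15N patterns, not
#' by an automated changepoint method).  Phases are contiguous
#' half-open intervals \code{[startCm, endCm)} covering the full
#' profile, counted from the gingival end.
#'
#' @param profile a \code{\linkS4class{BaleenProfile}}.
#' @param boundariesCm strictly increasing interior boundaries, cm;
#'   empty for a single phase.
#' @param labels optional phase labels (length = number of phases).
#' @return a \code{\linkS4class{PhaseSegmentation}} with per-phase mean,
#'   SD and amplitude (max - min) of d13C.
#' @export
segmentPhases <- function(profile, boundariesCm = numeric(), labels = NULL) {
  stopifnot(is(profile, "BaleenProfile"))
  extent <- max(profile@distanceCm) + profile@spacingCm
  if (length(boundariesCm)) {
    if (any(diff(boundariesCm) <= 0)) stop("boundaries must be strictly increasing")
    if (min(boundariesCm) <= 0 || max(boundariesCm) >= extent)
      stop("boundary outside the profile extent")
  }
  edges <- c(0, boundariesCm, extent)
  k <- length(edges) - 1
  if (is.null(labels)) labels <- paste0("P", seq_len(k))
  if (length(labels) != k) stop("need one label per phase")
  rows <- lapply(seq_len(k), function(p) {
    inPhase <- profile@distanceCm >= edges[p] & profile@distanceCm < edges[p + 1]
    v <- profile@d13c[inPhase]
    data.frame(startCm = edges[p], endCm = edges[p + 1], label = labels[p],
               n = sum(inPhase),
               meanD13c = if (length(v)) mean(v) else NA_real_,
               sdD13c = if (length(v) > 1) sd(v) else NA_real_,
               amplitude = if (length(v)) diff(range(v)) else NA_real_)
  })
  new("PhaseSegmentation", phases = do.call(rbind, rows))
}

#' Full time calibration of a baleen profile
#'
#' Runs both growth-rate estimators (periodogram periodicity and mean
#' peak spacing) on the chosen isotope column, converts the periodogram
#' period to a growth rate, and dates every sample from the anchor.
#' The two estimators are reported side by side; the periodogram drives
#' the date assignment.
#'
#' @param profile a \code{\linkS4class{BaleenProfile}} carrying the
#'   chosen column.
#' @param anchorDate date assumed for the gingival-most sample.
#' @param column \code{"d15n"} (default; the nitrogen cycle is used for
#'   calibration so carbon stays free for movement inference) or
#'   \code{"d13c"}.
#' @param ... passed to \code{\link{estimatePeriod}}.
#' @return a \code{\linkS4class{CalibrationResult}}.
#' @export
calibrateProfile <- function(profile, anchorDate, column = c("d15n", "d13c"),
                             ...) {
  stopifnot(is(profile, "BaleenProfile"))
  column <- match.arg(column)
  x <- if (column == "d15n") profile@d15n else profile@d13c
  if (!length(x)) stop("profile carries no ", column, " values")
  per <- estimatePeriod(x, profile@spacingCm, ...)
  spacing <- tryCatch(peakSpacing(x, profile@spacingCm),
                      error = function(e) NA_real_)
  g <- growthRateFromPeriod(as.numeric(per))
  dated <- assignDates(profile, g, anchorDate)
  new("CalibrationResult", periodCm = as.numeric(per),
      periodResolutionCm = attr(per, "resolutionCm"),
      pValue = attr(per, "pValue"),
      peakSpacingCm = as.numeric(spacing), growthRate = g,
      anchorDate = as.Date(anchorDate), sampleDates = dated@dates,
      spacingCm = profile@spacingCm)
}
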