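#' Construct a BaleenProfile
#'
#' @param distanceCm distances from the gingival end, cm, strictly
#'   increasing and uniformly spaced.
#' @param d13c carbon isotope values, per mil VPDB.
#' @param d15n optional nitrogen isotope values, per mil AIR.
#' @param pctC,pctN optional weight-percent elemental composition.
#' @param dates optional per-sample calendar dates.
#' @return a \code{\linkS4class{BaleenProfile}}.
#' @export
baleenProfile <- function(distanceCm, d13c, d15n = numeric(),
                          pctC = numeric(), pctN = numeric(),
                          dates = as.Date(character())) {
  new("BaleenProfile", distanceCm = as.numeric(distanceCm),
      d13c = as.numeric(d13c), d15n = as.numeric(d15n),
      pctC = as.numeric(pctC), pctN = as.numeric(pctN),
      dates = as.Date(dates),
      spacingCm = if (length(distanceCm) > 1) diff(distanceCm)[1] else 1)
}

#' Read a baleen profile from CSV
#'
#' Expects columns \code{distance_cm} and \code{d13c}; columns
#' \code{d15n}, \code{pct_c}, \code{pct_n} and \code{date} are picked up
#' when present.  Non-uniform spacing triggers a warning (downstream
#' calibration assumes equal spacing through time).
#'
#' @param path CSV file.
#' @return a \code{\linkS4class{BaleenProfile}}.
#' @export
readProfile <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("distance_cm", "d13c")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("format error: missing required column(s): ",
         paste(missing, collapse = ", "))
  dd <- diff(d$distance_cm)
  if (length(dd) && max(abs(dd - dd[1])) > 1e-6 * max(1, abs(dd[1])))
    warning("non-uniform sample spacing in ", basename(path))
  baleenProfile(d$distance_cm, d$d13c,
                d15n = if ("d15n" %in% names(d)) d$d15n else numeric(),
                pctC = if ("pct_c" %in% names(d)) d$pct_c else numeric(),
                pctN = if ("pct_n" %in% names(d)) d$pct_n else numeric(),
                dates = if ("date" %in% names(d)) as.Date(d$date) else as.Date(character()))
}

#' Write a baleen profile to CSV
#'
#' @param profile a \code{\linkS4class{BaleenProfile}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "BaleenProfile"))
  d <- profileData(profile)
  if ("date" %in% names(d)) d$date <- format(d$date)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Carbon-to-nitrogen mass ratio of profile samples
#'
#' Computed from the weight-percent columns as \code{pct_c / pct_n}, the
#' convention for keratin quality control (pure keratin is expected near
#' 3.4; multiply by 14/12 for the atomic ratio).
#'
#' @param profile a \code{\linkS4class{BaleenProfile}} carrying pct_c
#'   and pct_n.
#' @return numeric vector of C:N mass ratios with a \code{"range"}
#'   attribute.
#' @export
cnRatio <- function(profile) {
  stopifnot(is(profile, "BaleenProfile"))
  if (!length(profile@pctC) || !length(profile@pctN))
    stop("profile carries no elemental composition columns")
  r <- profile@pctC / profile@pctN
  attr(r, "range") <- range(r)
  r
}
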