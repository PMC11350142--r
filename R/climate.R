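#' @useDynLib worldseasons, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd rnorm runif setNames coef
#' @importFrom utils read.csv write.csv combn head
NULL

# lowercase month keys used throughout (column names, reference CSVs)
MONTH_KEYS <- tolower(month.abb)

# denominator floor for monthly aridity when PET is (near) zero, in mm
PET_FLOOR_MM <- 0.1

#' Monthly midpoint temperature
#'
#' The temperature variable used throughout the classifier is the midpoint
#' between the monthly minimum and monthly maximum temperature.
#'
#' @param tmin,tmax numeric vectors of equal length (degrees Celsius),
#'   calendar order January..December.
#' @return numeric vector `(tmin + tmax) / 2`.
#' @examples
#' midpoint_temperature(rep(10, 12), rep(20, 12))
#' @export
midpoint_temperature <- function(tmin, tmax) {
  if (length(tmin) != length(tmax))
    stop("tmin and tmax must have equal length")
  bad <- which(!is.finite(tmin) | !is.finite(tmax))
  if (length(bad))
    stop("non-finite temperature at month index ", paste(bad, collapse = ", "))
  (tmin + tmax) / 2
}

#' Aggregate a dated series to monthly climatological means
#'
#' Pools all observations falling in each calendar month (across years) and
#' averages them, yielding a 12-value climatology. Months with no
#' observations propagate `NA` rather than raising an error.
#'
#' @param values numeric observations (e.g. weekly NDVI composites).
#' @param dates `Date` vector (or coercible) parallel to `values`.
#' @return numeric vector of length 12, January..December.
#' @export
monthly_from_weekly <- function(values, dates) {
  if (length(values) != length(dates))
    stop("values and dates must have equal length")
  dates <- as.Date(dates)
  m <- as.integer(format(dates, "%m"))
  out <- rep(NA_real_, 12)
  for (i in seq_len(12)) {
    v <- values[m == i & !is.na(values)]
    if (length(v)) out[i] <- mean(v)
  }
  out
}

#' Circular month-over-month lag
#'
#' First difference of a 12-month series computed circularly: the January
#' lag is January minus December. The sign captures whether a variable is
#' rising or falling, which separates e.g. spring (warming) from autumn
#' (cooling). The twelve lags of any series sum to zero.
#'
#' @param v numeric vector of length 12.
#' @return numeric vector of length 12 of differences `v[m] - v[m-1]`.
#' @export
circular_lag <- function(v) {
  if (length(v) != 12) stop("circular_lag expects a 12-month vector")
  v - v[c(12, 1:11)]
}

#' Z-score normalization with a zero-variance guard
#'
#' Centers and scales by the sample (n-1) standard deviation so that each
#' variable contributes comparably to cluster distances irrespective of its
#' unit. Constant (or all-missing) vectors normalize to zeros rather than
#' NaN, which makes degenerate features (e.g. NDVI lag over barren desert)
#' drop out of the distance silently.
#'
#' @param v numeric vector; `NA` allowed.
#' @return numeric vector of the same length.
#' @export
znormalize <- function(v) {
  m <- mean(v, na.rm = TRUE)
  s <- sd(v, na.rm = TRUE)
  if (!is.finite(m) || !is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - m) / s
}

#' Assemble a single-location climate record with derived features
#'
#' Bundles the twelve-month climate normals of one grid cell and derives the
#' fields the classifier consumes: midpoint temperature, monthly aridity
#' (precipitation / PET, denominator floored at 0.1 mm), and circular lags
#' of temperature, NDVI, and precipitation.
#'
#' @param tmin,tmax monthly minimum / maximum temperature, deg C, length 12.
#' @param precip monthly precipitation, mm.
#' @param srad monthly solar radiation (any consistent unit).
#' @param ndvi monthly NDVI in -1..1, or `NULL` if unavailable (the NDVI lag
#'   then degenerates to zeros via the normalization guard).
#' @param pet monthly potential evapotranspiration, mm; may be `NULL` when a
#'   precomputed `aridity` vector is supplied.
#' @param aridity optional precomputed monthly aridity ratio.
#' @return an object of class `pixel_climate`: a list of 12-vectors
#'   `tmin, tmax, tmid, precip, srad, ndvi, pet, aridity, lag_tmid,
#'   lag_ndvi, lag_precip`, with attribute `pet_floored` marking months
#'   where the PET floor was applied.
#' @export
pixel_climate <- function(tmin, tmax, precip, srad, ndvi = NULL, pet = NULL,
                          aridity = NULL) {
  for (nm in c("tmin", "tmax", "precip", "srad")) {
    v <- get(nm)
    if (length(v) != 12) stop(nm, " must have length 12")
  }
  if (is.null(ndvi)) ndvi <- rep(NA_real_, 12)
  if (length(ndvi) != 12) stop("ndvi must have length 12")
  bad <- which(is.finite(tmin) & is.finite(tmax) & tmin > tmax)
  if (length(bad))
    stop("tmin exceeds tmax at month index ", paste(bad, collapse = ", "))
  floored <- integer(0)
  if (is.null(aridity)) {
    if (is.null(pet)) stop("either pet or aridity must be supplied")
    if (length(pet) != 12) stop("pet must have length 12")
    floored <- which(is.finite(pet) & pet < PET_FLOOR_MM)
    aridity <- precip / pmax(pet, PET_FLOOR_MM)
  } else {
    if (length(aridity) != 12) stop("aridity must have length 12")
    if (is.null(pet)) pet <- rep(NA_real_, 12)
  }
  if (any(is.finite(aridity) & aridity < 0)) stop("aridity must be >= 0")
  tmid <- (tmin + tmax) / 2
  px <- list(
    tmin = tmin, tmax = tmax, tmid = tmid, precip = precip, srad = srad,
    ndvi = ndvi, pet = pet, aridity = aridity,
    lag_tmid = circular_lag(tmid),
    lag_ndvi = if (all(is.finite(ndvi))) circular_lag(ndvi) else rep(NA_real_, 12),
    lag_precip = circular_lag(precip)
  )
  attr(px, "pet_floored") <- floored
  class(px) <- "pixel_climate"
  px
}

#' @export
print.pixel_climate <- function(x, ...) {
  cat("<pixel_climate>\n")
  tab <- rbind(tmid = x$tmid, precip = x$precip, srad = x$srad,
               ndvi = x$ndvi, aridity = x$aridity)
  colnames(tab) <- month.abb
  print(round(tab, 2))
  invisible(x)
}
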