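# Coordinate projection and solar day/night classification.
#
# The spatial model works in planar Universal Transverse Mercator (UTM)
# coordinates; the whole study domain is projected into a single zone
# (zone 28, central meridian 15 W, covering the spawning grounds west of
# the British Isles) to avoid distortions from the curvature of the earth.
# Day/night classification follows the civil-dawn convention: night is when
# the sun is six degrees or more below the horizon.

# WGS84 ellipsoid
.WGS84_A <- 6378137
.WGS84_F <- 1 / 298.257223563

# Krueger series coefficients for the transverse Mercator mapping, expanded
# in the third flattening n (Karney-style, order n^6; millimetre-accurate
# well beyond the width of the study domain).
.tm_consts <- local({
  f <- .WGS84_F
  n <- f / (2 - f)
  n2 <- n^2; n3 <- n^3; n4 <- n^4; n5 <- n^5; n6 <- n^6
  list(
    e = sqrt(f * (2 - f)),
    A1 = .WGS84_A / (1 + n) * (1 + n2 / 4 + n4 / 64 + n6 / 256),
    alpha = c(
      n / 2 - 2 / 3 * n2 + 5 / 16 * n3 + 41 / 180 * n4 - 127 / 288 * n5 +
        7891 / 37800 * n6,
      13 / 48 * n2 - 3 / 5 * n3 + 557 / 1440 * n4 + 281 / 630 * n5 -
        1983433 / 1935360 * n6,
      61 / 240 * n3 - 103 / 140 * n4 + 15061 / 26880 * n5 +
        167603 / 181440 * n6,
      49561 / 161280 * n4 - 179 / 168 * n5 + 6601661 / 7257600 * n6,
      34729 / 80640 * n5 - 3418889 / 1995840 * n6,
      212378941 / 319334400 * n6),
    beta = c(
      n / 2 - 2 / 3 * n2 + 37 / 96 * n3 - 1 / 360 * n4 - 81 / 512 * n5 +
        96199 / 604800 * n6,
      1 / 48 * n2 + 1 / 15 * n3 - 437 / 1440 * n4 + 46 / 105 * n5 -
        1118711 / 3870720 * n6,
      17 / 480 * n3 - 37 / 840 * n4 - 209 / 4480 * n5 + 5569 / 90720 * n6,
      4397 / 161280 * n4 - 11 / 504 * n5 - 830251 / 7257600 * n6,
      4583 / 161280 * n5 - 108847 / 3991680 * n6,
      20648693 / 638668800 * n6))
})

.UTM_K0 <- 0.9996
.UTM_FE <- 5e5

#' Project geographic coordinates to UTM
#'
#' Maps WGS84 longitude/latitude to planar UTM eastings and northings
#' (metres) using a high-order transverse Mercator series. The northern
#' hemisphere convention is used (no false northing), and the zone is not
#' inferred from the longitude: the whole domain is projected into the one
#' requested zone, as required when a single planar coordinate system must
#' cover the full spawning area.
#'
#' @param lon,lat numeric vectors of degrees east (-180..180) and degrees
#'   north. Latitudes must lie in -80..84 (the UTM validity band).
#' @param zone UTM zone number (1..60); default 28 (central meridian 15 W).
#' @return a data.frame with columns `east` and `north` in metres.
#' @examples
#' utm_project(-15, 53)   # on the central meridian: east = 500000
#' @export
utm_project <- function(lon, lat, zone = 28L) {
  stopifnot(length(zone) == 1L, zone >= 1, zone <= 60)
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("utm_project: lon/lat must be finite")
  if (any(lon < -180 | lon > 180))
    stop("utm_project: longitude outside [-180, 180]")
  if (any(lat < -80 | lat > 84))
    stop("utm_project: latitude outside the UTM band [-80, 84]")
  cc <- .tm_consts
  lon0 <- (zone * 6 - 183) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180 - lon0
  tau <- tan(phi)
  sig <- sinh(cc$e * atanh(cc$e * tau / sqrt(1 + tau^2)))
  taup <- tau * sqrt(1 + sig^2) - sig * sqrt(1 + tau^2)
  xip <- atan2(taup, cos(lam))
  etap <- asinh(sin(lam) / sqrt(taup^2 + cos(lam)^2))
  xi <- xip
  eta <- etap
  for (j in 1:6) {
    xi <- xi + cc$alpha[j] * sin(2 * j * xip) * cosh(2 * j * etap)
    eta <- eta + cc$alpha[j] * cos(2 * j * xip) * sinh(2 * j * etap)
  }
  data.frame(east = .UTM_FE + .UTM_K0 * cc$A1 * eta,
             north = .UTM_K0 * cc$A1 * xi)
}

#' Inverse UTM projection
#'
#' Inverse of [utm_project()]: recovers WGS84 longitude/latitude from UTM
#' eastings/northings (northern-hemisphere convention). Round-trip error is
#' far below 1 m over the study domain.
#'
#' @param east,north numeric vectors, metres.
#' @param zone UTM zone number (1..60).
#' @return data.frame with columns `lon`, `lat` in degrees.
#' @export
utm_unproject <- function(east, north, zone = 28L) {
  stopifnot(length(zone) == 1L, zone >= 1, zone <= 60)
  if (any(!is.finite(east)) || any(!is.finite(north)))
    stop("utm_unproject: east/north must be finite")
  cc <- .tm_consts
  lon0 <- (zone * 6 - 183) * pi / 180
  xi <- north / (.UTM_K0 * cc$A1)
  eta <- (east - .UTM_FE) / (.UTM_K0 * cc$A1)
  xip <- xi
  etap <- eta
  for (j in 1:6) {
    xip <- xip - cc$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    etap <- etap - cc$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  taup <- sin(xip) / sqrt(sinh(etap)^2 + cos(xip)^2)
  # Newton iteration for tan(latitude) given the conformal tangent
  e <- cc$e
  tau <- taup / (1 - e^2)
  for (it in 1:8) {
    sig <- sinh(e * atanh(e * tau / sqrt(1 + tau^2)))
    ftau <- tau * sqrt(1 + sig^2) - sig * sqrt(1 + tau^2) - taup
    dtau <- (sqrt(1 + sig^2) * sqrt(1 + tau^2) - sig * tau) * (1 - e^2) *
      sqrt(1 + tau^2) / (1 + (1 - e^2) * tau^2)
    tau <- tau - ftau / dtau
  }
  lam <- atan2(sinh(etap), cos(xip))
  data.frame(lon = (lam + lon0) * 180 / pi, lat = atan(tau) * 180 / pi)
}

#' Apparent solar elevation
#'
#' Solar elevation angle (degrees above the horizon) at a given UTC instant
#' and position, via the low-precision almanac formulas (mean solar
#' longitude and anomaly, ecliptic longitude, declination from the mean
#' obliquity, and sidereal-time hour angle). Accuracy is of order 0.01
#' degrees over 1900-2100 — far tighter than needed for a -6 degree
#' day/night threshold. No atmospheric refraction correction is applied.
#'
#' @param time a `POSIXct` vector (UTC) or strings parseable as ISO-8601 UTC.
#' @param lon,lat position in degrees.
#' @return numeric vector of elevations, degrees.
#' @export
solar_elevation <- function(time, lon, lat) {
  if (is.character(time)) time <- parse_utc(time)
  stopifnot(inherits(time, "POSIXct"))
  yr <- as.integer(format(time, "%Y", tz = "UTC"))
  if (any(yr < 1900 | yr > 2100))
    stop("solar_elevation: instants must lie within 1900-2100")
  d2r <- pi / 180
  # days since J2000.0 (2000-01-01 12:00 UTC)
  nd <- (as.numeric(time) - 946728000) / 86400
  L <- (280.460 + 0.9856474 * nd) %% 360
  g <- ((357.528 + 0.9856003 * nd) %% 360) * d2r
  lam <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * d2r
  eps <- (23.439 - 0.0000004 * nd) * d2r
  dec <- asin(sin(eps) * sin(lam))
  ra <- atan2(cos(eps) * sin(lam), cos(lam))
  gmst <- (280.46061837 + 360.98564736629 * nd) %% 360
  H <- (gmst + lon - ra / d2r) * d2r
  phi <- lat * d2r
  elev <- asin(sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(H))
  elev / d2r
}

#' Day/night classification from solar elevation
#'
#' Civil-dawn convention: night is when the sun is six degrees or more
#' below the horizon (elevation <= -6); civil twilight counts as day.
#'
#' @param elevation numeric vector, degrees above horizon.
#' @return factor with levels `day`, `night`.
#' @export
classify_daynight <- function(elevation) {
  if (any(!is.finite(elevation)))
    stop("classify_daynight: elevation must be finite")
  factor(ifelse(elevation <= -6, "night", "day"), levels = c("day", "night"))
}

#' Parse ISO-8601 UTC timestamps
#'
#' Strict parser for `YYYY-MM-DDTHH:MM:SS` (optionally suffixed `Z`, or
#' with a space instead of `T`). Anything else, including offsets other
#' than Z, yields `NA` — silent local-time guessing is deliberately not
#' supported.
#'
#' @param x character vector.
#' @return POSIXct (UTC) with `NA` for unparseable entries.
#' @export
parse_utc <- function(x) {
  x <- sub("Z$", "", sub(" ", "T", x))
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$", x)
  out <- as.POSIXct(rep(NA_character_, length(x)), tz = "UTC")
  out[ok] <- as.POSIXct(x[ok], format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out
}

# Day of year on a fixed 365-day cycle: Feb 29 shares doy 60 with Mar 1.
doy365 <- function(time) {
  yd <- as.integer(format(time, "%j", tz = "UTC"))
  yr <- as.integer(format(time, "%Y", tz = "UTC"))
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
  ifelse(leap & yd > 60, yd - 1L, yd)
}

#' Append derived model covariates to an observation table
#'
#' Adds the covariates the spatiotemporal model is built on: projected
#' coordinates `east`/`north` (metres, UTM), `doy` (day of year on a
#' 365-day cycle; Feb 29 maps to 60), `year`, solar elevation
#' `solar_elev_deg` and the day/night factor `dn`.
#'
#' @param df data.frame with columns `lon`, `lat` and `datetime_utc`
#'   (POSIXct or ISO-8601 strings).
#' @param zone UTM zone used for projection.
#' @return the input with derived columns appended.
#' @export
derive_covariates <- function(df, zone = 28L) {
  stopifnot(all(c("lon", "lat", "datetime_utc") %in% names(df)))
  tm <- df$datetime_utc
  if (is.character(tm)) tm <- parse_utc(tm)
  pr <- utm_project(df$lon, df$lat, zone = zone)
  df$east <- pr$east
  df$north <- pr$north
  df$doy <- doy365(tm)
  df$year <- as.integer(format(tm, "%Y", tz = "UTC"))
  df$solar_elev_deg <- solar_elevation(tm, df$lon, df$lat)
  df$dn <- classify_daynight(df$solar_elev_deg)
  df
}
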