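# Synthetic CPR-like survey generator.
#
# A known two-component spawning "truth" — Gaussian spatial bumps in
# projected coordinates, Gaussian seasonal windows on a circular
# day-of-year axis, component-specific interannual trends and a day/night
# catchability offset — is sampled along ship-of-opportunity style routes
# (points every 10 nautical miles, a mid-month-peaked within-month
# sampling cycle, year-dependent route coverage emulating the reduced
# Rockall coverage after 1975). Presences are Bernoulli draws from the
# truth probability; observed abundances are categorical, as recorded by
# the CPR survey. The fitter never sees this functional form: downstream
# stages are validated by recovering its parameters.

#' One synthetic spawning component
#'
#' @param lon,lat geographic centre of the component (projected internally).
#' @param spatial_sd isotropic Gaussian spatial scale, metres.
#' @param peak_doy day of year of peak spawning (1..366).
#' @param seasonal_sd Gaussian seasonal width, days.
#' @param amplitude peak contribution on the logit scale.
#' @param year_trend function mapping year -> logit offset for this
#'   component (defaults to no trend).
#' @param name label.
#' @return list of class `bw_component`.
#' @export
spawning_component <- function(lon, lat, spatial_sd, peak_doy, seasonal_sd,
                               amplitude, year_trend = function(year) 0 * year,
                               name = "component") {
  stopifnot(peak_doy >= 1, peak_doy <= 366, spatial_sd > 0, seasonal_sd > 0)
  ctr <- utm_project(lon, lat)
  structure(list(name = name, lon = lon, lat = lat,
                 east = ctr$east, north = ctr$north,
                 spatial_sd = spatial_sd, peak_doy = peak_doy,
                 seasonal_sd = seasonal_sd, amplitude = amplitude,
                 year_trend = year_trend),
            class = "bw_component")
}

#' Truth configuration for the synthetic world
#'
#' @param components list of [spawning_component()]s (at least one).
#' @param base_logit background logit of presence far from all components.
#' @param dn_effect day-minus-night logit offset (the day/night
#'   catchability difference; positive means larvae are more catchable by
#'   day).
#' @param years inclusive integer range of years the truth is defined on.
#' @param seed default seed for simulation helpers.
#' @return list of class `bw_truth`.
#' @export
truth_config <- function(components, base_logit = -7.5, dn_effect = 0.17,
                         years = 1950:2005, seed = 1L) {
  if (inherits(components, "bw_component")) components <- list(components)
  stopifnot(length(components) >= 1,
            all(vapply(components, inherits, TRUE, "bw_component")))
  cfg <- structure(list(components = components, base_logit = base_logit,
                        dn_effect = dn_effect, years = years, seed = seed),
                   class = "bw_truth")
  # reject configurations that saturate the probability scale
  pk <- base_logit + sum(vapply(components, `[[`, 0, "amplitude")) +
    max(0, dn_effect) +
    sum(vapply(components, function(cp) max(cp$year_trend(years)), 0))
  if (!is.finite(pk) || pk >= 36 || base_logit <= -36)
    stop("truth_config: implied probabilities leave (0, 1)")
  cfg
}

# circular day-of-year distance on a 365-day cycle
circ_doy_dist <- function(doy, peak, period = 365) {
  d <- abs(doy - peak) %% period
  pmin(d, period - d)
}

#' Truth occurrence probability
#'
#' Evaluates the synthetic truth: inverse-logit of background + per
#' component amplitude x Gaussian spatial bump x Gaussian (circular)
#' seasonal window + that component's year trend (weighted by the same
#' bump, so the trend applies where the component lives) + the day/night
#' offset for daytime samples.
#'
#' @param cfg a `bw_truth`.
#' @param east,north position, metres (UTM).
#' @param doy day of year (1..366).
#' @param year calendar year within `cfg$years`.
#' @param dn `"day"` or `"night"` (vector ok).
#' @return vector of probabilities in (0, 1).
#' @export
truth_probability <- function(cfg, east, north, doy, year, dn) {
  stopifnot(inherits(cfg, "bw_truth"))
  if (any(doy < 1 | doy > 366)) stop("truth_probability: doy outside [1, 366]")
  if (any(!(year %in% cfg$years))) stop("truth_probability: year outside cfg$years")
  eta <- rep(cfg$base_logit, length(east))
  for (cp in cfg$components) {
    bump <- exp(-((east - cp$east)^2 + (north - cp$north)^2) /
                  (2 * cp$spatial_sd^2))
    season <- exp(-circ_doy_dist(doy, cp$peak_doy)^2 / (2 * cp$seasonal_sd^2))
    eta <- eta + bump * season * (cp$amplitude + cp$year_trend(year))
  }
  eta <- eta + cfg$dn_effect * (dn == "day")
  stats::plogis(eta)
}

#' Survey sampling design
#'
#' @param routes list of routes; each route is a list with `name`, `lon`,
#'   `lat` (polyline vertices, >= 2) and optional `years` (active years;
#'   default all).
#' @param segment_nmi nautical miles of tow per sample (default 10).
#' @param monthly_weight length-31 non-negative weights for the start day
#'   of each monthly traversal; default peaks mid-month, emulating the
#'   within-month sampling cycle of the survey.
#' @param knots ship speed used to space sample instants along a route.
#' @return list of class `bw_design_survey`.
#' @export
sampling_design <- function(routes, segment_nmi = 10,
                            monthly_weight = NULL, knots = 12) {
  stopifnot(segment_nmi > 0)
  for (r in routes) {
    stopifnot(!is.null(r$lon), !is.null(r$lat), length(r$lon) >= 2,
              length(r$lon) == length(r$lat))
  }
  if (is.null(monthly_weight))
    monthly_weight <- pmax(0, 1 - abs(seq_len(31) - 15.5) / 15)
  stopifnot(length(monthly_weight) == 31, all(monthly_weight >= 0),
            sum(monthly_weight) > 0)
  structure(list(routes = routes, segment_nmi = segment_nmi,
                 monthly_weight = monthly_weight, knots = knots),
            class = "bw_design_survey")
}

# great-circle distance in nautical miles (haversine)
gc_dist_nmi <- function(lon1, lat1, lon2, lat2) {
  d2r <- pi / 180
  a <- sin((lat2 - lat1) * d2r / 2)^2 +
    cos(lat1 * d2r) * cos(lat2 * d2r) * sin((lon2 - lon1) * d2r / 2)^2
  2 * asin(pmin(1, sqrt(a))) * 180 * 60 / pi
}

# points every step_nmi along a polyline (linear interpolation in lon/lat)
.route_points <- function(lon, lat, step_nmi) {
  seg <- gc_dist_nmi(lon[-length(lon)], lat[-length(lat)],
                     lon[-1], lat[-1])
  total <- sum(seg)
  if (total < step_nmi) return(data.frame(lon = numeric(0), lat = numeric(0),
                                          dist_nmi = numeric(0)))
  at <- seq(step_nmi / 2, total, by = step_nmi)  # sample midpoints
  cum <- c(0, cumsum(seg))
  i <- findInterval(at, cum, rightmost.closed = TRUE)
  fr <- (at - cum[i]) / seg[i]
  data.frame(lon = lon[i] + fr * (lon[i + 1] - lon[i]),
             lat = lat[i] + fr * (lat[i + 1] - lat[i]),
             dist_nmi = at)
}

#' Generate survey sample positions and instants
#'
#' Every route active in a given year is traversed once per month: sample
#' points are emitted every `segment_nmi` along the polyline, the
#' traversal start day is drawn from the within-month weight profile, and
#' instants advance along the route at the design's ship speed (so a
#' traversal spans day and night). Reproducible given the seed.
#'
#' @param design a [sampling_design()].
#' @param years integer vector of years to simulate.
#' @param seed integer seed.
#' @return data.frame with `lon`, `lat`, `datetime_utc` (POSIXct, UTC).
#' @export
generate_samples <- function(design, years, seed = 1L) {
  stopifnot(inherits(design, "bw_design_survey"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- vector("list", 0)
  mw <- design$monthly_weight / sum(design$monthly_weight)
  for (r in design$routes) {
    pts <- .route_points(r$lon, r$lat, design$segment_nmi)
    if (nrow(pts) == 0) next
    hours <- pts$dist_nmi / design$knots
    active <- if (is.null(r$years)) years else intersect(years, r$years)
    for (yr in active) {
      for (mo in 1:12) {
        ndays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[mo]
        day0 <- sample.int(31, 1, prob = mw)
        day0 <- min(day0, ndays)
        start <- as.POSIXct(sprintf("%04d-%02d-%02d 00:00:00", yr, mo, day0),
                            tz = "UTC") + round(stats::runif(1, 0, 24) * 3600)
        out[[length(out) + 1L]] <-
          data.frame(lon = pts$lon, lat = pts$lat,
                     datetime_utc = start + round(hours * 3600),
                     route = r$name %||% "route")
      }
    }
  }
  if (!length(out))
    return(data.frame(lon = numeric(0), lat = numeric(0),
                      datetime_utc = as.POSIXct(character(0), tz = "UTC"),
                      route = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' CPR abundance category scheme
#'
#' Ordered categories with inclusive count ranges. The default scheme is
#' 0; 1; 2; 3; 4-11; 12-25 — exact counts up to three larvae, ranges
#' beyond. Counts above the last range are clamped into it (the scheme is
#' extensible via `extra`).
#'
#' @param extra optional data.frame with columns `label`, `lo`, `hi` to
#'   append beyond 12-25.
#' @return data.frame with `label`, `lo`, `hi`, class `bw_categories`.
#' @export
abundance_scheme <- function(extra = NULL) {
  sch <- data.frame(label = c("0", "1", "2", "3", "4-11", "12-25"),
                    lo = c(0, 1, 2, 3, 4, 12),
                    hi = c(0, 1, 2, 3, 11, 25),
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) sch <- rbind(sch, extra)
  stopifnot(all(diff(sch$lo) > 0), all(sch$lo <= sch$hi),
            all(sch$lo[-1] == sch$hi[-nrow(sch)] + 1))
  structure(sch, class = c("bw_categories", "data.frame"))
}

#' Map counts to abundance category labels
#' @param count non-negative integer vector.
#' @param scheme an [abundance_scheme()].
#' @return character vector of labels.
#' @export
category_from_count <- function(count, scheme = abundance_scheme()) {
  stopifnot(all(count >= 0))
  count <- pmin(count, max(scheme$hi))  # clamp beyond the last range
  i <- findInterval(count, scheme$lo)
  scheme$label[i]
}

#' Inclusive count range of category labels
#' @param label character vector of category labels.
#' @param scheme an [abundance_scheme()].
#' @return data.frame with `lo`, `hi`.
#' @export
category_range <- function(label, scheme = abundance_scheme()) {
  i <- match(label, scheme$label)
  if (anyNA(i)) stop("category_range: unknown label(s): ",
                     paste(unique(label[is.na(i)]), collapse = ", "))
  data.frame(lo = scheme$lo[i], hi = scheme$hi[i])
}

#' Simulate presence/absence observations from the truth
#'
#' Derives the model covariates for each sample (projection, day of year,
#' day/night from solar elevation), draws presence from
#' `Bernoulli(truth_probability)` and, for presences, a count from a
#' geometric distribution (single larvae dominate, as in the survey's
#' category distribution) mapped through the category scheme. Absences get
#' category "0".
#'
#' @param cfg a `bw_truth`.
#' @param samples output of [generate_samples()] (or any table with `lon`,
#'   `lat`, `datetime_utc`).
#' @param seed integer seed.
#' @param count_prob success probability of the geometric count model for
#'   presences (counts are `1 + rgeom`).
#' @param scheme category scheme.
#' @return observation table: `id`, `lon`, `lat`, `datetime_utc`,
#'   `category_label`, plus derived `east`, `north`, `doy`, `year`, `dn`,
#'   `presence` and the true probability `p_true`.
#' @export
simulate_observations <- function(cfg, samples, seed = 1L, count_prob = 0.55,
                                  scheme = abundance_scheme()) {
  stopifnot(inherits(cfg, "bw_truth"))
  df <- derive_covariates(samples)
  df$p_true <- truth_probability(cfg, df$east, df$north, df$doy, df$year, df$dn)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(df)
  df$presence <- as.integer(stats::runif(n) < df$p_true)
  count <- integer(n)
  np <- sum(df$presence)
  if (np > 0) count[df$presence == 1L] <- 1L + stats::rgeom(np, count_prob)
  df$category_label <- category_from_count(count, scheme)
  df$id <- seq_len(n)
  df[c("id", "lon", "lat", "datetime_utc", "category_label", "east", "north",
       "doy", "year", "dn", "solar_elev_deg", "presence", "p_true")]
}

#' Default two-component spawning truth
#'
#' The stated synthetic world: a southern component off the Porcupine
#' Seabight (peak day-of-year 80) and a northern component in the Rockall
#' Trough (peak 120; a 40-day offset), the northern component larger in
#' amplitude and more protracted in season, distinct interannual trends
#' per component, a +0.17 logit day/night offset and a rare-presence
#' background, tuned once so that the default survey yields roughly 2%
#' presences overall.
#'
#' @param years year range of the truth.
#' @return a `bw_truth`.
#' @export
default_truth <- function(years = 1950:2005) {
  south <- spawning_component(
    lon = -12.5, lat = 50.0, spatial_sd = 170e3, peak_doy = 80,
    seasonal_sd = 30, amplitude = 6.1,
    year_trend = function(year) 0.9 - 0.03 * (year - 1950),
    name = "south")
  north <- spawning_component(
    lon = -9.5, lat = 56.5, spatial_sd = 210e3, peak_doy = 120,
    seasonal_sd = 38, amplitude = 7.6,
    year_trend = function(year) 0.6 * sin(2 * pi * (year - 1950) / 28),
    name = "north")
  truth_config(list(north = north, south = south), base_logit = -6.6,
               dn_effect = 0.17, years = years)
}

#' Default CPR-like sampling design
#'
#' Four ship-of-opportunity style routes west of the British Isles and
#' Ireland, each traversed monthly in 10-nautical-mile samples. The two
#' Rockall-area routes are active only through 1974, emulating the reduced
#' Rockall coverage after the closure of the ocean weather ships; the
#' remaining routes span the full period.
#'
#' @param rockall_until last active year of the Rockall routes.
#' @return a [sampling_design()].
#' @export
default_design <- function(rockall_until = 1974) {
  routes <- list(
    list(name = "rockall_west",
         lon = c(-6.5, -12.5), lat = c(55.7, 57.2),
         years = 1900:rockall_until),
    list(name = "north_channel",
         lon = c(-5.8, -7.5), lat = c(55.2, 57.6)),
    list(name = "hebrides_south",
         lon = c(-7.5, -9.5), lat = c(55.0, 52.5)),
    list(name = "ireland_west",
         lon = c(-7.0, -11.0), lat = c(53.4, 53.8)),
    list(name = "irish_shelf",
         lon = c(-8.5, -13.0), lat = c(51.3, 50.6)),
    list(name = "porcupine",
         lon = c(-10.0, -13.8), lat = c(51.2, 49.0)),
    list(name = "biscay_edge",
         lon = c(-6.0, -9.0), lat = c(49.0, 48.3)))
  sampling_design(routes)
}

#' Write / read the truth sidecar file
#'
#' Plain-text key-value record of a truth configuration, so recovery tests
#' and downstream users can compare fits against the generating truth.
#' Year trends are stored as values tabulated per year.
#'
#' @param cfg a `bw_truth`.
#' @param path file path.
#' @return `read_truth_sidecar` returns a list mirroring the config
#'   (with tabulated year trends).
#' @export
write_truth_sidecar <- function(cfg, path) {
  ln <- c(sprintf("base_logit=%.10g", cfg$base_logit),
          sprintf("dn_effect=%.10g", cfg$dn_effect),
          sprintf("years=%d:%d", min(cfg$years), max(cfg$years)))
  for (cp in cfg$components) {
    ln <- c(ln, sprintf(
      "component=%s lon=%.6f lat=%.6f east=%.3f north=%.3f spatial_sd=%.6g peak_doy=%g seasonal_sd=%.6g amplitude=%.6g trend=%s",
      cp$name, cp$lon, cp$lat, cp$east, cp$north, cp$spatial_sd,
      cp$peak_doy, cp$seasonal_sd, cp$amplitude,
      paste(sprintf("%.6g", cp$year_trend(cfg$years)), collapse = ",")))
  }
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_truth_sidecar
#' @export
read_truth_sidecar <- function(path) {
  ln <- readLines(path)
  kv <- function(key) sub(paste0("^", key, "="), "", grep(paste0("^", key, "="), ln, value = TRUE))
  yr <- as.integer(strsplit(kv("years"), ":")[[1]])
  comps <- lapply(grep("^component=", ln, value = TRUE), function(s) {
    fld <- strsplit(s, " ")[[1]]
    get1 <- function(key) sub(paste0("^", key, "="), "", grep(paste0("^", key, "="), fld, value = TRUE))
    list(name = get1("component"), lon = as.numeric(get1("lon")),
         lat = as.numeric(get1("lat")), east = as.numeric(get1("east")),
         north = as.numeric(get1("north")),
         spatial_sd = as.numeric(get1("spatial_sd")),
         peak_doy = as.numeric(get1("peak_doy")),
         seasonal_sd = as.numeric(get1("seasonal_sd")),
         amplitude = as.numeric(get1("amplitude")),
         trend = as.numeric(strsplit(get1("trend"), ",")[[1]]))
  })
  names(comps) <- vapply(comps, `[[`, "", "name")
  list(base_logit = as.numeric(kv("base_logit")),
       dn_effect = as.numeric(kv("dn_effect")),
       years = yr[1]:yr[2], components = comps)
}
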