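# Observation table readers/writers and region-of-interest filtering.
#
# The interchange format is a plain CSV with columns id, lon, lat,
# datetime_utc (ISO-8601 UTC) and category_label (the recorder's
# abundance categories). Reading converts categories to presence/absence
# (any non-zero category is a presence) and appends the derived model
# covariates. Timestamps must be ISO-8601 UTC; anything else is rejected
# rather than guessed.

#' Read an observation table
#'
#' Parses and validates a CSV of recorder samples, converts the abundance
#' category to a presence flag (`category_label != "0"`), and appends the
#' derived covariates (`east`, `north`, `doy`, `year`, `solar_elev_deg`,
#' `dn`). Malformed rows (bad coordinates, unparseable timestamps,
#' unknown categories) are collected with their file line numbers,
#' dropped with a warning, and attached as attribute `"malformed"`; more
#' than 1% malformed rows is a fatal error.
#'
#' @param path CSV file with header `id, lon, lat, datetime_utc,
#'   category_label`.
#' @param scheme abundance category scheme used for validation.
#' @param zone UTM zone for the projected covariates.
#' @return validated observation data.frame.
#' @export
read_observations <- function(path, scheme = abundance_scheme(),
                              zone = 28L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(category_label = "character"))
  need <- c("id", "lon", "lat", "datetime_utc", "category_label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_observations: missing columns: ", paste(miss, collapse = ", "))
  tm <- parse_utc(as.character(df$datetime_utc))
  bad_time <- is.na(tm)
  bad_lon <- !is.finite(df$lon) | df$lon < -180 | df$lon > 180
  bad_lat <- !is.finite(df$lat) | df$lat < -90 | df$lat > 90
  bad_cat <- !(df$category_label %in% scheme$label)
  bad <- bad_time | bad_lon | bad_lat | bad_cat
  if (any(bad)) {
    lines <- which(bad) + 1L   # header is line 1
    why <- ifelse(bad_lon[bad], "bad lon",
                  ifelse(bad_lat[bad], "bad lat",
                         ifelse(bad_time[bad], "bad datetime", "bad category")))
    report <- data.frame(line = lines, reason = why)
    if (mean(bad) > 0.01)
      stop(sprintf(
        "read_observations: %d of %d rows malformed (> 1%%); first offenders: %s",
        sum(bad), nrow(df),
        paste(sprintf("line %d (%s)", utils::head(lines, 5),
                      utils::head(why, 5)), collapse = "; ")))
    warning(sprintf("read_observations: dropped %d malformed row(s) (lines %s)",
                    sum(bad), paste(utils::head(lines, 10), collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
    tm <- tm[!bad]
  } else report <- data.frame(line = integer(0), reason = character(0))
  df$datetime_utc <- tm
  df$presence <- as.integer(df$category_label != "0")
  df <- derive_covariates(df, zone = zone)
  attr(df, "malformed") <- report
  df
}

#' Write an observation table
#'
#' Writes the interchange columns (`id, lon, lat, datetime_utc,
#' category_label`) as CSV with ISO-8601 UTC timestamps; derived columns
#' are not written (they are recomputed on read).
#'
#' @param df observation table.
#' @param path output path.
#' @export
write_observations <- function(df, path) {
  out <- data.frame(id = df$id, lon = df$lon, lat = df$lat,
                    datetime_utc = format(df$datetime_utc,
                                          "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    category_label = df$category_label)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Region-of-interest polygon
#'
#' A closed ring of lon/lat vertices. The ring is closed automatically if
#' the last vertex differs from the first; self-intersecting rings are
#' rejected.
#'
#' @param lon,lat vertex coordinates (>= 3 distinct vertices).
#' @param name label.
#' @return object of class `bw_polygon`.
#' @export
region_polygon <- function(lon, lat, name = "region") {
  stopifnot(length(lon) == length(lat), length(lon) >= 3,
            all(is.finite(lon)), all(is.finite(lat)))
  if (lon[1] != lon[length(lon)] || lat[1] != lat[length(lat)]) {
    lon <- c(lon, lon[1]); lat <- c(lat, lat[1])
  }
  if (.self_intersects(lon, lat))
    stop("region_polygon: polygon is self-intersecting")
  structure(list(lon = lon, lat = lat, name = name), class = "bw_polygon")
}

# proper-crossing test between non-adjacent edges (shared endpoints allowed)
.self_intersects <- function(lon, lat) {
  n <- length(lon) - 1L
  if (n < 4) return(FALSE)
  sgn <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next   # adjacent through the closure
      d1 <- sgn(lon[i], lat[i], lon[i + 1], lat[i + 1], lon[j], lat[j])
      d2 <- sgn(lon[i], lat[i], lon[i + 1], lat[i + 1], lon[j + 1], lat[j + 1])
      d3 <- sgn(lon[j], lat[j], lon[j + 1], lat[j + 1], lon[i], lat[i])
      d4 <- sgn(lon[j], lat[j], lon[j + 1], lat[j + 1], lon[i + 1], lat[i + 1])
      if (d1 * d2 < 0 && d3 * d4 < 0) return(TRUE)
    }
  }
  FALSE
}

#' Default region of interest
#'
#' An approximation of the study region: the 20W-10E, 44-64N box of the
#' modern reanalysis, optionally with the sparsely sampled Bay of Biscay
#' (south-east) and Norwegian Sea (north-east) corners notched out
#' (both on by default).
#'
#' @param biscay_notch exclude the Bay of Biscay corner (east of 8W below
#'   48N).
#' @param norwegian_notch exclude the Norwegian Sea corner (east of 2E
#'   above 62N).
#' @return a `bw_polygon`.
#' @export
default_region <- function(biscay_notch = TRUE, norwegian_notch = TRUE) {
  lon <- c(-20)
  lat <- c(44)
  if (biscay_notch) { lon <- c(lon, -8, -8); lat <- c(lat, 44, 48) }
  lon <- c(lon, 10); lat <- c(lat, if (biscay_notch) 48 else 44)
  if (norwegian_notch) { lon <- c(lon, 10, 2, 2); lat <- c(lat, 62, 62, 64) }
  else { lon <- c(lon, 10); lat <- c(lat, 64) }
  lon <- c(lon, -20); lat <- c(lat, 64)
  region_polygon(lon, lat, name = "study-region")
}

# even-odd ray casting with boundary-inclusive convention
.point_in_poly <- function(px, py, vx, vy) {
  n <- length(vx) - 1L
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  eps <- 1e-12
  for (i in seq_len(n)) {
    x1 <- vx[i]; y1 <- vy[i]; x2 <- vx[i + 1]; y2 <- vy[i + 1]
    # on-segment test
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    within <- px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    onedge <- onedge | (abs(cross) <= eps * max(1, abs(x2 - x1) + abs(y2 - y1)) & within)
    # even-odd crossing
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses)
  }
  inside | onedge
}

#' Filter observations to a region of interest
#'
#' Even-odd ray-casting point-in-polygon test in lon/lat; points exactly
#' on the boundary are retained. The exclusion report (attribute
#' `"exclusion_report"`) counts total and presence rows retained and
#' excluded.
#'
#' @param df observation table with `lon`, `lat` (and optionally
#'   `presence`).
#' @param polygon a `bw_polygon`.
#' @return the retained rows, with the exclusion report attached.
#' @export
filter_region <- function(df, polygon = default_region()) {
  stopifnot(inherits(polygon, "bw_polygon"))
  keep <- .point_in_poly(df$lon, df$lat, polygon$lon, polygon$lat)
  pres <- if (!is.null(df$presence)) df$presence == 1 else rep(FALSE, nrow(df))
  report <- data.frame(
    n_input = nrow(df), n_retained = sum(keep), n_excluded = sum(!keep),
    presences_input = sum(pres), presences_retained = sum(pres & keep),
    presences_excluded = sum(pres & !keep))
  out <- df[keep, , drop = FALSE]
  attr(out, "exclusion_report") <- report
  out
}
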