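# Derived spawning-distribution products from a fitted model: evaluation
# on a regular (east, north, doy) grid per year, normalised per-component
# spatial densities, peak-timing maps masked to the highest-density core,
# zonally integrated latitude x day-of-year distributions, and annual
# abundance indices with posterior confidence intervals.
#
# All normalised products are per-component probability density functions:
# the integral over each component's own domain is 1, so relative
# abundance between the components is deliberately NOT preserved and must
# not be compared across the dividing latitude. Annual distributions are
# normalised per year first and then averaged (the mean of the per-year
# normalised distributions), so no single year dominates.

.check_axis <- function(x, name) {
  if (length(x) < 1 || any(diff(x) <= 0))
    stop(sprintf("grid axis '%s' must be strictly increasing", name))
  if (length(x) > 1) {
    d <- diff(x)
    if (max(abs(d - mean(d))) > 1e-6 * mean(d))
      stop(sprintf("grid axis '%s' must be uniformly spaced", name))
    mean(d)
  } else 1
}

#' Default grid axes for a fitted model
#'
#' A regular lattice over the model's training domain: `ne` x `nn` spatial
#' cells and day-of-year at `doy_step`-day resolution (cell midpoints).
#'
#' @param model a `bw_gam`.
#' @param ne,nn number of easting/northing cells.
#' @param doy_step day-of-year step, days.
#' @return list with `east`, `north`, `doy` axes.
#' @export
default_grid_axes <- function(model, ne = 50, nn = 80, doy_step = 5) {
  re <- model$ranges$east
  rn <- model$ranges$north
  list(east = seq(re[1], re[2], length.out = ne),
       north = seq(rn[1], rn[2], length.out = nn),
       doy = seq(doy_step / 2, 365, by = doy_step))
}

#' Evaluate a fitted model on a regular space-season grid
#'
#' Evaluates occurrence probabilities on the (east, north, doy) lattice
#' for each requested year. The day/night state is fixed by convention:
#' `"average"` (the mean of the day and night predictions, the default,
#' since the derived figures do not condition on one state), `"day"` or
#' `"night"`. Each spatial cell is labelled north/south of the model's
#' dividing latitude via inverse projection.
#'
#' @param model a `bw_gam`.
#' @param axes list with strictly increasing, uniformly spaced `east`,
#'   `north` (metres) and `doy` axes; default [default_grid_axes()].
#' @param years years to evaluate (default: the model's training years,
#'   or a single reference layer if the model has no year term).
#' @param dn day/night convention.
#' @return object of class `bw_grid`: probability array `p`
#'   (east x north x doy x year), cell latitude/component matrices, axis
#'   vectors and cell measures.
#' @export
evaluate_grid <- function(model, axes = default_grid_axes(model),
                          years = NULL, dn = c("average", "day", "night"),
                          support_km = 80) {
  dn <- match.arg(dn)
  stopifnot(inherits(model, "bw_gam"))
  if (is.null(years))
    years <- if (model$spec$year == "none") model$years[1] else model$years
  de <- .check_axis(axes$east, "east")
  dnr <- .check_axis(axes$north, "north")
  dd <- .check_axis(axes$doy, "doy")
  ne <- length(axes$east); nn <- length(axes$north); nd <- length(axes$doy)
  sp <- expand.grid(east = axes$east, north = axes$north,
                    KEEP.OUT.ATTRS = FALSE)
  geo <- utm_unproject(sp$east, sp$north)
  lat_mat <- matrix(geo$lat, ne, nn)
  comp_mat <- matrix(as.character(component_factor(geo$lat,
                                                   model$spec$split_latitude)),
                     ne, nn)
  p <- array(NA_real_, c(ne, nn, nd, length(years)),
             dimnames = list(NULL, NULL, NULL, years))
  states <- if (dn == "average") c("day", "night") else dn
  for (iy in seq_along(years)) {
    for (id in seq_len(nd)) {
      nd_df <- data.frame(east = sp$east, north = sp$north,
                          doy = axes$doy[id], year = years[iy],
                          lat = geo$lat)
      acc <- 0
      for (st in states) {
        nd_df$dn <- st
        acc <- acc + predict.bw_gam(model, nd_df, type = "response")
      }
      p[, , id, iy] <- matrix(acc / length(states), ne, nn)
    }
  }
  supported <- support_fraction(model, axes$east, axes$north, support_km)
  structure(list(p = p, east = axes$east, north = axes$north,
                 doy = axes$doy, years = years, supported = supported,
                 lat = lat_mat, comp = comp_mat,
                 measure = c(de = de, dn = dnr, dd = dd),
                 dn_convention = dn,
                 split_latitude = model$spec$split_latitude),
            class = "bw_grid")
}

# mean over years of the per-year, per-component normalised field.
# x_y: function(iy) returning an array whose cells are grouped by `groups`
# (a character array of the same shape); cell measure `meas`.
.mean_normalised <- function(grid, field_fun, groups, meas) {
  out <- 0
  for (iy in seq_along(grid$years)) {
    f <- field_fun(iy)
    for (g in unique(as.vector(groups))) {
      sel <- groups == g
      tot <- sum(f[sel]) * meas
      f[sel] <- if (tot > 0) f[sel] / tot else 0
    }
    out <- out + f / length(grid$years)
  }
  for (g in unique(as.vector(groups))) {  # renormalise the mean
    sel <- groups == g
    tot <- sum(out[sel]) * meas
    if (tot > 0) out[sel] <- out[sel] / tot
  }
  out
}

#' Per-component spatial spawning density
#'
#' Integrates the gridded occurrence probability over day of year for each
#' year, normalises each year's field within each component's spatial
#' domain, and averages the normalised fields over years. The result is a
#' probability density function per component: the spatial integral over
#' each component's own domain is 1 (so densities are not comparable
#' across components).
#'
#' @param grid a `bw_grid`.
#' @return object of class `bw_spatial_pdf`: density matrix
#'   (east x north, units 1/m^2), component labels, axes.
#' @export
spatial_pdf <- function(grid) {
  stopifnot(inherits(grid, "bw_grid"))
  meas <- unname(grid$measure["de"] * grid$measure["dn"])
  dens <- .mean_normalised(
    grid,
    function(iy) apply(grid$p[, , , iy, drop = FALSE], c(1, 2), sum) *
      grid$measure["dd"] * grid$supported,
    grid$comp, meas)
  structure(list(density = dens, east = grid$east, north = grid$north,
                 comp = grid$comp, lat = grid$lat, measure = meas),
            class = "bw_spatial_pdf")
}

#' @export
as.data.frame.bw_spatial_pdf <- function(x, ...) {
  data.frame(east = rep(x$east, length(x$north)),
             north = rep(x$north, each = length(x$east)),
             lat = as.vector(x$lat), comp = as.vector(x$comp),
             density = as.vector(x$density))
}

#' Spawning-centre location per component
#'
#' Estimates each component's spawning centre as the density-weighted
#' centroid of the cells holding the core `core_mass` of its spatial
#' density (the highest-density region). For a symmetric spawning bump
#' the trimmed centroid coincides with the mode, and it is far more
#' stable than the raw argmax cell, which wanders on the broad plateau of
#' a smooth density. The raw argmax cell is reported alongside.
#'
#' @param pdf a `bw_spatial_pdf`.
#' @param core_mass fraction of the component's mass defining the core.
#' @return data.frame: `comp`, centroid `east`/`north`/`lon`/`lat`, and
#'   the argmax cell `east_max`/`north_max`.
#' @export
component_modes <- function(pdf, core_mass = 0.75) {
  stopifnot(inherits(pdf, "bw_spatial_pdf"))
  ee <- rep(pdf$east, length(pdf$north))
  nn <- rep(pdf$north, each = length(pdf$east))
  out <- lapply(sort(unique(as.vector(pdf$comp))), function(g) {
    sel <- as.vector(pdf$comp == g)
    dens <- as.vector(pdf$density)[sel]
    inc <- .hdr_include(dens, pdf$measure, core_mass)
    w <- dens[inc]
    data.frame(comp = g,
               east = sum(ee[sel][inc] * w) / sum(w),
               north = sum(nn[sel][inc] * w) / sum(w),
               east_max = ee[sel][which.max(dens)],
               north_max = nn[sel][which.max(dens)])
  })
  out <- do.call(rbind, out)
  geo <- utm_unproject(out$east, out$north)
  cbind(out[, c("comp", "east", "north")], geo,
        out[, c("east_max", "north_max")])
}

# Highest-density-region inclusion: order cells by density (descending,
# ties broken by cell index for determinism) and accumulate mass until the
# core fraction is reached.
.hdr_include <- function(dens, meas, core_mass) {
  o <- order(-dens, seq_along(dens))
  cum <- cumsum(dens[o]) * meas
  ninc <- which(cum >= core_mass - 1e-12)[1]
  if (is.na(ninc)) ninc <- length(dens)
  inc <- logical(length(dens))
  inc[o[seq_len(ninc)]] <- TRUE
  inc
}

#' Peak-timing map masked to the component cores
#'
#' For each spatial cell, the day of year at which the (year-averaged)
#' occurrence probability peaks. Cells outside the smallest set containing
#' `core_mass` of each component's spatial density (the highest-density
#' region) are masked, as are cells with a flat seasonal profile (argmax
#' ill-defined; counted in attribute `n_flat`).
#'
#' @param grid a `bw_grid`.
#' @param core_mass fraction of each component's spatial mass to keep
#'   (default 0.75: the core 75% of the larval distribution).
#' @return data.frame `east`, `north`, `lat`, `comp`, `peak_doy`,
#'   `in_core`; attribute `n_flat`.
#' @export
peak_timing_map <- function(grid, core_mass = 0.75) {
  stopifnot(inherits(grid, "bw_grid"), core_mass > 0, core_mass <= 1)
  pbar <- apply(grid$p, c(1, 2, 3), mean)      # year-averaged
  rng <- apply(pbar, c(1, 2), function(v) diff(range(v)))
  imax <- apply(pbar, c(1, 2), which.max)
  peak <- matrix(grid$doy[imax], nrow(imax), ncol(imax))
  flat <- rng < 1e-12
  peak[flat] <- NA_real_
  pdf <- spatial_pdf(grid)
  in_core <- matrix(FALSE, length(grid$east), length(grid$north))
  for (g in unique(as.vector(grid$comp))) {
    sel <- grid$comp == g
    inc <- .hdr_include(pdf$density[sel], pdf$measure, core_mass)
    in_core[sel] <- inc
  }
  in_core[flat] <- FALSE
  # unsupported cells carry zero density, so they never enter the core;
  # their argmax is pure extrapolation and is not reported
  peak[grid$supported == 0] <- NA_real_
  in_core[grid$supported == 0] <- FALSE
  out <- data.frame(east = rep(grid$east, length(grid$north)),
                    north = rep(grid$north, each = length(grid$east)),
                    lat = as.vector(grid$lat), comp = as.vector(grid$comp),
                    peak_doy = as.vector(peak),
                    in_core = as.vector(in_core))
  attr(out, "n_flat") <- sum(flat)
  out
}

#' Zonally integrated latitude x day-of-year distribution
#'
#' Integrates the eastings out of the gridded probability, per component
#' (a cell contributes to its own component's marginal), normalises each
#' year within each component and averages over years. Each component's
#' (northing, doy) marginal integrates to 1. The northing axis is
#' reported alongside the latitude at the domain-centre easting for ease
#' of interpretation.
#'
#' @param grid a `bw_grid`.
#' @return object of class `bw_zonal`: array `density`
#'   (north x doy x component, units 1/(m day)), `lat` per northing row,
#'   axes.
#' @export
zonal_marginal <- function(grid) {
  stopifnot(inherits(grid, "bw_grid"))
  comps <- sort(unique(as.vector(grid$comp)))
  nn <- length(grid$north); ndy <- length(grid$doy)
  meas <- unname(grid$measure["dn"] * grid$measure["dd"])
  groups <- array(rep(comps, each = nn * ndy), c(nn, ndy, length(comps)))
  field_fun <- function(iy) {
    out <- array(0, c(nn, ndy, length(comps)))
    for (ic in seq_along(comps)) {
      msk <- (grid$comp == comps[ic]) * grid$supported * grid$measure["de"]
      for (id in seq_len(ndy))
        out[, id, ic] <- colSums(grid$p[, , id, iy] * msk)
    }
    out
  }
  dens <- .mean_normalised(grid, field_fun, groups, meas)
  lat_mid <- utm_unproject(rep(mean(range(grid$east)), nn), grid$north)$lat
  structure(list(density = dens, north = grid$north, doy = grid$doy,
                 comps = comps, lat = lat_mid, measure = meas),
            class = "bw_zonal")
}

#' Peak spawning day per component from a zonal marginal
#'
#' The day of year maximising each component's latitude-integrated
#' seasonal profile; the basis for the southern-lead timing offset.
#'
#' @param zm a `bw_zonal`.
#' @return named numeric vector of peak days, one per component.
#' @export
zonal_peak_days <- function(zm) {
  stopifnot(inherits(zm, "bw_zonal"))
  out <- vapply(seq_along(zm$comps), function(ic) {
    prof <- colSums(zm$density[, , ic])
    zm$doy[which.max(prof)]
  }, 0)
  names(out) <- zm$comps
  out
}

#' Annual abundance index with posterior confidence intervals
#'
#' For each posterior coefficient draw, integrates the occurrence
#' probability over the spatial domain and day of year, per year and
#' component; reports the median and central 67% interval (one standard
#' deviation) per year and component. Units are arbitrary but linear in
#' probability x area x days.
#'
#' @param model a `bw_gam`.
#' @param axes grid axes as in [evaluate_grid()].
#' @param years years to index (default: training years).
#' @param n_draws posterior draws.
#' @param seed integer seed (results are reproducible given the seed).
#' @param dn day/night convention, as in [evaluate_grid()].
#' @return data.frame of class `bw_index`: `year`, `comp`, `median`,
#'   `lo67`, `hi67`.
#' @export
annual_index <- function(model, axes = default_grid_axes(model),
                         years = NULL, n_draws = 500, seed = 1L,
                         dn = c("average", "day", "night"),
                         support_km = 80) {
  dn <- match.arg(dn)
  stopifnot(inherits(model, "bw_gam"))
  if (is.null(years)) years <- model$years
  de <- .check_axis(axes$east, "east")
  dnr <- .check_axis(axes$north, "north")
  dd <- .check_axis(axes$doy, "doy")
  meas <- de * dnr * dd
  B <- posterior_draws(model, n_draws, seed)   # n_draws x p
  sp <- expand.grid(east = axes$east, north = axes$north,
                    KEEP.OUT.ATTRS = FALSE)
  geo <- utm_unproject(sp$east, sp$north)
  comp <- as.character(component_factor(geo$lat, model$spec$split_latitude))
  wsup <- as.vector(support_fraction(model, axes$east, axes$north, support_km))
  comp[wsup == 0] <- NA
  comps <- sort(unique(stats::na.omit(comp)))
  states <- if (dn == "average") c("day", "night") else dn
  rows <- list()
  for (yr in years) {
    tot <- matrix(0, length(comps), n_draws, dimnames = list(comps, NULL))
    for (id in seq_along(axes$doy)) {
      nd_df <- data.frame(east = sp$east, north = sp$north,
                          doy = axes$doy[id], year = yr, lat = geo$lat)
      pm <- 0
      for (st in states) {
        nd_df$dn <- st
        G <- .predict_design(model, nd_df)
        pm <- pm + stats::plogis(G %*% t(B))   # ncells x n_draws
      }
      pm <- pm / length(states)
      for (ic in seq_along(comps)) {
        cc <- which(comp == comps[ic])
        tot[ic, ] <- tot[ic, ] +
          colSums(pm[cc, , drop = FALSE] * wsup[cc]) * meas
      }
    }
    for (ic in seq_along(comps)) {
      q <- stats::quantile(tot[ic, ], c(0.165, 0.5, 0.835), names = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(year = yr, comp = comps[ic], median = q[2],
                   lo67 = q[1], hi67 = q[3])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bw_index", "data.frame")
  out
}
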