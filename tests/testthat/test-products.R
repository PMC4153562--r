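# Derived products: gridded evaluation, normalised spatial and zonal
# densities, peak-timing maps, annual indices. One reduced synthetic fit
# is shared across the tests in this file.

prod_env <- new.env()
prod_model <- function() {
  if (is.null(prod_env$m)) {
    yrs <- 1970:1977
    truth <- default_truth(yrs)
    smp <- generate_samples(default_design(), yrs, seed = 50)
    obs <- simulate_observations(truth, smp, seed = 51)
    prod_env$m <- bw_gam(obs, model_spec("te3", "common"),
                         fast_settings(optim_maxit = 30))
  }
  prod_env$m
}

test_that("a one-cell grid reproduces point prediction", {
  m <- prod_model()
  axes <- list(east = 8e5, north = 6e6, doy = 100)
  grid <- evaluate_grid(m, axes, years = 1972, dn = "day",
                        support_km = NULL)
  nd <- data.frame(east = 8e5, north = 6e6, doy = 100, year = 1972,
                   dn = "day", lat = utm_unproject(8e5, 6e6)$lat)
  expect_equal(as.vector(grid$p), predict(m, nd), tolerance = 1e-12)
  # the day/night average convention is the mean of the two states
  gav <- evaluate_grid(m, axes, years = 1972, support_km = NULL)
  nd$dn <- "night"
  expect_equal(as.vector(gav$p),
               (predict(m, nd) + as.vector(grid$p)) / 2, tolerance = 1e-12)
})

test_that("grid cells are labelled by the dividing latitude", {
  m <- prod_model()
  axes <- default_grid_axes(m, ne = 10, nn = 14, doy_step = 60)
  grid <- evaluate_grid(m, axes, years = 1972)
  expect_true(all((grid$comp == "north") == (grid$lat >= 53)))
  expect_error(evaluate_grid(m, list(east = c(2, 1), north = 1, doy = 1)),
               "increasing")
})

test_that("spatial and zonal densities integrate to one per component", {
  m <- prod_model()
  axes <- default_grid_axes(m, ne = 16, nn = 24, doy_step = 15)
  grid <- evaluate_grid(m, axes, years = c(1971, 1974, 1977))
  pdf <- spatial_pdf(grid)
  for (g in c("north", "south"))
    expect_equal(sum(pdf$density[grid$comp == g]) * pdf$measure, 1,
                 tolerance = 1e-6)
  zm <- zonal_marginal(grid)
  for (ic in seq_along(zm$comps))
    expect_equal(sum(zm$density[, , ic]) * zm$measure, 1, tolerance = 1e-6)
  # long-format accessor matches the array
  df <- as.data.frame(pdf)
  expect_equal(nrow(df), 16 * 24)
  expect_equal(df$density[df$east == pdf$east[3] & df$north == pdf$north[5]],
               pdf$density[3, 5])
})

test_that("the fitted spawning centres recover the truth", {
  m <- prod_model()
  axes <- default_grid_axes(m, ne = 30, nn = 45, doy_step = 10)
  grid <- evaluate_grid(m, axes, years = seq(1970, 1977, by = 2))
  md <- component_modes(spatial_pdf(grid))
  tc <- default_truth_centres()
  for (g in c("north", "south")) {
    got <- md[md$comp == g, ]
    d_km <- km_dist(got$east, got$north, tc[g, "east"], tc[g, "north"])
    expect_lt(d_km, 150)   # reduced-n smoke bound; acceptance uses 100
  }
  # the northward seasonal delay shows as a monotone zonal ridge
  zm <- zonal_marginal(grid)
  dens <- zm$density[, , 1] + zm$density[, , 2]
  rows <- which(apply(dens, 1, max) > 0.05 * max(dens))
  ridge <- zm$doy[apply(dens[rows, , drop = FALSE], 1, which.max)]
  expect_gt(cor(zm$lat[rows], ridge, method = "spearman"), 0.8)
})

test_that("highest-density-region mask covers the advertised mass", {
  m <- prod_model()
  axes <- default_grid_axes(m, ne = 16, nn = 24, doy_step = 15)
  grid <- evaluate_grid(m, axes, years = 1973)
  pdf <- spatial_pdf(grid)
  pt <- peak_timing_map(grid, core_mass = 0.75)
  for (g in c("north", "south")) {
    sel <- pt$comp == g & pt$in_core
    mass <- sum(as.vector(pdf$density)[sel]) * pdf$measure
    expect_gte(mass, 0.75 - 1e-9)
    # minimality: dropping the smallest included cell goes below the core
    expect_lt(mass - min(as.vector(pdf$density)[sel]) * pdf$measure, 0.75)
    # peaks inside the core are well-defined days
    expect_true(all(is.finite(pt$peak_doy[sel])))
    expect_true(all(pt$peak_doy[sel] >= 0 & pt$peak_doy[sel] <= 365))
  }
})

test_that("a uniform density yields a 75%-of-cells core", {
  # hand-built grid: probability constant in space, seasonal in doy
  ne <- 10; nn <- 20; ndy <- 12
  east <- seq(5e5, 9e5, length.out = ne)
  north <- seq(5.6e6, 6.4e6, length.out = nn)
  doy <- seq(15, 355, length.out = ndy)
  p <- array(rep(1e-3 * (1 + sin(2 * pi * doy / 365)),
                 each = ne * nn), c(ne, nn, ndy, 1))
  lat <- matrix(utm_unproject(rep(east, nn), rep(north, each = ne))$lat,
                ne, nn)
  grid <- structure(list(
    p = p, east = east, north = north, doy = doy, years = 1970,
    supported = matrix(TRUE, ne, nn), lat = lat,
    comp = matrix(ifelse(lat >= 53, "north", "south"), ne, nn),
    measure = c(de = diff(east)[1], dn = diff(north)[1], dd = diff(doy)[1]),
    dn_convention = "average", split_latitude = 53), class = "bw_grid")
  pt <- peak_timing_map(grid, core_mass = 0.75)
  for (g in c("north", "south")) {
    ncells <- sum(pt$comp == g)
    expect_lte(abs(sum(pt$in_core[pt$comp == g]) - ceiling(0.75 * ncells)), 1)
  }
  # flat seasonal profile: argmax ill-defined, everything masked
  grid$p[] <- 1e-3
  pt2 <- peak_timing_map(grid)
  expect_true(all(is.na(pt2$peak_doy)))
  expect_equal(attr(pt2, "n_flat"), ne * nn)
})

test_that("the annual index is reproducible, linear and honest about zero variance", {
  m <- prod_model()
  axes <- default_grid_axes(m, ne = 12, nn = 18, doy_step = 30)
  idx <- annual_index(m, axes, years = c(1971, 1975), n_draws = 80, seed = 7)
  expect_identical(idx,
                   annual_index(m, axes, years = c(1971, 1975),
                                n_draws = 80, seed = 7))
  expect_true(all(idx$lo67 <= idx$median & idx$median <= idx$hi67))
  # zero posterior variance: degenerate intervals at the plug-in integral
  m0 <- m
  m0$Vb[] <- 0
  idx0 <- annual_index(m0, axes, years = 1971, n_draws = 40, seed = 7)
  expect_equal(idx0$lo67, idx0$median, tolerance = 1e-12)
  expect_equal(idx0$hi67, idx0$median, tolerance = 1e-12)
  grid <- evaluate_grid(m, axes, years = 1971)
  meas <- prod(grid$measure)
  for (g in c("north", "south")) {
    w <- grid$supported * (grid$comp == g)
    plug <- sum(vapply(seq_along(grid$doy),
                       function(id) sum(grid$p[, , id, 1] * w), 0)) * meas
    expect_equal(idx0$median[idx0$comp == g], plug, tolerance = 1e-9)
  }
  # halving the doy step and doubling spatial resolution: index stable
  axes2 <- default_grid_axes(m, ne = 24, nn = 36, doy_step = 15)
  idx2 <- annual_index(m0, axes2, years = 1971, n_draws = 10, seed = 7)
  expect_equal(idx2$median, idx0$median, tolerance = 0.01)
})
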