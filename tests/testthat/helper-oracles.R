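# Independent oracles used across the suite. These deliberately do NOT
# share code paths with the package: the solar oracle follows the NOAA
# fractional-year formulation (the package uses the almanac mean-longitude
# formulas), the AUC oracle counts pairs by brute force (the package uses
# ranks), and the projection oracle is a frozen table from an external
# geodesy library (pyproj, EPSG:32628).

# NOAA "General Solar Position Calculations" (fractional-year Fourier
# series for declination and the equation of time).
noaa_elevation <- function(time, lon, lat) {
  t <- as.POSIXlt(time, tz = "UTC")
  doy <- t$yday + 1
  hour <- t$hour + t$min / 60 + t$sec / 3600
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  tst <- hour * 60 + eqtime + 4 * lon
  ha <- (tst / 4 - 180) * pi / 180
  phi <- lat * pi / 180
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  90 - acos(pmin(pmax(cosz, -1), 1)) * 180 / pi
}

# Brute-force concordant-pair AUC with ties counted one half.
auc_bruteforce <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# Frozen UTM zone 28 reference coordinates (WGS84 -> EPSG:32628, pyproj).
utm28_reference <- function() {
  m <- rbind(
    c(-15.0, 53.0, 500000.000, 5872270.528),
    c(-12.0, 55.0, 691875.632, 6098907.825),
    c(-20.0, 50.0, 141743.632, 5550619.375),
    c(-9.5, 56.5, 838377.654, 6275290.406),
    c(-25.0, 44.0, -301872.006, 4920736.610),
    c(5.0, 64.0, 1465782.386, 7250673.166),
    c(-12.5, 50.0, 679157.864, 5541625.750),
    c(-6.0, 49.0, 1157898.634, 5466603.011))
  data.frame(lon = m[, 1], lat = m[, 2], east = m[, 3], north = m[, 4])
}

# Small observation table for fitting tests: covariates on the model's
# native scales, response from a smooth logit surface.
sim_obs_table <- function(n, seed = 1,
                          eta_fun = function(d) -2 +
                            1.2 * sin(2 * pi * d$doy / 365) +
                            0.2 * (d$dn == "day")) {
  set.seed(seed)
  d <- data.frame(
    east = runif(n, 5e5, 1.1e6), north = runif(n, 5.4e6, 6.4e6),
    doy = sample(365, n, replace = TRUE),
    year = sample(1960:1979, n, replace = TRUE),
    dn = sample(c("day", "night"), n, replace = TRUE),
    lat = runif(n, 44, 64))
  d$presence <- rbinom(n, 1, plogis(eta_fun(d)))
  d
}

# Fast settings for unit-test fits.
fast_settings <- function(optim_maxit = 40, ...) {
  fit_settings(k = list(k1 = 6, k2 = 4, k3 = c(4, 4, 5), kyear = 5),
               optim_maxit = optim_maxit, multistart = FALSE, ...)
}

# Truth centres of the default synthetic world, projected.
default_truth_centres <- function() {
  rbind(north = utm_project(-9.5, 56.5), south = utm_project(-12.5, 50))
}

km_dist <- function(e1, n1, e2, n2) sqrt((e1 - e2)^2 + (n1 - n2)^2) / 1000
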