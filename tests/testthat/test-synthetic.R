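# Synthetic CPR-like world: truth surface, survey design, observation
# simulation and abundance categories.

flat_component <- function(amplitude = 0, name = "flat")
  spawning_component(-10, 52, 1e5, 100, 20, amplitude, name = name)

test_that("truth probability: saturation, background and circular season", {
  ctr <- utm_project(-10, 52)
  big <- truth_config(spawning_component(-10, 52, 1e5, 100, 20,
                                         amplitude = 30),
                      base_logit = -5, dn_effect = 0, years = 1990:1999)
  expect_gt(truth_probability(big, ctr$east, ctr$north, 100, 1995, "night"),
            0.999)
  # far from every component the background level remains
  p_far <- truth_probability(big, ctr$east + 5e6, ctr$north + 5e6,
                             100, 1995, "night")
  expect_equal(p_far, plogis(-5), tolerance = 1e-6)
  # circular day-of-year distance: doy 360 vs peak 10 is 15 days away
  wrap <- truth_config(spawning_component(-10, 52, 1e5, 10, 20, 3),
                       base_logit = -4, dn_effect = 0, years = 1990:1999)
  p360 <- truth_probability(wrap, ctr$east, ctr$north, 360, 1995, "night")
  p25 <- truth_probability(wrap, ctr$east, ctr$north, 25, 1995, "night")
  expect_equal(p360, p25, tolerance = 1e-12)
  # preconditions
  expect_error(truth_probability(wrap, 0, 0, 400, 1995, "day"), "doy")
  expect_error(truth_probability(wrap, 0, 0, 100, 1890, "day"), "year")
  # configurations saturating the probability scale are rejected
  expect_error(truth_config(spawning_component(-10, 52, 1e5, 100, 20, 50),
                            base_logit = 0), "\\(0, 1\\)")
})

test_that("route traversal emits one sample per 10 nautical miles", {
  # a meridional route of exactly 100 nmi
  route <- list(name = "straight", lon = c(-10, -10), lat = c(50, 50 + 100 / 60))
  des <- sampling_design(list(route))
  smp <- generate_samples(des, 1980, seed = 3)
  expect_equal(nrow(smp), 12 * 10)   # 12 monthly traversals x 10 samples
  expect_true(all(format(smp$datetime_utc, "%Y") == "1980"))
  # determinism
  expect_identical(smp, generate_samples(des, 1980, seed = 3))
  expect_false(identical(smp, generate_samples(des, 1980, seed = 4)))
  # route-year filtering: a route retired in 1974 yields nothing in 1980
  old <- list(name = "old", lon = c(-10, -10), lat = c(50, 52),
              years = 1950:1974)
  expect_equal(nrow(generate_samples(sampling_design(list(old)), 1980, 1)), 0L)
  expect_gt(nrow(generate_samples(sampling_design(list(old)), 1970, 1)), 0L)
  # empty design is an empty table, not an error
  expect_equal(nrow(generate_samples(sampling_design(list()), 1980, 1)), 0L)
})

test_that("observation simulation is Bernoulli in the truth probability", {
  route <- list(name = "r", lon = c(-12, -8), lat = c(51, 55))
  smp <- generate_samples(sampling_design(list(route)), 1990:1994, seed = 5)
  # forced certainty
  sure <- truth_config(flat_component(), base_logit = 12, dn_effect = 0,
                       years = 1990:1994)
  obs <- simulate_observations(sure, smp, seed = 6)
  expect_true(all(obs$presence == 1))
  expect_true(all(obs$category_label != "0"))
  # a fair coin: empirical fraction within the binomial Monte-Carlo bound
  half <- truth_config(flat_component(), base_logit = 0, dn_effect = 0,
                       years = 1990:1994)
  n <- nrow(smp)
  obs2 <- simulate_observations(half, smp, seed = 7)
  expect_lt(abs(mean(obs2$presence) - 0.5), 3 * sqrt(0.25 / n))
  # identical seeds give identical tables
  expect_identical(obs2, simulate_observations(half, smp, seed = 7))
})

test_that("the day/night effect shows up as the right odds ratio", {
  # constant-probability world apart from the +0.17 day offset
  cfg <- truth_config(flat_component(), base_logit = -3.5,
                      dn_effect = 0.17, years = 1990:1999)
  set.seed(8)
  n <- 3e5
  # midsummer noon vs midwinter midnight at 55N force day/night
  tm <- ifelse(runif(n) < 0.5, "1995-06-21T12:00:00", "1995-01-05T00:00:00")
  smp <- data.frame(lon = -10, lat = 55, datetime_utc = tm)
  obs <- simulate_observations(cfg, smp, seed = 9)
  expect_setequal(unique(as.character(obs$dn)), c("day", "night"))
  tab <- table(obs$dn, obs$presence)
  lor <- log(tab["day", "1"] / tab["day", "0"]) -
    log(tab["night", "1"] / tab["night", "0"])
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(lor - 0.17), 4 * se)
})

test_that("abundance categories round-trip and stay ordered", {
  sch <- abundance_scheme()
  expect_equal(sch$label, c("0", "1", "2", "3", "4-11", "12-25"))
  counts <- 0:25
  lab <- category_from_count(counts, sch)
  rng <- category_range(lab, sch)
  expect_true(all(counts >= rng$lo & counts <= rng$hi))
  # counts beyond the last range are clamped into it (documented)
  expect_equal(category_from_count(40), "12-25")
  expect_error(category_range("26-50"), "unknown")
  expect_error(abundance_scheme(data.frame(label = "30+", lo = 30, hi = 99)))
})

test_that("the default world is rare-presence with two offset components", {
  truth <- default_truth(1965:1969)
  smp <- generate_samples(default_design(), 1965:1969, seed = 10)
  obs <- simulate_observations(truth, smp, seed = 11)
  # matches the order of magnitude of the real survey (1-3% presences)
  expect_gt(mean(obs$presence), 0.01)
  expect_lt(mean(obs$presence), 0.03)
  # the two components and their 40-day phenology offset
  pk <- vapply(truth$components, `[[`, 0, "peak_doy")
  expect_equal(unname(pk["north"] - pk["south"]), 40)
  # sidecar round trip
  f <- tempfile(fileext = ".txt")
  write_truth_sidecar(truth, f)
  back <- read_truth_sidecar(f)
  expect_equal(back$dn_effect, 0.17)
  expect_equal(back$components$north$peak_doy, 120)
  expect_equal(back$components$south$spatial_sd, 170e3)
  expect_equal(back$years, 1965:1969)
})
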