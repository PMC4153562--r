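# Bernoulli GAM engine: design assembly, PIRLS, smoothness selection,
# information criteria, prediction and posterior draws.

test_that("design assembly follows the model structure", {
  d <- sim_obs_table(400)
  st <- fast_settings()
  # fully separable structure: three univariate smooth blocks
  des1 <- assemble_design(d, model_spec("add", "none"), st)
  expect_named(des1$blocks, c("parametric", "east", "north", "doy"))
  expect_equal(ncol(des1$X), 2 + 3 * (st$k$k1 - 1))
  expect_length(des1$penalties, 3L)
  # full 3-D interaction with component-wise year smooths
  des10 <- assemble_design(d, model_spec("te3", "by_comp"), st)
  expect_named(des10$blocks,
               c("parametric", "space_doy", "year:north", "year:south"))
  expect_length(des10$penalties, 5L)   # 3 tensor margins + 2 year blocks
  expect_equal(ncol(des10$X),
               2 + (prod(st$k$k3) - 1) + 2 * (st$k$kyear - 1))
  # degenerate structure: intercept + day/night only
  des0 <- assemble_design(d, model_spec("none", "none"), st)
  expect_equal(ncol(des0$X), 2L)
  expect_length(des0$penalties, 0L)
  # by-component terms need both components present
  dd <- d; dd$lat <- 45
  expect_error(assemble_design(dd, model_spec("te3", "by_comp"), st),
               "zero observations")
})

test_that("PIRLS reproduces closed-form and oracle GLM fits", {
  set.seed(11)
  # intercept-only: fitted probability is the sample mean
  y <- rbinom(300, 1, 0.23)
  f0 <- fit_pirls(matrix(1, 300, 1), list(), y, numeric(0))
  expect_equal(plogis(f0$beta), mean(y), tolerance = 1e-9)
  expect_equal(f0$edf, 1, tolerance = 1e-9)
  expect_equal(f0$deviance, f0$null_deviance, tolerance = 1e-9)
  # unpenalized full-rank fit equals the independent IRLS oracle (glm)
  n <- 400
  X <- cbind(1, rnorm(n), runif(n), rbinom(n, 1, 0.5))
  yy <- rbinom(n, 1, plogis(drop(X %*% c(-1, 0.7, -1.2, 0.4))))
  fit <- fit_pirls(X, list(), yy, numeric(0))
  orc <- stats::glm.fit(X, yy, family = binomial())
  expect_lt(max(abs(fit$beta - orc$coefficients)), 1e-6)
  expect_equal(fit$deviance, orc$deviance, tolerance = 1e-9)
})

test_that("the penalized deviance trace is non-increasing", {
  d <- sim_obs_table(600, seed = 12)
  des <- assemble_design(d, model_spec("add", "none"), fast_settings())
  fit <- fit_pirls(des$X, des$penalties, des$y, rep(0.1, 3))
  expect_true(all(diff(fit$pdev_trace) <= 1e-6))
  expect_true(fit$converged)
})

test_that("heavy smoothing collapses the fit to the penalty null space", {
  set.seed(13)
  x <- runif(500, 0, 10)
  y <- rbinom(500, 1, plogis(0.3 * x - 1.5))
  b <- cubic_basis(x, 8)
  Z <- bwspawn:::constraint_null(colSums(basis_matrix(b, x)))
  X <- cbind(1, basis_matrix(b, x) %*% Z)
  pen <- list(list(S = crossprod(Z, b$S %*% Z), cols = 2:8))
  f_hi <- fit_pirls(X, pen, y, 1e9)
  # intercept + the surviving linear direction of the difference penalty
  expect_equal(f_hi$edf, 2, tolerance = 0.05)
  # edf is monotone non-increasing in lambda
  edfs <- vapply(10^seq(-2, 8, by = 2),
                 function(l) fit_pirls(X, pen, y, l)$edf, 0)
  expect_true(all(diff(edfs) < 1e-6))
})

test_that("smoothness selection behaves like a UBRE criterion should", {
  d <- sim_obs_table(900, seed = 14)
  des <- assemble_design(d, model_spec("add", "none"), fast_settings())
  sel <- select_lambda(des$X, des$penalties, des$y, fast_settings())
  expect_lt(sel$fit$edf, ncol(des$X))
  expect_lt(sel$fit$deviance, sel$fit$null_deviance)
  # a larger overfit penalty never increases the effective df
  sel10 <- select_lambda(des$X, des$penalties, des$y,
                         fast_settings(gamma = 1.0))
  expect_lte(sel$fit$edf, sel10$fit$edf + 0.05)
  # pure-noise response: smooth terms shrink towards their null space
  set.seed(15)
  dn <- d; dn$presence <- rbinom(nrow(d), 1, 0.15)
  desn <- assemble_design(dn, model_spec("add", "none"), fast_settings())
  seln <- select_lambda(desn$X, desn$penalties, desn$y, fast_settings())
  # doy smooth is cyclic (null space = constants, absorbed): edf near 0
  doy_cols <- desn$blocks$doy$cols
  expect_lt(sum(seln$fit$edf_col[doy_cols]), 1.5)
})

test_that("AIC uses effective df and prefers truly present structure", {
  d <- sim_obs_table(300, seed = 16)
  m0 <- bw_gam(d, model_spec("none", "none"), fast_settings())
  expect_equal(m0$aic, m0$deviance + 2 * m0$edf, tolerance = 1e-9)
  expect_equal(m0$edf, 2, tolerance = 1e-6)    # intercept + DN
  expect_equal(AIC(m0), m0$aic)
  # data with a strong seasonal signal: the model with the doy smooth wins
  wins <- 0L
  for (r in 1:8) {
    dr <- sim_obs_table(700, seed = 100 + r,
                        eta_fun = function(d) -1.5 +
                          2 * sin(2 * pi * d$doy / 365))
    mA <- bw_gam(dr, model_spec("add", "none"), fast_settings())
    mB <- bw_gam(dr, model_spec("none", "none"), fast_settings())
    wins <- wins + (AIC(mA) < AIC(mB))
    expect_lte(mA$deviance, mB$deviance + 1e-6)  # likelihood monotonicity
  }
  expect_gte(wins, 7L)
})

test_that("deviance explained matches its brute-force recomputation", {
  d <- sim_obs_table(500, seed = 17)
  m <- bw_gam(d, model_spec("add", "none"), fast_settings())
  p0 <- mean(d$presence)
  dev <- -2 * sum(d$presence * log(m$fitted) +
                    (1 - d$presence) * log(1 - m$fitted))
  dev0 <- -2 * sum(d$presence * log(p0) + (1 - d$presence) * log(1 - p0))
  expect_equal(deviance_explained(m), 1 - dev / dev0, tolerance = 1e-7)
  expect_gte(deviance_explained(m), 0)
  expect_equal(deviance_explained(bw_gam(d, model_spec("none", "none"),
                                         fast_settings())),
               0, tolerance = 0.01)
})

test_that("prediction is consistent and additive in the DN factor", {
  d <- sim_obs_table(500, seed = 18)
  m <- bw_gam(d, model_spec("add", "common"), fast_settings())
  # in-sample reproduction
  expect_equal(predict(m, d), m$fitted, tolerance = 1e-9)
  expect_true(all(predict(m, d) > 0 & predict(m, d) < 1))
  # toggling day -> night shifts the linear predictor by the DN coefficient
  nd <- d[1:20, ]
  nd$dn <- "day"; eta_day <- predict(m, nd, type = "link")
  nd$dn <- "night"; eta_night <- predict(m, nd, type = "link")
  expect_equal(eta_day - eta_night, rep(m$dn_coef, 20), tolerance = 1e-9)
})

test_that("posterior draws have the advertised moments and determinism", {
  d <- sim_obs_table(500, seed = 19)
  m <- bw_gam(d, model_spec("none", "common"), fast_settings())
  B <- posterior_draws(m, 10000, seed = 42)
  expect_identical(B, posterior_draws(m, 10000, seed = 42))
  se <- sqrt(diag(m$Vb))
  expect_true(all(abs(colMeans(B) - m$beta) < 4 * se / sqrt(10000)))
  V <- cov(B)
  expect_lt(norm(V - m$Vb, "F") / norm(m$Vb, "F"), 0.1)
})

test_that("the engine agrees with mgcv on a shared 1-D problem", {
  skip_if_not_installed("mgcv")
  set.seed(20)
  n <- 1500
  x <- runif(n, 0, 365)
  y <- rbinom(n, 1, plogis(-1 + 1.5 * sin(2 * pi * x / 365)))
  d <- data.frame(east = runif(n, 6e5, 8e5), north = runif(n, 5.9e6, 6.1e6),
                  doy = x, year = 1970, dn = "day", lat = 50, presence = y)
  m <- bw_gam(d, model_spec("add", "none"),
              fit_settings(k = list(k1 = 8), multistart = FALSE))
  g <- mgcv::gam(y ~ s(x, bs = "cc", k = 8), family = binomial,
                 gamma = 1.4, knots = list(x = c(0, 365)))
  expect_gt(cor(m$fitted, fitted(g)), 0.97)
  expect_lt(mean(abs(m$fitted - fitted(g))), 0.02)
})
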