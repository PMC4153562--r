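# Penalized spline building blocks.

test_that("cubic basis: partition of unity, penalty null space, guards", {
  set.seed(5)
  x <- runif(300, 2, 9)
  for (k in c(4, 7, 10)) {
    b <- cubic_basis(x, k)
    M <- basis_matrix(b, x)
    expect_equal(dim(M), c(300L, k))
    expect_lt(max(abs(rowSums(M) - 1)), 1e-10)
    # brute-force second-difference quadratic form agrees with S
    cf <- rnorm(k)
    brute <- sum((cf[1:(k - 2)] - 2 * cf[2:(k - 1)] + cf[3:k])^2)
    expect_equal(drop(crossprod(cf, b$S %*% cf)), brute, tolerance = 1e-12)
    # constants and linear patterns unpenalized, curvature is not
    expect_equal(drop(crossprod(rep(1, k), b$S %*% rep(1, k))), 0)
    lin <- seq_len(k)
    expect_equal(drop(crossprod(lin, b$S %*% lin)), 0)
    quad <- lin^2
    expect_gt(drop(crossprod(quad, b$S %*% quad)), 0)
    # null space dimension equals the penalty order
    expect_equal(sum(abs(eigen(b$S, symmetric = TRUE)$values) < 1e-8), 2L)
  }
  expect_error(cubic_basis(x, 3), "k")
  expect_error(cubic_basis(rep(1:4, 10), 6), "distinct")
})

test_that("cubic basis extends linearly beyond the knot range", {
  x <- runif(100, 0, 10)
  b <- cubic_basis(x, 6)
  cf <- rnorm(6)
  hi <- max(x)
  f <- function(z) drop(basis_matrix(b, z) %*% cf)
  slope <- (f(hi) - f(hi - 1e-6)) / 1e-6
  expect_equal(f(hi + 3), f(hi) + 3 * slope, tolerance = 1e-4)
  expect_equal(attr(basis_matrix(b, c(hi + 3, 5)), "extrapolated"), 1L)
})

test_that("cyclic basis is periodic with a wrapped penalty", {
  set.seed(6)
  x <- runif(300, 0, 365)
  for (k in c(4, 8, 12)) {
    b <- cyclic_basis(x, k, 365)
    cf <- rnorm(k)
    f <- function(z) drop(basis_matrix(b, z) %*% cf)
    # exact periodicity and boundary continuity
    z <- runif(20, 0, 365)
    expect_equal(f(z), f(z + 365), tolerance = 1e-12)
    expect_lt(abs(f(1e-9) - f(365 - 1e-9)), 1e-6)
    expect_lt(max(abs(rowSums(basis_matrix(b, x)) - 1)), 1e-10)
    # constants unpenalized; null space is constants only
    expect_equal(drop(crossprod(rep(1, k), b$S %*% rep(1, k))), 0)
    expect_equal(sum(abs(eigen(b$S, symmetric = TRUE)$values) < 1e-8), 1L)
  }
})

test_that("tensor products: dimensions, penalties, brute-force contraction", {
  set.seed(7)
  x1 <- runif(200); x2 <- runif(200, 0, 365)
  b1 <- cubic_basis(x1, 5, name = "x1")
  b2 <- cyclic_basis(x2, 5, 365, name = "x2")
  te <- tensor_product(list(b1, b2))
  expect_equal(te$K, 25L)
  expect_length(te$S, 2L)
  # every expanded penalty is PSD and annihilates the constant vector
  for (S in te$S) {
    expect_gt(min(eigen(S, symmetric = TRUE)$values), -1e-8)
    expect_lt(max(abs(S %*% rep(1, 25))), 1e-10)
  }
  # row-wise Kronecker design contracted with a coefficient tensor equals
  # the explicit double-loop summation
  d <- data.frame(x1 = runif(7), x2 = runif(7, 0, 365))
  X <- eval_term(te, d)
  C <- matrix(rnorm(25), 5, 5)   # C[i, j] multiplies B1_i * B2_j
  cf <- as.vector(t(C))          # first margin varies slowest
  M1 <- basis_matrix(b1, d$x1); M2 <- basis_matrix(b2, d$x2)
  brute <- sapply(seq_len(7), function(r) {
    tot <- 0
    for (i in 1:5) for (j in 1:5) tot <- tot + C[i, j] * M1[r, i] * M2[r, j]
    tot
  })
  expect_equal(drop(X %*% cf), brute, tolerance = 1e-12)
  expect_error(tensor_product(list(b1, b2), cap = 10), "cap")
})

test_that("by-component expansion masks and duplicates blocks", {
  set.seed(8)
  d <- data.frame(x1 = runif(50))
  te <- tensor_product(list(cubic_basis(d$x1, 5, name = "x1")))
  X <- eval_term(te, d)
  comp <- factor(rep(c("north", "south"), 25), levels = c("north", "south"))
  ex <- by_component(X, te, comp)
  expect_equal(ncol(ex$X), 10L)
  south_rows <- which(comp == "south")
  expect_true(all(ex$X[south_rows, ex$cols$north] == 0))
  expect_true(all(ex$X[-south_rows, ex$cols$south] == 0))
  expect_equal(ex$X[south_rows, ex$cols$south], X[south_rows, ],
               ignore_attr = TRUE)
  bad <- factor(rep("west", 50))
  expect_error(by_component(X, te, bad), "north")
  one <- factor(rep("north", 50), levels = c("north", "south"))
  expect_error(by_component(X, te, one), "zero observations")
})

test_that("constraint absorption preserves the fitted-value space", {
  # a penalized fit with the sum-to-zero constraint absorbed must give the
  # same fitted probabilities as the unconstrained (rank-deficient, ridge-
  # stabilised) parameterisation
  set.seed(9)
  n <- 400
  x <- runif(n, 0, 10)
  y <- rbinom(n, 1, plogis(sin(x) - 0.5))
  b <- cubic_basis(x, 8)
  Xraw <- basis_matrix(b, x)
  Z <- bwspawn:::constraint_null(colSums(Xraw))
  lam <- 0.5
  # constrained: intercept + centered block
  Xc <- cbind(1, Xraw %*% Z)
  Sc <- crossprod(Z, b$S %*% Z)
  fit_c <- fit_pirls(Xc, list(list(S = Sc, cols = 2:8)), y, lam)
  # unconstrained: intercept + raw block, tiny ridge on the flat direction
  Xu <- cbind(1, Xraw)
  Su <- b$S
  fit_u <- fit_pirls(Xu, list(list(S = Su, cols = 2:9),
                              list(S = diag(9), cols = 1:9)),
                     y, c(lam, 1e-9))
  pc <- plogis(drop(Xc %*% fit_c$beta))
  pu <- plogis(drop(Xu %*% fit_u$beta))
  expect_lt(max(abs(pc - pu)), 1e-6)
})
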