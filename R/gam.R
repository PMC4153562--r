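# Bernoulli GAM engine: model specification, design assembly, penalized
# IRLS fitting, UBRE-type smoothness selection with an overfit-penalty
# multiplier, effective degrees of freedom, AIC, predictions and posterior
# coefficient draws.
#
# The linear predictor is
#   logit p = intercept + DN + f(east, north, doy) [+ s(year)]
# where f ranges from fully additive univariate smooths to a full
# three-dimensional tensor-product interaction, the day-of-year smooth is
# cyclic, and the day-of-year and/or year terms may be conditioned on the
# spawning component (north/south of a dividing latitude).

#' Specify one candidate model structure
#'
#' @param space representation of space and season: `"add"`
#'   (`east + north + doy`, univariate smooths), `"te2"`
#'   (`east*north + doy`, a 2-D spatial tensor plus a cyclic seasonal
#'   smooth) or `"te3"` (`east*north*doy`, the full 3-D tensor).
#' @param year interannual term: `"none"`, `"common"` (one year smooth) or
#'   `"by_comp"` (separate year smooth per component).
#' @param doy_by_comp condition the separate day-of-year smooth on the
#'   component (only meaningful for `space != "te3"`, where the seasonal
#'   smooth is a separate term).
#' @param split_latitude dividing latitude between the northern and
#'   southern components (degrees north); observations at or above it are
#'   northern.
#' @return object of class `bw_spec`.
#' @export
model_spec <- function(space = c("add", "te2", "te3", "none"),
                       year = c("none", "common", "by_comp"),
                       doy_by_comp = FALSE, split_latitude = 53) {
  space <- match.arg(space)
  year <- match.arg(year)
  if (doy_by_comp && space %in% c("te3", "none"))
    stop("model_spec: doy_by_comp applies only when the seasonal smooth is a separate term")
  structure(list(space = space, year = year, doy_by_comp = doy_by_comp,
                 split_latitude = split_latitude),
            class = "bw_spec")
}

#' @export
format.bw_spec <- function(x, ...) {
  f <- switch(x$space,
              add = "east + north + doy",
              te2 = "east*north + doy",
              te3 = "east*north*doy",
              none = "1")
  if (x$doy_by_comp) f <- sub("doy", "doy x comp", f)
  if (x$year == "common") f <- paste(f, "+ syear")
  if (x$year == "by_comp") f <- paste(f, "+ syear x comp")
  f
}

#' @export
print.bw_spec <- function(x, ...) {
  cat("model structure:", format(x), "\n")
  invisible(x)
}

#' Number of components implied by a model structure
#' @param spec a `bw_spec`.
#' @return 1 or 2.
#' @export
n_components <- function(spec) {
  if (spec$doy_by_comp || spec$year == "by_comp") 2L else 1L
}

#' Fitting settings
#'
#' @param gamma overfit-penalty multiplier in the smoothness-selection
#'   criterion (>= 1); 1.4 inflates the effective-degrees-of-freedom cost
#'   to guard against overfitting.
#' @param max_iter,tol penalized IRLS iteration cap and relative
#'   penalized-deviance convergence tolerance.
#' @param optim_maxit,optim_reltol Nelder-Mead budget for the outer
#'   smoothing-parameter search.
#' @param multistart start the search from both a rough and a smooth
#'   initial guess.
#' @param k basis dimensions: `k1` for univariate smooths, `k2` for the
#'   2-D spatial tensor margins, `k3` (length 3) for the 3-D tensor
#'   (east, north, doy; the doy margin is largest as it carries the
#'   phenology), `kyear` for the year smooth.
#' @param lambda_clamp bounds for log smoothing parameters.
#' @return list of class `bw_settings`.
#' @export
fit_settings <- function(gamma = 1.4, max_iter = 200, tol = 1e-8,
                         optim_maxit = 120, optim_reltol = 1e-5,
                         multistart = TRUE,
                         k = list(), lambda_clamp = c(-15, 15)) {
  stopifnot(gamma >= 1)
  kd <- list(k1 = 10, k2 = 8, k3 = c(6, 6, 8), kyear = 10)
  kd[names(k)] <- k
  structure(list(gamma = gamma, max_iter = max_iter, tol = tol,
                 optim_maxit = optim_maxit, optim_reltol = optim_reltol,
                 multistart = multistart, k = kd,
                 lambda_clamp = lambda_clamp),
            class = "bw_settings")
}

# Component factor from latitude: equality goes north.
component_factor <- function(lat, split_latitude = 53) {
  factor(ifelse(lat >= split_latitude, "north", "south"),
         levels = c("north", "south"))
}

# Append one smooth block (optionally by component) to a design under
# construction. Mutates and returns the accumulator list.
.add_block <- function(acc, term, data, comp, by_comp, name) {
  Xraw <- eval_term(term, data)
  if (by_comp) {
    ex <- by_component(Xraw, term, comp)
    for (lv in names(ex$cols)) {
      Xl <- ex$X[, ex$cols[[lv]], drop = FALSE]
      Z <- constraint_null(colSums(Xl))
      Xc <- Xl %*% Z
      cols <- ncol(acc$X) + seq_len(ncol(Xc))
      acc$X <- cbind(acc$X, Xc)
      bname <- paste0(name, ":", lv)
      acc$blocks[[bname]] <- list(name = bname, term = term, Z = Z,
                                  by = lv, cols = cols)
      for (j in seq_along(term$S))
        acc$penalties[[length(acc$penalties) + 1L]] <-
          list(S = crossprod(Z, term$S[[j]] %*% Z), cols = cols,
               block = bname, margin = j)
    }
  } else {
    Z <- constraint_null(colSums(Xraw))
    Xc <- Xraw %*% Z
    cols <- ncol(acc$X) + seq_len(ncol(Xc))
    acc$X <- cbind(acc$X, Xc)
    acc$blocks[[name]] <- list(name = name, term = term, Z = Z,
                               by = NA_character_, cols = cols)
    for (j in seq_along(term$S))
      acc$penalties[[length(acc$penalties) + 1L]] <-
        list(S = crossprod(Z, term$S[[j]] %*% Z), cols = cols,
             block = name, margin = j)
  }
  acc
}

# Build the smooth terms a spec calls for, from training data.
.build_terms <- function(data, spec, settings) {
  k <- settings$k
  terms <- list()
  if (spec$space == "add") {
    terms$east <- tensor_product(list(cubic_basis(data$east, k$k1, name = "east")))
    terms$north <- tensor_product(list(cubic_basis(data$north, k$k1, name = "north")))
    terms$doy <- tensor_product(list(cyclic_basis(data$doy, k$k1, 365, name = "doy")))
  } else if (spec$space == "te2") {
    terms$space <- tensor_product(list(cubic_basis(data$east, k$k2, name = "east"),
                                       cubic_basis(data$north, k$k2, name = "north")))
    terms$doy <- tensor_product(list(cyclic_basis(data$doy, k$k1, 365, name = "doy")))
  } else if (spec$space == "te3") {
    terms$space_doy <- tensor_product(list(
      cubic_basis(data$east, k$k3[1], name = "east"),
      cubic_basis(data$north, k$k3[2], name = "north"),
      cyclic_basis(data$doy, k$k3[3], 365, name = "doy")))
  }
  if (spec$year != "none") {
    nyr <- length(unique(data$year))
    kyr <- min(k$kyear, nyr)
    if (kyr < 4)
      stop("assemble_design: fewer than 4 distinct years; cannot build a year smooth")
    terms$year <- tensor_product(list(cubic_basis(data$year, kyr, name = "year")))
  }
  terms
}

#' Assemble the model design matrix and penalty list
#'
#' Builds intercept + day/night indicator + the smooth blocks a model
#' structure calls for. Each smooth block is centered (sum-to-zero over the
#' training rows, absorbed by a QR reparameterization that drops one
#' column), and each tensor margin contributes one penalty matrix aligned
#' with the block's columns. By-component blocks are duplicated and masked
#' per component.
#'
#' @param data observation table with columns `presence`, `east`, `north`,
#'   `doy`, `year`, `dn` and `lat` (for component labelling).
#' @param spec a `bw_spec`.
#' @param settings a `bw_settings` (basis dimensions).
#' @return list of class `bw_design`: design matrix `X`, `penalties`,
#'   `blocks`, response `y`, component factor `comp`.
#' @export
assemble_design <- function(data, spec, settings = fit_settings()) {
  stopifnot(inherits(spec, "bw_spec"))
  need <- c("presence", "east", "north", "doy", "year", "dn")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("assemble_design: missing columns: ", paste(miss, collapse = ", "))
  if (nrow(data) == 0) stop("assemble_design: no observations")
  y <- as.numeric(data$presence)
  if (!all(y %in% c(0, 1))) stop("assemble_design: presence must be 0/1")
  dn <- data$dn
  if (!is.factor(dn)) dn <- factor(dn, levels = c("day", "night"))
  two_comp <- n_components(spec) == 2L
  comp <- NULL
  if (two_comp) {
    if (is.null(data$lat))
      stop("assemble_design: by-component terms need a 'lat' column")
    comp <- component_factor(data$lat, spec$split_latitude)
    if (any(table(comp) == 0))
      stop("assemble_design: a spawning component has zero observations; ",
           "cannot fit a by-component term")
  }
  acc <- list(X = cbind(intercept = 1, dn_day = as.numeric(dn == "day")),
              blocks = list(), penalties = list())
  acc$blocks$parametric <- list(name = "parametric", term = NULL, Z = NULL,
                                by = NA_character_, cols = 1:2)
  terms <- .build_terms(data, spec, settings)
  for (nm in names(terms)) {
    by_c <- (nm == "doy" && spec$doy_by_comp) ||
      (nm == "year" && spec$year == "by_comp")
    acc <- .add_block(acc, terms[[nm]], data, comp, by_c, nm)
  }
  structure(list(X = acc$X, penalties = acc$penalties, blocks = acc$blocks,
                 y = y, comp = comp, spec = spec, settings = settings),
            class = "bw_design")
}

.bern_deviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# Cholesky with escalating ridge jitter for near-singular systems.
.chol_safe <- function(A) {
  d <- mean(diag(A))
  for (j in 0:8) {
    R <- tryCatch(chol(A + diag(d * 10^(j - 10) * (j > 0), ncol(A))),
                  error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  stop("fit_pirls: normal-equations matrix is numerically singular")
}

#' Penalized IRLS fit at fixed smoothing parameters
#'
#' Maximizes the penalized Bernoulli log-likelihood
#' `l(beta) - 0.5 * sum_j lambda_j beta' S_j beta` by iteratively
#' reweighted least squares with step halving (the penalized deviance is
#' non-increasing across accepted steps). The effective degrees of freedom
#' are the trace of the influence matrix and the coefficient covariance is
#' the Bayesian posterior covariance `(X'WX + sum lambda_j S_j)^-1`.
#'
#' @param X design matrix.
#' @param penalties list of `list(S, cols)` penalty blocks.
#' @param y 0/1 response.
#' @param lambda non-negative vector, one per penalty.
#' @param control list with `max_iter`, `tol`.
#' @param beta_init optional warm start.
#' @return list: `beta`, `Vb`, `edf` (total), `edf_col` (per column),
#'   `deviance`, `null_deviance`, `loglik`, `iter`, `converged`,
#'   `separation` flag, `pdev_trace`.
#' @export
fit_pirls <- function(X, penalties, y, lambda,
                      control = list(max_iter = 200, tol = 1e-8),
                      beta_init = NULL) {
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(lambda) == length(penalties), all(lambda >= 0))
  Spen <- matrix(0, p, p)
  for (j in seq_along(penalties))
    Spen[penalties[[j]]$cols, penalties[[j]]$cols] <-
      Spen[penalties[[j]]$cols, penalties[[j]]$cols] +
      lambda[j] * penalties[[j]]$S
  pen_quad <- function(b) drop(crossprod(b, Spen %*% b))
  beta <- beta_init
  eta <- if (is.null(beta)) stats::qlogis(rep((sum(y) + 0.5) / (n + 1), n)) else drop(X %*% beta)
  pdev_old <- if (is.null(beta)) Inf else .bern_deviance(y, stats::plogis(eta)) + pen_quad(beta)
  pdev_trace <- numeric(0)
  converged <- FALSE
  max_iter <- control$max_iter %||% 200
  tol <- control$tol %||% 1e-8
  R <- NULL
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    mu <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    XtWX <- crossprod(X, X * w)
    R <- .chol_safe(XtWX + Spen)
    beta_new <- backsolve(R, backsolve(R, crossprod(X, w * z), transpose = TRUE))
    # step halving against penalized-deviance increase
    step <- 1
    repeat {
      beta_try <- if (is.null(beta)) beta_new else beta + step * (beta_new - beta)
      eta_try <- drop(X %*% beta_try)
      pdev <- .bern_deviance(y, stats::plogis(eta_try)) + pen_quad(beta_try)
      if (is.finite(pdev) && (pdev <= pdev_old + 1e-12 || step < 1e-10 || is.null(beta))) break
      step <- step / 2
    }
    beta <- drop(beta_try)
    eta <- eta_try
    pdev_trace <- c(pdev_trace, pdev)
    if (is.finite(pdev_old) && abs(pdev_old - pdev) < tol * (abs(pdev) + 0.1)) {
      converged <- TRUE
      pdev_old <- pdev
      break
    }
    pdev_old <- pdev
  }
  # curvature at the final coefficients
  mu <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
  w <- mu * (1 - mu)
  XtWX <- crossprod(X, X * w)
  R <- .chol_safe(XtWX + Spen)
  Vb <- chol2inv(R)
  edf_col <- rowSums(Vb * XtWX)   # diag of Vb %*% X'WX (both symmetric)
  dev <- .bern_deviance(y, mu)
  p0 <- mean(y)
  list(beta = beta, Vb = Vb, edf = sum(edf_col), edf_col = edf_col,
       deviance = dev, null_deviance = .bern_deviance(y, rep(p0, length(y))),
       loglik = -dev / 2, iter = length(pdev_trace), converged = converged,
       separation = max(abs(eta)) > 30, pdev_trace = pdev_trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select smoothing parameters by a UBRE-type criterion
#'
#' Minimizes `deviance/n + 2 * gamma * edf / n - 1` (the unbiased-risk
#' criterion for a known-scale family, scale fixed at 1 for Bernoulli
#' data, with the overfit-penalty multiplier gamma) over log smoothing
#' parameters using derivative-free Nelder-Mead search with an optional
#' second start, falling back to a coarse log-grid search if the optimizer
#' fails. Inner fits are warm-started.
#'
#' @param X,penalties,y as [fit_pirls()].
#' @param settings a `bw_settings`.
#' @return list: `lambda`, `fit` (final [fit_pirls()] result at the
#'   selected lambda), `criterion`, `log` (search diagnostics).
#' @export
select_lambda <- function(X, penalties, y, settings = fit_settings()) {
  m <- length(penalties)
  n <- length(y)
  ctrl_in <- list(max_iter = 60, tol = max(settings$tol, 1e-7))
  if (m == 0) {
    fit <- fit_pirls(X, penalties, y, numeric(0),
                     control = list(max_iter = settings$max_iter, tol = settings$tol))
    return(list(lambda = numeric(0), fit = fit,
                criterion = fit$deviance / n - 1 + 2 * settings$gamma * fit$edf / n,
                log = list(evals = 0L, method = "none")))
  }
  env <- new.env()
  env$beta <- NULL
  env$evals <- 0L
  obj <- function(rho) {
    rho <- pmin(pmax(rho, settings$lambda_clamp[1]), settings$lambda_clamp[2])
    f <- fit_pirls(X, penalties, y, exp(rho), control = ctrl_in,
                   beta_init = env$beta)
    env$beta <- f$beta
    env$evals <- env$evals + 1L
    f$deviance / n + 2 * settings$gamma * f$edf / n - 1
  }
  starts <- list(rep(2, m))
  if (settings$multistart) starts <- c(starts, list(rep(7, m)))
  best <- NULL
  if (m == 1L) {   # golden-section search in one dimension
    method <- "optimize"
    op <- tryCatch(
      stats::optimize(function(r) obj(r), interval = settings$lambda_clamp,
                      tol = 0.01),
      error = function(e) NULL)
    if (!is.null(op)) best <- list(par = op$minimum, value = op$objective)
  } else {
    method <- "nelder-mead"
    for (s in starts) {
      env$beta <- NULL
      op <- tryCatch(
        stats::optim(s, obj, method = "Nelder-Mead",
                     control = list(maxit = settings$optim_maxit,
                                    reltol = settings$optim_reltol)),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
  }
  if (is.null(best)) {    # coarse shared-lambda grid fallback
    method <- "grid"
    grid <- seq(-4, 10, by = 2)
    vals <- vapply(grid, function(g) obj(rep(g, m)), 0)
    best <- list(par = rep(grid[which.min(vals)], m), value = min(vals))
  }
  rho <- pmin(pmax(best$par, settings$lambda_clamp[1]), settings$lambda_clamp[2])
  env$beta <- NULL
  fit <- fit_pirls(X, penalties, y, exp(rho),
                   control = list(max_iter = settings$max_iter, tol = settings$tol))
  list(lambda = exp(rho), fit = fit, criterion = best$value,
       log = list(evals = env$evals, method = method,
                  starts = length(starts)))
}

#' Fit a Bernoulli spatiotemporal GAM
#'
#' High-level fit: assembles the design for a model structure, selects
#' smoothing parameters and returns a fitted-model object supporting
#' prediction, posterior draws and the derived spawning products.
#'
#' @param data observation table (see [assemble_design()]); a `lat` column
#'   is required for two-component structures and recommended always.
#' @param spec a `bw_spec` from [model_spec()].
#' @param settings a `bw_settings` from [fit_settings()].
#' @return object of class `bw_gam`.
#' @export
bw_gam <- function(data, spec, settings = fit_settings()) {
  des <- assemble_design(data, spec, settings)
  sel <- select_lambda(des$X, des$penalties, des$y, settings)
  fit <- sel$fit
  blocks <- des$blocks
  edf_block <- vapply(blocks, function(b) sum(fit$edf_col[b$cols]), 0)
  dn_i <- 2L
  dn_se <- sqrt(fit$Vb[dn_i, dn_i])
  structure(list(
    spec = des$spec, settings = settings, blocks = blocks,
    years = sort(unique(data$year)),
    ranges = list(east = range(data$east), north = range(data$north),
                  doy = range(data$doy)),
    support = support_build(data$east, data$north),
    penalties = des$penalties, lambda = sel$lambda,
    beta = fit$beta, Vb = fit$Vb,
    edf = fit$edf, edf_block = edf_block, edf_col = fit$edf_col,
    deviance = fit$deviance, null_deviance = fit$null_deviance,
    loglik = fit$loglik, n = nrow(des$X), p = ncol(des$X),
    aic = fit$deviance + 2 * fit$edf,
    fitted = stats::plogis(drop(des$X %*% fit$beta)),
    y = des$y,
    dn_coef = fit$beta[dn_i], dn_se = dn_se,
    dn_ci95 = fit$beta[dn_i] + c(-1, 1) * stats::qnorm(0.975) * dn_se,
    converged = fit$converged, separation = fit$separation,
    fit_log = c(sel$log, list(pirls_iter = fit$iter,
                              criterion = sel$criterion))),
    class = "bw_gam")
}

#' @export
print.bw_gam <- function(x, ...) {
  cat("Bernoulli spatiotemporal GAM\n")
  cat("  structure : ", format(x$spec), "\n", sep = "")
  cat(sprintf("  n = %d, edf = %.2f, deviance = %.2f (null %.2f)\n",
              x$n, x$edf, x$deviance, x$null_deviance))
  cat(sprintf("  AIC = %.2f, deviance explained = %.3f\n",
              x$aic, deviance_explained(x)))
  cat(sprintf("  DN (day) coefficient = %.3f [%.3f, %.3f]\n",
              x$dn_coef, x$dn_ci95[1], x$dn_ci95[2]))
  invisible(x)
}

#' Conditional AIC of a fitted model
#'
#' `-2 * loglik + 2 * edf`, with the effective (not raw) degrees of
#' freedom — the complexity measure appropriate for penalized smooths.
#'
#' @param object a `bw_gam`.
#' @param ... unused.
#' @param k unused (signature compatibility).
#' @export
AIC.bw_gam <- function(object, ..., k = 2) object$aic

#' @export
logLik.bw_gam <- function(object, ...) {
  structure(object$loglik, df = object$edf, class = "logLik")
}

#' Fraction of deviance explained
#'
#' `1 - deviance / null deviance`; the GAM analogue of R squared.
#' @param model a `bw_gam`.
#' @return scalar in `[0, 1]` for intercept-containing fits.
#' @export
deviance_explained <- function(model) {
  1 - model$deviance / model$null_deviance
}

# Build the design matrix for new data from a fitted model's blocks.
.predict_design <- function(model, newdata) {
  n <- nrow(newdata)
  two_comp <- n_components(model$spec) == 2L
  comp <- NULL
  if (two_comp) {
    lat <- newdata$lat
    if (is.null(lat)) {
      if (is.null(newdata$east) || is.null(newdata$north))
        stop("predict: need 'lat' or east/north to label components")
      lat <- utm_unproject(newdata$east, newdata$north)$lat
    }
    comp <- component_factor(lat, model$spec$split_latitude)
  }
  dn <- newdata$dn
  if (is.null(dn)) stop("predict: newdata needs a 'dn' column")
  if (!is.factor(dn)) dn <- factor(dn, levels = c("day", "night"))
  X <- matrix(0, n, model$p)
  X[, 1] <- 1
  X[, 2] <- as.numeric(dn == "day")
  n_extra <- 0L
  for (b in model$blocks) {
    if (is.null(b$term)) next
    Xraw <- eval_term(b$term, newdata)
    n_extra <- n_extra + attr(Xraw, "extrapolated")
    if (!is.na(b$by)) Xraw <- Xraw * as.numeric(comp == b$by)
    X[, b$cols] <- Xraw %*% b$Z
  }
  attr(X, "extrapolated") <- n_extra
  X
}

#' Predict occurrence probabilities
#'
#' @param object fitted `bw_gam`.
#' @param newdata data.frame with `east`, `north`, `doy`, `dn` (and `year`
#'   if the model has a year term; `lat` for two-component models, else
#'   derived by inverse projection).
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.bw_gam <- function(object, newdata, type = c("response", "link"),
                           ...) {
  type <- match.arg(type)
  X <- .predict_design(object, newdata)
  eta <- drop(X %*% object$beta)
  out <- if (type == "link") eta else stats::plogis(eta)
  # flag (but allow) evaluations beyond the training knot range
  if (isTRUE(attr(X, "extrapolated") > 0))
    attr(out, "extrapolated") <- attr(X, "extrapolated")
  out
}

#' Draw coefficients from the posterior of the fit
#'
#' Samples from `N(beta_hat, Vb)` where `Vb` is the Bayesian posterior
#' covariance of the penalized fit; the basis of the confidence intervals
#' on derived quantities. An eigendecomposition square root is used so a
#' semi-definite (including zero) covariance is valid.
#'
#' @param model fitted `bw_gam`.
#' @param n_draws number of draws.
#' @param seed integer seed (draws are reproducible given the seed).
#' @return matrix `n_draws` x `p` of coefficient vectors.
#' @export
posterior_draws <- function(model, n_draws, seed = 1L) {
  p <- model$p
  # deterministic square root: Cholesky when positive definite (stable
  # under tiny serialization round-off), eigendecomposition otherwise
  # (covers semi-definite and exactly zero covariances)
  L <- tryCatch(t(chol(model$Vb)), error = function(e) NULL)
  if (is.null(L)) {
    ee <- eigen(model$Vb, symmetric = TRUE)
    L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), p)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  Zr <- matrix(stats::rnorm(n_draws * p), n_draws, p)
  sweep(Zr %*% t(L), 2, model$beta, `+`)
}
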