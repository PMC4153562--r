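# Penalized spline building blocks: univariate cubic B-spline bases with
# second-order difference penalties (P-splines), cyclic bases for day of
# year, tensor-product terms, by-component duplication, and sum-to-zero
# identifiability constraints. B-splines with difference penalties are used
# in place of classic cubic regression splines: the same function class and
# the same penalty rationale, with a simpler and more robust construction.

#' Cubic B-spline marginal basis
#'
#' Builds an order-4 (cubic) B-spline basis of dimension `k` with interior
#' knots at the data quantiles and a second-order difference penalty on the
#' coefficients. Constants and linear coefficient patterns are unpenalized
#' (penalty null space of dimension 2).
#'
#' @param x numeric data the knots are placed on.
#' @param k basis dimension (>= 4; an order-4 basis cannot be smaller).
#' @param name variable name carried for labelling.
#' @return an object of class `bw_basis` with fields `knots`, `k`,
#'   `cyclic`, `S` (penalty matrix) and `xrange`.
#' @export
cubic_basis <- function(x, k = 10, name = deparse(substitute(x))) {
  if (k < 4) stop("cubic_basis: k must be >= 4 for a cubic basis")
  x <- x[is.finite(x)]
  ux <- sort(unique(x))
  if (length(ux) < k)
    stop(sprintf("cubic_basis: k = %d exceeds the %d distinct data values",
                 k, length(ux)))
  rng <- range(ux)
  if (k > 4) {
    inter <- stats::quantile(x, probs = seq_len(k - 4) / (k - 3),
                             names = FALSE, type = 7)
    # nudge coincident interior knots apart (heavily tied data)
    inter <- pmin(pmax(inter, rng[1]), rng[2])
    if (any(duplicated(inter)))
      inter <- seq(rng[1], rng[2], length.out = k - 2)[2:(k - 3)]
  } else inter <- numeric(0)
  knots <- c(rep(rng[1], 4), inter, rep(rng[2], 4))
  D <- diff(diag(k), differences = 2)
  structure(list(name = name, k = k, cyclic = FALSE, knots = knots,
                 xrange = rng, S = crossprod(D)),
            class = "bw_basis")
}

#' Cyclic cubic B-spline basis
#'
#' Periodic cubic B-spline basis on `[0, period]` with uniformly spaced
#' knots; basis functions that overlap the period boundary are wrapped so
#' that the represented function and its derivatives are continuous across
#' the boundary. The penalty is the wrapped (circular) second-order
#' difference penalty; only constants are unpenalized.
#'
#' @param x data vector (used only for validation; knots are uniform).
#' @param k basis dimension (>= 4).
#' @param period cycle length; 365 for day of year.
#' @param name variable label.
#' @return `bw_basis` object with `cyclic = TRUE`.
#' @export
cyclic_basis <- function(x, k = 10, period = 365,
                         name = deparse(substitute(x))) {
  if (k < 4) stop("cyclic_basis: k must be >= 4")
  x <- x[is.finite(x)]
  if (length(unique(x)) < k)
    stop(sprintf("cyclic_basis: k = %d exceeds the %d distinct data values",
                 k, length(unique(x))))
  h <- period / k
  knots <- (seq(-3, k + 3)) * h
  idx <- seq_len(k)
  D <- matrix(0, k, k)
  for (i in idx) {
    D[i, i] <- 1
    D[i, (i %% k) + 1L] <- -2
    D[i, ((i + 1L) %% k) + 1L] <- 1
  }
  structure(list(name = name, k = k, cyclic = TRUE, knots = knots,
                 period = period, xrange = c(0, period), S = crossprod(D)),
            class = "bw_basis")
}

#' Evaluate a marginal basis
#'
#' Returns the n-by-k matrix of basis function values at `x`. For
#' non-cyclic bases, points outside the knot range are handled by linear
#' extension of the basis (value plus first derivative at the boundary);
#' the number of such points is attached as attribute `extrapolated`.
#' Cyclic bases reduce `x` modulo the period.
#'
#' @param basis a `bw_basis` object.
#' @param x numeric vector of evaluation points.
#' @return matrix (length(x) rows, `basis$k` columns).
#' @export
basis_matrix <- function(basis, x) {
  stopifnot(inherits(basis, "bw_basis"))
  n <- length(x)
  if (basis$cyclic) {
    xr <- x %% basis$period
    Mf <- splines::splineDesign(basis$knots, xr, ord = 4)
    k <- basis$k
    M <- Mf[, seq_len(k), drop = FALSE]
    M[, 1:3] <- M[, 1:3] + Mf[, k + 1:3, drop = FALSE]
    attr(M, "extrapolated") <- 0L
    return(M)
  }
  lo <- basis$xrange[1]; hi <- basis$xrange[2]
  xin <- pmin(pmax(x, lo), hi)
  M <- splines::splineDesign(basis$knots, xin, ord = 4)
  out <- which(x < lo | x > hi)
  if (length(out)) {
    for (i in out) {
      b <- if (x[i] < lo) lo else hi
      v <- splines::splineDesign(basis$knots, b, ord = 4)
      d <- splines::splineDesign(basis$knots, b, ord = 4, derivs = 1L)
      M[i, ] <- v + (x[i] - b) * d
    }
  }
  attr(M, "extrapolated") <- length(out)
  M
}

#' Tensor-product smooth term
#'
#' Combines one to three marginal bases into a tensor-product term: the
#' design is the row-wise Kronecker product of the marginal designs (first
#' margin varying slowest) and each margin contributes one expanded
#' penalty `I %x% ... %x% S_m %x% ... %x% I`, so each direction carries
#' its own smoothing parameter.
#'
#' @param margins list of `bw_basis` objects (length 1-3).
#' @param cap maximum allowed product of basis dimensions.
#' @return object of class `bw_term` with fields `margins`, `K` (product
#'   dimension) and `S` (list of K-by-K penalty matrices).
#' @export
tensor_product <- function(margins, cap = 10000) {
  if (inherits(margins, "bw_basis")) margins <- list(margins)
  stopifnot(length(margins) >= 1, length(margins) <= 3,
            all(vapply(margins, inherits, TRUE, "bw_basis")))
  ks <- vapply(margins, `[[`, 0, "k")
  K <- prod(ks)
  if (K > cap)
    stop(sprintf(paste0("tensor_product: combined dimension %d exceeds cap %d; ",
                        "reduce the marginal basis dimensions"), K, cap))
  m <- length(margins)
  S <- vector("list", m)
  for (j in seq_len(m)) {
    left <- if (j > 1) prod(ks[seq_len(j - 1)]) else 1
    right <- if (j < m) prod(ks[(j + 1):m]) else 1
    S[[j]] <- diag(left) %x% margins[[j]]$S %x% diag(right)
  }
  label <- paste(vapply(margins, `[[`, "", "name"), collapse = ",")
  structure(list(margins = margins, K = K, S = S,
                 label = sprintf("te(%s)", label)),
            class = "bw_term")
}

#' Evaluate a tensor term's raw (unconstrained) design
#'
#' @param term `bw_term` object.
#' @param data data.frame holding the margin variables (matched by name).
#' @return n-by-K design matrix.
#' @export
eval_term <- function(term, data) {
  stopifnot(inherits(term, "bw_term"))
  X <- matrix(1, nrow(data), 1)
  n_extra <- 0L
  for (b in term$margins) {
    if (is.null(data[[b$name]]))
      stop(sprintf("eval_term: variable '%s' not found", b$name))
    B <- basis_matrix(b, data[[b$name]])
    n_extra <- n_extra + attr(B, "extrapolated")
    km <- ncol(B)
    X <- X[, rep(seq_len(ncol(X)), each = km), drop = FALSE] *
      B[, rep(seq_len(km), times = ncol(X)), drop = FALSE]
  }
  attr(X, "extrapolated") <- n_extra
  X
}

# Sum-to-zero constraint absorption: given the raw block design, returns
# the (K x (K-1)) reparameterization Z with colSums(X %*% Z) = 0, obtained
# from the QR complement of the column-sum vector.
constraint_null <- function(colsums) {
  cs <- matrix(colsums, ncol = 1)
  if (sum(abs(cs)) < 1e-12) return(diag(length(colsums))[, -1, drop = FALSE])
  qr.Q(qr(cs), complete = TRUE)[, -1, drop = FALSE]
}

#' Duplicate a term per component (`by`-factor expansion)
#'
#' Expands a smooth term into one independent copy per component level:
#' design columns are duplicated and masked by component membership, and
#' each copy carries its own penalty block (and hence its own smoothing
#' parameter), so the northern and southern components each get their own
#' smooth function.
#'
#' @param X raw block design matrix (n x K).
#' @param term the `bw_term` the block came from.
#' @param comp factor of component labels (levels `north`, `south`).
#' @return list with the expanded design `X` (n x 2K) and per-level column
#'   index list `cols`.
#' @export
by_component <- function(X, term, comp) {
  lv <- levels(comp)
  if (!all(lv %in% c("north", "south")))
    stop("by_component: component labels must be 'north'/'south'")
  if (any(table(comp) == 0))
    stop("by_component: a component has zero observations")
  K <- ncol(X)
  out <- matrix(0, nrow(X), K * length(lv))
  cols <- list()
  for (i in seq_along(lv)) {
    idx <- (i - 1L) * K + seq_len(K)
    mask <- as.numeric(comp == lv[i])
    out[, idx] <- X * mask
    cols[[lv[i]]] <- idx
  }
  list(X = out, cols = cols)
}
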