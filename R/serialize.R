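# Saved-model archive: a single self-describing, versioned JSON text file
# holding the model structure, basis knots, constraint transforms,
# coefficients, posterior covariance, smoothing parameters and fit
# summary. A loaded model supports prediction, posterior draws and all
# derived products (it is not refittable: the training design is not
# stored).

.ARCHIVE_VERSION <- "bwspawn-model-1"

.basis_to_list <- function(b) {
  list(name = b$name, k = b$k, cyclic = b$cyclic, knots = b$knots,
       period = if (b$cyclic) b$period else NULL, xrange = b$xrange)
}

.basis_from_list <- function(l) {
  k <- l$k
  if (isTRUE(l$cyclic)) {
    idx <- seq_len(k)
    D <- matrix(0, k, k)
    for (i in idx) {
      D[i, i] <- 1
      D[i, (i %% k) + 1L] <- -2
      D[i, ((i + 1L) %% k) + 1L] <- 1
    }
    S <- crossprod(D)
  } else {
    S <- crossprod(diff(diag(k), differences = 2))
  }
  structure(list(name = l$name, k = k, cyclic = isTRUE(l$cyclic),
                 knots = as.numeric(l$knots),
                 period = if (isTRUE(l$cyclic)) l$period else NULL,
                 xrange = as.numeric(l$xrange), S = S),
            class = "bw_basis")
}

#' Save a fitted model to a JSON archive
#'
#' @param model a `bw_gam`.
#' @param path output path (conventionally `.json`).
#' @export
bw_gam_save <- function(model, path) {
  stopifnot(inherits(model, "bw_gam"))
  blocks <- lapply(model$blocks, function(b) {
    if (is.null(b$term)) return(list(name = b$name, cols = b$cols))
    list(name = b$name, cols = b$cols, by = b$by, Z = b$Z,
         margins = lapply(b$term$margins, .basis_to_list))
  })
  obj <- list(
    version = .ARCHIVE_VERSION,
    spec = unclass(model$spec),
    settings = unclass(model$settings),
    blocks = blocks,
    lambda = model$lambda, beta = model$beta, Vb = model$Vb,
    edf = model$edf, edf_block = as.list(model$edf_block),
    deviance = model$deviance, null_deviance = model$null_deviance,
    loglik = model$loglik, n = model$n, p = model$p, aic = model$aic,
    dn_coef = model$dn_coef, dn_se = model$dn_se, dn_ci95 = model$dn_ci95,
    years = model$years, ranges = model$ranges,
    support = if (!is.null(model$support)) unclass(model$support),
    converged = model$converged,
    fit_log = model$fit_log[c("evals", "method", "pirls_iter", "criterion")])
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' Load a fitted model from a JSON archive
#'
#' @param path archive written by [bw_gam_save()].
#' @return a `bw_gam` (prediction-capable; not refittable).
#' @export
bw_gam_load <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(obj$version, .ARCHIVE_VERSION))
    stop("bw_gam_load: unsupported archive version: ", obj$version)
  blocks <- lapply(obj$blocks, function(b) {
    if (is.null(b$margins))
      return(list(name = b$name, term = NULL, Z = NULL,
                  by = NA_character_, cols = as.integer(b$cols)))
    margins <- lapply(seq_len(nrow_or_len(b$margins)), function(i)
      .basis_from_list(index_record(b$margins, i)))
    list(name = b$name, term = tensor_product(margins),
         Z = as.matrix(b$Z),
         by = if (is.null(b$by) || is.na(b$by)) NA_character_ else b$by,
         cols = as.integer(b$cols))
  })
  spec <- structure(obj$spec, class = "bw_spec")
  settings <- structure(obj$settings, class = "bw_settings")
  structure(list(
    spec = spec, settings = settings, blocks = blocks,
    years = as.numeric(obj$years),
    ranges = lapply(obj$ranges, as.numeric),
    support = if (!is.null(obj$support))
      structure(list(e0 = obj$support$e0, e1 = obj$support$e1,
                     n0 = obj$support$n0, n1 = obj$support$n1,
                     nbins = obj$support$nbins,
                     occ = matrix(as.logical(obj$support$occ),
                                  obj$support$nbins, obj$support$nbins)),
                class = "bw_support"),
    penalties = NULL, lambda = as.numeric(obj$lambda),
    beta = as.numeric(obj$beta), Vb = as.matrix(obj$Vb),
    edf = obj$edf, edf_block = unlist(obj$edf_block),
    deviance = obj$deviance, null_deviance = obj$null_deviance,
    loglik = obj$loglik, n = obj$n, p = obj$p, aic = obj$aic,
    dn_coef = obj$dn_coef, dn_se = obj$dn_se,
    dn_ci95 = as.numeric(obj$dn_ci95),
    converged = obj$converged, fit_log = obj$fit_log),
    class = "bw_gam")
}

# jsonlite may simplify a homogeneous list of records to a data.frame
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
index_record <- function(x, i) {
  if (is.data.frame(x)) lapply(x, function(col)
    if (is.list(col)) col[[i]] else col[i])
  else x[[i]]
}
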