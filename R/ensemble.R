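# The candidate model ensemble: ten structures ranging from fully
# separable space/season effects to a full 3-D space-season interaction,
# with one- and two-component variants (day-of-year and/or year terms
# conditioned on the spawning component), compared by AIC, in-sample AUC
# and deviance explained. The day/night factor is present in every model.

#' Build the ten-model candidate ensemble
#'
#' Models 1-6 are one-component structures of increasing interaction
#' (`east + north + doy`, `east*north + doy`, `east*north*doy`, each with
#' and without a year smooth); models 7-10 condition the year and/or
#' day-of-year terms on the spawning component split at `split_latitude`.
#'
#' @param split_latitude dividing latitude for the two-component models.
#' @return named list of 10 `bw_spec` objects.
#' @export
build_ensemble <- function(split_latitude = 53) {
  sl <- split_latitude
  list(
    `1` = model_spec("add", "none", split_latitude = sl),
    `2` = model_spec("add", "common", split_latitude = sl),
    `3` = model_spec("te2", "none", split_latitude = sl),
    `4` = model_spec("te2", "common", split_latitude = sl),
    `5` = model_spec("te3", "none", split_latitude = sl),
    `6` = model_spec("te3", "common", split_latitude = sl),
    `7` = model_spec("te2", "by_comp", split_latitude = sl),
    `8` = model_spec("te2", "common", doy_by_comp = TRUE, split_latitude = sl),
    `9` = model_spec("te2", "by_comp", doy_by_comp = TRUE, split_latitude = sl),
    `10` = model_spec("te3", "by_comp", split_latitude = sl))
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen presence receives a higher score
#' than a randomly chosen absence, with ties counted one half (equivalent
#' to trapezoidal integration of the ROC curve). Computed from average
#' ranks, so it is exact including ties.
#'
#' @param y 0/1 labels (both classes must be present).
#' @param p numeric scores.
#' @return scalar in `[0, 1]`.
#' @export
auc <- function(y, p) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("auc: both presences and absences are required")
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit and compare the model ensemble
#'
#' Fits each candidate structure to the same data and tabulates the
#' comparison in ensemble order (no sorting): deviance explained,
#' in-sample AUC, AIC, the AIC difference from the best one-component
#' model (for one-component rows), the AIC difference from the best model
#' overall, a flag for differences above 20 ("essentially no empirical
#' support"), and the day/night coefficient. Individual fit failures are
#' recorded per row and excluded from the AIC reference computations;
#' the comparison proceeds.
#'
#' @param data observation table (see [assemble_design()]).
#' @param specs list of `bw_spec` (default [build_ensemble()]).
#' @param settings a `bw_settings`.
#' @param keep_models return the fitted models alongside the table.
#' @return object of class `bw_ensemble`: a list with `table`
#'   (data.frame) and `models` (list, possibly of NULLs).
#' @export
compare_ensemble <- function(data, specs = build_ensemble(),
                             settings = fit_settings(),
                             keep_models = TRUE) {
  stopifnot(length(specs) >= 2)
  nm <- names(specs) %||% as.character(seq_along(specs))
  models <- vector("list", length(specs))
  names(models) <- nm
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    fit <- tryCatch(bw_gam(data, sp, settings), error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(
        model = nm[i], f = format(sp), comps = n_components(sp),
        dev_expl = NA_real_, auc = NA_real_, aic = NA_real_,
        edf = NA_real_, dn = NA_real_, error = conditionMessage(fit),
        stringsAsFactors = FALSE)
    } else {
      if (keep_models) models[[i]] <- fit
      rows[[i]] <- data.frame(
        model = nm[i], f = format(sp), comps = n_components(sp),
        dev_expl = deviance_explained(fit), auc = auc(fit$y, fit$fitted),
        aic = fit$aic, edf = fit$edf, dn = fit$dn_coef,
        error = NA_character_, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$aic)
  one <- ok & tab$comps == 1
  tab$delta_aic_1 <- ifelse(one, tab$aic - min(tab$aic[one], na.rm = TRUE),
                            NA_real_)
  tab$delta_aic_all <- ifelse(ok, tab$aic - min(tab$aic[ok]), NA_real_)
  tab$no_support <- tab$delta_aic_all > 20
  structure(list(table = tab, models = models, settings = settings),
            class = "bw_ensemble")
}

#' @export
print.bw_ensemble <- function(x, ...) {
  cat("Candidate model comparison (ensemble order preserved):\n")
  tb <- x$table
  tb$dev_expl <- round(tb$dev_expl, 3)
  tb$auc <- round(tb$auc, 3)
  tb$aic <- round(tb$aic, 1)
  tb$edf <- round(tb$edf, 1)
  tb$dn <- round(tb$dn, 3)
  tb$delta_aic_1 <- round(tb$delta_aic_1, 1)
  tb$delta_aic_all <- round(tb$delta_aic_all, 1)
  print(tb[, setdiff(names(tb), "error")], row.names = FALSE)
  if (any(!is.na(tb$error)))
    cat("failed fits:", paste(tb$model[!is.na(tb$error)], collapse = ", "), "\n")
  invisible(x)
}

#' Best model of an ensemble comparison
#' @param x a `bw_ensemble` from [compare_ensemble()].
#' @return the fitted `bw_gam` with the lowest AIC.
#' @export
best_model <- function(x) {
  stopifnot(inherits(x, "bw_ensemble"))
  ok <- which(!is.na(x$table$aic))
  i <- ok[which.min(x$table$aic[ok])]
  m <- x$models[[i]]
  if (is.null(m)) stop("best_model: models were not kept; refit with keep_models = TRUE")
  m
}
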