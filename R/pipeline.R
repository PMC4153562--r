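# Pipeline configuration and the end-to-end driver tying the stages
# together: (optionally) simulate a synthetic survey, read and
# region-filter the observations, fit and compare the model ensemble,
# and write the derived spawning products, with a plain-text run log
# capturing seeds and settings.

.config_keys <- c("input", "simulate", "outdir", "seed", "years", "models",
                  "split_latitude", "gamma", "k", "optim_maxit", "n_draws",
                  "grid", "region", "index_years")

#' Build and validate a pipeline configuration
#'
#' @param input path to an observation CSV (ignored when `simulate` is
#'   TRUE: the pipeline then writes and reads its own synthetic survey).
#' @param simulate generate a synthetic survey from the default truth and
#'   design instead of reading `input`.
#' @param outdir output directory (created if needed).
#' @param seed master integer seed; stage seeds are derived from it.
#' @param years year range for simulation (inclusive bounds,
#'   `c(first, last)`).
#' @param models ensemble member ids to fit (subset of `"1"`..`"10"`).
#' @param split_latitude component dividing latitude.
#' @param gamma overfit-penalty multiplier.
#' @param k basis dimension overrides (see [fit_settings()]).
#' @param optim_maxit smoothing-parameter search budget.
#' @param n_draws posterior draws for the annual index.
#' @param grid list `ne`, `nn`, `doy_step` for the product grids.
#' @param region list with `biscay_notch`, `norwegian_notch`, or `lon` and
#'   `lat` vertex vectors for a custom polygon.
#' @param index_years optional years for the annual index (default: fitted
#'   years).
#' @return validated config list (class `bw_config`).
#' @export
pipeline_config <- function(input = NULL, simulate = is.null(input),
                            outdir = "bwspawn-out", seed = 1L,
                            years = c(1950, 2005),
                            models = as.character(1:10),
                            split_latitude = 53, gamma = 1.4, k = list(),
                            optim_maxit = 120, n_draws = 500,
                            grid = list(), region = list(),
                            index_years = NULL) {
  gd <- list(ne = 50, nn = 80, doy_step = 5)
  unknown <- setdiff(names(grid), names(gd))
  if (length(unknown))
    stop("pipeline_config: unknown grid key(s): ", paste(unknown, collapse = ", "))
  gd[names(grid)] <- grid
  if (!all(models %in% as.character(1:10)))
    stop("pipeline_config: models must be ids '1'..'10'")
  if (!simulate && is.null(input))
    stop("pipeline_config: either an input path or simulate = TRUE is required")
  structure(list(input = input, simulate = simulate, outdir = outdir,
                 seed = as.integer(seed), years = years, models = models,
                 split_latitude = split_latitude, gamma = gamma, k = k,
                 optim_maxit = optim_maxit, n_draws = n_draws, grid = gd,
                 region = region, index_years = index_years),
            class = "bw_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Unknown keys are a startup error (named in the message), so typos never
#' silently fall back to defaults.
#'
#' @param path JSON file of configuration keys.
#' @return a `bw_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("read_pipeline_config: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

.region_from_config <- function(region) {
  if (!is.null(region$lon))
    return(region_polygon(region$lon, region$lat, name = "custom"))
  default_region(biscay_notch = region$biscay_notch %||% TRUE,
                 norwegian_notch = region$norwegian_notch %||% TRUE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order: `simulate` (write a synthetic
#' survey and its truth sidecar), `fit` (read, region-filter, fit the
#' configured ensemble members, write the comparison table and the
#' best-model archive) and `products` (evaluate the best model on the
#' product grid and write the spatial density, peak-timing, zonal marginal
#' and annual index CSVs). A `run.log` records timestamps, seeds and
#' settings; outputs of completed stages are preserved if a later stage
#' fails.
#'
#' @param config a `bw_config`.
#' @param stages subset of `c("simulate", "fit", "products")` in pipeline
#'   order.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "fit", "products")) {
  stopifnot(inherits(config, "bw_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "run.log")
  logln <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                     tz = "UTC"), sprintf(...))
    cat(msg, "\n", sep = "", file = logfile, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    logln("stage %s: start", name)
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    logln("stage %s: done", name)
    res
  }
  logln("run_pipeline: seed=%d outdir=%s stages=%s", config$seed,
        config$outdir, paste(stages, collapse = ","))
  obs_path <- config$input
  if ("simulate" %in% stages) {
    obs_path <- file.path(config$outdir, "observations.csv")
    stage("simulate", {
      truth <- default_truth(years = config$years[1]:config$years[2])
      design <- default_design()
      samples <- generate_samples(design, config$years[1]:config$years[2],
                                  seed = config$seed)
      obs <- simulate_observations(truth, samples, seed = config$seed + 1L)
      write_observations(obs, obs_path)
      write_truth_sidecar(truth, file.path(config$outdir, "truth.txt"))
      logln("simulate: %d samples, %.2f%% presences", nrow(obs),
            100 * mean(obs$presence))
    })
  }
  settings <- fit_settings(gamma = config$gamma, k = config$k,
                           optim_maxit = config$optim_maxit)
  model <- NULL
  if ("fit" %in% stages) {
    stage("fit", {
      if (is.null(obs_path)) stop("no input observations configured")
      obs <- read_observations(obs_path)
      obs <- filter_region(obs, .region_from_config(config$region))
      rep <- attr(obs, "exclusion_report")
      logln("filter: retained %d/%d rows (%d/%d presences)",
            rep$n_retained, rep$n_input, rep$presences_retained,
            rep$presences_input)
      utils::write.csv(rep, file.path(config$outdir, "exclusion_report.csv"),
                       row.names = FALSE)
      specs <- build_ensemble(config$split_latitude)[config$models]
      ens <- if (length(specs) >= 2) {
        compare_ensemble(obs, specs, settings)
      } else {
        m1 <- bw_gam(obs, specs[[1]], settings)
        structure(list(table = data.frame(
          model = names(specs), f = format(specs[[1]]),
          comps = n_components(specs[[1]]),
          dev_expl = deviance_explained(m1), auc = auc(m1$y, m1$fitted),
          aic = m1$aic, edf = m1$edf, dn = m1$dn_coef,
          error = NA_character_, delta_aic_1 = NA_real_,
          delta_aic_all = 0, no_support = FALSE),
          models = list(m1), settings = settings), class = "bw_ensemble")
      }
      utils::write.csv(ens$table, file.path(config$outdir, "ensemble.csv"),
                       row.names = FALSE)
      model <- best_model(ens)
      bw_gam_save(model, file.path(config$outdir, "model_best.json"))
      logln("fit: best model '%s' (AIC %.1f, edf %.1f)",
            ens$table$model[which.min(ens$table$aic)], model$aic, model$edf)
    })
  }
  if ("products" %in% stages) {
    stage("products", {
      if (is.null(model)) {
        mp <- file.path(config$outdir, "model_best.json")
        if (!file.exists(mp)) stop("no fitted model available; run 'fit' first")
        model <- bw_gam_load(mp)
      }
      axes <- default_grid_axes(model, ne = config$grid$ne,
                                nn = config$grid$nn,
                                doy_step = config$grid$doy_step)
      grid <- evaluate_grid(model, axes)
      pdf <- spatial_pdf(grid)
      utils::write.csv(as.data.frame(pdf),
                       file.path(config$outdir, "spatial_pdf.csv"),
                       row.names = FALSE)
      utils::write.csv(peak_timing_map(grid),
                       file.path(config$outdir, "peak_timing.csv"),
                       row.names = FALSE)
      zm <- zonal_marginal(grid)
      zdf <- data.frame(
        north = rep(zm$north, times = length(zm$doy) * length(zm$comps)),
        lat = rep(zm$lat, times = length(zm$doy) * length(zm$comps)),
        doy = rep(rep(zm$doy, each = length(zm$north)), length(zm$comps)),
        comp = rep(zm$comps, each = length(zm$north) * length(zm$doy)),
        density = as.vector(zm$density))
      utils::write.csv(zdf, file.path(config$outdir, "zonal_marginal.csv"),
                       row.names = FALSE)
      idx <- annual_index(model, axes, years = config$index_years,
                          n_draws = config$n_draws,
                          seed = config$seed + 2L)
      utils::write.csv(idx, file.path(config$outdir, "annual_index.csv"),
                       row.names = FALSE)
      pk <- zonal_peak_days(zm)
      logln("products: peak days [%s]",
            paste(sprintf("%s=%g", names(pk), pk), collapse = ", "))
    })
  }
  logln("run_pipeline: complete")
  invisible(config$outdir)
}
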