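#' Regressor specification for grid runs
#'
#' @param family one of \code{"PLSR"}, \code{"LWR"}, \code{"MLR"},
#'   \code{"ANN"}, \code{"SVR"}.
#' @param ... family-specific hyperparameters passed to the corresponding
#'   \code{fit_*} function (e.g. \code{n_components} for PLSR).
#' @return An object of class \code{regressor_spec}.
#' @export
regressor_spec <- function(family, ...) {
  family <- match.arg(family, c("PLSR", "LWR", "MLR", "ANN", "SVR"))
  structure(list(family = family, hyper = list(...)),
            class = "regressor_spec")
}

.fit_regressor <- function(spec, X, y) {
  args <- c(list(X, y), spec$hyper)
  switch(spec$family,
         PLSR = do.call(fit_plsr, args),
         LWR = do.call(fit_lwr, args),
         MLR = do.call(fit_mlr, args),
         ANN = do.call(fit_ann, args),
         SVR = do.call(fit_svr, args))
}

#' Experiment grid configuration
#'
#' Bundles everything one reproducible experiment grid needs: the data
#' source (a [generator_config] or in-memory spectra + traits), the trait
#' to model, the pretreatment arms, optional CARS wavelength selection,
#' the models, the split parameters and the seeds.
#'
#' @param data a [generator_config], or a list with \code{$spectra}
#'   (a [spectra_matrix]) and \code{$traits} (data.frame with \code{id}
#'   and trait columns).
#' @param trait trait column name to model.
#' @param pretreatments character vector drawn from \code{"raw"},
#'   \code{"MWS"}, \code{"SG"}, \code{"FDR"}, \code{"SDR"}, \code{"WT"}.
#' @param selection \code{"none"} or \code{"CARS"}.
#' @param models list of [regressor_spec], [deep2d_spec] or [deepfc_spec]
#'   objects.
#' @param split list: \code{cal_pred_ratio}, \code{val_fraction},
#'   \code{seed}.
#' @param cars list of [cars_select] arguments (runs, cv_folds, ...).
#' @param train a [train_config] for deep models.
#' @param outdir optional artifact directory.
#' @param seed master seed used where a finer one is not given.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(data = generator_config(), trait = "ssc",
                       pretreatments = "raw", selection = "none",
                       models = list(regressor_spec("PLSR",
                                                    n_components = 10L)),
                       split = list(cal_pred_ratio = c(2, 1),
                                    val_fraction = 0.15, seed = 1L),
                       cars = list(runs = 50L, cv_folds = 5L,
                                   mc_fraction = 0.8, max_components = 10L),
                       train = train_config(), outdir = NULL, seed = 1L) {
  if (!length(models)) stop("at least one model is required")
  selection <- match.arg(selection, c("none", "CARS"))
  bad <- setdiff(pretreatments, c("raw", "MWS", "SG", "FDR", "SDR", "WT"))
  if (length(bad)) stop("unknown pretreatments: ", paste(bad, collapse = ", "))
  structure(list(data = data, trait = trait, pretreatments = pretreatments,
                 selection = selection, models = models, split = split,
                 cars = cars, train = train, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

.resolve_data <- function(config) {
  if (inherits(config$data, "generator_config")) {
    g <- generate_spectra(config$data)
    list(spectra = g$spectra, traits = g$traits)
  } else {
    stopifnot(inherits(config$data$spectra, "spectra_matrix"),
              is.data.frame(config$data$traits))
    config$data
  }
}

.model_label <- function(m) {
  if (inherits(m, "regressor_spec")) m$family
  else if (inherits(m, "deep2d_spec")) "Deep2D"
  else if (inherits(m, "deepfc_spec")) "DeepFC"
  else stop("unsupported model spec of class ", class(m)[1])
}

#' Run a (pretreatment x selection x model) experiment grid
#'
#' For every grid cell: pretreat the spectra, split them (after
#' pretreatment, so the representative-sampling step sees what the model
#' sees), optionally run CARS on the calibration samples only and restrict
#' all splits to the selected bands, fit, and evaluate on the three
#' splits. Deep models always consume the raw spectra (their premise is
#' end-to-end learning without manual feature engineering), split on the
#' raw axis. A failing cell is recorded and skipped, never fatal.
#'
#' @param config a [run_config].
#' @return List: \code{$results} (one [evaluate_model] row per successful
#'   cell, with selection bookkeeping columns), \code{$failures}
#'   (data.frame of failed cells and messages), \code{$artifacts} (paths
#'   written, when \code{outdir} is set), \code{$cars} (per-cell
#'   [cars_select] results).
#' @export
run_grid <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dat <- .resolve_data(config)
  y_all <- dat$traits[[config$trait]]
  if (is.null(y_all)) stop("trait not found in traits table: ", config$trait)
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  rows <- list(); fails <- list(); artifacts <- character(0)
  cars_store <- list()
  for (m in config$models) {
    label <- .model_label(m)
    is_deep <- !inherits(m, "regressor_spec")
    arms <- if (is_deep) "raw" else config$pretreatments
    for (tt in arms) {
      cell <- paste(label, tt, config$selection, sep = "_")
      res <- tryCatch({
        Xp <- pretreat(dat$spectra, tt)
        split <- split_samples(Xp, config$split$cal_pred_ratio,
                               config$split$val_fraction,
                               config$split$seed %||% config$seed)
        n_bands <- ncol(Xp$values)
        if (!is_deep && config$selection == "CARS") {
          cal_idx <- split$calibration
          cs <- do.call(cars_select,
                        c(list(Xp[cal_idx, ], y_all[cal_idx],
                               seed = config$seed), config$cars))
          cars_store[[cell]] <- cs
          Xp <- apply_bands(Xp, cs$selected)
          n_bands <- length(cs$selected)
          if (!is.null(outdir)) {
            cp <- file.path(outdir, paste0(cell, "_cars.json"))
            write_cars(cs, cp)
            artifacts <- c(artifacts, cp)
          }
        }
        model <- if (is_deep) {
          built <- if (inherits(m, "deep2d_spec")) build_deep2d(m)
                   else build_deepfc(m)
          train_deep(built, Xp[split$calibration, ],
                     y_all[split$calibration],
                     Xp[split$validation, ], y_all[split$validation],
                     config$train)
        } else {
          .fit_regressor(m, Xp[split$calibration, ],
                         y_all[split$calibration])
        }
        rep <- evaluate_model(model, split, Xp, y_all, model_tag = label,
                              treatment_tag = tt)
        rep$selection <- if (is_deep) "none" else config$selection
        rep$n_bands <- n_bands
        rep$seed <- config$seed
        rep
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fails[[cell]] <- conditionMessage(res)
      } else {
        rows[[cell]] <- res
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(results)) rownames(results) <- NULL
  failures <- if (length(fails))
    data.frame(cell = names(fails), message = unlist(fails),
               row.names = NULL, stringsAsFactors = FALSE)
  else data.frame(cell = character(0), message = character(0))
  if (!is.null(outdir) && !is.null(results)) {
    rp <- file.path(outdir, "results.csv")
    utils::write.csv(results, rp, row.names = FALSE)
    cfgp <- file.path(outdir, "run_config.json")
    jsonlite::write_json(list(trait = config$trait,
                              pretreatments = config$pretreatments,
                              selection = config$selection,
                              models = vapply(config$models, .model_label, ""),
                              split = config$split, seed = config$seed),
                         cfgp, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, rp, cfgp)
  }
  list(results = results, failures = failures, artifacts = artifacts,
       cars = cars_store)
}
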