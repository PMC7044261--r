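#' Run configuration
#'
#' Bundles everything a reproducible pipeline run needs: a mode, a seed,
#' an output directory, the generating parameter fixture (or a JSON
#' parameter file) and optional design overrides. Every run writes a
#' manifest recording the seed, parameters and design, sufficient to
#' regenerate its outputs bit-identically.
#'
#' @param mode one of \code{"simulate-psychophysics"},
#'   \code{"simulate-eeg"}, \code{"fit"}, \code{"reproduce-table1"}.
#' @param seed integer seed for all stochastic stages.
#' @param out output directory (created; refuses to overwrite a non-empty
#'   directory unless \code{overwrite = TRUE}).
#' @param fixture name of a shipped parameter fixture (see
#'   \code{\link{fixture_names}}), or NULL.
#' @param params_file path to a JSON parameter bundle, or NULL.
#' @param data path(s) to input dataset(s) for fitting modes.
#' @param model \code{"gain"} or \code{"linear"} (fitting modes).
#' @param fix named list of fixed parameters for fitting.
#' @param overrides named list of design overrides (\code{pedestals},
#'   \code{depths}, \code{n_reps}, \code{n_participants},
#'   \code{noise_sd}).
#' @param overwrite allow writing into an existing non-empty directory.
#' @param verbose print one log line per stage.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(mode = c("simulate-psychophysics", "simulate-eeg",
                                "fit", "reproduce-table1"),
                       seed = 1, out = "binsum-run", fixture = NULL,
                       params_file = NULL, data = NULL,
                       model = c("gain", "linear"), fix = list(),
                       overrides = list(), overwrite = FALSE,
                       verbose = TRUE) {
  structure(list(mode = match.arg(mode), seed = as.integer(seed), out = out,
                 fixture = fixture, params_file = params_file, data = data,
                 model = match.arg(model), fix = fix, overrides = overrides,
                 overwrite = overwrite, verbose = verbose),
            class = "run_config")
}

.resolve_params <- function(cfg) {
  if (!is.null(cfg$params_file)) return(read_params(cfg$params_file))
  fixture <- cfg$fixture %||% "6a"
  if (!fixture %in% fixture_names()) {
    stop("unknown fixture '", fixture, "'; available fixtures: ",
         paste(fixture_names(), collapse = ", "))
  }
  table1_params(fixture)
}

.prepare_out <- function(cfg) {
  if (dir.exists(cfg$out) && length(list.files(cfg$out)) > 0 &&
      !cfg$overwrite) {
    stop("output directory '", cfg$out, "' is not empty; pass ",
         "overwrite = TRUE to reuse it")
  }
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  invisible(cfg$out)
}

.log_stage <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message("[binsum] ", sprintf(...))
  invisible(NULL)
}

.write_manifest <- function(cfg, extra = list()) {
  manifest <- c(list(mode = cfg$mode, seed = cfg$seed,
                     fixture = cfg$fixture, model = cfg$model,
                     overrides = cfg$overrides,
                     package_version = as.character(
                       utils::packageVersion("binsum"))),
                extra)
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}

#' Simulate and save a discrimination experiment
#'
#' Runs \code{\link{simulate_experiment}} under a \code{\link{run_config}}
#' and writes the threshold dataset, the full trial log and a manifest to
#' the output directory.
#'
#' @param cfg a \code{\link{run_config}} (mode
#'   \code{"simulate-psychophysics"}).
#' @return the \code{dipper_dataset}, invisibly; files
#'   \code{thresholds.tsv}, \code{trials.tsv}, \code{params.json},
#'   \code{manifest.json} in \code{cfg$out}.
#' @export
run_simulate_psychophysics <- function(cfg) {
  .prepare_out(cfg)
  params <- .resolve_params(cfg)
  ov <- cfg$overrides
  pedestals <- ov$pedestals %||% c(0, 1, 2, 4, 8, 16, 32, 64)
  n_reps <- ov$n_reps %||% 3
  n_participants <- ov$n_participants %||% 1
  .log_stage(cfg, "simulate-psychophysics: seed %d, %d pedestal(s), %d rep(s), %d participant(s)",
             cfg$seed, length(pedestals), n_reps, n_participants)
  ds <- simulate_experiment(params, n_reps = n_reps,
                            n_participants = n_participants,
                            seed = cfg$seed, pedestals = pedestals,
                            keep_trials = TRUE)
  write_dipper_dataset(ds, file.path(cfg$out, "thresholds.tsv"))
  write_trial_log(attr(ds, "trials"), file.path(cfg$out, "trials.tsv"))
  write_params(params, file.path(cfg$out, "params.json"))
  .write_manifest(cfg, list(n_trials = sum(ds$n_trials),
                            pedestals = pedestals))
  .log_stage(cfg, "wrote %d thresholds (%d trials) to %s", nrow(ds),
             sum(ds$n_trials), cfg$out)
  invisible(ds)
}

#' Simulate and save a steady-state EEG experiment
#'
#' Runs \code{\link{simulate_eeg_experiment}} under a
#' \code{\link{run_config}} and writes the SNR dataset and a manifest.
#'
#' @param cfg a \code{\link{run_config}} (mode \code{"simulate-eeg"}).
#' @return the \code{eeg_dataset}, invisibly; files \code{snr.tsv},
#'   \code{params.json}, \code{manifest.json} in \code{cfg$out}.
#' @export
run_simulate_eeg <- function(cfg) {
  .prepare_out(cfg)
  params <- .resolve_params(cfg)
  if (is.na(params$sigma35)) {
    stop("the chosen fixture has no sigma35; EEG simulation needs one ",
         "(use an EEG fixture such as '6d')")
  }
  ov <- cfg$overrides
  depths <- ov$depths %||% c(6.25, 12.5, 25, 50, 100)
  n_reps <- ov$n_reps %||% 10
  n_participants <- ov$n_participants %||% 12
  noise_sd <- ov$noise_sd %||% 1
  .log_stage(cfg, "simulate-eeg: seed %d, %d depth(s), %d rep(s), %d participant(s)",
             cfg$seed, length(depths), n_reps, n_participants)
  ds <- simulate_eeg_experiment(params, noise_sd = noise_sd, depths = depths,
                                n_reps = n_reps,
                                n_participants = n_participants,
                                seed = cfg$seed)
  write_eeg_dataset(ds, file.path(cfg$out, "snr.tsv"))
  write_params(params, file.path(cfg$out, "params.json"))
  .write_manifest(cfg, list(depths = depths, noise_sd = noise_sd,
                            gain = as.list(attr(ds, "gain"))))
  .log_stage(cfg, "wrote %d SNR cells to %s", nrow(ds), cfg$out)
  invisible(ds)
}

.load_any_dataset <- function(path) {
  header <- names(utils::read.table(path, header = TRUE, sep = "\t",
                                    nrows = 1))
  if ("snr" %in% header) read_eeg_dataset(path) else
    read_dipper_dataset(path)
}

#' Fit a model to a saved dataset
#'
#' Loads a threshold or SNR dataset (auto-detected by its columns), fits
#' the requested model and writes the fit result JSON plus prediction
#' curves for plotting.
#'
#' @param cfg a \code{\link{run_config}} (mode \code{"fit"}) with
#'   \code{data} set to a dataset path.
#' @return the \code{fit_result}, invisibly.
#' @export
run_fit <- function(cfg) {
  .prepare_out(cfg)
  if (is.null(cfg$data)) {
    stop("no input dataset; generate one with run_simulate_psychophysics() ",
         "or run_simulate_eeg() and pass its thresholds.tsv / snr.tsv path")
  }
  data <- .load_any_dataset(if (is.list(cfg$data)) cfg$data[[1]] else
    cfg$data)
  model <- if (cfg$model == "linear") "linear_sum" else "gain_control"
  n_restarts <- cfg$overrides$n_restarts %||% 20
  .log_stage(cfg, "fit: %s model, %s data, %d restarts, seed %d", model,
             if (inherits(data, "eeg_dataset")) "EEG" else "dipper",
             n_restarts, cfg$seed)
  fit <- if (inherits(data, "eeg_dataset")) {
    fit_eeg(data, model, fix = cfg$fix, n_restarts = n_restarts,
            seed = cfg$seed)
  } else {
    fit_dipper(data, model, fix = cfg$fix, n_restarts = n_restarts,
               seed = cfg$seed)
  }
  write_fit_result(fit, file.path(cfg$out, "fit.json"))
  .write_predictions(fit, cfg$out)
  .write_manifest(cfg, list(data = cfg$data, rmse = fit$rmse,
                            units = fit$units))
  .log_stage(cfg, "RMSE = %.4g %s", fit$rmse, fit$units)
  invisible(fit)
}

# prediction curves on a dense grid, for plotting
.write_predictions <- function(fit, out_dir, label = "fit") {
  path <- file.path(out_dir, paste0("predictions_", label, ".tsv"))
  if (fit$data_kind == "dipper") {
    peds <- c(0, 10^seq(-0.5, log10(64), length.out = 25))
    rows <- lapply(psy_conditions(), function(cond) {
      data.frame(condition = cond, pedestal_pct = peds,
                 threshold_db = dipper_curve(cond, peds, fit$params,
                                             fit$model, on_fail = "na"),
                 stringsAsFactors = FALSE)
    })
  } else {
    depths <- 10^seq(log10(6.25), 2, length.out = 25)
    rows <- lapply(eeg_conditions(), function(cond) {
      eeg_response_curve(cond, depths, fit$params, fit$model)
    })
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full model-comparison program
#'
#' Executes the eight canonical fit/evaluation configurations against a
#' pair of datasets (one discrimination, one EEG): the free gain-control
#' fit, its \eqn{\omega = 1} evaluation and the \eqn{\omega = 1} refit for
#' each data type, plus the linear-summation fit to each data type. Writes
#' the comparison table (TSV and JSON), per-fit JSON and dense prediction
#' curves.
#'
#' @param cfg a \code{\link{run_config}} (mode \code{"reproduce-table1"})
#'   with \code{data} a length-2 vector/list: the dipper dataset path and
#'   the EEG dataset path (either may be NULL to skip that data type).
#' @param dipper,eeg alternatively, pass the datasets directly.
#' @return the \code{model_comparison} table, invisibly.
#' @export
run_reproduce_table1 <- function(cfg, dipper = NULL, eeg = NULL) {
  .prepare_out(cfg)
  if (is.null(dipper) && !is.null(cfg$data[[1]])) {
    dipper <- read_dipper_dataset(cfg$data[[1]])
  }
  if (is.null(eeg) && length(cfg$data) > 1 && !is.null(cfg$data[[2]])) {
    eeg <- read_eeg_dataset(cfg$data[[2]])
  }
  if (is.null(dipper) && is.null(eeg)) {
    stop("no input datasets; generate them with ",
         "run_simulate_psychophysics() and run_simulate_eeg() first")
  }
  n_restarts <- cfg$overrides$n_restarts %||% 20
  fits <- list()
  if (!is.null(dipper)) {
    .log_stage(cfg, "dipper: free gain-control fit")
    fits[["6a"]] <- fit_dipper(dipper, "gain_control",
                               n_restarts = n_restarts, seed = cfg$seed)
    .log_stage(cfg, "dipper: omega = 1 evaluation")
    fits[["6b"]] <- evaluate_fixed(fits[["6a"]]$params, list(omega = 1),
                                   dipper, "gain_control")
    .log_stage(cfg, "dipper: omega = 1 refit")
    fits[["6c"]] <- fit_dipper(dipper, "gain_control", fix = list(omega = 1),
                               n_restarts = n_restarts, seed = cfg$seed)
    .log_stage(cfg, "dipper: linear-summation fit")
    fits[["7a"]] <- fit_dipper(dipper, "linear_sum",
                               n_restarts = n_restarts, seed = cfg$seed)
  }
  if (!is.null(eeg)) {
    .log_stage(cfg, "eeg: free gain-control fit")
    fits[["6d"]] <- fit_eeg(eeg, "gain_control", n_restarts = n_restarts,
                            seed = cfg$seed)
    .log_stage(cfg, "eeg: omega = 1 evaluation")
    fits[["6e"]] <- evaluate_fixed(fits[["6d"]]$params, list(omega = 1),
                                   eeg, "gain_control")
    .log_stage(cfg, "eeg: omega = 1 refit")
    fits[["6f"]] <- fit_eeg(eeg, "gain_control", fix = list(omega = 1),
                            n_restarts = n_restarts, seed = cfg$seed)
    .log_stage(cfg, "eeg: linear-summation fit")
    fits[["7b"]] <- fit_eeg(eeg, "linear_sum", n_restarts = n_restarts,
                            seed = cfg$seed)
  }
  report <- table1_report(fits, datasets = list(dipper = dipper, eeg = eeg))
  utils::write.table(as.data.frame(report),
                     file.path(cfg$out, "comparison.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.data.frame(report),
                       file.path(cfg$out, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  for (nm in names(fits)) {
    write_fit_result(fits[[nm]], file.path(cfg$out,
                                           paste0("fit_", nm, ".json")))
    .write_predictions(fits[[nm]], cfg$out, nm)
  }
  .write_manifest(cfg, list(rows = nrow(report)))
  .log_stage(cfg, "wrote comparison table with %d rows to %s",
             nrow(report), cfg$out)
  invisible(report)
}
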