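#' Read and write threshold datasets
#'
#' Dipper datasets travel as tab-delimited text with columns
#' \code{condition}, \code{pedestal_pct}, \code{threshold_db},
#' \code{n_trials} and (optionally) \code{pooled}.
#'
#' @param data a \code{dipper_dataset}.
#' @param path file path.
#' @return \code{read_dipper_dataset} returns a \code{dipper_dataset};
#'   writers return \code{path} invisibly.
#' @export
write_dipper_dataset <- function(data, path) {
  utils::write.table(as.data.frame(data), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dipper_dataset
#' @export
read_dipper_dataset <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("condition", "pedestal_pct", "threshold_db")
  if (!all(need %in% names(d))) {
    stop("dipper dataset needs columns: ", paste(need, collapse = ", "))
  }
  if (!"pooled" %in% names(d)) {
    d$pooled <- d$pedestal_pct == 0 &
      d$condition %in% c("MON", "DICH", "HALF_BIN")
  }
  class(d) <- c("dipper_dataset", "data.frame")
  d
}

#' Read and write steady-state SNR datasets
#'
#' EEG SNR datasets travel as tab-delimited text with columns
#' \code{condition}, \code{depth_pct}, \code{freq} (\code{F40}/\code{F35}),
#' \code{snr} and optionally \code{n_participants}.
#'
#' @param data an \code{eeg_dataset}.
#' @param path file path.
#' @return \code{read_eeg_dataset} returns an \code{eeg_dataset}; writers
#'   return \code{path} invisibly.
#' @export
write_eeg_dataset <- function(data, path) {
  utils::write.table(as.data.frame(data), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_eeg_dataset
#' @export
read_eeg_dataset <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("condition", "depth_pct", "freq", "snr")
  if (!all(need %in% names(d))) {
    stop("EEG dataset needs columns: ", paste(need, collapse = ", "))
  }
  class(d) <- c("eeg_dataset", "data.frame")
  d
}

#' Write a trial log
#'
#' Staircase trial logs travel as tab-delimited text (one row per trial).
#'
#' @param trials data.frame of trial records.
#' @param path file path.
#' @export
write_trial_log <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Serialize a fit result as JSON
#'
#' @param fit a \code{fit_result}.
#' @param path file path.
#' @return \code{read_fit_result} returns the parsed list; the writer
#'   returns \code{path} invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  out <- list(model = fit$model, data = fit$data_kind,
              params = unclass(fit$params), fixed = fit$fixed,
              rmse = fit$rmse, units = fit$units,
              n_restarts = fit$n_restarts, seed = fit$seed,
              converged = fit$converged)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_fit_result
#' @export
read_fit_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
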