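#' Root-mean-square error between model and data
#'
#' The fit metric: the square root of the mean squared difference between
#' model predictions and data across all points in a panel. \code{rmse_db}
#' is used for threshold data (dB units), \code{rmse_snr} for steady-state
#' SNR data (linear SNR units); the arithmetic is identical, the names
#' record the units.
#'
#' @param model_values,data_values numeric vectors of equal length.
#' @return the RMSE, in the units of the inputs.
#' @export
rmse_db <- function(model_values, data_values) {
  if (length(model_values) != length(data_values)) {
    stop("model and data index sets differ: ", length(model_values),
         " vs ", length(data_values), " points")
  }
  if (any(!is.finite(data_values))) stop("data values must be finite")
  sqrt(mean((model_values - data_values)^2))
}

#' @rdname rmse_db
#' @export
rmse_snr <- rmse_db

# ---- objective point sets --------------------------------------------------

# collapse the pooled MON/DICH/HALF_BIN detection rows to a single point so
# the shared detection threshold enters the objective once
.dipper_points <- function(data, count_pooled_once = TRUE) {
  d <- as.data.frame(data)[, c("condition", "pedestal_pct", "threshold_db",
                               if ("pooled" %in% names(data)) "pooled")]
  if (!"pooled" %in% names(d)) d$pooled <- FALSE
  if (count_pooled_once && any(d$pooled)) {
    pooled <- d[d$pooled, ]
    keep <- pooled[1, , drop = FALSE]
    d <- rbind(d[!d$pooled, ], keep)
  }
  d[order(d$condition, d$pedestal_pct), ]
}

# the seven fitted SNR curves: 40-Hz readouts of the five conditions that
# drive a 40-Hz response, plus 35-Hz readouts of the two cross conditions
# (the cross-monaural condition is omitted from the objective)
.EEG_FIT_CURVES <- data.frame(
  condition = c("MON", "BIN", "DICH", "CROSS_BIN", "CROSS_DICH",
                "CROSS_BIN", "CROSS_DICH"),
  freq = c("F40", "F40", "F40", "F40", "F40", "F35", "F35"),
  stringsAsFactors = FALSE)

.eeg_points <- function(data) {
  d <- as.data.frame(data)[, c("condition", "depth_pct", "freq", "snr")]
  d <- merge(d, .EEG_FIT_CURVES, by = c("condition", "freq"))
  d[order(d$condition, d$freq, d$depth_pct), ]
}

# precomputed per-point stimulus design for the EEG objective: depth of each
# ear at the readout tag, and each ear's total depth (the suppressive input
# to the opposite ear), so predictions vectorise over points
.eeg_design <- function(points, masker = 50) {
  n <- nrow(points)
  CLa <- CRa <- oL <- oR <- numeric(n)
  for (i in seq_len(n)) {
    arr <- eeg_arrangement(points$condition[i], points$depth_pct[i], masker)
    f <- points$freq[i]
    CLa[i] <- if (arr$left$tag == f) arr$left$depth else 0
    CRa[i] <- if (arr$right$tag == f) arr$right$depth else 0
    oL[i] <- arr$left$depth
    oR[i] <- arr$right$depth
  }
  list(CLa = CLa, CRa = CRa, oL = oL, oR = oR,
       sigma_is_40 = points$freq == "F40")
}

.predict_eeg_design <- function(design, params, model) {
  if (model == "gain_control") {
    p <- params$p; q <- params$q; Zq <- params$Z^q; w <- params$omega
    resp <- design$CLa^p / (Zq + design$CLa^q + w * design$oR^q) +
            design$CRa^p / (Zq + design$CRa^q + w * design$oL^q)
  } else {
    S <- design$CLa + design$CRa
    resp <- S^params$p / (params$Z^params$q + S^params$q)
  }
  sigma <- ifelse(design$sigma_is_40, params$sigma40, params$sigma35)
  (resp + sigma) / sigma
}

# ---- constraint-preserving reparameterisation ------------------------------

# free parameters live in an unconstrained log space that enforces the fit
# constraints exactly: q = 2 + exp(a), p = q + exp(b), Z = exp(c),
# omega = exp(d), sigma = exp(g)
.FREE_RANGES <- list(
  q = c(-4, 1.0), p = c(-3, 1.0), Z = c(0, 4.6),
  omega = c(-5, 0.7), sigma40 = c(-3, 2), sigma35 = c(-3, 2))

.theta_to_params <- function(theta, free, fixed) {
  g <- function(name) {
    if (name %in% free) theta[match(name, free)] else fixed[[name]]
  }
  q <- if ("q" %in% free) 2 + exp(g("q")) else fixed$q
  p <- if ("p" %in% free) q + exp(g("p")) else fixed$p
  Z <- if ("Z" %in% free) exp(g("Z")) else fixed$Z
  omega <- if ("omega" %in% free) exp(g("omega")) else fixed$omega
  sigma40 <- if ("sigma40" %in% free) exp(g("sigma40")) else fixed$sigma40
  sigma35 <- if ("sigma35" %in% free) exp(g("sigma35")) else fixed$sigma35
  model_params(p = p, q = q, Z = Z, omega = omega,
               sigma40 = sigma40, sigma35 = sigma35, strict = FALSE)
}

.free_set <- function(model, data_kind, fix) {
  free <- c("q", "p", "Z", "omega", "sigma40",
            if (data_kind == "eeg") "sigma35")
  if (model == "linear_sum") free <- setdiff(free, "omega")
  setdiff(free, names(fix))
}

.multi_start_fit <- function(objective, free, n_restarts, seed, maxit) {
  set.seed(seed)
  k <- length(free)
  lows <- vapply(.FREE_RANGES[free], `[`, numeric(1), 1)
  highs <- vapply(.FREE_RANGES[free], `[`, numeric(1), 2)
  starts <- lhs::randomLHS(n_restarts, k)
  starts <- sweep(sweep(starts, 2, highs - lows, `*`), 2, lows, `+`)
  safe_obj <- function(theta) {
    v <- objective(theta)
    if (!is.finite(v)) 1e6 else v
  }
  best <- NULL
  evals <- 0L
  for (i in seq_len(n_restarts)) {
    fit <- stats::optim(starts[i, ], safe_obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    evals <- evals + fit$counts[["function"]]
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best$start <- i
    }
  }
  # polish the winner from its own optimum
  fit <- stats::optim(best$par, safe_obj, method = "Nelder-Mead",
                      control = list(maxit = 4 * maxit, reltol = 1e-12))
  evals <- evals + fit$counts[["function"]]
  if (fit$value < best$value) { fit$start <- best$start; best <- fit }
  best$evals <- evals
  best
}

.new_fit_result <- function(model, params, rmse, units, data_kind,
                            fixed = list(), n_restarts = 0, seed = NA,
                            converged = TRUE, evals = 0, start = NA) {
  structure(list(model = model, params = params, rmse = rmse, units = units,
                 data_kind = data_kind, fixed = fixed,
                 n_restarts = n_restarts, seed = seed, converged = converged,
                 evals = evals, best_start = start),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s model fit to %s data\n",
              if (x$model == "gain_control") "Gain-control" else
                "Linear-summation", x$data_kind))
  cat(" ", format(x$params), "\n")
  if (length(x$fixed)) {
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                          collapse = ", "), "\n")
  }
  cat(sprintf("  RMSE = %.4g %s (%d restart(s), seed %s, converged: %s)\n",
              x$rmse, x$units, x$n_restarts, as.character(x$seed),
              x$converged))
  invisible(x)
}

# ---- fits ------------------------------------------------------------------

#' Fit a combination model to discrimination thresholds
#'
#' Minimises the dB-unit RMSE between predicted and observed dipper
#' functions. Constraints (all parameters positive, \eqn{q \ge 2},
#' \eqn{p > q}) are enforced exactly by reparameterisation
#' (\eqn{q = 2 + e^a}, \eqn{p = q + e^b}, log-space for the rest);
#' optimisation is derivative-free (Nelder-Mead) from \code{n_restarts}
#' Latin-hypercube starting points, and the best restart is polished and
#' returned. The pooled detection threshold shared by the monaural,
#' dichotic and half-binaural conditions enters the objective once.
#'
#' The free parameters are \eqn{p, q, Z, \omega, \sigma_{40}} for the
#' gain-control model and \eqn{p, q, Z, \sigma_{40}} for the
#' linear-summation model (which has no suppression weight); any parameter
#' named in \code{fix} is held at the given value instead.
#'
#' @param data a \code{dipper_dataset} (columns \code{condition},
#'   \code{pedestal_pct}, \code{threshold_db}, optionally \code{pooled}).
#' @param model \code{"gain_control"} or \code{"linear_sum"}.
#' @param fix named list of parameters to hold fixed, e.g.
#'   \code{list(omega = 1)}.
#' @param n_restarts number of Latin-hypercube starting points.
#' @param seed integer seed controlling the starting points (fits are
#'   deterministic given data, spec and seed).
#' @param maxit Nelder-Mead iteration cap per restart.
#' @param count_pooled_once if TRUE (default) the pooled detection point
#'   enters the objective once; FALSE counts it per condition.
#' @return a \code{fit_result}: fitted \code{\link{model_params}}, RMSE,
#'   and optimisation provenance.
#' @export
fit_dipper <- function(data, model = c("gain_control", "linear_sum"),
                       fix = list(), n_restarts = 20, seed = 1, maxit = 500,
                       count_pooled_once = TRUE) {
  model <- match.arg(model)
  pts <- .dipper_points(data, count_pooled_once)
  design <- .psy_design(pts$condition, pts$pedestal_pct)
  fixed <- utils::modifyList(list(omega = 0, sigma35 = NA_real_), fix)
  free <- .free_set(model, "dipper", fix)
  objective <- function(theta) {
    params <- .theta_to_params(theta, free, fixed)
    pred <- .solve_increment(design, params, model, params$sigma40)
    pred_db <- 20 * log10(pred)
    pred_db[!is.finite(pred_db)] <- 100  # out-of-range prediction penalty
    rmse_db(pred_db, pts$threshold_db)
  }
  best <- .multi_start_fit(objective, free, n_restarts, seed, maxit)
  params <- .theta_to_params(best$par, free, fixed)
  .new_fit_result(model, params, objective(best$par), "dB", "dipper",
                  fixed = fix, n_restarts = n_restarts, seed = seed,
                  converged = best$convergence == 0, evals = best$evals,
                  start = best$start)
}

#' Fit a combination model to steady-state SNR data
#'
#' Minimises the SNR-unit RMSE between predicted and observed modulation
#' response functions over the seven fitted curves (40-Hz readouts of the
#' monaural, binaural, dichotic, cross-binaural and cross-dichotic
#' conditions; 35-Hz readouts of the two cross conditions). The
#' gain-control model has six free parameters
#' (\eqn{p, q, Z, \omega, \sigma_{40}, \sigma_{35}}), the linear-summation
#' model five (no \eqn{\omega}). Machinery as in \code{\link{fit_dipper}}.
#'
#' @param data an \code{eeg_dataset} (columns \code{condition},
#'   \code{depth_pct}, \code{freq}, \code{snr}).
#' @param masker masker depth used by the masked conditions, percent.
#' @inheritParams fit_dipper
#' @return a \code{fit_result}.
#' @export
fit_eeg <- function(data, model = c("gain_control", "linear_sum"),
                    fix = list(), n_restarts = 20, seed = 1, maxit = 500,
                    masker = 50) {
  model <- match.arg(model)
  pts <- .eeg_points(data)
  if (nrow(pts) == 0) stop("no fittable curves found in the dataset")
  design <- .eeg_design(pts, masker)
  fixed <- utils::modifyList(list(omega = 0), fix)
  free <- .free_set(model, "eeg", fix)
  objective <- function(theta) {
    params <- .theta_to_params(theta, free, fixed)
    rmse_snr(.predict_eeg_design(design, params, model), pts$snr)
  }
  best <- .multi_start_fit(objective, free, n_restarts, seed, maxit)
  params <- .theta_to_params(best$par, free, fixed)
  .new_fit_result(model, params, objective(best$par), "SNR", "eeg",
                  fixed = fix, n_restarts = n_restarts, seed = seed,
                  converged = best$convergence == 0, evals = best$evals,
                  start = best$start)
}

#' Evaluate a parameter set with overrides, without refitting
#'
#' Recomputes predictions and RMSE for an existing parameter bundle after
#' overriding some of its values (typically raising the suppression weight
#' to \eqn{\omega = 1} while leaving the other parameters at their fitted
#' values). No optimisation is performed.
#'
#' @param params a \code{\link{model_params}} (e.g. from a prior fit).
#' @param override named list of parameter overrides, e.g.
#'   \code{list(omega = 1)}.
#' @param data a \code{dipper_dataset} or \code{eeg_dataset}.
#' @param model \code{"gain_control"} or \code{"linear_sum"}.
#' @param masker masker depth for EEG data, percent.
#' @param count_pooled_once see \code{\link{fit_dipper}}.
#' @return a \code{fit_result} with \code{n_restarts = 0}.
#' @export
evaluate_fixed <- function(params, override = list(), data,
                           model = c("gain_control", "linear_sum"),
                           masker = 50, count_pooled_once = TRUE) {
  model <- match.arg(model)
  vals <- utils::modifyList(unclass(params)[c("p", "q", "Z", "omega",
                                              "sigma40", "sigma35")],
                            override)
  new_params <- model_params(p = vals$p, q = vals$q, Z = vals$Z,
                             omega = vals$omega, sigma40 = vals$sigma40,
                             sigma35 = vals$sigma35, strict = FALSE)
  if (inherits(data, "eeg_dataset") ||
      (is.data.frame(data) && "snr" %in% names(data))) {
    pts <- .eeg_points(data)
    design <- .eeg_design(pts, masker)
    rmse <- rmse_snr(.predict_eeg_design(design, new_params, model), pts$snr)
    kind <- "eeg"; units <- "SNR"
  } else {
    pts <- .dipper_points(data, count_pooled_once)
    pred <- increment_threshold(pts$condition, pts$pedestal_pct, new_params,
                                model, on_fail = "na")
    pred_db <- 20 * log10(pred)
    pred_db[!is.finite(pred_db)] <- 100
    rmse <- rmse_db(pred_db, pts$threshold_db)
    kind <- "dipper"; units <- "dB"
  }
  .new_fit_result(model, new_params, rmse, units, kind, fixed = override)
}

#' Model-comparison summary table
#'
#' Collates a list of \code{fit_result}s into one comparison table, one row
#' per fit or evaluation, with columns for the parameters
#' (\eqn{p, q, Z, \sigma_{40}, \sigma_{35}, \omega}), the RMSE and its
#' units. Linear-summation rows report \code{omega} as NA (the model has
#' no suppression weight). Every row's RMSE is recomputed from its own
#' parameters when the corresponding dataset is supplied, guaranteeing
#' self-consistency.
#'
#' @param fits named list of \code{fit_result}s; names label the rows.
#' @param datasets optional named list with elements \code{dipper} and/or
#'   \code{eeg}, used to verify each row's RMSE by recomputation.
#' @return a data.frame of class \code{model_comparison}.
#' @export
table1_report <- function(fits, datasets = NULL) {
  if (length(fits) == 0) {
    out <- data.frame(label = character(), model = character(),
                      data = character(), p = numeric(), q = numeric(),
                      Z = numeric(), sigma40 = numeric(), sigma35 = numeric(),
                      omega = numeric(), rmse = numeric(),
                      units = character(), stringsAsFactors = FALSE)
    class(out) <- c("model_comparison", "data.frame")
    return(out)
  }
  if (is.null(names(fits))) names(fits) <- seq_along(fits)
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    rmse <- f$rmse
    if (!is.null(datasets)) {
      dat <- datasets[[f$data_kind]]
      if (!is.null(dat)) {
        rmse <- evaluate_fixed(f$params, list(), dat, model = f$model)$rmse
        if (abs(rmse - f$rmse) > 1e-6 + 1e-4 * abs(f$rmse)) {
          warning("RMSE for '", nm, "' did not recompute: stored ", f$rmse,
                  " vs ", rmse)
        }
      }
    }
    data.frame(label = nm, model = f$model, data = f$data_kind,
               p = f$params$p, q = f$params$q, Z = f$params$Z,
               sigma40 = f$params$sigma40, sigma35 = f$params$sigma35,
               omega = if (f$model == "linear_sum") NA_real_ else
                 f$params$omega,
               rmse = rmse, units = f$units, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat("Model comparison (one row per fit/evaluation):\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(col) signif(col, digits))
  print.data.frame(y, ...)
  invisible(x)
}
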