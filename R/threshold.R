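# Per-cell stimulus geometry for the increment-threshold solver. In every
# condition the signal-interval depths are affine in the target increment:
# left = pedestal + coefL * dm, right = pedR0 + coefR * dm.
.psy_design <- function(condition, pedestal) {
  n <- max(length(condition), length(pedestal))
  condition <- rep_len(condition, n)
  pedestal <- rep_len(pedestal, n)
  bad <- !condition %in% .PSY_CONDITIONS
  if (any(bad)) stop("unknown condition(s): ",
                     paste(unique(condition[bad]), collapse = ", "))
  both_ped <- condition %in% c("BIN", "HALF_BIN")
  list(
    Ls = pedestal,
    Rs = ifelse(both_ped, pedestal, 0),
    Lg0 = pedestal,
    coefL = ifelse(condition == "DICH", 0, 1),
    Rg0 = ifelse(both_ped, pedestal, 0),
    coefR = ifelse(condition == "BIN", 1,
            ifelse(condition == "DICH", 1, 0)),
    n = n)
}

# combination-rule response, elementwise over vectors or matrices of depths
.resp_raw <- function(L, R, params, model) {
  if (model == "gain_control") {
    p <- params$p; q <- params$q; Zq <- params$Z^q; w <- params$omega
    L^p / (Zq + L^q + w * R^q) + R^p / (Zq + R^q + w * L^q)
  } else {
    S <- L + R
    S^params$p / (params$Z^params$q + S^params$q)
  }
}

# Vectorised signed response change when a target increment dm is added to
# the pedestal per the condition's interaural arrangement. condition,
# pedestal and dm are recycled to a common length.
.delta_resp <- function(condition, pedestal, dm, params,
                        model = c("gain_control", "linear_sum")) {
  model <- match.arg(model)
  d <- .psy_design(condition, pedestal)
  dm <- rep_len(dm, d$n)
  .resp_raw(d$Lg0 + d$coefL * dm, d$Rg0 + d$coefR * dm, params, model) -
    .resp_raw(d$Ls, d$Rs, params, model)
}

# Core solver on a precomputed design: coarse log-grid bracketing of the
# first upward crossing of sigma, then vectorised bisection on log dm.
# Returns NA where the criterion is not bracketable in [lower, upper].
.solve_increment <- function(design, params, model, sigma,
                             lower = 1e-4, upper = 1e4, rel_tol = 1e-6) {
  n <- design$n
  resp_std <- .resp_raw(design$Ls, design$Rs, params, model)
  n_per_decade <- 25
  lg <- seq(log(lower), log(upper),
            length.out = ceiling(n_per_decade * log10(upper / lower)) + 1)
  dm_grid <- exp(lg)
  # n x length(lg) matrices of signal-interval depths
  Lg <- design$Lg0 + design$coefL %o% dm_grid
  Rg <- design$Rg0 + design$coefR %o% dm_grid
  crossed <- (.resp_raw(Lg, Rg, params, model) - resp_std >= sigma)
  crossed[is.na(crossed)] <- FALSE  # overflowed responses cannot bracket
  crossed <- crossed + 0
  any_cross <- rowSums(crossed) > 0
  first_cross <- max.col(crossed, ties.method = "first")
  bad <- !any_cross | first_cross == 1
  out <- rep(NA_real_, n)
  ok <- !bad
  if (any(ok)) {
    lo <- lg[first_cross[ok] - 1]
    hi <- lg[first_cross[ok]]
    Lg0 <- design$Lg0[ok]; cL <- design$coefL[ok]
    Rg0 <- design$Rg0[ok]; cR <- design$coefR[ok]
    std <- resp_std[ok]
    n_iter <- ceiling(log2((lg[2] - lg[1]) / (rel_tol / 2))) + 2
    for (i in seq_len(n_iter)) {
      mid <- (lo + hi) / 2
      dm <- exp(mid)
      above <- .resp_raw(Lg0 + cL * dm, Rg0 + cR * dm, params, model) -
        std >= sigma
      above[is.na(above)] <- TRUE  # overflow only at large dm; shrink hi
      hi[above] <- mid[above]
      lo[!above] <- mid[!above]
    }
    out[ok] <- exp((lo + hi) / 2)
  }
  out
}

#' Predicted increment threshold
#'
#' Finds the smallest target depth increment \eqn{\Delta m > 0} at which the
#' model response in the signal interval exceeds the response in the
#' standard (pedestal-only) interval by the criterion \code{sigma} (the
#' signed response increase must equal \code{sigma}; a transient response
#' decrement, possible under strong interaural suppression in the dichotic
#' condition, is passed over until the signed increase reaches the
#' criterion).
#'
#' The solver evaluates the response change on a logarithmic grid over
#' \code{[lower, upper]} percent to bracket the first upward crossing of the
#' criterion, then bisects on \eqn{\log \Delta m} to a relative tolerance of
#' \code{rel_tol}. Vectorised over \code{condition} and \code{pedestal}.
#'
#' @param condition psychophysical condition label(s); see
#'   \code{\link{psy_arrangement}}.
#' @param pedestal pedestal depth(s), percent (>= 0).
#' @param params a \code{\link{model_params}} object.
#' @param model \code{"gain_control"} or \code{"linear_sum"}.
#' @param sigma response-increment criterion; defaults to
#'   \code{params$sigma40}.
#' @param lower,upper bracketing range for \eqn{\Delta m}, percent.
#' @param rel_tol relative tolerance on the returned \eqn{\Delta m}.
#' @param on_fail \code{"error"} to signal when no crossing lies in range,
#'   \code{"na"} to return NA for those cells (used inside fitting
#'   objectives, where an out-of-range prediction is penalised, not fatal).
#' @return numeric vector of threshold increments, percent.
#' @examples
#' pars <- table1_params("6a")
#' increment_threshold("BIN", 8, pars)   # ~ 2% at the dip
#' @export
increment_threshold <- function(condition, pedestal, params,
                                model = c("gain_control", "linear_sum"),
                                sigma = params$sigma40,
                                lower = 1e-4, upper = 1e4, rel_tol = 1e-6,
                                on_fail = c("error", "na")) {
  model <- match.arg(model)
  on_fail <- match.arg(on_fail)
  if (any(pedestal < 0)) stop("pedestal must be >= 0")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  design <- .psy_design(condition, pedestal)
  out <- .solve_increment(design, params, model, sigma,
                          lower = lower, upper = upper, rel_tol = rel_tol)
  if (anyNA(out) && on_fail == "error") {
    bad <- is.na(out)
    stop("increment_threshold: criterion not bracketable in [", lower, ", ",
         upper, "] % for cell(s): ",
         paste(sprintf("%s@%g", rep_len(condition, design$n)[bad],
                       rep_len(pedestal, design$n)[bad]), collapse = ", "))
  }
  out
}

#' Predicted dipper function
#'
#' Increment thresholds across a pedestal grid, expressed in dB
#' (\eqn{20 \log_{10}(100 m)}, i.e. dB re 1 percent modulation). Plotted
#' against pedestal these curves show facilitation (the dip) followed by
#' masking (the rising handle).
#'
#' @inheritParams increment_threshold
#' @param pedestals vector of pedestal depths, percent.
#' @return numeric vector of thresholds in dB, one per pedestal.
#' @export
dipper_curve <- function(condition, pedestals, params,
                         model = c("gain_control", "linear_sum"),
                         sigma = params$sigma40, on_fail = c("error", "na")) {
  thr <- increment_threshold(condition, pedestals, params, model,
                             sigma = sigma, on_fail = match.arg(on_fail))
  20 * log10(thr)
}

#' Convert between percent modulation depth and dB
#'
#' The dB convention used throughout: \eqn{20 \log_{10}(100 m)} where
#' \eqn{100 m} is the depth in percent, so 1 percent modulation is 0 dB and
#' 100 percent is 40 dB.
#'
#' @param pct depth in percent.
#' @param db depth in dB re 1 percent.
#' @return the converted value.
#' @export
depth_to_db <- function(pct) 20 * log10(pct)

#' @rdname depth_to_db
#' @export
db_to_depth <- function(db) 10^(db / 20)

#' Predicted steady-state SNR response functions
#'
#' Model SNR versus signal modulation depth for one frequency-tagged EEG
#' condition. Responses are read out at both tag frequencies via
#' \code{\link{tagged_response}} and converted to SNR with the
#' frequency-appropriate noise parameter (\code{sigma40} for 40-Hz
#' readouts, \code{sigma35} for 35-Hz readouts).
#'
#' For the linear-summation model, each tag's response pools the depths of
#' ears carrying that tag through the transducer; ears carrying the other
#' tag do not contribute (there is no interaural suppression term to carry
#' them).
#'
#' @param condition an EEG condition label; see \code{\link{eeg_arrangement}}.
#' @param depths vector of signal modulation depths, percent.
#' @param params a \code{\link{model_params}} object; \code{sigma35} must be
#'   set for 35-Hz readouts.
#' @param model \code{"gain_control"} or \code{"linear_sum"}.
#' @param masker masker depth, percent, where the condition uses one.
#' @param freqs which tag frequencies to read out.
#' @return data.frame with columns \code{condition}, \code{depth_pct},
#'   \code{freq} (\code{"F40"}/\code{"F35"}) and \code{snr}.
#' @export
eeg_response_curve <- function(condition, depths, params,
                               model = c("gain_control", "linear_sum"),
                               masker = 50, freqs = c("F40", "F35")) {
  model <- match.arg(model)
  condition <- match.arg(condition, .EEG_CONDITIONS)
  freqs <- match.arg(freqs, c("F40", "F35"), several.ok = TRUE)
  if ("F35" %in% freqs && is.na(params$sigma35)) {
    stop("sigma35 is required to read out 35-Hz SNRs")
  }
  resp_at <- function(arr, at) {
    if (model == "gain_control") {
      tagged_response(arr$left, arr$right, at, params)
    } else {
      S <- sum(c(if (arr$left$tag == at) arr$left$depth else 0,
                 if (arr$right$tag == at) arr$right$depth else 0))
      linear_sum_response(S, 0, params)
    }
  }
  sig <- c(F40 = params$sigma40, F35 = params$sigma35)
  rows <- lapply(depths, function(d) {
    arr <- eeg_arrangement(condition, d, masker)
    data.frame(
      condition = condition, depth_pct = d, freq = freqs,
      snr = vapply(freqs, function(f)
        snr_transform(resp_at(arr, f), sig[[f]]), numeric(1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
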