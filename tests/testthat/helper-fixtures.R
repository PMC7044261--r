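# shared fixtures: noiseless datasets generated straight from the model, the
# standard design grids, and a compact random-parameter generator for
# property-style tests

PEDESTALS <- c(0, 1, 2, 4, 8, 16, 32, 64)
EEG_DEPTHS <- c(6.25, 12.5, 25, 50, 100)

noiseless_dipper <- function(params, model = "gain_control",
                             pedestals = PEDESTALS) {
  rows <- do.call(rbind, lapply(psy_conditions(), function(cc) {
    data.frame(condition = cc, pedestal_pct = pedestals,
               threshold_db = dipper_curve(cc, pedestals, params, model),
               n_trials = NA_integer_, stringsAsFactors = FALSE)
  }))
  rows$pooled <- rows$pedestal_pct == 0 &
    rows$condition %in% c("MON", "DICH", "HALF_BIN")
  class(rows) <- c("dipper_dataset", "data.frame")
  rows
}

noiseless_eeg <- function(params, model = "gain_control",
                          depths = EEG_DEPTHS) {
  rows <- do.call(rbind, lapply(eeg_conditions(), function(cc) {
    eeg_response_curve(cc, depths, params, model)
  }))
  rows$n_participants <- NA_integer_
  class(rows) <- c("eeg_dataset", "data.frame")
  rows
}

# random valid parameter bundle respecting q >= 2, p > q
random_params <- function() {
  q <- 2 + stats::runif(1, 0.01, 1.5)
  model_params(p = q + stats::runif(1, 0.05, 1.5), q = q,
               Z = 10^stats::runif(1, 0.3, 1.8),
               omega = stats::runif(1, 0, 1),
               sigma40 = 10^stats::runif(1, -1.5, 0.3),
               sigma35 = 10^stats::runif(1, -1.5, 0.3))
}

# exhaustive log-grid threshold search, the independent oracle for the
# bracketing/bisection solver
grid_search_threshold <- function(condition, pedestal, params, sigma,
                                  points_per_decade = 2000,
                                  lower = 1e-4, upper = 1e4) {
  lg <- seq(log10(lower), log10(upper),
            by = 1 / points_per_decade)
  dm <- 10^lg
  delta <- binsum:::.delta_resp(rep(condition, length(dm)),
                                rep(pedestal, length(dm)), dm, params)
  idx <- which(delta >= sigma)
  if (length(idx) == 0) return(NA_real_)
  dm[idx[1]]
}
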