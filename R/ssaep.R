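#' Amplitude-modulated stimulus waveform
#'
#' The stimulus equation: a sinusoidal carrier at \code{f_c} Hz whose
#' envelope is modulated at \code{f_m} Hz with depth \code{m},
#' \deqn{w(t) = 0.5\,(1 + m \cos(2\pi f_m t + \pi))\,\sin(2\pi f_c t).}
#' The envelope phase of \eqn{\pi} puts the modulation minimum at stimulus
#' onset.
#'
#' @param t time in seconds (vectorised).
#' @param m modulation depth, 0 to 1.
#' @param f_m modulation frequency, Hz.
#' @param f_c carrier frequency, Hz.
#' @return waveform sample values.
#' @export
am_waveform <- function(t, m, f_m = 40, f_c = 1000) {
  if (m < 0 || m > 1) stop("modulation depth m must be in [0, 1]")
  0.5 * (1 + m * cos(f_m * t * 2 * pi + pi)) * sin(f_c * t * 2 * pi)
}

#' Synthesize a set of frequency-tagged EEG trials
#'
#' Forward model for the steady-state EEG experiment: the scalp response is
#' a single virtual sensor carrying one sinusoid per tag frequency, with
#' amplitude \code{gain * resp} where \code{resp} is the combination
#' model's tagged response to the condition's stimulus, plus white
#' Gaussian noise. Signal phases are drawn once and held fixed across
#' repetitions (so coherent averaging preserves the signal); noise is
#' independent per repetition.
#'
#' The tag amplitudes are calibrated so that the analysis chain is
#' unbiased for the model's linking function: the neighbour-bin SNR
#' estimator applied to a sinusoid of amplitude \eqn{A} in noise has
#' expectation \eqn{E|A+n| \cdot E[1/\bar D]} (a Rice mean over a noisy
#' floor estimate), and the generator inverts that expectation so that the
#' expected analysed SNR equals \eqn{gain \cdot resp / floor + 1}, where
#' \eqn{floor = \sigma_N \sqrt{\pi/(N R)}} is the expected coherently
#' averaged noise floor. With the default gain calibration
#' (\code{\link{eeg_gain_for}}) this target is exactly the model's
#' \eqn{(resp+\sigma)/\sigma} curve. A zero response maps to amplitude 0
#' (depth-0 trials are pure noise), and with \code{noise_sd = 0} no
#' calibration applies — the trial set carries exactly \code{gain * resp}.
#'
#' @param condition an EEG condition label; see \code{\link{eeg_arrangement}}.
#' @param depth signal modulation depth, percent.
#' @param params generating \code{\link{model_params}}.
#' @param gain scalar or named vector \code{c(F40 = , F35 = )}: scalp
#'   amplitude per unit model response.
#' @param noise_sd standard deviation of the additive sensor noise.
#' @param n_reps number of repetitions (trials).
#' @param seed optional integer seed.
#' @param fs sample rate, Hz.
#' @param duration trial duration, seconds.
#' @param masker masker depth, percent, where the condition uses one.
#' @return an \code{eeg_trialset}: list with \code{trials} (matrix,
#'   repetitions x samples), \code{fs}, \code{condition}, \code{depth},
#'   \code{freqs}, \code{amplitudes}.
#' @export
synth_trial <- function(condition, depth, params, gain = 1, noise_sd = 1,
                        n_reps = 10, seed = NULL, fs = 1000, duration = 11,
                        masker = 50) {
  condition <- match.arg(condition, .EEG_CONDITIONS)
  if (!is.null(seed)) set.seed(seed)
  gain <- if (length(gain) == 1) c(F40 = unname(gain), F35 = unname(gain))
          else gain[c("F40", "F35")]
  arr <- eeg_arrangement(condition, depth, masker)
  resp <- c(F40 = tagged_response(arr$left, arr$right, "F40", params),
            F35 = tagged_response(arr$left, arr$right, "F35", params))
  n <- round(fs * duration)
  n_analysis <- n - round(fs)  # samples left after the 1-s onset discard
  if (noise_sd > 0) {
    s <- noise_sd * sqrt(2 / (n_analysis * n_reps))  # per-component SD
    floor_amp <- s * sqrt(pi / 2)
    target_snr <- gain * resp / floor_amp + 1
    amp <- vapply(target_snr, .rice_amp_for_snr, numeric(1), s = s)
    names(amp) <- names(resp)
  } else {
    amp <- gain * resp
  }
  t <- seq(0, by = 1 / fs, length.out = n)
  phases <- stats::runif(2, 0, 2 * pi)
  sig <- amp[["F40"]] * sin(2 * pi * 40 * t + phases[1]) +
         amp[["F35"]] * sin(2 * pi * 35 * t + phases[2])
  trials <- matrix(stats::rnorm(n_reps * n, sd = noise_sd),
                   nrow = n_reps, ncol = n)
  trials <- sweep(trials, 2, sig, `+`)
  structure(list(trials = trials, fs = fs, condition = condition,
                 depth = depth, freqs = c(F40 = 40, F35 = 35),
                 amplitudes = amp, phases = phases),
            class = "eeg_trialset")
}

# mean of the Rice distribution: E|A e^{i phi} + n| for complex noise with
# per-component SD s, via the Laguerre-1/2 form with scaled Bessel
# functions; asymptotic expansion where besselI underflows (A >> s)
.rice_mean <- function(A, s) {
  x <- A^2 / (2 * s^2)
  if (x > 5e4) return(A + s^2 / (2 * A))
  s * sqrt(pi / 2) * ((1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
                      x * besselI(x / 2, 1, expon.scaled = TRUE))
}

# amplitude whose analysed neighbour-bin SNR has the given expectation:
# E[SNR] = E|A+n| * E[1/Dbar] with Dbar the mean of 10 neighbour Rayleigh
# amplitudes; E[1/Dbar] ~ (1 + CV^2)/E[Dbar] to second order
.rice_amp_for_snr <- function(target_snr, s, n_neighbours = 10) {
  cv2 <- (4 / pi - 1) / n_neighbours
  floor_amp <- s * sqrt(pi / 2)
  target_mean <- target_snr * floor_amp / (1 + cv2)
  if (target_mean <= floor_amp) return(0)
  stats::uniroot(function(A) .rice_mean(A, s) - target_mean,
                 lower = 0, upper = target_mean + 6 * s,
                 tol = 1e-12 * floor_amp)$root
}

#' Coherent spectral average of repeated trials
#'
#' Discards the onset segment of every repetition (removing stimulus-onset
#' transients), Fourier transforms the remaining window of each repetition,
#' and averages the complex coefficients across repetitions. Because the
#' signal phase is reproducible across repetitions while noise phase is
#' random, the signal survives the complex mean and the noise floor falls
#' as the square root of the number of repetitions.
#'
#' Amplitudes are one-sided (a unit-amplitude sinusoid on an exact bin
#' yields amplitude 1). With a 10-s analysis window at 1 kHz the bin
#' spacing is exactly 0.1 Hz, so the 40- and 35-Hz tags fall on bins with
#' no spectral leakage under the rectangular window.
#'
#' @param x an \code{eeg_trialset}, or a repetitions-by-samples matrix.
#' @param fs sample rate, Hz (taken from the trial set when available).
#' @param discard_s onset duration to discard, seconds.
#' @return a \code{spectrum_estimate}: list with \code{freq} (Hz),
#'   \code{amplitude}, \code{coef} (complex, same scaling), \code{df} (bin
#'   spacing), \code{n_reps}, \code{n_samples}.
#' @export
coherent_average <- function(x, fs = NULL, discard_s = 1) {
  if (inherits(x, "eeg_trialset")) {
    fs <- x$fs
    x <- x$trials
  }
  if (is.null(fs)) stop("fs must be supplied for a bare trial matrix")
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  n_drop <- round(discard_s * fs)
  if (ncol(x) <= n_drop) stop("trials shorter than the discarded onset")
  seg <- x[, (n_drop + 1):ncol(x), drop = FALSE]
  N <- ncol(seg)
  # complex mean across repetitions of the per-repetition coefficients
  coefs <- stats::mvfft(t(seg)) / N          # samples x reps, two-sided 1/N
  avg <- rowMeans(coefs)
  half <- floor(N / 2)
  one_sided <- avg[1:(half + 1)]
  scale <- c(1, rep(2, half - 1), if (N %% 2 == 0) 1 else 2)
  coef <- one_sided * scale
  structure(list(freq = (0:half) * fs / N, amplitude = Mod(coef),
                 coef = coef, df = fs / N, n_reps = ncol(coefs),
                 n_samples = N),
            class = "spectrum_estimate")
}

#' Neighbour-bin signal-to-noise ratio
#'
#' SNR at a frequency of interest: the amplitude in the bin at \code{f}
#' divided by the mean amplitude in the surrounding 10 bins (\eqn{\pm 0.1}
#' to \eqn{\pm 0.5} Hz in 0.1-Hz steps, excluding the centre bin). For
#' noise alone the expected value is 1; a reproducible signal raises it.
#'
#' @param spec a \code{spectrum_estimate}.
#' @param f frequency of interest, Hz; must lie on the bin grid.
#' @param n_neighbours neighbour bins per side.
#' @return the SNR (dimensionless).
#' @export
snr_at_frequency <- function(spec, f, n_neighbours = 5) {
  i <- round(f / spec$df) + 1
  if (abs(spec$freq[i] - f) > 1e-9) {
    stop("frequency ", f, " Hz is not on the ", spec$df, " Hz bin grid")
  }
  nb <- i + c(-(n_neighbours:1), 1:n_neighbours)
  if (any(nb < 1) || any(nb > length(spec$amplitude))) {
    stop("neighbour bins fall outside the spectrum")
  }
  denom <- mean(spec$amplitude[nb])
  if (denom <= 0) {
    stop("neighbour-bin mean amplitude is zero; SNR undefined for a ",
         "noiseless spectrum")
  }
  spec$amplitude[i] / denom
}

#' Per-frequency scalp gain matching a target SNR transform
#'
#' Chooses the forward-model gain at each tag frequency so that the
#' expected analysed SNR of synthetic trials reproduces the model's
#' \code{(resp + sigma)/sigma} curves: the coherently-averaged noise floor
#' has expected amplitude \eqn{\sigma_N \sqrt{\pi/(N R)}} (for noise SD
#' \eqn{\sigma_N}, window length \eqn{N} samples, \eqn{R} repetitions), and
#' the gain is that floor divided by the frequency's noise parameter.
#'
#' @param params a \code{\link{model_params}} with \code{sigma35} set.
#' @param noise_sd sensor noise standard deviation.
#' @param n_reps repetitions per trial set.
#' @param n_samples analysis window length, samples.
#' @return named vector \code{c(F40 = , F35 = )} of gains.
#' @export
eeg_gain_for <- function(params, noise_sd = 1, n_reps = 10,
                         n_samples = 10000) {
  if (is.na(params$sigma35)) stop("sigma35 must be set to calibrate gains")
  floor_amp <- noise_sd * sqrt(pi / (n_samples * n_reps))
  c(F40 = floor_amp / params$sigma40, F35 = floor_amp / params$sigma35)
}

#' Analyse synthesized EEG trials into an SNR dataset
#'
#' Applies the full analysis chain — onset discard, coherent averaging,
#' neighbour-bin SNR at both tag frequencies — per participant, then
#' averages the absolute SNRs across participants.
#'
#' @param trialsets_by_participant a list over participants; each element a
#'   list of \code{eeg_trialset}s (one per condition-by-depth cell).
#' @return an \code{eeg_dataset}: data.frame with columns \code{condition},
#'   \code{depth_pct}, \code{freq}, \code{snr}, \code{n_participants}.
#' @export
analyze_experiment <- function(trialsets_by_participant) {
  per_part <- lapply(seq_along(trialsets_by_participant), function(part) {
    rows <- lapply(trialsets_by_participant[[part]], function(ts) {
      spec <- coherent_average(ts)
      data.frame(participant = part, condition = ts$condition,
                 depth_pct = ts$depth, freq = c("F40", "F35"),
                 snr = c(snr_at_frequency(spec, 40),
                         snr_at_frequency(spec, 35)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  long <- do.call(rbind, per_part)
  out <- stats::aggregate(snr ~ condition + depth_pct + freq, data = long,
                          FUN = mean)
  out$n_participants <- length(trialsets_by_participant)
  out <- out[order(out$condition, out$depth_pct, out$freq), ]
  rownames(out) <- NULL
  class(out) <- c("eeg_dataset", "data.frame")
  attr(out, "n_participants") <- length(trialsets_by_participant)
  out
}

#' Simulate the full steady-state EEG experiment
#'
#' Generates and analyses the complete frequency-tagged design: each
#' synthetic participant contributes \code{n_reps} repetitions of every
#' condition-by-depth cell, analysed by coherent averaging and
#' neighbour-bin SNR, with absolute SNRs averaged across participants.
#' By default the per-frequency gains are calibrated with
#' \code{\link{eeg_gain_for}} so the expected SNR curves equal the model's
#' \code{(resp + sigma)/sigma} transform.
#'
#' @param true_params generating \code{\link{model_params}} (needs
#'   \code{sigma35}).
#' @param gain scalar or named per-frequency gain; \code{NULL} to
#'   calibrate automatically.
#' @param noise_sd sensor noise standard deviation.
#' @param depths signal depth grid, percent.
#' @param conditions EEG condition labels to run.
#' @param n_reps repetitions per cell per participant.
#' @param n_participants number of synthetic participants.
#' @param seed integer seed; per-cell substreams are derived
#'   deterministically.
#' @param fs sample rate, Hz.
#' @param duration trial duration, seconds.
#' @param masker masker depth, percent.
#' @return an \code{eeg_dataset} (see \code{\link{analyze_experiment}})
#'   with attributes \code{seed}, \code{gain}, \code{noise_sd}.
#' @export
simulate_eeg_experiment <- function(true_params, gain = NULL, noise_sd = 1,
                                    depths = c(6.25, 12.5, 25, 50, 100),
                                    conditions = eeg_conditions(),
                                    n_reps = 10, n_participants = 12,
                                    seed = 1, fs = 1000, duration = 11,
                                    masker = 50) {
  n_samples <- round((duration - 1) * fs)
  if (is.null(gain)) {
    gain <- eeg_gain_for(true_params, noise_sd, n_reps, n_samples)
  }
  cells <- expand.grid(condition = conditions, depth = depths,
                       stringsAsFactors = FALSE)
  idx <- 0L
  # synthesize and analyse one participant at a time; raw trials are large
  # and only their SNRs are retained
  per_part <- lapply(seq_len(n_participants), function(part) {
    sets <- lapply(seq_len(nrow(cells)), function(ci) {
      idx <<- idx + 1L
      synth_trial(cells$condition[ci], cells$depth[ci], true_params,
                  gain = gain, noise_sd = noise_sd, n_reps = n_reps,
                  seed = .substream_seed(seed, idx), fs = fs,
                  duration = duration, masker = masker)
    })
    one <- analyze_experiment(list(sets))
    one$participant <- part
    one
  })
  long <- do.call(rbind, lapply(per_part, as.data.frame))
  out <- stats::aggregate(snr ~ condition + depth_pct + freq, data = long,
                          FUN = mean)
  out$n_participants <- n_participants
  out <- out[order(out$condition, out$depth_pct, out$freq), ]
  rownames(out) <- NULL
  class(out) <- c("eeg_dataset", "data.frame")
  attr(out, "n_participants") <- n_participants
  attr(out, "seed") <- seed
  attr(out, "gain") <- gain
  attr(out, "noise_sd") <- noise_sd
  out
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf(
    "Steady-state EEG SNR dataset: %d cells (%d condition(s) x %d depth(s) x 2 tags), %d participant(s)\n",
    nrow(x), length(unique(x$condition)), length(unique(x$depth_pct)),
    attr(x, "n_participants") %||% NA_integer_))
  print.data.frame(x, ...)
  invisible(x)
}
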